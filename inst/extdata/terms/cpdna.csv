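Locus,Type,Name,IntronExonNumber
matK,CDS,matK,
matK,CDS,maturase K,
matK,CDS,maturase,
matK,CDS,MATK,
rbcL,CDS,rbcL,
rbcL,CDS,RBCL,
rbcL,CDS,"ribulose-1,5-bisphosphate carboxylase/oxygenase large subunit",
rbcL,CDS,ribulose 1-5-bisphosphate carboxylase large subunit,
rbcL,CDS,RuBisCO large subunit,
atpA,CDS,atpA,
atpA,CDS,ATP synthase CF1 alpha subunit,
atpB,CDS,atpB,
atpB,CDS,ATP synthase CF1 beta subunit,
atpE,CDS,atpE,
atpE,CDS,ATP synthase CF1 epsilon subunit,
ndhA,CDS,ndhA,
ndhA,CDS,NADH dehydrogenase subunit A,
ndhB,CDS,ndhB,
ndhB,CDS,NADH dehydrogenase subunit B,
ndhF,CDS,ndhF,
ndhF,CDS,NADH dehydrogenase subunit F,
psaA,CDS,psaA,
psaA,CDS,photosystem I P700 apoprotein A1,
psaB,CDS,psaB,
psaB,CDS,photosystem I P700 apoprotein A2,
psbA,CDS,psbA,
psbA,CDS,photosystem II protein D1,
psbB,CDS,psbB,
psbB,CDS,photosystem II 47 kDa protein,
psbC,CDS,psbC,
psbC,CDS,photosystem II 44 kDa protein,
psbD,CDS,psbD,
psbD,CDS,photosystem II protein D2,
rpoA,CDS,rpoA,
rpoA,CDS,RNA polymerase alpha subunit,
rpoB,CDS,rpoB,
rpoB,CDS,RNA polymerase beta subunit,
rpoC1,CDS,rpoC1,
rpoC1,CDS,RNA polymerase beta' subunit,
rpoC2,CDS,rpoC2,
rpoC2,CDS,RNA polymerase beta'' subunit,
accD,CDS,accD,
accD,CDS,acetyl-CoA carboxylase beta subunit,
ccsA,CDS,ccsA,
ccsA,CDS,cytochrome c biogenesis protein,
cemA,CDS,cemA,
cemA,CDS,envelope membrane protein,
clpP,CDS,clpP,
clpP,CDS,ATP-dependent Clp protease proteolytic subunit,
petA,CDS,petA,
petA,CDS,cytochrome f,
petB,CDS,petB,
petB,CDS,cytochrome b6,
rps2,CDS,rps2,
rps2,CDS,ribosomal protein S2,
rps4,CDS,rps4,
rps4,CDS,ribosomal protein S4,
rpl2,CDS,rpl2,
rpl2,CDS,ribosomal protein L2,
ycf1,CDS,ycf1,
ycf1,CDS,hypothetical chloroplast RF1,
ycf2,CDS,ycf2,
ycf2,CDS,hypothetical chloroplast RF2,
rrn16,rRNA,16S ribosomal RNA,
rrn16,rRNA,rrn16,
rrn23,rRNA,23S ribosomal RNA,
rrn23,rRNA,rrn23,
trnH_GUG,tRNA,tRNA-His,
trnH_GUG,tRNA,trnH-GUG,
trnK_UUU,tRNA,tRNA-Lys,
trnK_UUU,tRNA,trnK-UUU,
trnL_UAA,tRNA,tRNA-Leu,
trnL_UAA,tRNA,trnL-UAA,
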