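# geneharvest

Offline extraction of gene subsequences from GenBank flat files, driven by
annotations and gene-name synonym dictionaries.

## The problem

A large share of the usable sequence data for phylogenetics and DNA
barcoding does not sit in single-gene records: it is embedded in
mitochondrial and chloroplast genomes, rDNA cistrons, and concatenated
multi-gene submissions. Pulling one locus out of those records is blocked by
two things. First, the feature-table **location grammar** — a gene may live
at `complement(join(3300..4037, 4100..4500))`, span segments on opposite
strands (trans-spliced genes), or carry partial markers (`<1..206`). Second,
**name instability**: the same gene appears as `COI`, `CO1`, `COX1`, `cox1`,
`COXI`, `COX-I`, or `cytochrome c oxidase subunit I` depending on the
submitter. geneharvest solves both: it parses flat files locally (no network
retrieval — fetch records however you like), matches every annotated feature
against a synonym table, resolves the matched location exactly, and writes
one FASTA file per locus plus a species × locus accession table ready for
supermatrix assembly.

Matching semantics: a term-table row `(Locus, Type, Name)` matches a feature
when the feature key equals `Type` and `Name` equals (case-insensitive,
whitespace-trimmed) one of the feature's `gene` / `product` /
`standard_name` / `note` qualifier values, in that precedence; `D-loop` rows
match by key alone; intron/exon rows additionally dispatch on the `/number`
qualifier. Whole-value matching is the default so `COI` can never match
`COIII`. Resolution of a location `join(s_1, ..., s_k)` concatenates the
segments in listed order, reverse-complementing minus-strand segments;
`complement(join(a, b))` is normalized to `revcomp(seq[b]), revcomp(seq[a])`.
CDS extractions can be translated under NCBI genetic codes 1, 2, 5 and 11,
honoring `/transl_table` and `/codon_start`.

Four synonym dictionaries ship with the package: `mtDNA-animal` (13
protein-coding genes, 22 tRNAs, 2 rRNAs, control region), `mtDNA-plant`,
`cpDNA` (including the matK and rbcL barcodes) and `rDNA` (18S, 5.8S, 28S,
ITS1, ITS2). They are plain CSV (`Locus,Type,Name,IntronExonNumber`) and can
be extended and merged with `merge_terms()`.

## Worked example

Everything below is runnable offline: the synthetic-record generator plants
known loci (both strands, spliced/trans-spliced locations, duplicate copies,
near-miss decoy names) and records the exact expected subsequences in a
manifest.

```r
library(geneharvest)

fx <- generate_fixture(fixture_spec(seed = 7, n_records = 4, n_species = 3))
writeLines(fx$text, "demo.gb", sep = "")

recs <- read_genbank("demo.gb")$records
res  <- extract_records(recs, load_search_terms("mtDNA-animal"),
                        extraction_config(loci = c("COI", "CYTB",
                                                   "rRNA_12S", "D_loop")))
head(res$sequences[, c("locus", "accession", "organism", "matched_synonym")])
#>      locus accession          organism                matched_synonym
#> 1      COI SYNF00001 Genus_1 species_1                         MT-CO1
#> 2     CYTB SYNF00001 Genus_1 species_1                           CYTB
#> 3 rRNA_12S SYNF00001 Genus_1 species_1                         s-rRNA
#> 4   D_loop SYNF00001 Genus_1 species_1
#> 5      COI SYNF00002 Genus_1 species_2 cytochrome c oxidase subunit I
#> 6     CYTB SYNF00002 Genus_1 species_2                          cyt b
```

Each row is one recovered subsequence with its provenance: which synonym
matched (note the three different COI spellings across records) and which
feature supplied it. The report gives every (accession, locus) pair exactly
one status — here all 16 are `found`; loci absent from a feature table come
back `not_found` rather than disappearing:

```r
table(res$report$status)
#> found
#>    16

build_accession_table(res$report, recs)
#>             Species       COI      CYTB  rRNA_12S    D_loop
#> 1 Genus_1 species_1 SYNF00001 SYNF00001 SYNF00001 SYNF00001
#> 2 Genus_1 species_2 SYNF00002 SYNF00002 SYNF00002 SYNF00002
#> 3 Genus_1 species_3 SYNF00003 SYNF00003 SYNF00003 SYNF00003
```

The accession table has one row per species and one column per requested
locus; each cell names the accession that supplied the sequence (species_1
spans two accessions here, so the first found wins and a warning reports the
4 extra sources). FASTA output is one file per locus, headers
`>{organism}_{accession}`, wrapped at 80 columns:

```r
write_fasta(res$sequences, "out")
#> out/COI.fasta:
#> >Genus_1_species_1_SYNF00001
#> atgagcgacacacttagtcaccaggctgagattgccgcacccctggctgggcacgatccg...

find_longest_seq(recs)
#>             species accession length
#> 1 Genus_1 species_1 SYNF00001   9546
#> 2 Genus_1 species_2 SYNF00002   9823
#> 3 Genus_1 species_3 SYNF00003   9564
```

`find_longest_seq()` picks one accession per species (the longest; ties go
to the lexicographically least accession) for one-sequence-per-species
datasets.

### Command line

```sh
inst/cli/geneharvest bust --in demo.gb --terms mtDNA-animal --out out/ \
    --duplicates --translate --transl-table 2
inst/cli/geneharvest terms --list
inst/cli/geneharvest longest --in demo.gb --out longest.csv
inst/cli/geneharvest fixtures --seed 7 --n-records 4 --out fx/
```

`bust` writes per-locus FASTA, `accession_table.csv`, `report.csv` and a
JSON run manifest; exit status is 0 on success, 1 on usage errors, 2 on data
errors.

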