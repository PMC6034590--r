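# In-code record builders and tiny flat-file fixtures.

# A gb_record with arbitrary planted features. `features` is a list of
# list(key=, loc=, quals=data.frame(name,value)).
make_test_record <- function(sequence, features = list(),
                             accession = "TST00001",
                             organism = "Genus_1 species_1") {
  flist <- c(
    list(new_feature("source", parse_location(sprintf("1..%d", nchar(sequence))),
                     data.frame(name = "organism", value = organism))),
    lapply(features, function(f) {
      new_feature(f$key, parse_location(f$loc), f$quals)
    }))
  new_record(accession, sequence, organism = organism, features = flist)
}

quals_df <- function(...) {
  kv <- c(...)
  data.frame(name = names(kv), value = unname(kv))
}

# Minimal hand-written flat file: one record, one CDS. Relabel every
# occurrence of the accession (gsub) to build multi-record streams.
mini_flatfile <- function() {
  paste(c(
    "LOCUS       MINI0001                  40 bp    DNA     linear   UNA 01-JAN-2018",
    "DEFINITION  Genus_1 species_1 mini record.",
    "ACCESSION   MINI0001",
    "VERSION     MINI0001.1",
    "SOURCE      Genus_1 species_1",
    "  ORGANISM  Genus_1 species_1",
    "FEATURES             Location/Qualifiers",
    "     source          1..40",
    "                     /organism=\"Genus_1 species_1\"",
    "     CDS             5..13",
    "                     /gene=\"COI\"",
    "                     /transl_table=2",
    "ORIGIN",
    "        1 aaaaatgaaa cgaaaaaaaa aaaaaaaaaa aaaaaaaaaa",
    "//"), collapse = "\n")
}

# One-row search-term table.
terms1 <- function(locus, type, name, number = NA_integer_) {
  search_terms(data.frame(Locus = locus, Type = type, Name = name,
                          IntronExonNumber = number))
}
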