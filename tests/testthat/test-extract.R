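test_that("match_feature follows the stated matching rules", {
  mt <- load_search_terms("mtDNA-animal")
  cfg <- extraction_config()

  f <- new_feature("CDS", parse_location("1..9"),
                   quals_df(product = "cytochrome c oxidase subunit I"))
  m <- match_feature(f, mt, cfg)
  expect_equal(m$locus, "COI")
  expect_equal(m$matched_qualifier, "product")

  # whole-value matching: COIII never matches a lone COI synonym row
  f <- new_feature("CDS", parse_location("1..9"), quals_df(gene = "COIII"))
  expect_null(match_feature(f, terms1("COI", "CDS", "COI"), cfg))
  # ... but matches its own locus in the bundled table
  expect_equal(match_feature(f, mt, cfg)$locus, "COIII")

  # D-loop row with empty name matches by key alone
  f <- new_feature("D-loop", parse_location("1..9"),
                   data.frame(name = character(0), value = character(0)))
  expect_equal(match_feature(f, mt, cfg)$locus, "D_loop")

  # key/type comparison is case-insensitive
  f <- new_feature("cds", parse_location("1..9"), quals_df(gene = "coi"))
  expect_equal(match_feature(f, mt, cfg)$locus, "COI")

  # wrong feature type does not match even with the right name
  f <- new_feature("tRNA", parse_location("1..9"), quals_df(gene = "COI"))
  expect_null(match_feature(f, mt, cfg))

  # first matching row wins when two loci share a synonym
  tab <- search_terms(data.frame(Locus = c("A", "B"), Type = "CDS",
                                 Name = c("shared", "shared")))
  f <- new_feature("CDS", parse_location("1..9"), quals_df(gene = "shared"))
  expect_equal(match_feature(f, tab, cfg)$locus, "A")

  # qualifier precedence within a row: gene beats product and note
  tab <- search_terms(data.frame(Locus = "A", Type = "CDS", Name = "xname"))
  f <- new_feature("CDS", parse_location("1..9"),
                   quals_df(note = "xname", product = "xname", gene = "xname"))
  expect_equal(match_feature(f, tab, cfg)$matched_qualifier, "gene")
  # ... but table row order trumps qualifier precedence across rows
  tab <- search_terms(data.frame(Locus = c("A", "B"), Type = "CDS",
                                 Name = c("bname", "aname")))
  f <- new_feature("CDS", parse_location("1..9"),
                   quals_df(product = "bname", gene = "aname"))
  expect_equal(match_feature(f, tab, cfg)$locus, "A")

  # word-boundary mode finds synonyms inside longer product strings
  wb <- extraction_config(match_mode = "word_boundary")
  f <- new_feature("CDS", parse_location("1..9"),
                   quals_df(product = "putative COI protein"))
  expect_equal(match_feature(f, terms1("COI", "CDS", "COI"), wb)$locus, "COI")
  f <- new_feature("CDS", parse_location("1..9"),
                   quals_df(product = "putative COIII protein"))
  expect_null(match_feature(f, terms1("COI", "CDS", "COI"), wb))
})

test_that("extract_record recovers planted loci and reports absences", {
  seq100 <- paste(sample(c("a", "c", "g", "t"), 100, replace = TRUE),
                  collapse = "")
  g <- "atgaaacgactataa"
  seq <- paste0(substr(seq100, 1, 20), reverse_complement(g),
                substr(seq100, 36, 100))
  rec <- make_test_record(seq, features = list(
    list(key = "CDS", loc = "complement(21..35)",
         quals = quals_df(gene = "COI", transl_table = "2"))))
  tab <- load_search_terms("mtDNA-animal")

  res <- extract_record(rec, tab, extraction_config(loci = c("COI", "D_loop")))
  expect_equal(nrow(res$sequences), 1L)
  expect_identical(res$sequences$sequence, g)
  expect_equal(res$sequences$matched_synonym, "COI")
  # D-loop absent from the feature table: reported, no output
  expect_equal(res$report$status[res$report$locus == "D_loop"], "not_found")
  expect_equal(nrow(res$report), 2L)

  # translation honors the feature's own transl_table qualifier
  res <- extract_record(rec, tab,
                        extraction_config(loci = "COI", translate = TRUE,
                                          transl_table = 1))
  expect_identical(res$sequences$sequence,
                   as.character(translate_cds(g, 2)))
  expect_true(res$sequences$was_translated)
})

test_that("duplicate handling and copy indices follow record order", {
  rec <- make_test_record(paste(rep("acgtaacc", 30), collapse = ""),
    features = list(
      list(key = "tRNA", loc = "11..30", quals = quals_df(product = "tRNA-Met")),
      list(key = "tRNA", loc = "51..70", quals = quals_df(product = "tRNA-Met"))))
  tab <- load_search_terms("mtDNA-animal")

  one <- extract_record(rec, tab, extraction_config(loci = "tRNA_Met"))
  expect_equal(nrow(one$sequences), 1L)
  expect_equal(one$sequences$copy_index, 1L)

  both <- extract_record(rec, tab,
                         extraction_config(loci = "tRNA_Met", duplicates = TRUE))
  expect_equal(both$sequences$copy_index, c(1L, 2L))
  expect_identical(both$sequences$sequence[1],
                   substr(rec$sequence, 11, 30))
  expect_equal(both$report$status, "found")
})

test_that("location failures are isolated per locus", {
  rec <- make_test_record(paste(rep("acgt", 30), collapse = ""),
    features = list(
      list(key = "CDS", loc = "11..19", quals = quals_df(gene = "COI")),
      list(key = "CDS", loc = "30..44", quals = quals_df(gene = "CYTB"))))
  # make CYTB out of bounds, keep the record as-is otherwise
  rec$features[[3]]$location <- new_location(
    data.frame(start = 300, end = 340, strand = "+",
               partial_start = FALSE, partial_end = FALSE))
  tab <- load_search_terms("mtDNA-animal")
  res <- extract_record(rec, tab, extraction_config(loci = c("COI", "CYTB")))
  expect_equal(res$report$status[res$report$locus == "COI"], "found")
  expect_equal(res$report$status[res$report$locus == "CYTB"], "out_of_bounds")

  # unparseable location (kept as NULL by the parser)
  rec$features[[3]]$location <- NULL
  rec$features[[3]]$raw_location <- "30..44^50"
  res <- extract_record(rec, tab, extraction_config(loci = c("COI", "CYTB")))
  expect_equal(res$report$status[res$report$locus == "CYTB"],
               "unparseable_location")
  expect_equal(nrow(res$sequences), 1L)
})

test_that("gene-key features are a fallback, never a duplicate source", {
  tab <- load_search_terms("mtDNA-animal")
  seq <- paste(rep("acgt", 30), collapse = "")
  # CDS plus enclosing gene: one extraction only
  rec <- make_test_record(seq, features = list(
    list(key = "gene", loc = "9..22", quals = quals_df(gene = "COI")),
    list(key = "CDS", loc = "11..19", quals = quals_df(gene = "COI"))))
  res <- extract_record(rec, tab, extraction_config(loci = "COI",
                                                    duplicates = TRUE))
  expect_equal(nrow(res$sequences), 1L)
  expect_equal(res$sequences$feature_key, "CDS")

  # gene-only annotation: fallback extracts from the gene feature
  rec <- make_test_record(seq, features = list(
    list(key = "gene", loc = "9..22", quals = quals_df(gene = "COI"))))
  res <- extract_record(rec, tab, extraction_config(loci = "COI"))
  expect_equal(res$report$status, "found")
  expect_equal(res$sequences$feature_key, "gene")
})

test_that("intron/exon rows dispatch on the number qualifier", {
  tab <- search_terms(data.frame(Locus = "rps12_ex2", Type = "exon",
                                 Name = "rps12", IntronExonNumber = 2L))
  seq <- paste(rep("gattaca", 20), collapse = "")
  rec <- make_test_record(seq, features = list(
    list(key = "exon", loc = "11..25", quals = quals_df(gene = "rps12", number = "1")),
    list(key = "exon", loc = "41..55", quals = quals_df(gene = "rps12", number = "2"))))
  res <- extract_record(rec, tab)
  expect_equal(res$report$status, "found")
  expect_identical(res$sequences$sequence, substr(seq, 41, 55))

  # requesting exon 3: nothing annotated -> not_found
  tab3 <- search_terms(data.frame(Locus = "rps12_ex3", Type = "exon",
                                  Name = "rps12", IntronExonNumber = 3L))
  expect_equal(extract_record(rec, tab3)$report$status, "not_found")

  # gene present but no intron features at all -> not_found
  tabi <- search_terms(data.frame(Locus = "rps12_int1", Type = "intron",
                                  Name = "rps12", IntronExonNumber = 1L))
  expect_equal(extract_record(rec, tabi)$report$status, "not_found")
})

test_that("report completeness holds across records and loci filters", {
  set.seed(33)
  fx <- generate_fixture(fixture_spec(seed = 5, n_records = 6,
                                      terms = load_search_terms("rDNA"),
                                      sequence_length_range = c(500L, 20000L)),
                         check = FALSE)
  recs <- parse_flatfile(fx$text)$records
  tab <- load_search_terms("rDNA")
  for (loci in list(NULL, c("18S", "ITS2"), "28S")) {
    cfg <- extraction_config(loci = loci)
    res <- extract_records(recs, tab, cfg)
    n_loci <- if (is.null(loci)) length(unique(tab$Locus)) else length(loci)
    expect_equal(nrow(res$report), length(recs) * n_loci)
    expect_true(all(res$report$status %in%
                      c("found", "not_found", "unparseable_location",
                        "out_of_bounds")))
    expect_equal(anyDuplicated(paste(res$report$accession, res$report$locus)), 0L)
  }
})

test_that("untranslated output equals plain location resolution", {
  fx <- generate_fixture(fixture_spec(seed = 9, n_records = 2), check = FALSE)
  recs <- parse_flatfile(fx$text)$records
  res <- extract_records(recs, fx$spec$terms,
                         extraction_config(duplicates = TRUE))
  by_acc <- stats::setNames(recs, vapply(recs, `[[`, "", "accession"))
  m <- fx$manifest
  key <- function(d) paste(d$accession, d$locus, d$copy_index)
  idx <- match(key(res$sequences), key(m))
  expect_false(anyNA(idx))
  for (i in seq_len(nrow(res$sequences))) {
    expect_identical(
      res$sequences$sequence[i],
      resolve_location(by_acc[[res$sequences$accession[i]]],
                       parse_location(m$location[idx[i]])))
  }
})
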