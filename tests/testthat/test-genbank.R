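test_that("location grammar parses the stated forms", {
  l <- parse_location("467")
  expect_equal(l$segments$start, 467L)
  expect_equal(l$segments$end, 467L)
  expect_equal(l$segments$strand, "+")

  l <- parse_location("complement(3300..4037)")
  expect_equal(nrow(l$segments), 1L)
  expect_equal(l$segments$strand, "-")
  expect_equal(location_width(l), 738L)

  # trans-spliced form: listed order preserved, both minus
  l <- parse_location("join(complement(1210..1310),complement(100..200))")
  expect_equal(l$segments$start, c(1210L, 100L))
  expect_equal(l$segments$strand, c("-", "-"))

  l <- parse_location("<1..206")
  expect_true(l$segments$partial_start)
  expect_false(l$segments$partial_end)
  expect_equal(c(l$segments$start, l$segments$end), c(1L, 206L))

  # complement(join(...)) stores assembly order: last listed segment first
  l <- parse_location("complement(join(100..200,300..400))")
  expect_equal(l$segments$start, c(300L, 100L))
  expect_equal(l$segments$strand, c("-", "-"))
})

test_that("unsupported and malformed location forms error explicitly", {
  expect_error(parse_location("102^103"), "unsupported form")
  expect_error(parse_location("J00194.1:100..202"), "unsupported form")
  expect_error(parse_location("banana"), "unrecognized")
  expect_error(parse_location("join(10..20"), "unbalanced")
  expect_error(parse_location("50..10"), "inverted")
})

test_that("resolve_location matches hand-resolved examples", {
  rec <- list(sequence = "aatgcca")
  expect_identical(resolve_location(rec, parse_location("2..5")), "atgc")
  expect_identical(resolve_location(rec, parse_location("complement(2..5)")), "gcat")
  expect_identical(resolve_location(rec, parse_location("join(1..2,6..7)")), "aaca")
  expect_error(resolve_location(rec, parse_location("2..9")), "out of bounds")
})

test_that("reverse_complement is correct and an involution", {
  expect_identical(reverse_complement("acgt"), "acgt")
  expect_identical(reverse_complement("aaa"), "ttt")
  expect_identical(reverse_complement(""), "")
  expect_error(reverse_complement("acgxz"), "non-IUPAC character 'x' at offset 4")
  set.seed(11)
  for (i in 1:25) {
    x <- paste(sample(c("a", "c", "g", "t", "n", "r", "y", "w", "s"),
                      sample(1:60, 1), replace = TRUE), collapse = "")
    expect_identical(reverse_complement(reverse_complement(x)), x)
  }
})

test_that("reverse_complement agrees with Biostrings on random sequences", {
  skip_if_not_installed("Biostrings")
  set.seed(12)
  for (i in 1:20) {
    x <- paste(sample(c("a", "c", "g", "t", "n"), sample(5:80, 1),
                      replace = TRUE), collapse = "")
    expect_identical(
      reverse_complement(x),
      tolower(as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))))
  }
})

test_that("location resolver agrees with the per-base oracle", {
  set.seed(101)
  for (i in 1:150) {
    seqlen <- sample(40:120, 1)
    seq <- paste(sample(c("a", "c", "g", "t"), seqlen, replace = TRUE),
                 collapse = "")
    loc_text <- random_location_string(seqlen)
    loc <- parse_location(loc_text)
    got <- resolve_location(list(sequence = seq), loc)
    expect_identical(got, oracle_resolve(loc_text, seq), info = loc_text)
    expect_equal(nchar(got), location_width(loc), info = loc_text)
  }
})

test_that("strand involution: complement(L) resolves to revcomp of L", {
  set.seed(7)
  seq <- paste(sample(c("a", "c", "g", "t"), 100, replace = TRUE), collapse = "")
  rec <- list(sequence = seq)
  for (i in 1:20) {
    ab <- sort(sample(100, 2))
    plain <- sprintf("%d..%d", ab[1], ab[2])
    expect_identical(
      resolve_location(rec, parse_location(sprintf("complement(%s)", plain))),
      reverse_complement(resolve_location(rec, parse_location(plain))))
  }
})

test_that("minimal and multi-record flat files parse", {
  out <- parse_flatfile(mini_flatfile())
  expect_length(out$records, 1L)
  expect_equal(nrow(out$issues), 0L)
  r <- out$records[[1]]
  expect_equal(r$accession, "MINI0001")
  expect_equal(r$organism, "Genus_1 species_1")
  expect_equal(nchar(r$sequence), 40L)
  expect_equal(r$declared_length, 40L)
  keys <- vapply(r$features, `[[`, "", "key")
  expect_equal(keys, c("source", "CDS"))
  cds <- r$features[[2]]
  expect_equal(cds$qualifiers$value[cds$qualifiers$name == "gene"], "COI")
  expect_identical(resolve_location(r, cds$location), "atgaaacga")

  two <- parse_flatfile(paste(mini_flatfile(),
                              gsub("MINI0001", "MINI0002", mini_flatfile()),
                              sep = "\n"))
  expect_length(two$records, 2L)
  expect_equal(vapply(two$records, `[[`, "", "accession"),
               c("MINI0001", "MINI0002"))
})

test_that("parser reports issues instead of dropping content", {
  expect_length(parse_flatfile("")$records, 0L)
  expect_equal(nrow(parse_flatfile("")$issues), 0L)

  # out-of-bounds feature: record kept, one error issue
  txt <- sub("CDS             5..13", "CDS             900..950", mini_flatfile())
  out <- parse_flatfile(txt)
  expect_length(out$records, 1L)
  expect_equal(sum(out$issues$severity == "error"), 1L)
  expect_match(out$issues$message[out$issues$severity == "error"], "exceeds")

  # missing // terminator: best-effort record + error issue
  trimmed <- sub("\n//$", "", mini_flatfile())
  out <- parse_flatfile(trimmed)
  expect_length(out$records, 1L)
  expect_equal(out$records[[1]]$accession, "MINI0001")
  expect_true(any(grepl("terminator", out$issues$message)))

  # unparseable location: feature kept with NULL location
  txt <- sub("CDS             5..13", "CDS             5..13^20", mini_flatfile())
  out <- parse_flatfile(txt)
  expect_length(out$records, 1L)
  expect_true(any(grepl("unparseable location", out$issues$message)))
  expect_null(out$records[[1]]$features[[2]]$location)

  # order(...) treated as join with a warning issue
  txt <- sub("CDS             5..13", "CDS             order(5..7,10..13)",
             mini_flatfile())
  out <- parse_flatfile(txt)
  expect_true(any(out$issues$severity == "warning" &
                    grepl("order", out$issues$message)))
  expect_true(out$records[[1]]$features[[2]]$location$is_order)
})

test_that("write_flatfile round-trips records field-for-field", {
  rec <- make_test_record(
    paste(rep("acgt", 40), collapse = ""),  # 160 bp
    features = list(
      list(key = "CDS", loc = "complement(11..40)",
           quals = quals_df(gene = "COI", transl_table = "2")),
      list(key = "tRNA", loc = "join(50..70,90..100)",
           quals = quals_df(product = "tRNA-Phe")),
      list(key = "D-loop", loc = "<120..>150", quals = quals_df(note = "control"))))
  txt <- write_flatfile(rec)
  back <- parse_flatfile(txt)
  expect_equal(nrow(back$issues), 0L)
  r2 <- back$records[[1]]
  expect_equal(r2$accession, rec$accession)
  expect_equal(r2$version, rec$version)
  expect_equal(r2$organism, rec$organism)
  expect_identical(r2$sequence, rec$sequence)
  expect_equal(length(r2$features), length(rec$features))
  for (i in seq_along(rec$features)) {
    expect_equal(r2$features[[i]]$key, rec$features[[i]]$key)
    expect_equal(r2$features[[i]]$location$segments,
                 rec$features[[i]]$location$segments)
    expect_equal(r2$features[[i]]$qualifiers, rec$features[[i]]$qualifiers)
  }
  # write(parse(write(r))) is idempotent
  expect_identical(write_flatfile(back$records), txt)
})

test_that("ORIGIN block arithmetic and writer guard rails", {
  rec <- new_record("LEN00130", paste(rep("a", 130), collapse = ""))
  txt <- write_flatfile(rec)
  origin_lines <- grep("^\\s+\\d+ ", strsplit(txt, "\n")[[1]], value = TRUE)
  expect_length(origin_lines, 3L)
  expect_equal(as.integer(sub("^\\s*(\\d+) .*$", "\\1", origin_lines)),
               c(1L, 61L, 121L))

  expect_identical(write_flatfile(list()), "")

  bad <- new_record("BAD00001", "acgtacgt")
  bad$declared_length <- 99L
  expect_error(write_flatfile(bad), "refusing to write")
  bad2 <- make_test_record("acgtacgt")
  bad2$features[[1]]$location <- parse_location("1..50")
  expect_error(write_flatfile(bad2), "out of bounds")
})
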