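# Deterministic synthetic GenBank fixtures with a ground-truth manifest.
#
# The generator emulates organelle/concatenated records: every locus of a
# term table is planted as an annotated feature (CDS/tRNA/rRNA/misc_RNA/
# D-loop/intron/exon), on either strand, optionally spliced across two
# segments (including trans-spliced joins mixing strands), with partial
# markers, duplicate copies and near-miss decoy names. The manifest records
# the exact subsequence each planted feature must yield, so extraction can
# be checked byte-for-byte with no downloads. All randomness flows from one
# seed; identical specs produce byte-identical flat files.

#' Specification for a synthetic fixture
#'
#' Defaults are the stated test world: half the features on the minus
#' strand, a fifth spliced, 5% trans-spliced, 10% partial, 10% duplicated,
#' and decoy features at a fifth of the locus count. Planted CDS begin
#' `atg` and end with a stop valid under `transl_table`, with no internal
#' stops, so translation checks are meaningful.
#'
#' @param seed Integer seed; the only source of randomness.
#' @param n_records Number of records to emit.
#' @param terms `search_terms` table whose loci are planted (default the
#'   bundled animal-mtDNA dictionary).
#' @param sequence_length_range Record length bounds (bases); records are
#'   padded to the minimum and must fit the maximum.
#' @param minus_strand_fraction,join_fraction,trans_splice_fraction
#'   Per-feature probabilities of minus-strand placement, a two-segment
#'   `join`, and a mixed-strand (trans-spliced) join.
#' @param partial_fraction Probability of a `<` or `>` partial marker.
#' @param duplicate_fraction Per-locus probability of planting a second copy.
#' @param decoy_fraction Expected decoy features per locus: near-miss names
#'   (superstrings of real synonyms) that exact matching must not extract.
#' @param synonym_choice `"random"` picks the annotating synonym uniformly
#'   per feature; `"first"` always uses the first synonym of the locus.
#' @param transl_table Genetic code planted on CDS features (2, vertebrate
#'   mitochondrial, fits the default dictionary).
#' @param cds_length_range,feature_length_range Planted feature lengths in
#'   bases (CDS lengths are rounded to codons); deliberately compact so
#'   large fixtures stay fast while exercising the full location grammar.
#' @param n_species Number of distinct organisms; default half the record
#'   count so species span multiple accessions.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed, n_records,
                         terms = load_search_terms("mtDNA-animal"),
                         sequence_length_range = c(2000L, 60000L),
                         minus_strand_fraction = 0.5,
                         join_fraction = 0.2,
                         trans_splice_fraction = 0.05,
                         partial_fraction = 0.1,
                         duplicate_fraction = 0.1,
                         decoy_fraction = 0.2,
                         synonym_choice = c("random", "first"),
                         transl_table = 2L,
                         cds_length_range = c(120L, 300L),
                         feature_length_range = c(60L, 180L),
                         n_species = NULL) {
  synonym_choice <- match.arg(synonym_choice)
  if (!inherits(terms, "search_terms")) terms <- search_terms(terms)
  props <- c(minus_strand_fraction, join_fraction, trans_splice_fraction,
             partial_fraction, duplicate_fraction, decoy_fraction)
  stopifnot(all(props >= 0 & props <= 1), n_records >= 1L,
            length(sequence_length_range) == 2L,
            sequence_length_range[1] <= sequence_length_range[2])
  structure(list(seed = as.integer(seed), n_records = as.integer(n_records),
                 terms = terms,
                 sequence_length_range = as.integer(sequence_length_range),
                 minus_strand_fraction = minus_strand_fraction,
                 join_fraction = join_fraction,
                 trans_splice_fraction = trans_splice_fraction,
                 partial_fraction = partial_fraction,
                 duplicate_fraction = duplicate_fraction,
                 decoy_fraction = decoy_fraction,
                 synonym_choice = synonym_choice,
                 transl_table = as.integer(transl_table),
                 cds_length_range = as.integer(cds_length_range),
                 feature_length_range = as.integer(feature_length_range),
                 n_species = n_species),
            class = "fixture_spec")
}

# stop codons across the shipped codes; internal CDS codons avoid all of them
.STOPPISH <- c("taa", "tag", "tga", "aga", "agg")
.SAFE_CODONS <- {
  b <- c("t", "c", "a", "g")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, .STOPPISH)
}

#' Generate a synthetic flat file plus ground-truth manifest
#'
#' @param spec A [fixture_spec()].
#' @param check Re-parse the emitted text and re-resolve every manifest
#'   location as a self-consistency check (default `TRUE`).
#' @return A `gb_fixture`: list with `text` (flat-file string), `records`,
#'   `manifest` (one row per planted feature: accession, organism, locus,
#'   location string, strand, synonym, qualifier used, feature key,
#'   copy index, planted subsequence, expected peptide for CDS,
#'   transl_table) and `decoys` (accession, key, name).
#' @export
generate_fixture <- function(spec, check = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  terms <- spec$terms
  loci <- unique(terms$Locus)
  all_names_norm <- .norm_value(terms$Name[nzchar(terms$Name)])
  n_species <- spec$n_species %||% max(1L, ceiling(spec$n_records / 2))
  species_pool <- sprintf("Genus_%d species_%d",
                          ((seq_len(n_species) - 1L) %/% 3L) + 1L,
                          seq_len(n_species))

  records <- vector("list", spec$n_records)
  manifest <- list()
  decoys <- list()

  for (ri in seq_len(spec$n_records)) {
    accession <- sprintf("SYNF%05d", ri)
    organism <- species_pool[((ri - 1L) %% n_species) + 1L]
    parts <- character(0)
    pos <- 1L
    append_dna <- function(s) {
      parts[[length(parts) + 1L]] <<- s
      start <- pos
      pos <<- pos + nchar(s)
      c(start, pos - 1L)
    }
    spacer <- function() invisible(append_dna(.random_dna(sample(20:60, 1L))))

    feats <- list()
    plant <- function(locus, copy_index) {
      rows <- which(terms$Locus == locus)
      row <- if (spec$synonym_choice == "first") rows[1] else
        rows[[sample.int(length(rows), 1L)]]
      type <- terms$Type[row]
      name <- terms$Name[row]
      is_cds <- tolower(type) == "cds"
      g <- if (is_cds) {
        ncod <- sample(seq(spec$cds_length_range[1] %/% 3L,
                           spec$cds_length_range[2] %/% 3L), 1L)
        paste0("atg",
               paste(sample(.SAFE_CODONS, max(ncod - 2L, 1L), replace = TRUE),
                     collapse = ""),
               "taa")
      } else {
        .random_dna(sample(seq(spec$feature_length_range[1],
                               spec$feature_length_range[2]), 1L))
      }
      trans <- stats::runif(1) < spec$trans_splice_fraction
      joined <- trans || stats::runif(1) < spec$join_fraction
      minus <- stats::runif(1) < spec$minus_strand_fraction
      nseg <- if (joined) 2L else 1L

      glen <- nchar(g)
      if (nseg == 2L) {
        cut <- sample(seq(3L, glen - 3L), 1L)
        pieces <- c(substr(g, 1L, cut), substr(g, cut + 1L, glen))
      } else {
        pieces <- g
      }
      strands <- if (trans) {
        if (stats::runif(1) < 0.5) c("+", "-") else c("-", "+")
      } else {
        rep(if (minus) "-" else "+", nseg)
      }
      # surface form for an all-minus join: half the time the trans-spliced
      # INSDC complement(join(...)) spelling seen in trans-spliced annotations
      comp_join <- nseg == 2L && all(strands == "-") && stats::runif(1) < 0.5
      partial <- stats::runif(1) < spec$partial_fraction && !comp_join

      ivals <- matrix(0L, nrow = nseg, ncol = 2L)
      if (comp_join) {
        # assembly seg 1 occupies the later genome interval
        spacer(); ivals[2L, ] <- append_dna(reverse_complement(pieces[2L]))
        spacer(); ivals[1L, ] <- append_dna(reverse_complement(pieces[1L]))
        loc_raw <- sprintf("complement(join(%d..%d,%d..%d))",
                           ivals[2L, 1L], ivals[2L, 2L],
                           ivals[1L, 1L], ivals[1L, 2L])
      } else {
        atoms <- character(nseg)
        for (k in seq_len(nseg)) {
          spacer()
          emit <- if (strands[k] == "-") reverse_complement(pieces[k]) else pieces[k]
          ivals[k, ] <- append_dna(emit)
          a <- sprintf("%s%d..%s%d",
                       if (partial && k == 1L && stats::runif(1) < 0.5) "<" else "",
                       ivals[k, 1L],
                       if (partial && k == nseg) ">" else "",
                       ivals[k, 2L])
          atoms[k] <- if (strands[k] == "-") sprintf("complement(%s)", a) else a
        }
        loc_raw <- if (nseg == 1L) atoms else
          sprintf("join(%s)", paste(atoms, collapse = ","))
      }

      quals <- list()
      qname <- ""
      if (tolower(type) %in% c("intron", "exon")) {
        quals[[length(quals) + 1L]] <-
          list(name = "number", value = as.character(terms$IntronExonNumber[row]))
        qname <- "number"
        if (nzchar(name)) {
          quals[[length(quals) + 1L]] <- list(name = "gene", value = name)
          qname <- "gene"
        }
      } else if (nzchar(name)) {
        qname <- if (is_cds) sample(c("gene", "product"), 1L) else
          sample(c("product", "gene"), 1L, prob = c(0.8, 0.2))
        quals[[length(quals) + 1L]] <- list(name = qname, value = name)
      }
      if (is_cds) {
        quals[[length(quals) + 1L]] <-
          list(name = "transl_table", value = as.character(spec$transl_table))
        quals[[length(quals) + 1L]] <- list(name = "codon_start", value = "1")
      }
      qdf <- if (length(quals)) {
        data.frame(name = vapply(quals, `[[`, "", "name"),
                   value = vapply(quals, `[[`, "", "value"))
      } else NULL
      feats[[length(feats) + 1L]] <<-
        list(key = type, loc_raw = loc_raw, quals = qdf,
             sort_pos = min(ivals[, 1L]))
      manifest[[length(manifest) + 1L]] <<- data.frame(
        accession = accession, organism = organism, locus = locus,
        location = loc_raw,
        strand = if (length(unique(strands)) > 1L) "mixed" else strands[1L],
        synonym = name, qualifier = qname, feature_key = type,
        copy_index = copy_index, seq = g,
        peptide = if (is_cds)
          as.character(translate_cds(g, spec$transl_table)) else "",
        transl_table = if (is_cds) spec$transl_table else NA_integer_)
    }

    for (locus in loci) {
      plant(locus, 1L)
      if (stats::runif(1) < spec$duplicate_fraction) plant(locus, 2L)
    }

    n_decoys <- sum(stats::runif(length(loci)) < spec$decoy_fraction)
    for (d in seq_len(n_decoys)) {
      row <- sample(which(nzchar(terms$Name)), 1L)
      base_name <- terms$Name[row]
      decoy_name <- paste0(base_name,
                           sample(c(" pseudogene", "-like", " fragment"), 1L))
      while (.norm_value(decoy_name) %in% all_names_norm) {
        decoy_name <- paste0(decoy_name, "-x")
      }
      spacer()
      iv <- append_dna(.random_dna(sample(60:150, 1L)))
      feats[[length(feats) + 1L]] <- list(
        key = terms$Type[row],
        loc_raw = sprintf("%d..%d", iv[1L], iv[2L]),
        quals = data.frame(name = sample(c("gene", "product"), 1L),
                           value = decoy_name),
        sort_pos = iv[1L])
      decoys[[length(decoys) + 1L]] <-
        data.frame(accession = accession, key = terms$Type[row],
                   name = decoy_name)
    }
    spacer()

    seq_full <- paste(parts, collapse = "")
    if (nchar(seq_full) < spec$sequence_length_range[1]) {
      seq_full <- paste0(seq_full,
                         .random_dna(spec$sequence_length_range[1] - nchar(seq_full)))
    }
    if (nchar(seq_full) > spec$sequence_length_range[2]) {
      stop(sprintf(
        "infeasible fixture spec: planted features need %d bp, maximum is %d",
        nchar(seq_full), spec$sequence_length_range[2]), call. = FALSE)
    }

    feats <- feats[order(vapply(feats, `[[`, 0L, "sort_pos"))]
    flist <- c(
      list(new_feature("source", parse_location(sprintf("1..%d", nchar(seq_full))),
                       data.frame(name = "organism", value = organism))),
      lapply(feats, function(f) {
        new_feature(f$key, parse_location(f$loc_raw), f$quals,
                    raw_location = f$loc_raw)
      }))
    records[[ri]] <- new_record(
      accession, seq_full, organism = organism,
      definition = sprintf("%s synthetic test record %s.", organism, accession),
      features = flist)
  }

  manifest <- .bind_rows(manifest, data.frame())
  decoys <- .bind_rows(decoys,
                       data.frame(accession = character(0), key = character(0),
                                  name = character(0)))
  rownames(manifest) <- NULL
  text <- write_flatfile(records)

  if (check) {
    reparsed <- parse_flatfile(text)
    err <- reparsed$issues[reparsed$issues$severity == "error", , drop = FALSE]
    if (nrow(err)) {
      stop("internal: generated fixture has parse errors: ", err$message[1])
    }
    by_acc <- stats::setNames(reparsed$records,
                              vapply(reparsed$records, `[[`, "", "accession"))
    for (i in seq_len(nrow(manifest))) {
      got <- resolve_location(by_acc[[manifest$accession[i]]],
                              parse_location(manifest$location[i]))
      if (!identical(got, manifest$seq[i])) {
        stop(sprintf("internal: manifest mismatch at %s/%s",
                     manifest$accession[i], manifest$locus[i]))
      }
    }
  }
  structure(list(text = text, records = records, manifest = manifest,
                 decoys = decoys, spec = spec),
            class = "gb_fixture")
}

#' @export
print.gb_fixture <- function(x, ...) {
  cat(sprintf("<gb_fixture> %d records, %d planted features, %d decoys\n",
              length(x$records), nrow(x$manifest), nrow(x$decoys)))
  invisible(x)
}

#' Degrade a fixture to emulate real annotation failure modes
#'
#' Three modes mirror limitations seen in public records: concatenated
#' sequences annotated only as "contains genes X, Y, Z" with no per-gene
#' positions (`strip_positions`), a named feature missing from the table
#' (`drop_feature`), and the control region absent entirely (`drop_dloop`).
#' The output remains a parseable flat file.
#'
#' @param flatfile Flat-file text (e.g. `generate_fixture(...)$text`).
#' @param mode One of `"strip_positions"`, `"drop_feature"`, `"drop_dloop"`.
#' @param target For `drop_feature`: a feature key or synonym; features
#'   whose key or qualifier values equal it (case-insensitive) are removed.
#' @return Degraded flat-file text.
#' @export
degrade_fixture <- function(flatfile,
                            mode = c("strip_positions", "drop_feature", "drop_dloop"),
                            target = NULL) {
  mode <- match.arg(mode)
  parsed <- parse_flatfile(flatfile)
  recs <- lapply(parsed$records, function(rec) {
    is_source <- vapply(rec$features, function(f) tolower(f$key) == "source",
                        logical(1))
    if (mode == "strip_positions") {
      gene_names <- unlist(lapply(rec$features[!is_source], function(f) {
        f$qualifiers$value[f$qualifiers$name %in% c("gene", "product")]
      }))
      note <- if (length(gene_names)) {
        sprintf("contains genes: %s", paste(unique(gene_names), collapse = "; "))
      } else "contains unannotated genes"
      rec$features <- c(
        rec$features[is_source],
        list(new_feature("misc_feature",
                         parse_location(sprintf("1..%d", nchar(rec$sequence))),
                         data.frame(name = "note", value = note))))
    } else if (mode == "drop_dloop") {
      drop <- vapply(rec$features, function(f) {
        tolower(f$key) == "d-loop" ||
          (tolower(f$key) == "misc_feature" &&
             any(grepl("control region", f$qualifiers$value, ignore.case = TRUE)))
      }, logical(1))
      rec$features <- rec$features[!drop]
    } else {
      if (is.null(target)) stop("drop_feature needs a target", call. = FALSE)
      tgt <- .norm_value(target)
      drop <- vapply(rec$features, function(f) {
        !tolower(f$key) %in% "source" &&
          (tolower(f$key) == tgt || any(.norm_value(f$qualifiers$value) == tgt))
      }, logical(1))
      rec$features <- rec$features[!drop]
    }
    rec
  })
  write_flatfile(recs)
}
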