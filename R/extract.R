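# Feature-vs-synonym matching and subsequence extraction: the core of the
# toolkit. A feature matches a term row when its key equals the row's type
# and one of its qualifier values equals the row's synonym; the matched
# location is then resolved (strand, splicing, partials) and optionally
# translated. Everything is reported per (accession, locus) so absent or
# unextractable loci are visible, never silent.

#' Extraction configuration
#'
#' @param loci Optional character vector restricting extraction to these
#'   locus names; default all loci in the term table.
#' @param duplicates Extract every matching copy of a locus (`copy_index`
#'   2, 3, ... in record order) rather than the first only?
#' @param translate Translate CDS extractions to peptides?
#' @param transl_table Default NCBI genetic-code number for translation; a
#'   feature's own `/transl_table` qualifier overrides it (the record's
#'   self-description is more trustworthy than a global default).
#' @param qualifier_search_order Qualifier names consulted for synonym
#'   matching, most specific first.
#' @param match_mode `"exact_full_value"` compares the whole qualifier value
#'   (case-insensitive, whitespace-trimmed) to the synonym, so `COI` never
#'   matches `COIII`; `"word_boundary"` instead searches for the synonym as
#'   a whole word inside long product strings.
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(loci = NULL, duplicates = FALSE,
                              translate = FALSE, transl_table = 1L,
                              qualifier_search_order = c("gene", "product",
                                                         "standard_name", "note"),
                              match_mode = c("exact_full_value", "word_boundary")) {
  match_mode <- match.arg(match_mode)
  key <- as.character(as.integer(transl_table))
  if (!key %in% names(.GENETIC_CODES)) {
    stop(sprintf("transl_table %s is not a supported genetic code (%s)",
                 transl_table, paste(names(.GENETIC_CODES), collapse = ", ")),
         call. = FALSE)
  }
  stopifnot(length(qualifier_search_order) >= 1L)
  structure(list(loci = loci, duplicates = isTRUE(duplicates),
                 translate = isTRUE(translate),
                 transl_table = as.integer(transl_table),
                 qualifier_search_order = qualifier_search_order,
                 match_mode = match_mode),
            class = "extraction_config")
}

.norm_value <- function(x) tolower(trimws(x))

# Pre-normalize a term table for repeated matching.
.prep_terms <- function(table) {
  list(locus = table$Locus,
       type_lc = tolower(table$Type),
       name = table$Name,
       name_norm = .norm_value(table$Name),
       ie_number = table$IntronExonNumber)
}

# Qualifier values of a feature in search-precedence order: for each
# qualifier name in `order`, its values in file order.
.feature_qvals <- function(feature, order) {
  nm <- feature$qualifiers$name
  keep <- which(nm %in% order)
  if (!length(keep)) {
    return(list(qname = character(0), value = character(0)))
  }
  keep <- keep[order(match(nm[keep], order), keep)]
  list(qname = nm[keep], value = feature$qualifiers$value[keep])
}

#' Match one feature against a search-term table
#'
#' A row matches when the feature key equals the row's `Type`
#' (case-insensitive); `D-loop` rows with an empty `Name` match on the key
#' alone, named rows additionally require the synonym to match a qualifier
#' value in the configured search order, and intron/exon rows require the
#' feature's `/number` qualifier to equal the row's `IntronExonNumber`. The
#' first matching table row wins (row order is match priority).
#'
#' @param feature A `gb_feature`.
#' @param table A validated `search_terms` table.
#' @param config An [extraction_config()].
#' @param ignore_type Internal: match named rows regardless of feature key
#'   (used for the `gene`-key fallback).
#' @return `NULL` when nothing matches, else a list with `locus`, `row`,
#'   `matched_synonym`, `matched_qualifier`.
#' @export
match_feature <- function(feature, table, config = extraction_config(),
                          ignore_type = FALSE) {
  prep <- .prep_terms(table)
  .match_feature_prepped(feature, prep, config, ignore_type)
}

.match_feature_prepped <- function(feature, prep, config, ignore_type = FALSE) {
  key_lc <- tolower(feature$key)
  cand <- if (ignore_type) seq_along(prep$locus) else which(prep$type_lc == key_lc)
  if (!length(cand)) return(NULL)
  qv <- .feature_qvals(feature, config$qualifier_search_order)
  qv_norm <- .norm_value(qv$value)
  number_q <- feature$qualifiers$value[feature$qualifiers$name == "number"]
  for (i in cand) {
    if (prep$type_lc[i] %in% c("intron", "exon")) {
      if (ignore_type) next
      if (!length(number_q) ||
          suppressWarnings(as.integer(number_q[1])) != prep$ie_number[i]) next
      if (nzchar(prep$name[i])) {
        hit <- .value_hit(prep$name_norm[i], qv_norm, config$match_mode)
        if (is.na(hit)) next
        return(list(locus = prep$locus[i], row = i,
                    matched_synonym = prep$name[i],
                    matched_qualifier = qv$qname[hit]))
      }
      return(list(locus = prep$locus[i], row = i,
                  matched_synonym = "", matched_qualifier = "number"))
    }
    if (prep$type_lc[i] == "d-loop" && !ignore_type) {
      # D-loop rows match by feature key alone; report the qualifier when
      # the synonym also matched one.
      hit <- if (nzchar(prep$name[i])) {
        .value_hit(prep$name_norm[i], qv_norm, config$match_mode)
      } else NA_integer_
      return(list(locus = prep$locus[i], row = i,
                  matched_synonym = prep$name[i],
                  matched_qualifier = if (is.na(hit)) "" else qv$qname[hit]))
    }
    if (!nzchar(prep$name[i])) next
    hit <- .value_hit(prep$name_norm[i], qv_norm, config$match_mode)
    if (!is.na(hit)) {
      return(list(locus = prep$locus[i], row = i,
                  matched_synonym = prep$name[i],
                  matched_qualifier = qv$qname[hit]))
    }
  }
  NULL
}

# index of the first qualifier value matching a normalized synonym, or NA
.value_hit <- function(name_norm, qv_norm, mode) {
  if (!length(qv_norm)) return(NA_integer_)
  if (mode == "exact_full_value") {
    hit <- which(qv_norm == name_norm)
  } else {
    pat <- paste0("(^|[^[:alnum:]])", .rx_escape(name_norm), "([^[:alnum:]]|$)")
    hit <- which(grepl(pat, qv_norm))
  }
  if (length(hit)) hit[1] else NA_integer_
}

.rx_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Extract requested loci from one record
#'
#' Features are matched in record order against the term table. Features
#' with key `gene` are consulted only for loci that no CDS/tRNA/rRNA/other
#' feature matched, so a CDS and its enclosing `gene` never yield a
#' spurious duplicate. Matched locations are resolved; CDS extractions are
#' translated when the config requests it (honoring `/transl_table` and
#' `/codon_start` qualifiers). Every requested locus receives exactly one
#' status: `found`, `not_found`, `unparseable_location` or `out_of_bounds`.
#'
#' @param record A `gb_record`.
#' @param table A validated `search_terms` table.
#' @param config An [extraction_config()].
#' @return `list(sequences = <data.frame>, report = <data.frame>)`.
#'   `sequences` columns: `locus`, `accession`, `organism`, `sequence`,
#'   `copy_index`, `was_translated`, `feature_key`, `matched_synonym`,
#'   `matched_qualifier`, `partial`. `report` columns: `accession`, `locus`,
#'   `status`, `note`.
#' @export
extract_record <- function(record, table, config = extraction_config()) {
  stopifnot(inherits(record, "gb_record"))
  if (!inherits(table, "search_terms")) table <- search_terms(table)
  loci <- config$loci %||% unique(table$Locus)
  sub <- table[table$Locus %in% loci, , drop = FALSE]
  prep <- .prep_terms(sub)

  buckets <- stats::setNames(vector("list", length(loci)), loci)
  is_gene_key <- vapply(record$features, function(f) tolower(f$key) == "gene",
                        logical(1))
  skip_keys <- c("gene", "source")
  for (fi in seq_along(record$features)) {
    f <- record$features[[fi]]
    if (tolower(f$key) %in% skip_keys) next
    m <- .match_feature_prepped(f, prep, config)
    if (!is.null(m)) {
      buckets[[m$locus]] <- c(buckets[[m$locus]], list(c(m, list(fi = fi))))
    }
  }
  # gene-key fallback for loci nothing else matched
  if (any(is_gene_key)) {
    empty <- names(buckets)[vapply(buckets, length, integer(1)) == 0L]
    if (length(empty)) {
      sub2 <- sub[sub$Locus %in% empty & nzchar(sub$Name), , drop = FALSE]
      if (nrow(sub2)) {
        prep2 <- .prep_terms(sub2)
        for (fi in which(is_gene_key)) {
          f <- record$features[[fi]]
          m <- .match_feature_prepped(f, prep2, config, ignore_type = TRUE)
          if (!is.null(m) && length(buckets[[m$locus]]) == 0L) {
            buckets[[m$locus]] <- list(c(m, list(fi = fi)))
          }
        }
      }
    }
  }

  seq_rows <- list()
  rep_rows <- list()
  for (locus in loci) {
    hits <- buckets[[locus]]
    if (length(hits) == 0L) {
      rep_rows[[length(rep_rows) + 1L]] <-
        list(accession = record$accession, locus = locus,
             status = "not_found", note = "")
      next
    }
    if (!config$duplicates) hits <- hits[1]
    status <- NULL
    notes <- character(0)
    copy <- 0L
    for (h in hits) {
      f <- record$features[[h$fi]]
      if (is.null(f$location)) {
        if (is.null(status)) status <- "unparseable_location"
        notes <- c(notes, sprintf("location '%s' did not parse", f$raw_location))
        next
      }
      dna <- tryCatch(resolve_location(record, f$location), error = function(e) e)
      if (inherits(dna, "error")) {
        if (is.null(status)) status <- "out_of_bounds"
        notes <- c(notes, conditionMessage(dna))
        next
      }
      copy <- copy + 1L
      out_seq <- dna
      translated <- FALSE
      if (config$translate && tolower(f$key) == "cds") {
        tt <- .qual1(f, "transl_table", config$transl_table)
        cs <- .qual1(f, "codon_start", 1L)
        pep <- translate_cds(dna, tt, cs)
        if (attr(pep, "internal_stops") > 0L) {
          notes <- c(notes, sprintf("%d internal stop codon(s) in %s copy %d",
                                    attr(pep, "internal_stops"), locus, copy))
        }
        out_seq <- as.character(pep)
        translated <- TRUE
      }
      partial <- any(f$location$segments$partial_start |
                       f$location$segments$partial_end)
      seq_rows[[length(seq_rows) + 1L]] <-
        list(locus = locus, accession = record$accession,
             organism = record$organism, sequence = out_seq,
             copy_index = copy, was_translated = translated,
             feature_key = f$key, matched_synonym = h$matched_synonym,
             matched_qualifier = h$matched_qualifier, partial = partial)
      status <- "found"
    }
    rep_rows[[length(rep_rows) + 1L]] <-
      list(accession = record$accession, locus = locus,
           status = status %||% "not_found",
           note = paste(notes, collapse = "; "))
  }
  list(sequences = .rows_to_df(seq_rows, .empty_sequences()),
       report = .rows_to_df(rep_rows, .empty_report()))
}

.qual1 <- function(feature, name, default) {
  v <- feature$qualifiers$value[feature$qualifiers$name == name]
  if (length(v)) {
    iv <- suppressWarnings(as.integer(v[1]))
    if (!is.na(iv)) return(iv)
  }
  as.integer(default)
}

.bind_rows <- function(rows, empty) {
  if (length(rows)) do.call(rbind, rows) else empty
}

# list-of-row-lists into a data.frame shaped like `empty` (one data.frame
# call instead of one per row; this path is hot)
.rows_to_df <- function(rows, empty) {
  if (!length(rows)) return(empty)
  cols <- lapply(names(empty), function(cl) {
    proto <- empty[[cl]][0]
    vapply(rows, function(r) r[[cl]], FUN.VALUE = vector(typeof(proto), 1L))
  })
  names(cols) <- names(empty)
  do.call(data.frame, cols)
}

.empty_sequences <- function() {
  data.frame(locus = character(0), accession = character(0),
             organism = character(0), sequence = character(0),
             copy_index = integer(0), was_translated = logical(0),
             feature_key = character(0), matched_synonym = character(0),
             matched_qualifier = character(0), partial = logical(0))
}

.empty_report <- function() {
  data.frame(accession = character(0), locus = character(0),
             status = character(0), note = character(0))
}

#' Extract requested loci from many records
#'
#' Applies [extract_record()] to each record and row-binds the results. The
#' report always contains one row per (accession, requested locus) pair.
#'
#' @param records List of `gb_record` (e.g. from [read_genbank()]).
#' @inheritParams extract_record
#' @return `list(sequences, report)` as in [extract_record()].
#' @export
extract_records <- function(records, table, config = extraction_config()) {
  if (inherits(records, "gb_record")) records <- list(records)
  if (!inherits(table, "search_terms")) table <- search_terms(table)
  res <- lapply(records, extract_record, table = table, config = config)
  list(sequences = .bind_rows(lapply(res, `[[`, "sequences"), .empty_sequences()),
       report = .bind_rows(lapply(res, `[[`, "report"), .empty_report()))
}
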