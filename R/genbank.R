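# GenBank flat-file reading and writing.
#
# The parser targets the INSDC flat-file dialect as found in organelle and
# concatenated nucleotide records: LOCUS / DEFINITION / ACCESSION / VERSION /
# SOURCE-ORGANISM headers, the FEATURES table with multi-line locations and
# qualifiers (quoted values may span lines), and the ORIGIN sequence block.
# Malformed content is reported through parse issues, never dropped silently.

#' Construct a GenBank feature
#'
#' @param key Feature key (`CDS`, `tRNA`, `rRNA`, `misc_RNA`, `D-loop`,
#'   `intron`, `exon`, `gene`, `source`, ...).
#' @param location A `gb_location`, or `NULL` for a feature whose location
#'   string failed to parse (kept so callers can report it).
#' @param qualifiers `data.frame` with columns `name`, `value`, in file
#'   order; repeated names are allowed. Names are stored without the
#'   leading `/`.
#' @param raw_location Original location text (used when `location` is NULL).
#' @return Object of class `gb_feature`.
#' @export
new_feature <- function(key, location, qualifiers = NULL, raw_location = NULL) {
  stopifnot(is.character(key), nzchar(key))
  if (is.null(qualifiers)) {
    qualifiers <- data.frame(name = character(0), value = character(0))
  }
  structure(list(key = key, location = location,
                 qualifiers = qualifiers,
                 raw_location = raw_location %||%
                   (if (!is.null(location)) location$raw else NA_character_)),
            class = "gb_feature")
}

#' Construct a GenBank record
#'
#' @param accession Accession (without version suffix).
#' @param sequence Nucleotide sequence; canonicalized to lowercase.
#' @param version Accession.version string; defaults to `accession` + ".1".
#' @param definition Definition line.
#' @param organism Organism name.
#' @param features List of `gb_feature`.
#' @param declared_length Length stated on the LOCUS line; defaults to the
#'   sequence length.
#' @return Object of class `gb_record`.
#' @export
new_record <- function(accession, sequence, version = NULL, definition = "",
                       organism = "", features = list(),
                       declared_length = NULL) {
  sequence <- tolower(sequence)
  structure(list(accession = accession,
                 version = version %||% paste0(accession, ".1"),
                 definition = definition,
                 organism = organism,
                 sequence = sequence,
                 declared_length = as.integer(declared_length %||% nchar(sequence)),
                 features = features),
            class = "gb_record")
}

#' @export
print.gb_record <- function(x, ...) {
  cat(sprintf("<gb_record> %s (%s), %d bp, %d features\n",
              x$accession, x$organism, nchar(x$sequence), length(x$features)))
  invisible(x)
}

.issue <- function(severity, message, line) {
  data.frame(severity = severity, message = message, line = as.integer(line))
}

.no_issues <- function() {
  data.frame(severity = character(0), message = character(0), line = integer(0))
}

#' Read GenBank records from a file
#'
#' @param path Path to a GenBank flat file (one or many records).
#' @return As [parse_flatfile()].
#' @export
read_genbank <- function(path) {
  parse_flatfile(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' Parse GenBank flat-file text
#'
#' Splits the stream on `//` terminators and parses each entry into a
#' `gb_record`. Problems (unparseable locations, features beyond the declared
#' sequence length, `order(...)` locations, missing terminators) are returned
#' as issues with line numbers; the affected records and features are still
#' returned so nothing is dropped silently.
#'
#' @param text GenBank flat-file text.
#' @return `list(records = <list of gb_record>, issues = <data.frame>)` with
#'   issue columns `severity` (`"warning"`/`"error"`), `message`, `line`.
#' @export
parse_flatfile <- function(text) {
  stopifnot(is.character(text))
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1]]
  records <- list()
  issues <- list()
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    return(list(records = records, issues = .no_issues()))
  }
  term <- trimws(lines) == "//"
  bounds <- c(0L, which(term))
  blocks <- list()
  for (k in seq_len(length(bounds) - 1L)) {
    rng <- (bounds[k] + 1L):(bounds[k + 1L] - 1L)
    if (length(rng) && any(nzchar(trimws(lines[rng])))) {
      blocks[[length(blocks) + 1L]] <- list(lines = lines[rng], offset = bounds[k])
    }
  }
  # trailing content with no terminator: best-effort record plus an error issue
  if (bounds[length(bounds)] < length(lines)) {
    rng <- (bounds[length(bounds)] + 1L):length(lines)
    if (any(nzchar(trimws(lines[rng])))) {
      blocks[[length(blocks) + 1L]] <- list(lines = lines[rng],
                                            offset = bounds[length(bounds)])
      issues[[length(issues) + 1L]] <-
        .issue("error", "stream ends without '//' record terminator", length(lines))
    }
  }
  for (b in blocks) {
    res <- .parse_record_block(b$lines, b$offset)
    records[[length(records) + 1L]] <- res$record
    if (nrow(res$issues)) issues[[length(issues) + 1L]] <- res$issues
  }
  list(records = records,
       issues = if (length(issues)) do.call(rbind, issues) else .no_issues())
}

.parse_record_block <- function(lines, offset) {
  issues <- list()
  note <- function(sev, msg, ln) {
    issues[[length(issues) + 1L]] <<- .issue(sev, msg, offset + ln)
  }
  first_char <- substr(lines, 1L, 1L)
  kw <- ifelse(first_char != " " & nzchar(lines),
               sub("^([A-Z//]+).*$", "\\1", lines), "")

  get_kw_idx <- function(name) which(kw == name)

  accession <- version <- organism <- ""
  definition <- ""
  declared_length <- NA_integer_

  i_locus <- get_kw_idx("LOCUS")
  locus_name <- ""
  if (length(i_locus)) {
    toks <- strsplit(trimws(lines[i_locus[1]]), "[[:space:]]+")[[1]]
    if (length(toks) >= 2L) locus_name <- toks[2]
    bp <- which(toks == "bp")
    if (length(bp) && bp[1] > 1L) {
      declared_length <- suppressWarnings(as.integer(toks[bp[1] - 1L]))
    }
  } else {
    note("warning", "record without LOCUS line", 1L)
  }

  grab_multiline <- function(name) {
    i <- get_kw_idx(name)
    if (!length(i)) return("")
    i <- i[1]
    out <- sub(sprintf("^%s[[:space:]]*", name), "", lines[i])
    j <- i + 1L
    while (j <= length(lines) && (substr(lines[j], 1L, 1L) == " ") &&
           !grepl("^[[:space:]]{2}ORGANISM", lines[j])) {
      out <- paste(out, trimws(lines[j]))
      j <- j + 1L
    }
    trimws(out)
  }
  definition <- grab_multiline("DEFINITION")

  i_acc <- get_kw_idx("ACCESSION")
  if (length(i_acc)) {
    toks <- strsplit(trimws(lines[i_acc[1]]), "[[:space:]]+")[[1]]
    if (length(toks) >= 2L) accession <- toks[2]
  }
  i_ver <- get_kw_idx("VERSION")
  if (length(i_ver)) {
    toks <- strsplit(trimws(lines[i_ver[1]]), "[[:space:]]+")[[1]]
    if (length(toks) >= 2L) version <- toks[2]
  }
  i_org <- grep("^[[:space:]]{1,3}ORGANISM", lines)
  if (length(i_org)) {
    organism <- trimws(sub("^[[:space:]]*ORGANISM[[:space:]]*", "", lines[i_org[1]]))
  }
  if (!nzchar(accession)) accession <- locus_name
  if (!nzchar(version) && nzchar(accession)) version <- paste0(accession, ".1")

  # FEATURES table
  i_feat <- get_kw_idx("FEATURES")
  i_origin <- get_kw_idx("ORIGIN")
  i_end_feat <- if (length(i_origin)) i_origin[1] else length(lines) + 1L
  features <- list()
  if (length(i_feat)) {
    feat_lines <- if (i_feat[1] + 1L <= i_end_feat - 1L) {
      (i_feat[1] + 1L):(i_end_feat - 1L)
    } else integer(0)
    features <- .parse_features(lines, feat_lines, offset, note)
  }

  # ORIGIN sequence block
  sequence <- ""
  if (length(i_origin) && i_origin[1] < length(lines)) {
    seq_lines <- lines[(i_origin[1] + 1L):length(lines)]
    sequence <- tolower(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  }

  if (!is.na(declared_length) && nzchar(sequence) &&
      declared_length != nchar(sequence)) {
    note("error", sprintf(
      "declared length %d does not match sequence length %d (%s)",
      declared_length, nchar(sequence), accession),
      if (length(i_locus)) i_locus[1] else 1L)
  }
  if (is.na(declared_length)) declared_length <- nchar(sequence)

  seqlen <- if (nzchar(sequence)) nchar(sequence) else declared_length
  for (f in features) {
    if (!is.null(f$location) && !is.na(seqlen) && seqlen > 0L &&
        max(f$location$segments$end) > seqlen) {
      note("error", sprintf(
        "feature %s at %s exceeds %d bp sequence (%s)",
        f$key, f$location$raw, seqlen, accession), 1L)
    }
  }

  rec <- structure(list(accession = accession, version = version,
                        definition = definition, organism = organism,
                        sequence = sequence,
                        declared_length = as.integer(declared_length),
                        features = features),
                   class = "gb_record")
  list(record = rec,
       issues = if (length(issues)) do.call(rbind, issues) else .no_issues())
}

# Parse the FEATURES table lines (indices into `lines`). Feature keys sit in
# columns 6-20; locations and qualifiers start at column 22 and may continue
# on subsequent lines.
.parse_features <- function(lines, idx, offset, note) {
  features <- list()
  cur <- NULL        # list(key, locbuf, quals, line)
  qual_open <- NULL  # list(name, value, quoted_open)

  flush_qual <- function() {
    if (!is.null(qual_open)) {
      cur$quals[[length(cur$quals) + 1L]] <<-
        list(name = qual_open$name, value = qual_open$value)
      qual_open <<- NULL
    }
  }
  flush_feature <- function() {
    flush_qual()
    if (is.null(cur)) return()
    loc <- tryCatch(parse_location(cur$locbuf), error = function(e) e)
    if (inherits(loc, "error")) {
      note("error", sprintf("unparseable location for %s: %s",
                            cur$key, conditionMessage(loc)), cur$line)
      loc_obj <- NULL
    } else {
      loc_obj <- loc
      if (loc$is_order) {
        note("warning", sprintf(
          "order(...) location for %s treated as join(...)", cur$key), cur$line)
      }
    }
    q <- if (length(cur$quals)) {
      data.frame(name = vapply(cur$quals, `[[`, "", "name"),
                 value = vapply(cur$quals, `[[`, "", "value"))
    } else {
      data.frame(name = character(0), value = character(0))
    }
    features[[length(features) + 1L]] <<-
      new_feature(cur$key, loc_obj, q, raw_location = cur$locbuf)
    cur <<- NULL
  }

  for (i in idx) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    key_field <- trimws(substr(line, 1L, 20L))
    rest <- trimws(substr(line, 21L, nchar(line)))
    if (nzchar(key_field) && substr(line, 1L, 1L) == " ") {
      flush_feature()
      cur <- list(key = key_field, locbuf = rest, quals = list(), line = i)
      next
    }
    if (is.null(cur)) {
      note("warning", sprintf("stray feature-table line: %s", trimws(line)), i)
      next
    }
    if (!is.null(qual_open) && qual_open$quoted_open) {
      # continuation of a quoted qualifier value
      piece <- trimws(line)
      if (endsWith(piece, "\"")) {
        qual_open$value <- paste(qual_open$value, substr(piece, 1L, nchar(piece) - 1L))
        qual_open$quoted_open <- FALSE
      } else {
        qual_open$value <- paste(qual_open$value, piece)
      }
      next
    }
    if (startsWith(rest, "/") && grepl("^/[A-Za-z0-9_-]+(=|$)", rest)) {
      flush_qual()
      m <- regmatches(rest, regexec("^/([A-Za-z0-9_-]+)(=(.*))?$", rest))[[1]]
      qname <- m[2]
      if (!nzchar(m[3])) {
        qual_open <- list(name = qname, value = "", quoted_open = FALSE)
      } else {
        val <- m[4]
        if (startsWith(val, "\"")) {
          body <- substr(val, 2L, nchar(val))
          if (nzchar(body) && endsWith(body, "\"")) {
            qual_open <- list(name = qname,
                              value = substr(body, 1L, nchar(body) - 1L),
                              quoted_open = FALSE)
          } else {
            qual_open <- list(name = qname, value = body, quoted_open = TRUE)
          }
        } else {
          qual_open <- list(name = qname, value = val, quoted_open = FALSE)
        }
      }
      next
    }
    # location continuation (no qualifier started yet) or unquoted value cont.
    if (length(cur$quals) == 0L && is.null(qual_open)) {
      cur$locbuf <- paste0(cur$locbuf, trimws(line))
    } else if (!is.null(qual_open)) {
      qual_open$value <- paste(qual_open$value, trimws(line))
    }
  }
  flush_feature()
  features
}

#' Serialize records to GenBank flat-file text
#'
#' Writes a canonical flat file that [parse_flatfile()] reads back
#' field-for-field: lowercase sequence in ORIGIN blocks of 60 bases per line
#' (six 10-base groups with a leading position index), qualifiers one per
#' line in original order, and each feature's stored raw location text.
#' Records violating their invariants (declared length differing from the
#' sequence length, features out of bounds, empty keys) are refused.
#'
#' @param records List of `gb_record` (a single record is accepted).
#' @return Flat-file text (one string; empty string for an empty list).
#' @export
write_flatfile <- function(records) {
  if (inherits(records, "gb_record")) records <- list(records)
  stopifnot(is.list(records))
  if (length(records) == 0L) return("")
  out <- vapply(records, .write_record, character(1))
  paste0(paste(out, collapse = ""), collapse = "")
}

.write_record <- function(rec) {
  stopifnot(inherits(rec, "gb_record"))
  seqlen <- nchar(rec$sequence)
  if (rec$declared_length != seqlen) {
    stop(sprintf("refusing to write %s: declared length %d != sequence length %d",
                 rec$accession, rec$declared_length, seqlen), call. = FALSE)
  }
  if (grepl(sprintf("[^%s]", .IUPAC_FROM), rec$sequence)) {
    stop(sprintf("refusing to write %s: non-IUPAC characters in sequence",
                 rec$accession), call. = FALSE)
  }
  for (f in rec$features) {
    if (!nzchar(f$key)) stop("refusing to write: feature with empty key", call. = FALSE)
    if (is.null(f$location)) {
      stop(sprintf("refusing to write %s: feature %s has no parsed location",
                   rec$accession, f$key), call. = FALSE)
    }
    if (max(f$location$segments$end) > seqlen) {
      stop(sprintf("refusing to write %s: feature %s at %s out of bounds",
                   rec$accession, f$key, f$location$raw), call. = FALSE)
    }
  }
  con <- character(0)
  push <- function(...) con <<- c(con, paste0(...))
  push(sprintf("LOCUS       %-16s %11d bp    DNA     linear   UNA 01-JAN-2018",
               rec$accession, seqlen))
  push(sprintf("DEFINITION  %s", if (nzchar(rec$definition)) rec$definition else
    sprintf("%s %s.", rec$organism, rec$accession)))
  push(sprintf("ACCESSION   %s", rec$accession))
  push(sprintf("VERSION     %s", rec$version))
  push(sprintf("SOURCE      %s", rec$organism))
  push(sprintf("  ORGANISM  %s", rec$organism))
  push("FEATURES             Location/Qualifiers")
  for (f in rec$features) {
    push(sprintf("     %-16s%s", f$key, f$location$raw))
    if (nrow(f$qualifiers)) {
      for (qi in seq_len(nrow(f$qualifiers))) {
        nm <- f$qualifiers$name[qi]
        val <- f$qualifiers$value[qi]
        if (nm %in% c("number", "transl_table", "codon_start") &&
            grepl("^[0-9]+$", val)) {
          push(sprintf("                     /%s=%s", nm, val))
        } else if (!nzchar(val)) {
          push(sprintf("                     /%s", nm))
        } else {
          push(sprintf("                     /%s=\"%s\"", nm, val))
        }
      }
    }
  }
  push("ORIGIN")
  starts <- seq(1L, seqlen, by = 60L)
  for (s in starts) {
    chunk <- substr(rec$sequence, s, min(s + 59L, seqlen))
    groups <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    push(sprintf("%9d %s", s, paste(groups, collapse = " ")))
  }
  push("//")
  paste0(paste(con, collapse = "\n"), "\n")
}
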