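# Serialization of extraction results: per-locus FASTA files, the
# species-by-locus accession table, and longest-sequence-per-species
# selection for building one-accession-per-species datasets.

#' Write extracted sequences to per-locus FASTA files
#'
#' One file per locus present in `extracted`, named `{locus}.fasta`.
#' Headers are `>{accession}` or `>{organism with spaces as underscores}_
#' {accession}`; copies beyond the first get a `_copy{n}` suffix. Sequence
#' lines wrap at 80 columns. Loci with zero extractions produce no file.
#'
#' @param extracted `sequences` data frame from [extract_records()].
#' @param out_dir Output directory (created if absent).
#' @param header_style `"organism_accession"` (default; matches downstream
#'   species-keyed supermatrix use) or `"accession"`.
#' @param width Sequence line width.
#' @return Character vector of written file paths (empty for no input).
#' @export
write_fasta <- function(extracted, out_dir,
                        header_style = c("organism_accession", "accession"),
                        width = 80L) {
  header_style <- match.arg(header_style)
  stopifnot(is.data.frame(extracted))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir),
                  call. = FALSE)
  }
  if (file.access(out_dir, 2L) != 0L) {
    stop(sprintf("output directory '%s' is not writable", out_dir), call. = FALSE)
  }
  if (!nrow(extracted)) return(character(0))
  paths <- character(0)
  for (locus in unique(extracted$locus)) {
    sub <- extracted[extracted$locus == locus, , drop = FALSE]
    hdr <- if (header_style == "accession") {
      sub$accession
    } else {
      paste0(gsub("[[:space:]]+", "_", sub$organism), "_", sub$accession)
    }
    hdr <- ifelse(sub$copy_index > 1L,
                  paste0(hdr, "_copy", sub$copy_index), hdr)
    lines <- unlist(lapply(seq_len(nrow(sub)), function(i) {
      s <- sub$sequence[i]
      starts <- seq(1L, nchar(s), by = width)
      c(paste0(">", hdr[i]), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
    }))
    path <- file.path(out_dir, paste0(locus, ".fasta"))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  paths
}

#' Build the species-by-locus accession table
#'
#' One row per organism (falling back to the accession when the organism is
#' blank), one column per requested locus, each cell holding the accession
#' the locus was extracted from, or empty when it was not found. An organism
#' spanning several accessions occupies a single row citing each source
#' accession in the respective cell; conflicting sources for the same
#' (organism, locus) keep the first found, with a warning.
#'
#' @param report `report` data frame from [extract_records()].
#' @param records The parsed records the report came from (for the
#'   accession-to-organism mapping).
#' @return `data.frame` with first column `Species` then one column per
#'   locus, in requested order.
#' @export
build_accession_table <- function(report, records) {
  if (inherits(records, "gb_record")) records <- list(records)
  acc2org <- stats::setNames(
    vapply(records, function(r) r$organism, character(1)),
    vapply(records, function(r) r$accession, character(1)))
  loci <- unique(report$locus)
  org <- unname(acc2org[report$accession])
  org[is.na(org) | !nzchar(org)] <- report$accession[is.na(org) | !nzchar(org)]
  species <- unique(org)
  tab <- matrix("", nrow = length(species), ncol = length(loci),
                dimnames = list(species, loci))
  found <- report[report$status == "found", , drop = FALSE]
  found_org <- org[report$status == "found"]
  n_conflicts <- 0L
  for (i in seq_len(nrow(found))) {
    sp <- found_org[i]; lc <- found$locus[i]
    if (nzchar(tab[sp, lc])) {
      if (tab[sp, lc] != found$accession[i]) n_conflicts <- n_conflicts + 1L
      next
    }
    tab[sp, lc] <- found$accession[i]
  }
  if (n_conflicts > 0L) {
    warning(sprintf(
      "%d (species, locus) cells had additional source accessions; kept the first found",
      n_conflicts), call. = FALSE)
  }
  out <- data.frame(Species = species, tab, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Write / read an accession table as CSV
#'
#' Header row is `Species,{locus1},{locus2},...`; empty cells mark loci not
#' recovered for that species. Reading back returns an identical grid.
#'
#' @param table Accession table from [build_accession_table()].
#' @param path CSV path.
#' @return `path` (write) or the table (read).
#' @export
write_accession_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_accession_table
#' @export
read_accession_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  check.names = FALSE, na.strings = character(0))
}

#' Longest sequence per species
#'
#' Given (species, accession, length) entries — e.g. from records parsed
#' locally — selects for each species the accession with the maximal
#' sequence length. Ties break to the lexicographically least accession, so
#' the selection is invariant to input order.
#'
#' @param entries `data.frame` with columns `species`, `accession`,
#'   `length`; or a list of `gb_record`, from which the triples are derived.
#' @return `data.frame` with columns `species`, `accession`, `length`, one
#'   row per species, in first-appearance order of species.
#' @export
find_longest_seq <- function(entries) {
  if (is.list(entries) && !is.data.frame(entries) &&
      all(vapply(entries, inherits, logical(1), "gb_record"))) {
    entries <- data.frame(
      species = vapply(entries, function(r) r$organism, character(1)),
      accession = vapply(entries, function(r) r$accession, character(1)),
      length = vapply(entries, function(r) nchar(r$sequence), integer(1)))
  }
  stopifnot(is.data.frame(entries))
  if (!nrow(entries)) {
    return(data.frame(species = character(0), accession = character(0),
                      length = integer(0)))
  }
  stopifnot(all(c("species", "accession", "length") %in% names(entries)))
  if (any(entries$length <= 0L)) stop("lengths must be positive", call. = FALSE)
  species <- unique(entries$species)
  rows <- lapply(species, function(sp) {
    sub <- entries[entries$species == sp, , drop = FALSE]
    sub <- sub[order(-sub$length, sub$accession), , drop = FALSE]
    sub[1L, c("species", "accession", "length")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$length <- as.integer(out$length)
  out
}
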