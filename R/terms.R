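# Synonym search-term tables: schema, validation, bundled dictionaries,
# merging and CSV round trips.
#
# A term table maps the many names a locus is annotated under in feature
# tables to one output locus. Columns mirror the field-standard layout:
#   Locus            output group / FASTA file stem
#   Type             feature key to match (CDS, tRNA, rRNA, misc_RNA,
#                    D-loop, intron, exon, misc_feature)
#   Name             one synonym; empty only for D-loop rows (key-only match)
#   IntronExonNumber intron/exon ordinal, required for intron/exon rows
# Row order defines match priority.

.TERM_TYPES <- c("CDS", "tRNA", "rRNA", "misc_RNA", "D-loop",
                 "intron", "exon", "misc_feature")

.BUNDLED_TERMS <- c("mtDNA-animal" = "mtdna_animal.csv",
                    "mtDNA-plant"  = "mtdna_plant.csv",
                    "cpDNA"        = "cpdna.csv",
                    "rDNA"         = "rdna.csv")

#' Construct a search-term table
#'
#' @param df `data.frame` with columns `Locus`, `Type`, `Name` and optionally
#'   `IntronExonNumber` (added as all-`NA` when absent).
#' @param source_names Provenance labels carried as an attribute.
#' @param validate Stop on schema violations (default)?
#' @return A `search_terms` object (a `data.frame` subclass).
#' @export
search_terms <- function(df, source_names = "user", validate = TRUE) {
  stopifnot(is.data.frame(df))
  needed <- c("Locus", "Type", "Name")
  if (!all(needed %in% names(df))) {
    stop("search-term table needs columns Locus, Type, Name", call. = FALSE)
  }
  if (!"IntronExonNumber" %in% names(df)) df$IntronExonNumber <- NA_integer_
  df <- df[, c("Locus", "Type", "Name", "IntronExonNumber")]
  df$Locus <- as.character(df$Locus)
  df$Type <- as.character(df$Type)
  df$Name <- as.character(df$Name)
  df$Name[is.na(df$Name)] <- ""
  df$IntronExonNumber <- suppressWarnings(as.integer(df$IntronExonNumber))
  rownames(df) <- NULL
  out <- structure(df, class = c("search_terms", "data.frame"),
                   source_names = source_names)
  if (validate) {
    iss <- validate_terms(out)
    if (nrow(iss)) {
      stop(paste0("invalid search-term table:\n  ",
                  paste(iss$message, collapse = "\n  ")), call. = FALSE)
    }
  }
  out
}

#' Validate a search-term table
#'
#' Checks every row against the schema: non-empty `Locus` and `Type`, `Type`
#' drawn from the supported feature keys, `Name` empty only for D-loop rows,
#' and `IntronExonNumber` present exactly for intron/exon rows (and positive).
#'
#' @param table A `search_terms` table or plain `data.frame` with the same
#'   columns.
#' @return `data.frame` of issues (`severity`, `message`, `line` = row
#'   number); zero rows iff the table is valid.
#' @export
validate_terms <- function(table) {
  stopifnot(is.data.frame(table))
  if (!"IntronExonNumber" %in% names(table)) table$IntronExonNumber <- NA_integer_
  issues <- list()
  add <- function(msg, row) {
    issues[[length(issues) + 1L]] <<- .issue("error", msg, row)
  }
  for (i in seq_len(nrow(table))) {
    locus <- table$Locus[i]; type <- table$Type[i]; name <- table$Name[i]
    num <- table$IntronExonNumber[i]
    if (is.na(locus) || !nzchar(locus)) add(sprintf("row %d: empty Locus", i), i)
    if (is.na(type) || !nzchar(type)) {
      add(sprintf("row %d: empty Type", i), i)
      next
    }
    if (!tolower(type) %in% tolower(.TERM_TYPES)) {
      add(sprintf("row %d: unknown feature type '%s'", i, type), i)
    }
    is_ie <- tolower(type) %in% c("intron", "exon")
    if (is_ie && (is.na(num) || num < 1L)) {
      add(sprintf("row %d: %s row lacks a positive IntronExonNumber", i, type), i)
    }
    if (!is_ie && !is.na(num)) {
      add(sprintf("row %d: IntronExonNumber set on non-intron/exon row", i), i)
    }
    if ((is.na(name) || !nzchar(name)) && tolower(type) != "d-loop") {
      add(sprintf("row %d: empty Name on %s row", i, type), i)
    }
  }
  if (length(issues)) do.call(rbind, issues) else .no_issues()
}

#' Load a bundled or on-disk search-term table
#'
#' Four dictionaries ship with the package: `"mtDNA-animal"` (13 metazoan
#' mitochondrial protein-coding genes, 22 tRNAs, 2 rRNAs and the
#' D-loop/control region), `"mtDNA-plant"`, `"cpDNA"` (standard chloroplast
#' coding loci including matK and rbcL), and `"rDNA"` (18S, 5.8S, 28S, ITS1,
#' ITS2). Any other value is treated as a CSV path with header
#' `Locus,Type,Name,IntronExonNumber`.
#'
#' @param name Bundled set name or CSV file path.
#' @return A validated `search_terms` table.
#' @export
load_search_terms <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (name %in% names(.BUNDLED_TERMS)) {
    path <- system.file("extdata", "terms", .BUNDLED_TERMS[[name]],
                        package = "geneharvest", mustWork = TRUE)
    return(read_search_terms(path, source_names = name))
  }
  if (file.exists(name)) {
    return(read_search_terms(name, source_names = name))
  }
  stop(sprintf("unknown search-term set '%s'; bundled sets are: %s",
               name, paste(names(.BUNDLED_TERMS), collapse = ", ")),
       call. = FALSE)
}

#' Read a search-term table from CSV
#'
#' @param path CSV with header `Locus,Type,Name,IntronExonNumber` (the last
#'   column optional), UTF-8.
#' @param source_names Provenance label; defaults to the path.
#' @return A validated `search_terms` table.
#' @export
read_search_terms <- function(path, source_names = path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = character(0))
  if ("IntronExonNumber" %in% names(df)) {
    df$IntronExonNumber[!nzchar(df$IntronExonNumber)] <- NA
  }
  search_terms(df, source_names = source_names)
}

#' Write a search-term table to CSV
#'
#' @param table A `search_terms` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_search_terms <- function(table, path) {
  df <- as.data.frame(table)
  df$IntronExonNumber <- ifelse(is.na(df$IntronExonNumber), "",
                                as.character(df$IntronExonNumber))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Merge search-term tables
#'
#' Concatenates tables in argument order, dropping exact-duplicate rows (all
#' four fields equal, case-sensitive — case variants such as `cox1` and
#' `COX1` are distinct synonyms) while keeping the first occurrence, so
#' merging is idempotent. With `sort_by_locus` the rows are grouped into
#' contiguous locus blocks, preserving within-locus relative order (a stable
#' grouping, not an alphabetical sort).
#'
#' @param ... One or more `search_terms` tables (or conforming data frames).
#' @param sort_by_locus Group rows by locus?
#' @return A merged `search_terms` table.
#' @export
merge_terms <- function(..., sort_by_locus = FALSE) {
  tables <- list(...)
  if (length(tables) == 1L && is.list(tables[[1]]) && !is.data.frame(tables[[1]])) {
    tables <- tables[[1]]
  }
  if (length(tables) == 0L) stop("no tables to merge", call. = FALSE)
  tables <- lapply(tables, function(t) {
    if (!inherits(t, "search_terms")) t <- search_terms(t) else {
      iss <- validate_terms(t)
      if (nrow(iss)) stop("invalid table passed to merge_terms", call. = FALSE)
    }
    t
  })
  sources <- unlist(lapply(tables, function(t) attr(t, "source_names")))
  df <- do.call(rbind, lapply(tables, as.data.frame))
  key <- paste(df$Locus, df$Type, df$Name,
               ifelse(is.na(df$IntronExonNumber), "", df$IntronExonNumber),
               sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]
  if (sort_by_locus && nrow(df)) {
    ord <- order(match(df$Locus, unique(df$Locus)), seq_len(nrow(df)))
    df <- df[ord, , drop = FALSE]
  }
  rownames(df) <- NULL
  search_terms(df, source_names = unique(sources))
}
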