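# INSDC feature-location grammar: parsing, unparsing and resolution.
#
# Supported forms: N, N..M, partial markers < and >, complement(...),
# join(...), order(...), with nesting of complement inside join and join
# inside complement. Between-base locations (N^M) and remote-accession
# references (acc:loc) are rejected explicitly rather than skipped, because a
# silent misextraction is worse than a failure.

#' Construct a feature location
#'
#' A location is an ordered, strand-aware list of genomic segments in
#' *assembly order*: resolving the location concatenates the segments in the
#' order stored here, reverse-complementing minus-strand segments. For
#' `complement(join(a, b))` the stored order is therefore `b, a` with both
#' segments on the minus strand, which is exactly
#' `revcomp(seq[a] + seq[b]) = revcomp(seq[b]) + revcomp(seq[a])`.
#'
#' @param segments `data.frame` with columns `start`, `end` (1-based
#'   inclusive), `strand` (`"+"` or `"-"`), `partial_start`, `partial_end`
#'   (logical flags for the `<` / `>` markers; they never alter the numeric
#'   bounds).
#' @param is_order `TRUE` when the surface form used `order(...)` rather than
#'   `join(...)`; assembly treats both identically.
#' @param raw The original location string, regenerated with
#'   [unparse_location()] when the location was built programmatically.
#' @return An object of class `gb_location`.
#' @export
new_location <- function(segments, is_order = FALSE, raw = NULL) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1L)
  needed <- c("start", "end", "strand", "partial_start", "partial_end")
  missing_cols <- setdiff(needed, names(segments))
  for (cl in missing_cols) {
    segments[[cl]] <- switch(cl, strand = "+", FALSE)
  }
  segments <- segments[, needed]
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  if (any(segments$start < 1L) || any(segments$end < segments$start)) {
    stop("invalid interval: need 1 <= start <= end", call. = FALSE)
  }
  if (!all(segments$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  rownames(segments) <- NULL
  loc <- structure(list(segments = segments, is_order = isTRUE(is_order),
                        raw = raw %||% NA_character_),
                   class = "gb_location")
  if (is.na(loc$raw)) loc$raw <- unparse_location(loc)
  loc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gb_location <- function(x, ...) {
  cat("<gb_location> ", x$raw, "\n", sep = "")
  invisible(x)
}

#' Parse an INSDC feature-location string
#'
#' Decodes the location grammar subset used in organelle and concatenated
#' records: single base (`467`), range (`3300..4037`), partial markers
#' (`<1..206`, `100..>200`), `complement(...)`, `join(...)`, `order(...)`,
#' with nesting. Segments are returned in assembly order (see
#' [new_location()]); `order(...)` is treated as `join(...)` with the
#' `is_order` flag set so callers can attach a warning.
#'
#' @param text Location string.
#' @return A `gb_location`.
#' @seealso [resolve_location()]
#' @examples
#' parse_location("complement(3300..4037)")
#' parse_location("join(complement(1210..1310),complement(100..200))")
#' @export
parse_location <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  s <- gsub("[[:space:]]", "", text)
  if (!nzchar(s)) stop("empty location string", call. = FALSE)
  segs <- .parse_loc_expr(s)
  new_location(segs, is_order = isTRUE(attr(segs, "is_order")), raw = text)
}

.parse_loc_expr <- function(s) {
  if (startsWith(s, "complement(")) {
    inner <- .strip_call(s, "complement")
    segs <- .parse_loc_expr(inner)
    out <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
    out$strand <- ifelse(out$strand == "+", "-", "+")
    rownames(out) <- NULL
    attr(out, "is_order") <- isTRUE(attr(segs, "is_order"))
    return(out)
  }
  if (startsWith(s, "join(") || startsWith(s, "order(")) {
    kw <- if (startsWith(s, "join(")) "join" else "order"
    inner <- .strip_call(s, kw)
    parts <- .split_top_commas(inner)
    if (length(parts) == 0L) stop(sprintf("empty %s() in location", kw), call. = FALSE)
    pieces <- lapply(parts, .parse_loc_expr)
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    attr(out, "is_order") <- kw == "order" ||
      any(vapply(pieces, function(p) isTRUE(attr(p, "is_order")), logical(1)))
    return(out)
  }
  .parse_loc_atom(s)
}

.parse_loc_atom <- function(s) {
  if (grepl("^", s, fixed = TRUE)) {
    stop(sprintf("unsupported form: between-base location '%s'", s), call. = FALSE)
  }
  if (grepl(":", s, fixed = TRUE)) {
    stop(sprintf("unsupported form: remote-accession location '%s'", s), call. = FALSE)
  }
  m <- regmatches(s, regexec("^(<?)(\\d+)\\.\\.(>?)(\\d+)$", s))[[1]]
  if (length(m)) {
    start <- as.integer(m[3]); end <- as.integer(m[5])
    if (start > end) stop(sprintf("inverted range in location '%s'", s), call. = FALSE)
    return(data.frame(start = start, end = end, strand = "+",
                      partial_start = m[2] == "<", partial_end = m[4] == ">"))
  }
  m <- regmatches(s, regexec("^(<?)(\\d+)(>?)$", s))[[1]]
  if (length(m)) {
    p <- as.integer(m[3])
    return(data.frame(start = p, end = p, strand = "+",
                      partial_start = m[2] == "<", partial_end = m[4] == ">"))
  }
  stop(sprintf("unrecognized location token '%s'", s), call. = FALSE)
}

# Strip "kw(" prefix and the matching final ")"; error on imbalance/trailing text.
.strip_call <- function(s, kw) {
  body <- substr(s, nchar(kw) + 2L, nchar(s))
  if (!endsWith(body, ")")) {
    stop(sprintf("unbalanced parentheses in location '%s'", s), call. = FALSE)
  }
  inner <- substr(body, 1L, nchar(body) - 1L)
  depth <- 0L
  for (ch in strsplit(inner, "", fixed = TRUE)[[1]]) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) stop(sprintf("unbalanced parentheses in location '%s'", s), call. = FALSE)
  }
  if (depth != 0L) stop(sprintf("unbalanced parentheses in location '%s'", s), call. = FALSE)
  inner
}

.split_top_commas <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  cuts <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    else if (chars[i] == ")") depth <- depth - 1L
    else if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, nchar(s))
  out <- substring(s, starts, ends)
  out[nzchar(out)]
}

#' Render a location back to INSDC surface syntax
#'
#' Produces `start..end` atoms with partial markers, wraps minus-strand
#' segments in `complement(...)` and multi-segment locations in `join(...)`
#' (or `order(...)` when the flag is set). The output re-parses to the same
#' segment structure; it is a canonical form, not necessarily the byte-exact
#' original (e.g. `complement(join(...))` round-trips as
#' `join(complement(...), ...)`, which resolves identically).
#'
#' @param loc A `gb_location`.
#' @return Location string.
#' @export
unparse_location <- function(loc) {
  stopifnot(inherits(loc, "gb_location"))
  segs <- loc$segments
  atom <- function(i) {
    a <- segs$start[i]; b <- segs$end[i]
    core <- if (a == b && !segs$partial_start[i] && !segs$partial_end[i]) {
      as.character(a)
    } else {
      paste0(if (segs$partial_start[i]) "<" else "", a, "..",
             if (segs$partial_end[i]) ">" else "", b)
    }
    if (segs$strand[i] == "-") paste0("complement(", core, ")") else core
  }
  parts <- vapply(seq_len(nrow(segs)), atom, character(1))
  if (length(parts) == 1L) {
    parts
  } else {
    paste0(if (loc$is_order) "order(" else "join(", paste(parts, collapse = ","), ")")
  }
}

#' Total span of a location in bases
#'
#' @param loc A `gb_location`.
#' @return Sum of `end - start + 1` over all segments.
#' @export
location_width <- function(loc) {
  stopifnot(inherits(loc, "gb_location"))
  sum(loc$segments$end - loc$segments$start + 1L)
}

#' Extract the subsequence a location describes
#'
#' For each segment in assembly order, takes the 1-based inclusive substring
#' of the record's sequence, reverse-complements minus-strand segments, and
#' concatenates. The result length always equals [location_width()].
#'
#' @param record A `gb_record` (or any list with a `$sequence` string).
#' @param loc A `gb_location`.
#' @return DNA string.
#' @examples
#' rec <- list(sequence = "aatgcca")
#' resolve_location(rec, parse_location("2..5"))             # "atgc"
#' resolve_location(rec, parse_location("complement(2..5)")) # "gcat"
#' resolve_location(rec, parse_location("join(1..2,6..7)"))  # "aaca"
#' @export
resolve_location <- function(record, loc) {
  stopifnot(inherits(loc, "gb_location"))
  seqlen <- nchar(record$sequence)
  segs <- loc$segments
  if (any(segs$start < 1L | segs$end > seqlen)) {
    stop(sprintf("location '%s' out of bounds for %d bp sequence",
                 loc$raw, seqlen), call. = FALSE)
  }
  pieces <- substring(record$sequence, segs$start, segs$end)
  minus <- segs$strand == "-"
  if (any(minus)) pieces[minus] <- .revcomp_unchecked(pieces[minus])
  paste(pieces, collapse = "")
}
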