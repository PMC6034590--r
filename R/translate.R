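# Translation of coding sequences under NCBI genetic codes.

# Amino-acid strings in canonical NCBI codon order (base order t, c, a, g for
# positions 1, 2, 3). Codes shipped: 1 standard, 2 vertebrate mitochondrial,
# 5 invertebrate mitochondrial, 11 bacterial/archaeal/plastid.
.GENETIC_CODES <- list(
  `1`  = "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  `2`  = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSS**VVVVAAAADDEEGGGG",
  `5`  = "FFLLSSSSYY**CCWWLLLLPPPPHHQQRRRRIIMMTTTTNNKKSSSSVVVVAAAADDEEGGGG",
  `11` = "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"
)

#' Supported NCBI genetic-code numbers
#'
#' @return Integer vector of translation-table numbers this package ships.
#' @export
genetic_codes <- function() {
  as.integer(names(.GENETIC_CODES))
}

# codon (lowercase, 3 chars) -> amino acid under a code string; ambiguity -> X
.codon_index <- function(codon) {
  base <- match(strsplit(codon, "", fixed = TRUE)[[1]], c("t", "c", "a", "g"))
  if (anyNA(base)) return(NA_integer_)
  (base[1] - 1L) * 16L + (base[2] - 1L) * 4L + base[3]
}

#' Translate a coding sequence
#'
#' Skips `codon_start - 1` leading bases, translates successive triplets
#' under the numbered NCBI genetic code, drops an incomplete trailing codon,
#' and removes exactly one terminal stop when present. Internal stops are
#' retained as `*` and flagged via the `internal_stops` attribute (annotation
#' errors are a known hazard; flagging beats failing). Codons containing
#' ambiguity codes translate to `X`.
#'
#' @param dna DNA string (case-insensitive; `u` treated as `t`).
#' @param table_number NCBI genetic-code number; see [genetic_codes()].
#' @param codon_start Reading-frame offset 1, 2 or 3 (the `/codon_start`
#'   qualifier convention).
#' @return Peptide string with attributes `internal_stops` (count) and
#'   `terminal_stop_removed` (logical).
#' @examples
#' translate_cds("atgaaacgataa")            # "MKR"
#' translate_cds("catgaaa", codon_start = 2) # "MK"
#' @export
translate_cds <- function(dna, table_number = 1L, codon_start = 1L) {
  stopifnot(is.character(dna), length(dna) == 1L, nzchar(dna))
  key <- as.character(as.integer(table_number))
  if (!key %in% names(.GENETIC_CODES)) {
    stop(sprintf("undefined translation table %s; supported codes: %s",
                 table_number, paste(names(.GENETIC_CODES), collapse = ", ")),
         call. = FALSE)
  }
  if (!codon_start %in% 1:3) {
    stop("codon_start must be 1, 2 or 3", call. = FALSE)
  }
  code <- .GENETIC_CODES[[key]]
  s <- chartr("u", "t", tolower(dna))
  s <- substr(s, codon_start, nchar(s))
  n_codon <- nchar(s) %/% 3L
  if (n_codon == 0L) {
    out <- ""
    attr(out, "internal_stops") <- 0L
    attr(out, "terminal_stop_removed") <- FALSE
    return(out)
  }
  codons <- substring(s, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  aa <- vapply(codons, function(cd) {
    i <- .codon_index(cd)
    if (is.na(i)) "X" else substr(code, i, i)
  }, character(1), USE.NAMES = FALSE)
  terminal_removed <- FALSE
  if (aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]
    terminal_removed <- TRUE
  }
  out <- paste(aa, collapse = "")
  attr(out, "internal_stops") <- sum(aa == "*")
  attr(out, "terminal_stop_removed") <- terminal_removed
  out
}
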