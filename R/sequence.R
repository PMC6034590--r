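# Nucleotide sequence primitives shared across the package.

# IUPAC nucleotide codes and their complements. Sequences are canonicalized
# lowercase throughout; uppercase is accepted on input.
.IUPAC_FROM <- "acgtrymkswbdhvnuACGTRYMKSWBDHVNU"
.IUPAC_TO   <- "tgcayrkmswvhdbnaTGCAYRKMSWVHDBNA"

#' Reverse complement of a DNA sequence
#'
#' Complements every IUPAC nucleotide code (ambiguity codes map to their
#' complementary ambiguity code, `n` to `n`) and reverses the result. The
#' operation is an involution: applying it twice returns the input.
#'
#' @param seq Single DNA string over the IUPAC alphabet (case preserved).
#' @return The reverse-complemented string, same length and case as `seq`.
#' @examples
#' reverse_complement("aaa")   # "ttt"
#' reverse_complement("acgt")  # "acgt"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  if (!nzchar(seq)) {
    return(seq)
  }
  bad <- regexpr(sprintf("[^%s]", .IUPAC_FROM), seq)
  if (bad > 0L) {
    stop(sprintf("non-IUPAC character '%s' at offset %d",
                 substr(seq, bad, bad), bad), call. = FALSE)
  }
  comp <- chartr(.IUPAC_FROM, .IUPAC_TO, seq)
  intToUtf8(rev(utf8ToInt(comp)))
}

# Vectorized complement-and-reverse used on hot paths; inputs already checked.
.revcomp_unchecked <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(chartr(.IUPAC_FROM, .IUPAC_TO, s)))),
         character(1), USE.NAMES = FALSE)
}

# Uniformly random DNA string (used by the fixture generator).
.random_dna <- function(n) {
  paste(sample(c("a", "c", "g", "t"), n, replace = TRUE), collapse = "")
}
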