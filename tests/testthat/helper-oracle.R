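# Independent per-base oracle for location resolution: walks the grammar
# position by position (complement = reverse the base walk and flip strand)
# and complements single bases via a lookup table. Shares no code with the
# package's segment/substring implementation.

oracle_resolve <- function(loc_text, seq) {
  comp <- c(a = "t", c = "g", g = "c", t = "a", n = "n")
  walk <- function(s) {
    s <- gsub("[[:space:]]", "", s)
    if (startsWith(s, "complement(")) {
      inner <- substr(s, 12L, nchar(s) - 1L)
      df <- walk(inner)
      df <- df[rev(seq_len(nrow(df))), , drop = FALSE]
      df$strand <- ifelse(df$strand == "+", "-", "+")
      return(df)
    }
    if (startsWith(s, "join(") || startsWith(s, "order(")) {
      inner <- sub("^(join|order)\\(", "", s)
      inner <- substr(inner, 1L, nchar(inner) - 1L)
      cs <- strsplit(inner, "", fixed = TRUE)[[1]]
      depth <- 0L
      cut <- integer(0)
      for (i in seq_along(cs)) {
        if (cs[i] == "(") depth <- depth + 1L
        if (cs[i] == ")") depth <- depth - 1L
        if (cs[i] == "," && depth == 0L) cut <- c(cut, i)
      }
      parts <- substring(inner, c(1L, cut + 1L), c(cut - 1L, nchar(inner)))
      return(do.call(rbind, lapply(parts, walk)))
    }
    s2 <- gsub("[<>]", "", s)
    pos <- if (grepl("..", s2, fixed = TRUE)) {
      ab <- as.integer(strsplit(s2, "..", fixed = TRUE)[[1]])
      ab[1]:ab[2]
    } else {
      as.integer(s2)
    }
    data.frame(pos = pos, strand = "+")
  }
  df <- walk(loc_text)
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste(ifelse(df$strand == "+", bases[df$pos],
               unname(comp[bases[df$pos]])), collapse = "")
}

# Random location string over a sequence of length seqlen: 1-3 disjoint
# intervals, per-atom and whole-location complements, partial markers.
random_location_string <- function(seqlen, max_segments = 3L) {
  n <- sample.int(max_segments, 1L)
  pts <- sort(sample.int(seqlen, 2L * n, replace = FALSE))
  a <- pts[seq(1L, 2L * n, by = 2L)]
  b <- pts[seq(2L, 2L * n, by = 2L)]
  atoms <- sprintf("%s%d..%s%d",
                   ifelse(stats::runif(n) < 0.15, "<", ""), a,
                   ifelse(stats::runif(n) < 0.15, ">", ""), b)
  single <- stats::runif(n) < 0.1
  atoms[single] <- as.character(a[single])
  wrap <- stats::runif(n) < 0.5
  atoms[wrap] <- sprintf("complement(%s)", atoms[wrap])
  loc <- if (n == 1L) atoms else sprintf("join(%s)", paste(atoms, collapse = ","))
  if (stats::runif(1) < 0.3) loc <- sprintf("complement(%s)", loc)
  loc
}
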