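#' @importFrom stats median rnorm rpois runif rbinom aov TukeyHSD setNames
#' @importFrom utils head read.delim write.table
NULL

#' Random DNA sequence with a given GC content
#'
#' Draws i.i.d. nucleotides with P(G) = P(C) = gc/2.
#'
#' @param n Sequence length in bases.
#' @param gc GC content as a fraction in \[0, 1\].
#' @return A single character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Reverse complement of a DNA string
#' @param x Character string (ACGT alphabet).
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' GC fraction of character sequences
#' @param x Character vector of DNA sequences.
#' @return Numeric vector of GC fractions.
#' @export
gc_fraction <- function(x) {
  ss <- Biostrings::DNAStringSet(x)
  as.numeric(Biostrings::letterFrequency(ss, "GC", as.prob = TRUE))
}

#' Substitute random positions of a DNA string
#'
#' Each position is substituted independently with probability `rate`;
#' substitutions always change the base.
#'
#' @param x Character string.
#' @param rate Per-base substitution probability.
#' @return Mutated character string.
#' @export
mutate_seq <- function(x, rate) {
  if (rate <= 0) return(x)
  chars <- strsplit(x, NULL)[[1L]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Reference span of a CIGAR string
#'
#' Sums the lengths of reference-consuming operations (M, =, X, D, N).
#'
#' @param cigar Character vector of CIGAR strings ("*" gives NA).
#' @return Integer vector of reference spans.
#' @export
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
    n <- as.integer(sub("[MIDNSHP=X]", "", ops))
    op <- sub("\\d+", "", ops)
    sum(n[op %in% c("M", "=", "X", "D", "N")])
  }, integer(1L), USE.NAMES = FALSE)
}

# Contig lengths from a DNAStringSet, named numeric vector, or data.frame.
contig_lengths_of <- function(x) {
  if (methods::is(x, "DNAStringSet")) {
    setNames(Biostrings::width(x), names(x))
  } else if (is.numeric(x) && !is.null(names(x))) {
    x
  } else {
    stop("expected a named numeric vector of contig lengths or a DNAStringSet")
  }
}

#' @importFrom methods is
NULL
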