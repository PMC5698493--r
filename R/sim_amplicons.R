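#' Simulate an amplicon read mixture with known cluster fraction
#'
#' Emulates a targeted amplicon survey in which a fraction of reads
#' derive from the gene cluster of interest and the remainder from an
#' unrelated, divergent template. Each read is labelled `cluster` with
#' probability `mixture_fraction` (so the realised cluster fraction is
#' Binomial(n, mixture_fraction)/n); cluster reads are substrings of
#' the reference carrying independent substitution errors at
#' `error_rate`, while decoy reads are drawn from a copy of the
#' reference mutated at `decoy_divergence` of its sites (default 20%,
#' i.e. well below 90% identity).
#'
#' @param reference Cluster reference sequence
#'   ([Biostrings::DNAString] or character), e.g. the amplified
#'   ketosynthase region.
#' @param mixture_fraction Probability that a read derives from the
#'   cluster, in \[0, 1\].
#' @param n_reads Number of reads to simulate.
#' @param error_rate Per-base substitution probability on cluster (and
#'   decoy) reads (default 0.01).
#' @param read_length Read length in bases (default 251, a MiSeq
#'   forward read).
#' @param decoy_divergence Fraction of decoy template sites substituted
#'   relative to the reference (default 0.2).
#' @param seed Integer seed.
#' @return List of class `amplicon_sim`: `reads`
#'   ([Biostrings::DNAStringSet]), `labels` (`data.frame` with `read`,
#'   `label` in {cluster, other}, `start`), `decoy` (the decoy
#'   template as a character string).
#' @export
simulate_amplicons <- function(reference, mixture_fraction, n_reads,
                               error_rate = 0.01, read_length = 251L,
                               decoy_divergence = 0.2, seed = 1L) {
  stopifnot(mixture_fraction >= 0, mixture_fraction <= 1)
  set.seed(seed)
  ref <- toupper(as.character(reference))
  if (nchar(ref) < read_length) {
    stop("reference shorter than the read length")
  }
  decoy <- mutate_seq(ref, decoy_divergence)

  is_cluster <- runif(n_reads) < mixture_fraction
  starts <- sample.int(nchar(ref) - read_length + 1L, n_reads,
                       replace = TRUE)
  reads <- character(n_reads)
  for (i in seq_len(n_reads)) {
    tmpl <- if (is_cluster[i]) ref else decoy
    reads[i] <- mutate_seq(substring(tmpl, starts[i],
                                     starts[i] + read_length - 1L),
                           error_rate)
  }
  ids <- sprintf("amp_%06d", seq_len(n_reads))
  out <- Biostrings::DNAStringSet(reads)
  names(out) <- ids
  structure(list(reads = out,
                 labels = data.frame(read = ids,
                                     label = ifelse(is_cluster, "cluster",
                                                    "other"),
                                     start = starts,
                                     stringsAsFactors = FALSE),
                 decoy = decoy),
            class = "amplicon_sim")
}
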