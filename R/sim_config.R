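#' Simulation configuration for the synthetic symbiont genome
#'
#' Bundles and validates every tunable of the synthetic-data generator.
#' The defaults describe the study conditions used throughout the test
#' suite: a 300-kb chromosome carrying a 20-kb biosynthetic cluster
#' repeated seven times in tandem, with one 2-kb internal deletion
#' carried by two of the seven copies, sequenced as 2 x 101-bp
#' paired-end reads with ~300-bp inserts at 30-fold baseline coverage.
#'
#' @param genome_length Length in bases of the intact chromosome before
#'   any deletions are applied (unique regions plus all cluster copies).
#' @param gc_content GC fraction of the background sequence.
#' @param cluster_length Length in bases of one intact cluster copy.
#' @param n_copies Number of cluster copies (integer >= 1).
#' @param deletions `data.frame` with columns `offset` (1-based start of
#'   the deleted interval within the cluster), `length` (bases) and
#'   `carriers` (number of copies carrying the deletion). Deletions must
#'   be non-overlapping, fit inside the cluster, and each must be carried
#'   by at most `n_copies - 1` copies (the collapsed representative copy
#'   stays intact). `NULL` for none.
#' @param snps Optional `data.frame` with columns `offset` (position
#'   within the cluster), `alt` (alternate base) and `carriers`, planting
#'   point substitutions in a subset of copies. `NULL` for none.
#' @param inverted_copies Integer vector of copy indices placed in
#'   reverse-complement orientation on the chromosome (creates
#'   head-to-head / tail-to-tail junctions).
#' @param read_length Read length in bases (default 101).
#' @param insert_mean,insert_sd Mean and standard deviation in bases of
#'   the (truncated) normal insert-size distribution.
#' @param baseline_depth Fold coverage of single-copy regions.
#' @param pseudogene_fraction Fraction of simulated genes truncated
#'   relative to their homolog.
#' @param truncation_range Length-2 numeric: the truncation fraction of a
#'   pseudogene is drawn uniformly from this interval.
#' @param amplicon_cluster_fraction Fraction of simulated amplicon reads that
#'   derive from the cluster (the rest come from a divergent decoy).
#' @param seed Integer seed controlling every random draw of the
#'   generator.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(genome_length = 50000, cluster_length = 5000,
#'                   n_copies = 3, deletions = NULL)
#' @export
sim_config <- function(genome_length = 300000L,
                       gc_content = 0.52,
                       cluster_length = 20000L,
                       n_copies = 7L,
                       deletions = data.frame(offset = 8001L,
                                              length = 2000L,
                                              carriers = 2L),
                       snps = NULL,
                       inverted_copies = integer(0L),
                       read_length = 101L,
                       insert_mean = 300,
                       insert_sd = 30,
                       baseline_depth = 30,
                       pseudogene_fraction = 0.25,
                       truncation_range = c(0.3, 0.5),
                       amplicon_cluster_fraction = 0.8,
                       seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              gc_content = gc_content,
              cluster_length = as.integer(cluster_length),
              n_copies = as.integer(n_copies),
              deletions = deletions,
              snps = snps,
              inverted_copies = as.integer(inverted_copies),
              read_length = as.integer(read_length),
              insert_mean = insert_mean,
              insert_sd = insert_sd,
              baseline_depth = baseline_depth,
              pseudogene_fraction = pseudogene_fraction,
              truncation_range = truncation_range,
              amplicon_cluster_fraction = amplicon_cluster_fraction,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_copies < 1L) stop("n_copies must be >= 1")
    if (cluster_length * n_copies > genome_length) {
      stop("configuration error: cluster_length * n_copies exceeds genome_length")
    }
    fracs <- c(gc_content, pseudogene_fraction, amplicon_cluster_fraction,
               truncation_range)
    if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
    if (length(truncation_range) != 2L || diff(truncation_range) < 0) {
      stop("truncation_range must be an increasing fraction pair")
    }
    if (2 * read_length > insert_mean + 4 * insert_sd) {
      stop("read_length incompatible with the insert distribution: ",
           "2 * read_length exceeds the insert upper range")
    }
    if (!is.null(deletions)) {
      stopifnot(is.data.frame(deletions),
                all(c("offset", "length", "carriers") %in% names(deletions)))
      if (nrow(deletions)) {
        ends <- deletions$offset + deletions$length - 1L
        if (any(deletions$offset < 1L) || any(ends > cluster_length)) {
          stop("deletion offsets + lengths must fit inside cluster_length")
        }
        if (any(deletions$carriers > n_copies - 1L) ||
            any(deletions$carriers < 0L)) {
          stop("n_carrier_copies must be between 0 and n_copies - 1")
        }
        o <- order(deletions$offset)
        if (nrow(deletions) > 1L &&
            any(deletions$offset[o][-1L] <= ends[o][-nrow(deletions)])) {
          stop("deletions must be non-overlapping")
        }
      }
    }
    if (!is.null(snps) && nrow(snps)) {
      stopifnot(all(c("offset", "alt", "carriers") %in% names(snps)))
      if (any(snps$offset < 1L | snps$offset > cluster_length)) {
        stop("snp offsets must fall inside the cluster")
      }
      if (any(snps$carriers > n_copies - 1L | snps$carriers < 1L)) {
        stop("snp carriers must be between 1 and n_copies - 1")
      }
    }
    if (length(inverted_copies) &&
        (any(inverted_copies < 1L) || any(inverted_copies > n_copies))) {
      stop("inverted_copies must index existing cluster copies")
    }
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sprintf("%d-bp genome, %d-bp cluster x %d copies", x$genome_length,
              x$cluster_length, x$n_copies), "\n")
  ndel <- if (is.null(x$deletions)) 0L else nrow(x$deletions)
  cat(sprintf("  %d deletion(s); reads 2 x %d bp, insert %g +/- %g, depth %gx\n",
              ndel, x$read_length, x$insert_mean, x$insert_sd,
              x$baseline_depth))
  invisible(x)
}
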