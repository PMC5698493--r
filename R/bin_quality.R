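#' Genome-bin completeness from single-copy marker counts
#'
#' Completeness is the number of distinct markers detected at least
#' once, expressed as a percentage of the marker-set size (139 markers
#' in the standard bacterial set of Rinke et al.), reported to one
#' decimal place.
#'
#' @param counts Named (or bare) integer vector of per-marker
#'   occurrence counts in the bin; markers absent from the bin may be
#'   included as zeros or omitted (the set size is given separately).
#' @param set_size Size of the marker set (default 139).
#' @return Completeness percentage, rounded to one decimal.
#' @examples
#' completeness(rep(1L, 131))        # 94.2
#' completeness(rep(1L, 139))        # 100
#' @export
completeness <- function(counts, set_size = 139L) {
  if (set_size <= 0L) stop("marker set size must be positive")
  if (any(counts < 0L)) stop("marker counts must be nonnegative")
  round(100 * sum(counts >= 1L) / set_size, 1L)
}

#' Genome-bin purity from single-copy marker counts
#'
#' Purity is the fraction of detected markers that occur exactly once,
#' as a percentage of the number of detected markers, reported to one
#' decimal place. (Dividing instead by the full set size could never
#' reach 100% for an incomplete bin; the detected-marker denominator is
#' the convention that reproduces a "100% pure" call for a bin whose
#' every found marker is single-copy.)
#'
#' @param counts Named (or bare) integer vector of per-marker counts.
#' @return Purity percentage rounded to one decimal, or `NA` when no
#'   marker is present.
#' @examples
#' purity(rep(1L, 131))              # 100
#' purity(c(rep(1L, 9), 2L))         # 90
#' @export
purity <- function(counts) {
  if (any(counts < 0L)) stop("marker counts must be nonnegative")
  found <- sum(counts >= 1L)
  if (found == 0L) return(NA_real_)
  round(100 * sum(counts == 1L) / found, 1L)
}
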