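#' Segment a depth profile into integer copy-number tiers
#'
#' Windows are assigned the integer nearest to `depth / baseline`
#' (ties, x.5, round up), contiguous runs of equal integers become
#' segments, and segments shorter than `min_segment_length` are merged
#' into whichever neighbour has the closer mean depth — absorbing edge
#' artefacts and lone noisy windows. Each final segment's relative copy
#' number is `round(mean_depth / baseline)`.
#'
#' @param profile A `depth_profile` from [compute_depth()].
#' @param baseline Single-copy baseline depth (> 0), e.g. from
#'   [estimate_baseline()].
#' @param min_segment_length Minimum segment length in bases (default
#'   three windows' worth). A real event must span at least three
#'   windows to be kept as its own segment; shorter runs — lone noisy
#'   windows, contig-edge coverage ramps, and the occasional pair of
#'   adjacent windows that round to the wrong tier — are absorbed into
#'   a neighbour. With the 500-bp default window this makes 1.5 kb the
#'   smallest resolvable deletion.
#' @param tolerance If a segment's `mean_depth / baseline` differs from
#'   its integer copy by more than this, a warning reports the
#'   non-integer ratio (default 0.3).
#' @return An object of class `copy_number_model`: a list with
#'   `baseline`, `segments` (`contig`, `start`, `end`, `mean_depth`,
#'   `copy`) and `assembly_length`.
#' @export
segment_and_round <- function(profile, baseline,
                              min_segment_length = 3L * attr(profile, "window_size"),
                              tolerance = 0.3) {
  stopifnot(baseline > 0)
  if (is.null(min_segment_length)) min_segment_length <- 2500L
  segs <- lapply(split(seq_len(nrow(profile)), profile$contig), function(ix) {
    p <- profile[ix, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    copy <- floor(p$depth / baseline + 0.5)
    r <- rle(copy)
    hi <- cumsum(r$lengths)
    lo <- hi - r$lengths + 1L
    seg <- data.frame(contig = p$contig[1L],
                      start = p$start[lo], end = p$end[hi],
                      mean_depth = vapply(seq_along(lo), function(j) {
                        mean(p$depth[lo[j]:hi[j]])
                      }, numeric(1L)),
                      copy = r$values, stringsAsFactors = FALSE)
    merge_short_segments(seg, baseline, min_segment_length)
  })
  segments <- do.call(rbind, segs)
  rownames(segments) <- NULL
  segments$copy <- as.integer(segments$copy)

  off <- abs(segments$mean_depth / baseline - segments$copy)
  if (any(off > tolerance)) {
    warning(sprintf("%d segment(s) have depth ratios more than %.2f from an integer copy",
                    sum(off > tolerance), tolerance))
  }
  structure(list(baseline = baseline, segments = segments,
                 assembly_length = sum(as.numeric(
                   attr(profile, "contig_lengths")))),
            class = "copy_number_model")
}

# Iteratively merge sub-minimum-length segments into the neighbour with
# the closer mean depth, then collapse adjacent equal-copy runs.
merge_short_segments <- function(seg, baseline, min_len) {
  repeat {
    w <- seg$end - seg$start + 1L
    short <- which(w < min_len)
    if (!length(short) || nrow(seg) == 1L) break
    i <- short[which.min(w[short])]
    left_d <- if (i > 1L) abs(seg$mean_depth[i - 1L] - seg$mean_depth[i]) else Inf
    right_d <- if (i < nrow(seg)) abs(seg$mean_depth[i + 1L] - seg$mean_depth[i]) else Inf
    j <- if (left_d <= right_d) i - 1L else i + 1L
    wi <- w[i]; wj <- seg$end[j] - seg$start[j] + 1L
    md <- (seg$mean_depth[i] * wi + seg$mean_depth[j] * wj) / (wi + wj)
    seg$start[j] <- min(seg$start[i], seg$start[j])
    seg$end[j] <- max(seg$end[i], seg$end[j])
    seg$mean_depth[j] <- md
    seg$copy[j] <- floor(md / baseline + 0.5)
    seg <- seg[-i, , drop = FALSE]
  }
  # collapse adjacent segments that ended up with the same copy number
  repeat {
    same <- which(diff(seg$copy) == 0)
    if (!length(same)) break
    i <- same[1L]
    wi <- seg$end[i] - seg$start[i] + 1L
    wj <- seg$end[i + 1L] - seg$start[i + 1L] + 1L
    seg$mean_depth[i] <- (seg$mean_depth[i] * wi +
                            seg$mean_depth[i + 1L] * wj) / (wi + wj)
    seg$end[i] <- seg$end[i + 1L]
    seg <- seg[-(i + 1L), , drop = FALSE]
  }
  seg
}

#' Count the repeat copies carrying an internal deletion
#'
#' In a collapsed repeat, an internal deletion present in some copies
#' lowers the relative coverage of the deleted interval below that of
#' the flanking repeat: a deleted region at 5x inside a 7x repeat means
#' the deletion occurs in 7 - 5 = 2 of the 7 copies.
#'
#' @param segment_copy Integer relative copy number of the deleted
#'   segment.
#' @param flanking_copy Integer relative copy number of the flanking
#'   (full) repeat.
#' @return The number of copies carrying the deletion,
#'   `flanking_copy - segment_copy`.
#' @examples
#' deletion_carriers(5, 7)  # 2
#' @export
deletion_carriers <- function(segment_copy, flanking_copy) {
  segment_copy <- as.integer(segment_copy)
  flanking_copy <- as.integer(flanking_copy)
  if (any(segment_copy < 0L) || any(flanking_copy < 0L)) {
    stop("copy numbers must be nonnegative integers")
  }
  if (any(segment_copy > flanking_copy)) {
    stop("segment copy exceeds flanking copy: segmentation is inconsistent")
  }
  flanking_copy - segment_copy
}

#' Expand a collapsed assembly to its intact genome size
#'
#' Sums segment length times relative copy number over all segments of
#' a copy-number model: the size the genome would have if every
#' collapsed repeat were written out in full.
#'
#' @param model A `copy_number_model` from [segment_and_round()], or a
#'   bare segment `data.frame` with `start`, `end`, `copy`.
#' @return Intact genome size in bases.
#' @export
expand_genome <- function(model) {
  seg <- if (inherits(model, "copy_number_model")) model$segments else model
  sum((as.numeric(seg$end) - seg$start + 1) * seg$copy)
}

#' Per-gene dosage and genome fractions
#'
#' A gene's effective copy count is the minimum relative copy number
#' over the model segments it overlaps: a gene overlapping a deleted
#' interval (carried by some copies) is intact only in the copies
#' without the deletion, which is exactly the lower tier of the deleted
#' segment. Totals are expressed against the expanded (intact) genome
#' size and against the expanded coding capacity.
#'
#' @param genes Gene table with columns `id`, `contig`, `start`, `end`
#'   (1-based inclusive).
#' @param model A `copy_number_model`.
#' @param cluster_genes Optional character vector of gene ids forming
#'   the cluster of interest; totals (`total_intact_bp` and the two
#'   fractions) are computed over this subset (default: all genes).
#' @return A list of class `dosage_summary`: `genes` (the input plus
#'   `copy` and `intact_bp`), `total_intact_bp`, `intact_genome_size`,
#'   `coding_capacity_bp`, `fraction_of_genome` (percent),
#'   `fraction_of_coding` (percent).
#' @export
gene_dosage <- function(genes, model, cluster_genes = NULL) {
  stopifnot(inherits(model, "copy_number_model"))
  seg <- model$segments
  copy <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ci <- seg$contig == g$contig
    if (!any(ci)) {
      stop(sprintf("gene %s lies outside the segmented contigs", g$id))
    }
    if (g$start < min(seg$start[ci]) || g$end > max(seg$end[ci])) {
      stop(sprintf("gene %s extends beyond contig bounds", g$id))
    }
    ov <- ci & seg$start <= g$end & seg$end >= g$start
    min(seg$copy[ov])
  }, numeric(1L))
  genes$copy <- as.integer(copy)
  genes$intact_bp <- (genes$end - genes$start + 1L) * genes$copy

  sel <- if (is.null(cluster_genes)) rep(TRUE, nrow(genes))
         else genes$id %in% cluster_genes
  total_intact <- sum(as.numeric(genes$intact_bp[sel]))
  intact_size <- expand_genome(model)
  coding_capacity <- sum(as.numeric(genes$intact_bp))
  structure(list(genes = genes,
                 total_intact_bp = total_intact,
                 intact_genome_size = intact_size,
                 coding_capacity_bp = coding_capacity,
                 fraction_of_genome = 100 * total_intact / intact_size,
                 fraction_of_coding = 100 * total_intact / coding_capacity),
            class = "dosage_summary")
}

#' @export
print.copy_number_model <- function(x, ...) {
  cat(sprintf("copy_number_model: baseline %.2fx, %d segment(s), assembly %.0f bp, intact %.0f bp\n",
              x$baseline, nrow(x$segments), x$assembly_length,
              expand_genome(x)))
  print(x$segments, ...)
  invisible(x)
}

#' @export
print.dosage_summary <- function(x, ...) {
  cat(sprintf("dosage_summary: %d genes, %.0f intact bp = %.1f%% of the %.0f-bp intact genome (%.1f%% of coding capacity)\n",
              nrow(x$genes), x$total_intact_bp, x$fraction_of_genome,
              x$intact_genome_size, x$fraction_of_coding))
  invisible(x)
}
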