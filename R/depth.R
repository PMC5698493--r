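#' Windowed read-depth profile from alignments
#'
#' Computes per-base pileup depth on each contig (via run-length
#' coverage vectors) and averages it over non-overlapping windows.
#' Windows tile each contig; the last window of a contig may be short.
#' Unmapped records and secondary-style records (mapq below
#' `min_mapq`) are ignored; contigs with no aligned reads are still
#' reported, with depth 0.
#'
#' @param aln Alignment table (see [simulate_reads()] / [read_sam()]).
#' @param contigs Named vector of contig lengths or a
#'   [Biostrings::DNAStringSet].
#' @param window_size Window width in bases (default 500).
#' @param min_mapq Minimum mapping quality (default 0).
#' @return A `data.frame` of class `depth_profile` with columns
#'   `contig`, `start`, `end`, `depth`, and a `window_size` attribute.
#' @examples
#' lens <- c(chr = 1000)
#' aln <- data.frame(qname = "r1", mate = 1L, rname = "chr", pos = 1L,
#'                   mapq = 60L, strand = "+", cigar = "100M",
#'                   seq = NA, rnext = NA, pnext = NA, tlen = 0L,
#'                   mapped = TRUE)
#' compute_depth(aln, lens, window_size = 1000)$depth  # 0.1
#' @export
compute_depth <- function(aln, contigs, window_size = 500L, min_mapq = 0L) {
  if (window_size <= 0L) stop("window_size must be positive")
  lens <- contig_lengths_of(contigs)
  use <- aln[aln$mapped & aln$mapq >= min_mapq, , drop = FALSE]
  widths <- cigar_ref_width(use$cigar)

  out <- lapply(names(lens), function(ctg) {
    len <- as.integer(lens[[ctg]])
    sel <- which(use$rname == ctg)
    if (length(sel)) {
      r <- IRanges::IRanges(start = use$pos[sel], width = widths[sel])
      r <- IRanges::restrict(r, start = 1L, end = len)
      cov <- IRanges::coverage(r, width = len)
    } else {
      cov <- S4Vectors::Rle(0L, len)
    }
    ws <- seq.int(1L, len, by = window_size)
    we <- pmin(ws + window_size - 1L, len)
    v <- IRanges::Views(cov, start = ws, end = we)
    data.frame(contig = ctg, start = ws, end = we,
               depth = IRanges::viewMeans(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "window_size") <- as.integer(window_size)
  attr(out, "contig_lengths") <- lens
  class(out) <- c("depth_profile", "data.frame")
  out
}

#' Estimate the single-copy baseline depth
#'
#' The baseline is the median of per-window depths over user-designated
#' single-copy regions (for example, unique contigs flanking a repeat).
#' The median is robust to residual repeated windows inside the
#' designated regions.
#'
#' @param profile A `depth_profile` from [compute_depth()].
#' @param single_copy_regions Either a character vector of contig names
#'   or a `data.frame` with columns `contig`, `start`, `end`. Windows
#'   fully inside the regions contribute.
#' @return The baseline depth (fold coverage), a single number.
#' @export
estimate_baseline <- function(profile, single_copy_regions) {
  if (is.character(single_copy_regions)) {
    keep <- profile$contig %in% single_copy_regions
  } else {
    stopifnot(is.data.frame(single_copy_regions))
    keep <- rep(FALSE, nrow(profile))
    for (i in seq_len(nrow(single_copy_regions))) {
      r <- single_copy_regions[i, ]
      keep <- keep | (profile$contig == r$contig &
                        profile$start >= r$start & profile$end <= r$end)
    }
  }
  if (!any(keep)) stop("no windows fall in the designated single-copy regions")
  median(profile$depth[keep])
}
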