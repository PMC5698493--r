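#' Detect intra-repeat SNPs by pileup over a collapsed contig
#'
#' When near-identical repeat copies are collapsed onto one contig,
#' substitutions private to a subset of copies appear as minor-allele
#' positions in the pileup: a variant carried by 1 of 7 copies shows an
#' alternate-base fraction near 1/7. Positions where the most common
#' non-reference base reaches `min_alt_fraction` at depth `min_depth`
#' are reported. Fixed differences (alternate fraction 1, no reference
#' base observed) are not SNPs among copies and are excluded.
#'
#' @param aln Alignment table restricted (or restrictable) to one
#'   contig; records on other contigs are ignored.
#' @param reference Reference sequence of the contig
#'   ([Biostrings::DNAString] or character).
#' @param contig Contig name to scan.
#' @param min_alt_fraction Minimum alternate-base fraction (default 0.1).
#' @param min_depth Minimum pileup depth (default 10).
#' @return `data.frame` with columns `contig`, `pos`, `ref`, `alt`,
#'   `alt_fraction`, `depth`.
#' @export
detect_repeat_snps <- function(aln, reference, contig,
                               min_alt_fraction = 0.1, min_depth = 10L) {
  ref_chars <- strsplit(toupper(as.character(reference)), NULL)[[1L]]
  len <- length(ref_chars)
  use <- aln[aln$mapped & aln$rname == contig, , drop = FALSE]

  counts <- matrix(0L, nrow = 4L, ncol = len,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  if (nrow(use)) {
    lead <- integer(nrow(use))
    has_clip <- grepl("^\\d+S", use$cigar)
    lead[has_clip] <- as.integer(sub("^(\\d+)S.*", "\\1",
                                     use$cigar[has_clip]))
    widths <- cigar_ref_width(use$cigar)
    aligned <- substring(use$seq, lead + 1L, lead + widths)
    pos_list <- mapply(function(p, w) seq.int(p, p + w - 1L),
                       use$pos, widths, SIMPLIFY = FALSE)
    all_pos <- unlist(pos_list, use.names = FALSE)
    all_base <- unlist(strsplit(aligned, NULL), use.names = FALSE)
    ok <- all_pos >= 1L & all_pos <= len & all_base %in% rownames(counts)
    all_pos <- all_pos[ok]; all_base <- all_base[ok]
    for (b in rownames(counts)) {
      counts[b, ] <- tabulate(all_pos[all_base == b], nbins = len)
    }
  }
  depth <- colSums(counts)
  ref_idx <- match(ref_chars, rownames(counts))
  ref_count <- ifelse(is.na(ref_idx), 0L,
                      counts[cbind(ref_idx, seq_len(len))])
  alt_counts <- counts
  alt_counts[cbind(ref_idx[!is.na(ref_idx)], which(!is.na(ref_idx)))] <- 0L
  alt_best <- apply(alt_counts, 2L, max)
  alt_base <- rownames(counts)[apply(alt_counts, 2L, which.max)]
  alt_fraction <- ifelse(depth > 0, alt_best / depth, 0)

  hit <- which(depth >= min_depth & alt_fraction >= min_alt_fraction &
                 ref_count > 0L)
  data.frame(contig = rep(contig, length(hit)), pos = hit,
             ref = ref_chars[hit], alt = alt_base[hit],
             alt_fraction = alt_fraction[hit], depth = depth[hit],
             stringsAsFactors = FALSE)
}
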