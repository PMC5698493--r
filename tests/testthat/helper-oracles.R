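# Independent brute-force oracles used to cross-check the package's
# optimised implementations on small instances.

# per-base pileup depth, averaged over windows, computed position by
# position with no coverage machinery
bf_windowed_depth <- function(pos, width, contig_len, window_size) {
  depth <- numeric(contig_len)
  for (i in seq_along(pos)) {
    p <- pos[i]:(pos[i] + width[i] - 1L)
    p <- p[p >= 1L & p <= contig_len]
    depth[p] <- depth[p] + 1
  }
  ws <- seq(1L, contig_len, by = window_size)
  we <- pmin(ws + window_size - 1L, contig_len)
  vapply(seq_along(ws), function(j) mean(depth[ws[j]:we[j]]), numeric(1))
}

# exhaustive single change-point search minimising within-segment
# sum of squares over a window-depth vector
bf_changepoint <- function(d) {
  n <- length(d)
  sse <- vapply(1:(n - 1L), function(t) {
    sum((d[1:t] - mean(d[1:t]))^2) + sum((d[(t + 1):n] - mean(d[(t + 1):n]))^2)
  }, numeric(1))
  which.min(sse)  # last window of the left segment
}

# all maximal exact matches > min_len in a single sequence, both
# strands, by full diagonal scanning (no seeding)
bf_repeats <- function(seq, min_len) {
  s <- strsplit(seq, NULL)[[1L]]
  n <- length(s)
  rows <- list()
  emit <- function(a1, a2, b1, b2, ori) {
    if (a1 == b1 && a2 == b2) return()
    if (b1 < a1) { tmp <- c(a1, a2); a1 <- b1; a2 <- b2; b1 <- tmp[1]; b2 <- tmp[2] }
    rows[[length(rows) + 1L]] <<- data.frame(
      start_a = a1, end_a = a2, start_b = b1, end_b = b2,
      length = a2 - a1 + 1L, orientation = ori, stringsAsFactors = FALSE)
  }
  for (d in 1:(n - 1L)) {          # direct, offset d
    idx <- 1:(n - d)
    eq <- s[idx] == s[idx + d]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths > min_len)) {
      emit(starts[j], ends[j], starts[j] + d, ends[j] + d, "direct")
    }
  }
  rc <- strsplit(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq))), NULL)[[1L]]
  for (d in -(n - 1L):(n - 1L)) {  # inverted: s vs revcomp(s)
    idx <- max(1L, 1L - d):min(n, n - d)
    eq <- s[idx] == rc[idx + d]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values & r$lengths > min_len)) {
      a1 <- idx[1L] + starts[j] - 1L; a2 <- idx[1L] + ends[j] - 1L
      rb1 <- a1 + d; rb2 <- a2 + d       # run interval in rc coordinates
      b1 <- n - rb2 + 1L; b2 <- n - rb1 + 1L
      emit(a1, a2, b1, b2, "inverted")
    }
  }
  if (!length(rows)) {
    return(data.frame(start_a = integer(0), end_a = integer(0),
                      start_b = integer(0), end_b = integer(0),
                      length = integer(0), orientation = character(0)))
  }
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$start_a, out$start_b, out$orientation), ]
  rownames(out) <- NULL
  out
}

# union length of 1-based inclusive intervals by sort-and-sweep
bf_union_length <- function(start, end) {
  if (!length(start)) return(0L)
  o <- order(start)
  start <- start[o]; end <- end[o]
  tot <- 0L
  cur_s <- start[1L]; cur_e <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= cur_e + 1L) {
      cur_e <- max(cur_e, end[i])
    } else {
      tot <- tot + (cur_e - cur_s + 1L)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  tot + (cur_e - cur_s + 1L)
}

# per-copy enumeration of gene dosage: a gene is intact in a copy unless
# one of the copy's deletions overlaps it
bf_gene_copy_count <- function(gene_start, gene_end, n_copies, deletions) {
  intact <- 0L
  for (i in seq_len(n_copies)) {
    dels <- deletions[i >= 2L & i <= 1L + deletions$carriers, , drop = FALSE]
    hit <- FALSE
    for (j in seq_len(nrow(dels))) {
      ds <- dels$offset[j]; de <- ds + dels$length[j] - 1L
      if (ds <= gene_end && de >= gene_start) hit <- TRUE
    }
    if (!hit) intact <- intact + 1L
  }
  intact
}

# small helper: minimal alignment table row(s)
make_aln <- function(qname, mate, rname, pos, strand, width = 101L,
                     mapq = 60L, seq = NA_character_) {
  n <- length(qname)
  data.frame(qname = qname, mate = rep_len(mate, n), rname = rname,
             pos = pos, mapq = rep_len(mapq, n), strand = strand,
             cigar = rep_len(paste0(width, "M"), n),
             seq = rep_len(seq, n), rnext = rep_len(NA_character_, n),
             pnext = rep_len(NA_integer_, n), tlen = rep_len(0L, n),
             mapped = !is.na(pos),
             stringsAsFactors = FALSE)
}

# depth profile constructed directly from window depths
make_profile <- function(depths, contig = "ctg", window_size = 500L,
                         contig_len = length(depths) * window_size) {
  ws <- seq(1L, by = window_size, length.out = length(depths))
  out <- data.frame(contig = contig, start = ws,
                    end = pmin(ws + window_size - 1L, contig_len),
                    depth = depths, stringsAsFactors = FALSE)
  attr(out, "window_size") <- as.integer(window_size)
  attr(out, "contig_lengths") <- stats::setNames(contig_len, contig)
  class(out) <- c("depth_profile", "data.frame")
  out
}
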