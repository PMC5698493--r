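#' Find exact repeats by genome self-comparison
#'
#' Reports maximal exact matches longer than `min_length` (strict)
#' between distinct positions of the genome, on both strands, the way
#' a genome-vs-self alignment is used to quantify repeat content.
#' Matches are seeded with (`min_length` + 1)-mers shared between two
#' positions and extended to maximality; self-hits (identical
#' coordinates) and symmetric duplicates are removed, and seeds falling
#' inside an already-reported match on the same alignment diagonal are
#' skipped, so each maximal match is reported once.
#'
#' @param genome [Biostrings::DNAStringSet] or named character vector
#'   of contig sequences.
#' @param min_length Minimum repeat length, strict `>` (default 50).
#' @return `data.frame` of class `repeat_loci` with columns `contig_a`,
#'   `start_a`, `end_a`, `contig_b`, `start_b`, `end_b`, `length`,
#'   `orientation` (`direct` or `inverted`).
#' @export
find_repeats <- function(genome, min_length = 50L) {
  if (min_length <= 0L) stop("min_length must be positive")
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else {
    seqs <- genome
  }
  if (is.null(names(seqs))) names(seqs) <- sprintf("contig_%d", seq_along(seqs))
  empty <- data.frame(contig_a = character(0), start_a = integer(0),
                      end_a = integer(0), contig_b = character(0),
                      start_b = integer(0), end_b = integer(0),
                      length = integer(0), orientation = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("repeat_loci", "data.frame")
  if (!length(seqs) || all(nchar(seqs) == 0L)) return(empty)

  k <- as.integer(min_length) + 1L
  chars_fwd <- lapply(seqs, function(s) strsplit(s, NULL)[[1L]])
  chars_rc <- lapply(seqs, function(s) strsplit(revcomp(s), NULL)[[1L]])

  occ <- list()
  for (ci in names(seqs)) {
    n <- nchar(seqs[[ci]])
    if (n >= k) {
      km <- substring(seqs[[ci]], 1:(n - k + 1L), k:n)
      occ[[length(occ) + 1L]] <- data.frame(kmer = km, contig = ci,
                                            pos = 1:(n - k + 1L),
                                            strand = "+",
                                            stringsAsFactors = FALSE)
      rc <- revcomp(seqs[[ci]])
      km <- substring(rc, 1:(n - k + 1L), k:n)
      occ[[length(occ) + 1L]] <- data.frame(kmer = km, contig = ci,
                                            pos = 1:(n - k + 1L),
                                            strand = "-",
                                            stringsAsFactors = FALSE)
    }
  }
  occ <- do.call(rbind, occ)
  if (is.null(occ)) return(empty)
  groups <- split(seq_len(nrow(occ)), occ$kmer)
  groups <- groups[vapply(groups, length, 0L) >= 2L]

  covered <- new.env(parent = emptyenv())
  results <- list()
  for (g in groups) {
    for (a_i in seq_len(length(g) - 1L)) {
      for (b_i in (a_i + 1L):length(g)) {
        x <- occ[g[a_i], ]; y <- occ[g[b_i], ]
        if (x$strand == "-" && y$strand == "-") next  # mirror of (+,+)
        if (x$strand == "-") { tmp <- x; x <- y; y <- tmp }
        m <- extend_match(x, y, k, chars_fwd, chars_rc, covered,
                          nchar(seqs))
        if (!is.null(m)) results[[length(results) + 1L]] <- m
      }
    }
  }
  if (!length(results)) return(empty)
  out <- unique(do.call(rbind, results))
  out <- out[out$length > min_length, , drop = FALSE]
  out <- out[order(out$contig_a, out$start_a, out$contig_b, out$start_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("repeat_loci", "data.frame")
  out
}

# extend one seeded pair to its maximal exact match; x is always on the
# forward strand, y on forward (direct) or the reverse-complement
# strand (inverted, in rc-space coordinates)
extend_match <- function(x, y, k, chars_fwd, chars_rc, covered, lens) {
  inverted <- y$strand == "-"
  sa <- chars_fwd[[x$contig]]
  sb <- if (inverted) chars_rc[[y$contig]] else chars_fwd[[y$contig]]
  ia <- x$pos; ib <- y$pos
  if (!inverted && x$contig == y$contig && ia == ib) return(NULL)

  key <- if (inverted) sprintf("I|%s|%s|%d", x$contig, y$contig, ia + ib)
         else sprintf("D|%s|%s|%d", x$contig, y$contig, ib - ia)
  cov <- covered[[key]]
  if (!is.null(cov) && any(ia >= cov[, 1L] & ia <= cov[, 2L])) return(NULL)

  m <- min(ia, ib) - 1L
  lext <- 0L
  if (m > 0L) {
    xx <- sa[(ia - m):(ia - 1L)]; yy <- sb[(ib - m):(ib - 1L)]
    ne <- which(xx != yy)
    lext <- if (length(ne)) m - max(ne) else m
  }
  m <- min(length(sa) - (ia + k - 1L), length(sb) - (ib + k - 1L))
  rext <- 0L
  if (m > 0L) {
    xx <- sa[(ia + k):(ia + k - 1L + m)]; yy <- sb[(ib + k):(ib + k - 1L + m)]
    ne <- which(xx != yy)
    rext <- if (length(ne)) min(ne) - 1L else m
  }
  a1 <- ia - lext; a2 <- ia + k - 1L + rext
  b1 <- ib - lext; b2 <- ib + k - 1L + rext
  covered[[key]] <- rbind(cov, c(a1, a2))

  if (inverted) {
    nb <- lens[[y$contig]]
    bf1 <- nb - b2 + 1L; bf2 <- nb - b1 + 1L
  } else {
    bf1 <- b1; bf2 <- b2
  }
  if (x$contig == y$contig && a1 == bf1 && a2 == bf2) return(NULL)

  row <- data.frame(contig_a = x$contig, start_a = a1, end_a = a2,
                    contig_b = y$contig, start_b = bf1, end_b = bf2,
                    length = a2 - a1 + 1L,
                    orientation = if (inverted) "inverted" else "direct",
                    stringsAsFactors = FALSE)
  # canonical interval order removes symmetric duplicates
  if (row$contig_b < row$contig_a ||
      (row$contig_b == row$contig_a && row$start_b < row$start_a)) {
    row <- data.frame(contig_a = row$contig_b, start_a = row$start_b,
                      end_a = row$end_b, contig_b = row$contig_a,
                      start_b = row$start_a, end_b = row$end_a,
                      length = row$length, orientation = row$orientation,
                      stringsAsFactors = FALSE)
  }
  row
}

#' Summarise repeat content
#'
#' The repeat span is the length of the merged union of every interval
#' participating in a repeat (both sides of each match); the locus
#' count is the number of merged intervals.
#'
#' @param loci A `repeat_loci` table from [find_repeats()].
#' @param genome_length Total genome length in bases.
#' @return List: `repeat_span` (bases), `n_loci`, `repeat_fraction`
#'   (percent of the genome).
#' @examples
#' loci <- data.frame(contig_a = "c", start_a = 1, end_a = 100,
#'                    contig_b = "c", start_b = 901, end_b = 1000,
#'                    length = 100, orientation = "direct")
#' summarize_repeats(loci, 10000)  # span 200, 2 loci, 2%
#' @export
summarize_repeats <- function(loci, genome_length) {
  if (!nrow(loci)) {
    return(list(repeat_span = 0L, n_loci = 0L, repeat_fraction = 0))
  }
  iv <- rbind(data.frame(contig = loci$contig_a, start = loci$start_a,
                         end = loci$end_a),
              data.frame(contig = loci$contig_b, start = loci$start_b,
                         end = loci$end_b))
  merged <- lapply(split(iv, iv$contig), function(d) {
    IRanges::reduce(IRanges::IRanges(d$start, d$end))
  })
  span <- sum(vapply(merged, function(r) sum(IRanges::width(r)), 0))
  n_loci <- sum(vapply(merged, length, 0L))
  list(repeat_span = span, n_loci = n_loci,
       repeat_fraction = 100 * span / genome_length)
}
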