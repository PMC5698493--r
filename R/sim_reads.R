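#' Simulate paired-end reads and their collapsed-assembly alignments
#'
#' Draws fragment positions uniformly along the intact chromosome with
#' insert sizes from a normal distribution truncated at twice the read
#' length, then projects both mates onto the collapsed assembly through
#' the simulator's block map, so that reads from any cluster copy align
#' to the single collapsed copy. Reads whose body crosses a copy
#' junction or deletion breakpoint keep their longer side and are
#' soft-clipped on the other, the way a local aligner places
#' junction-spanning reads; together with their mates they provide the
#' junction-spanning pair evidence mined by [mine_joins()].
#'
#' @param sim A `bgc_sim` object from [build_genome()].
#' @param depth Target fold coverage (default: the configured baseline
#'   depth). The number of pairs is Poisson with mean
#'   `depth * intact_length / (2 * read_length)`.
#' @param seed Integer seed (default derived from the configuration).
#' @return A `data.frame` of class `bgc_alignments` with one row per
#'   read: `qname`, `mate` (1 or 2), `rname`, `pos` (1-based leftmost),
#'   `mapq`, `strand`, `cigar`, `seq` (reference-forward orientation),
#'   `rnext`, `pnext`, `tlen`, `mapped`, and the truth column
#'   `chrom_start`.
#' @examples
#' sim <- build_genome(sim_config(genome_length = 30000,
#'                                cluster_length = 4000, n_copies = 2,
#'                                deletions = NULL, seed = 3))
#' aln <- simulate_reads(sim, depth = 5)
#' table(aln$rname, useNA = "ifany")
#' @export
simulate_reads <- function(sim, depth = sim$config$baseline_depth,
                           seed = sim$config$seed + 1L) {
  stopifnot(inherits(sim, "bgc_sim"), depth >= 0)
  cfg <- sim$config
  rl <- cfg$read_length
  set.seed(seed)

  glen <- sim$truth$intact_length
  n_pairs <- rpois(1L, depth * glen / (2 * rl))
  if (n_pairs == 0L) {
    return(empty_alignments())
  }

  inserts <- as.integer(round(rnorm(n_pairs, cfg$insert_mean, cfg$insert_sd)))
  inserts <- pmax(inserts, 2L * rl)
  inserts <- pmin(inserts, glen)
  starts <- as.integer(floor(runif(n_pairs) * (glen - inserts + 1))) + 1L
  ends <- starts + inserts - 1L

  txt <- as.character(sim$intact)
  r1 <- map_interval(sim$blocks, starts, starts + rl - 1L)
  r2 <- map_interval(sim$blocks, ends - rl + 1L, ends)

  seq1 <- substring(txt, starts, starts + rl - 1L)
  seq2 <- substring(txt, ends - rl + 1L, ends)
  # store reference-forward sequence (SAM convention)
  flip1 <- r1$mapped & r1$block_strand == "-"
  flip2 <- r2$mapped & r2$block_strand == "-"
  seq1[flip1] <- vapply(seq1[flip1], revcomp, "")
  # mate 2 is read off the minus strand of the chromosome; its
  # reference-forward sequence is the chromosome-forward substring
  # unless the block itself is inverted
  seq2[flip2] <- vapply(seq2[flip2], revcomp, "")

  strand1 <- ifelse(flip1, "-", "+")
  strand2 <- ifelse(flip2, "+", "-")

  qname <- sprintf("pair_%06d", seq_len(n_pairs))
  cigar_of <- function(m) {
    # clips are recorded on the chromosome; reference order flips on
    # minus-strand blocks
    cl <- ifelse(m$block_strand == "-", m$clip_r, m$clip_l)
    cr <- ifelse(m$block_strand == "-", m$clip_l, m$clip_r)
    paste0(ifelse(cl > 0L, paste0(cl, "S"), ""), m$m_len, "M",
           ifelse(cr > 0L, paste0(cr, "S"), ""))
  }
  mk <- function(mate, m, seqs, strands, other) {
    data.frame(qname = qname, mate = mate,
               rname = ifelse(m$mapped, m$contig, NA_character_),
               pos = ifelse(m$mapped, m$pos, NA_integer_),
               mapq = ifelse(m$mapped, 60L, 0L),
               strand = ifelse(m$mapped, strands, NA_character_),
               cigar = ifelse(m$mapped, cigar_of(m), "*"),
               seq = seqs,
               rnext = ifelse(other$mapped, other$contig, NA_character_),
               pnext = ifelse(other$mapped, other$pos, NA_integer_),
               tlen = 0L,
               mapped = m$mapped,
               stringsAsFactors = FALSE)
  }
  a1 <- mk(1L, r1, seq1, strand1, r2)
  a2 <- mk(2L, r2, seq2, strand2, r1)
  a1$chrom_start <- starts
  a2$chrom_start <- ends - rl + 1L

  both <- a1$mapped & a2$mapped & a1$rname == a2$rname
  both[is.na(both)] <- FALSE
  lo <- pmin(a1$pos, a2$pos)
  hi <- pmax(a1$pos + r1$m_len - 1L, a2$pos + r2$m_len - 1L)
  span <- hi - lo + 1L
  a1$tlen[both] <- ifelse(a1$pos[both] <= a2$pos[both], span[both], -span[both])
  a2$tlen[both] <- -a1$tlen[both]

  out <- rbind(a1, a2)
  out <- out[order(out$qname, out$mate), ]
  rownames(out) <- NULL
  class(out) <- c("bgc_alignments", "data.frame")
  out
}

empty_alignments <- function() {
  out <- data.frame(qname = character(0), mate = integer(0),
                    rname = character(0), pos = integer(0),
                    mapq = integer(0), strand = character(0),
                    cigar = character(0), seq = character(0),
                    rnext = character(0), pnext = integer(0),
                    tlen = integer(0), mapped = logical(0),
                    chrom_start = integer(0), stringsAsFactors = FALSE)
  class(out) <- c("bgc_alignments", "data.frame")
  out
}

# Project intact-chromosome intervals [s, e] through the block map.
# Intervals fully inside one block map gaplessly; intervals crossing a
# junction keep their majority side and soft-clip the rest, the way a
# local aligner places a junction-spanning read. clip_l/clip_r are the
# clipped lengths on the chromosome-left/right side of the kept part.
map_interval <- function(blocks, s, e) {
  idx_s <- findInterval(s, blocks$chrom_start)
  idx_e <- findInterval(e, blocks$chrom_start)
  clean <- idx_e == idx_s
  len_l <- blocks$chrom_end[idx_s] - s + 1L
  len_r <- e - blocks$chrom_start[idx_e] + 1L
  keep_left <- clean | len_l >= len_r
  idx <- ifelse(keep_left, idx_s, idx_e)
  ks <- ifelse(keep_left, s, blocks$chrom_start[idx_e])
  ke <- ifelse(keep_left, pmin(e, blocks$chrom_end[idx_s]), e)
  strand <- blocks$strand[idx]
  pos <- ifelse(strand == "-",
                blocks$contig_start[idx] + (blocks$chrom_end[idx] - ke),
                blocks$contig_start[idx] + (ks - blocks$chrom_start[idx]))
  data.frame(mapped = rep(TRUE, length(s)), contig = blocks$contig[idx],
             pos = as.integer(pos), block_strand = strand,
             clip_l = as.integer(ks - s), clip_r = as.integer(e - ke),
             m_len = as.integer(ke - ks + 1L), stringsAsFactors = FALSE)
}
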