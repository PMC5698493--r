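#' Build a synthetic chromosome with a repeated gene cluster
#'
#' Constructs (i) the *intact chromosome*: a linear sequence consisting
#' of a left unique arm, `n_copies` of a cluster unit laid out in
#' tandem (optionally with some copies inverted and some carrying
#' internal deletions), and a right unique arm; and (ii) the *collapsed
#' assembly*: three contigs (`unique_left`, `cluster`, `unique_right`)
#' in which all cluster copies are represented by a single intact copy,
#' the way a short-read assembler collapses near-identical repeats.
#' A truth set records copy numbers, deletion carriers, planted SNPs and
#' all copy junctions for downstream scoring.
#'
#' Deletion (and SNP) carriers are assigned deterministically to copies
#' `2 .. 1 + carriers`, so copy 1 always equals the collapsed
#' representative and the length bookkeeping
#' `intact = collapsed + sum over extra copies of (cluster - carried deletions)`
#' holds exactly.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `bgc_sim`: a list with elements
#'   `config`, `intact` ([Biostrings::DNAString]), `collapsed`
#'   ([Biostrings::DNAStringSet] of the three contigs), `blocks` (the
#'   piecewise-linear map from intact-chromosome coordinates to
#'   collapsed-assembly coordinates) and `truth` (see Details).
#' @details The truth set is a list with `segments` (contig, start, end,
#'   copy), `deletion_carriers`, `snps`, `junctions` (endpoint pair,
#'   orientation), `intact_length` and `collapsed_length`.
#' @examples
#' sim <- build_genome(sim_config(genome_length = 50000,
#'                                cluster_length = 5000, n_copies = 3,
#'                                deletions = NULL, seed = 7))
#' names(sim$collapsed)
#' sim$truth$intact_length
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  k <- config$n_copies
  clen <- config$cluster_length
  unique_len <- config$genome_length - k * clen
  left_len <- unique_len %/% 2L
  right_len <- unique_len - left_len
  if (left_len < 1L || right_len < 1L) {
    stop("configuration error: no room for unique regions around the cluster")
  }

  left_seq <- random_dna(left_len, config$gc_content)
  cluster_seq <- random_dna(clen, config$gc_content)
  right_seq <- random_dna(right_len, config$gc_content)

  dels <- config$deletions
  if (is.null(dels)) dels <- data.frame(offset = integer(0),
                                        length = integer(0),
                                        carriers = integer(0))
  dels <- dels[order(dels$offset), , drop = FALSE]
  snps <- config$snps
  if (is.null(snps)) snps <- data.frame(offset = integer(0),
                                        alt = character(0),
                                        carriers = integer(0))

  # copy i carries deletion/snp j iff 2 <= i <= 1 + carriers_j
  carries <- function(i, carriers) i >= 2L & i <= 1L + carriers

  units <- list(list(name = "unique_left", seq = left_seq,
                     contig = "unique_left", pieces = NULL, strand = "+"))
  for (i in seq_len(k)) {
    di <- dels[carries(i, dels$carriers), , drop = FALSE]
    keep <- IRanges::setdiff(IRanges::IRanges(1L, clen),
                             IRanges::IRanges(di$offset, width = di$length))
    chars <- strsplit(cluster_seq, NULL)[[1L]]
    si <- snps[carries(i, snps$carriers), , drop = FALSE]
    if (nrow(si)) {
      in_del <- si$offset %in% unlist(mapply(seq, di$offset,
                                             di$offset + di$length - 1L,
                                             SIMPLIFY = FALSE))
      si <- si[!in_del, , drop = FALSE]
      chars[si$offset] <- si$alt
    }
    piece_df <- data.frame(start = IRanges::start(keep),
                           end = IRanges::end(keep))
    seq_i <- paste(chars[unlist(mapply(seq, piece_df$start, piece_df$end,
                                       SIMPLIFY = FALSE))], collapse = "")
    strand_i <- if (i %in% config$inverted_copies) "-" else "+"
    if (strand_i == "-") seq_i <- revcomp(seq_i)
    units[[length(units) + 1L]] <- list(name = sprintf("copy_%d", i),
                                        seq = seq_i, contig = "cluster",
                                        pieces = piece_df, strand = strand_i)
  }
  units[[length(units) + 1L]] <- list(name = "unique_right", seq = right_seq,
                                      contig = "unique_right", pieces = NULL,
                                      strand = "+")

  intact <- paste(vapply(units, `[[`, "", "seq"), collapse = "")

  # ---- block map: intact-chromosome intervals -> collapsed coordinates ----
  blocks <- list()
  cursor <- 1L
  for (u in units) {
    ulen <- nchar(u$seq)
    if (is.null(u$pieces)) {
      blocks[[length(blocks) + 1L]] <- data.frame(
        chrom_start = cursor, chrom_end = cursor + ulen - 1L,
        contig = u$contig, contig_start = 1L, contig_end = ulen,
        strand = "+", unit = u$name)
    } else {
      p <- u$pieces
      if (u$strand == "-") p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
      pos <- cursor
      for (j in seq_len(nrow(p))) {
        w <- p$end[j] - p$start[j] + 1L
        blocks[[length(blocks) + 1L]] <- data.frame(
          chrom_start = pos, chrom_end = pos + w - 1L,
          contig = "cluster", contig_start = p$start[j],
          contig_end = p$end[j], strand = u$strand, unit = u$name)
        pos <- pos + w
      }
    }
    cursor <- cursor + ulen
  }
  blocks <- do.call(rbind, blocks)
  intact_length <- cursor - 1L
  stopifnot(intact_length == nchar(intact))

  collapsed <- Biostrings::DNAStringSet(c(unique_left = left_seq,
                                          cluster = cluster_seq,
                                          unique_right = right_seq))

  truth <- list(
    segments = truth_segments(left_len, right_len, clen, k, dels),
    deletion_carriers = dels,
    snps = snps,
    junctions = truth_junctions(units, dels),
    intact_length = intact_length,
    collapsed_length = left_len + clen + right_len
  )

  structure(list(config = config, intact = Biostrings::DNAString(intact),
                 collapsed = collapsed, blocks = blocks, truth = truth),
            class = "bgc_sim")
}

# Ground-truth copy-number segments over the collapsed assembly.
truth_segments <- function(left_len, right_len, clen, k, dels) {
  seg <- data.frame(contig = c("unique_left", "unique_right"),
                    start = c(1L, 1L), end = c(left_len, right_len),
                    copy = c(1L, 1L))
  del_r <- IRanges::IRanges(dels$offset, width = dels$length)
  keep <- IRanges::setdiff(IRanges::IRanges(1L, clen), del_r)
  seg <- rbind(seg,
               data.frame(contig = "cluster", start = IRanges::start(keep),
                          end = IRanges::end(keep), copy = k),
               if (nrow(dels)) data.frame(contig = "cluster",
                                          start = dels$offset,
                                          end = dels$offset + dels$length - 1L,
                                          copy = k - dels$carriers))
  seg <- seg[order(seg$contig, seg$start), ]
  rownames(seg) <- NULL
  seg
}

# Ground-truth junction list: adjacencies between structural units plus
# internal deletion breakpoints, in the collapsed coordinate system.
truth_junctions <- function(units, dels) {
  side_of <- function(u, which) {
    # the cluster-coordinate side adjacent to the junction:
    # leaving a forward unit exposes its tail, entering exposes its head;
    # inverted copies swap the two.
    if (u$strand == "+") {
      if (which == "leave") "tail" else "head"
    } else {
      if (which == "leave") "head" else "tail"
    }
  }
  jn <- list()
  for (j in seq_len(length(units) - 1L)) {
    a <- units[[j]]; b <- units[[j + 1L]]
    jn[[length(jn) + 1L]] <- canonical_join(
      paste0(a$contig, ":", side_of(a, "leave")),
      paste0(b$contig, ":", side_of(b, "enter")),
      orientation_label(side_of(a, "leave"), side_of(b, "enter")))
  }
  if (nrow(dels)) {
    carried <- dels[dels$carriers >= 1L, , drop = FALSE]
    for (j in seq_len(nrow(carried))) {
      s <- carried$offset[j]; e <- s + carried$length[j] - 1L
      jn[[length(jn) + 1L]] <- canonical_join(
        sprintf("cluster:%d:L", s), sprintf("cluster:%d:R", e),
        "head-to-tail")
    }
  }
  out <- unique(do.call(rbind, jn))
  rownames(out) <- NULL
  out
}

orientation_label <- function(side_a, side_b) {
  if (side_a == "tail" && side_b == "tail") "tail-to-tail"
  else if (side_a == "head" && side_b == "head") "head-to-head"
  else "head-to-tail"
}

canonical_join <- function(a, b, orientation) {
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  data.frame(endpoint_a = a, endpoint_b = b, orientation = orientation)
}

#' @export
print.bgc_sim <- function(x, ...) {
  cat(sprintf("bgc_sim: intact chromosome %d bp; collapsed assembly %d bp (%d contigs)\n",
              x$truth$intact_length, x$truth$collapsed_length,
              length(x$collapsed)))
  invisible(x)
}
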