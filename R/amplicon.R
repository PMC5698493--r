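#' Dereplicate amplicon reads by primer identification
#'
#' Keeps reads that begin with the forward primer (allowing up to
#' `max_mismatches` substitutions) and trims it; reads whose reverse
#' complement begins with the forward primer are reverse-complemented
#' first, so every retained insert comes out in the same orientation.
#' If the reverse complement of the reverse primer is found at the 3'
#' end it is trimmed as well. Reads matching in neither orientation
#' are discarded and counted.
#'
#' @param reads [Biostrings::DNAStringSet] (or character vector).
#' @param forward_primer,reverse_primer Primer sequences (character).
#' @param max_mismatches Maximum substitutions tolerated in a primer
#'   match (default 1).
#' @return List: `inserts` (oriented, trimmed
#'   [Biostrings::DNAStringSet]) and `discarded` (count).
#' @export
dereplicate_primers <- function(reads, forward_primer, reverse_primer,
                                max_mismatches = 1L) {
  stopifnot(nchar(forward_primer) > 0L, nchar(reverse_primer) > 0L)
  reads <- Biostrings::DNAStringSet(reads)
  fwd <- Biostrings::DNAString(forward_primer)
  rev_rc <- Biostrings::reverseComplement(
    Biostrings::DNAString(reverse_primer))
  np <- length(fwd)

  starts_with_primer <- function(x) {
    length(x) >= np &&
      Biostrings::neditStartingAt(fwd, x, starting.at = 1L) <= max_mismatches
  }
  keep <- logical(length(reads))
  oriented <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    if (starts_with_primer(r)) {
      keep[i] <- TRUE
    } else {
      rc <- Biostrings::reverseComplement(r)
      if (starts_with_primer(rc)) {
        keep[i] <- TRUE
        r <- rc
      }
    }
    if (keep[i]) {
      r <- Biostrings::subseq(r, np + 1L)
      nr <- length(rev_rc)
      if (length(r) >= nr &&
          Biostrings::neditEndingAt(rev_rc, r, ending.at = length(r)) <=
            max_mismatches) {
        r <- Biostrings::subseq(r, 1L, length(r) - nr)
      }
      oriented[[i]] <- r
    }
  }
  inserts <- Biostrings::DNAStringSet(oriented[keep])
  names(inserts) <- names(reads)[keep]
  list(inserts = inserts, discarded = sum(!keep))
}

#' Classify amplicon reads against a cluster reference
#'
#' Aligns each read locally to the reference (match +1, mismatch -1,
#' gap -2 by default) and labels it `cluster` when the alignment
#' identity is at least `min_identity` *and* the aligned portion
#' exceeds `min_aligned_fraction` of the read length; identity is
#' matches over alignment columns (gaps included). The cluster
#' fraction is the proportion of classified reads labelled `cluster`.
#'
#' @param reads [Biostrings::DNAStringSet] (or character vector);
#'   must be non-empty.
#' @param reference Reference sequence (character or
#'   [Biostrings::DNAString]).
#' @param min_identity Identity threshold, `>=` comparison (default
#'   0.97).
#' @param min_aligned_fraction Aligned-fraction threshold, strict `>`
#'   comparison (default 0.90).
#' @param both_strands Also try the reverse complement of each read and
#'   keep the better-scoring orientation (default `FALSE`; primer
#'   dereplication already orients reads).
#' @param match,mismatch,gap Alignment scores (defaults 1, -1, -2).
#' @return List of class `amplicon_classification`: `reads`
#'   (`data.frame` with `read`, `label`, `identity`,
#'   `aligned_fraction`), `cluster_fraction`, `n`.
#' @export
classify_against_cluster <- function(reads, reference, min_identity = 0.97,
                                     min_aligned_fraction = 0.90,
                                     both_strands = FALSE,
                                     match = 1, mismatch = -1, gap = -2) {
  reads <- Biostrings::DNAStringSet(reads)
  if (!length(reads)) stop("empty read set")
  stopifnot(min_identity > 0, min_identity <= 1,
            min_aligned_fraction > 0, min_aligned_fraction <= 1)
  subject <- Biostrings::DNAString(as.character(reference))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  align <- function(patterns) {
    Biostrings::pairwiseAlignment(patterns, subject, type = "local",
                                  substitutionMatrix = mat,
                                  gapOpening = 0, gapExtension = -gap)
  }
  aln <- align(reads)
  score <- Biostrings::score(aln)
  if (both_strands) {
    aln_rc <- align(Biostrings::reverseComplement(reads))
    better <- Biostrings::score(aln_rc) > score
    identity <- ifelse(better, Biostrings::pid(aln_rc, type = "PID1"),
                       Biostrings::pid(aln, type = "PID1")) / 100
    alen <- ifelse(better,
                   Biostrings::width(Biostrings::pattern(aln_rc)),
                   Biostrings::width(Biostrings::pattern(aln)))
  } else {
    identity <- Biostrings::pid(aln, type = "PID1") / 100
    alen <- Biostrings::width(Biostrings::pattern(aln))
  }
  aligned_fraction <- alen / Biostrings::width(reads)
  label <- ifelse(identity >= min_identity &
                    aligned_fraction > min_aligned_fraction,
                  "cluster", "other")
  ids <- if (is.null(names(reads))) sprintf("read_%06d", seq_along(reads))
         else names(reads)
  tab <- data.frame(read = ids, label = label, identity = identity,
                    aligned_fraction = aligned_fraction,
                    stringsAsFactors = FALSE)
  structure(list(reads = tab,
                 cluster_fraction = mean(label == "cluster"),
                 n = length(reads)),
            class = "amplicon_classification")
}

#' Flag reads whose top database hits include trans-AT accessions
#'
#' A read is flagged when any of its first `top_n` ranked hits carries
#' an accession from the supplied trans-AT protein list.
#'
#' @param hits `data.frame` with columns `read`, `accession`, `rank`.
#' @param transat_accessions Character vector of trans-AT accessions.
#' @param top_n Rank window (default 500).
#' @param read_ids Optional character vector of all read ids; reads
#'   without hits are reported `FALSE`.
#' @return Named logical vector.
#' @export
classify_transat <- function(hits, transat_accessions, top_n = 500L,
                             read_ids = NULL) {
  flag_tab <- tapply(
    hits$rank <= top_n & hits$accession %in% transat_accessions,
    hits$read, any)
  ids <- if (is.null(read_ids)) names(flag_tab) else read_ids
  out <- setNames(rep(FALSE, length(ids)), ids)
  hitids <- intersect(ids, names(flag_tab))
  out[hitids] <- unname(flag_tab[hitids])
  out
}

#' Combine cluster and trans-AT calls into three-way read labels
#'
#' Reads classified `cluster` stay `cluster`; remaining reads flagged
#' by the trans-AT rule become `trans-AT-other`; the rest are `other`.
#'
#' @param classification An `amplicon_classification` from
#'   [classify_against_cluster()].
#' @param transat_flags Named logical vector from [classify_transat()].
#' @return The classification with labels updated.
#' @export
combine_amplicon_labels <- function(classification, transat_flags) {
  tab <- classification$reads
  flag <- transat_flags[tab$read]
  flag[is.na(flag)] <- FALSE
  tab$label <- ifelse(tab$label == "cluster", "cluster",
                      ifelse(flag, "trans-AT-other", "other"))
  classification$reads <- tab
  classification
}

#' @export
print.amplicon_classification <- function(x, ...) {
  cat(sprintf("amplicon_classification: %d reads, cluster fraction %.4f\n",
              x$n, x$cluster_fraction))
  invisible(x)
}
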