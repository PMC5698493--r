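#' Write alignments to a SAM file
#'
#' Emits a plain-text SAM (v1.6) file with `@SQ` header lines and the
#' eleven mandatory columns. Paired-end flags (paired, mate strand,
#' first/last in pair, unmapped) are derived from the alignment table.
#'
#' @param aln A `bgc_alignments` data.frame (see [simulate_reads()]).
#' @param contigs Named vector of contig lengths, or a
#'   [Biostrings::DNAStringSet].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_sam <- function(aln, contigs, path) {
  lens <- contig_lengths_of(contigs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(lens), as.integer(lens)),
               "@PG\tID:bgcdose\tPN:bgcdose"), con)
  if (!nrow(aln)) return(invisible(path))

  idx <- match(paste(aln$qname, 3L - aln$mate), paste(aln$qname, aln$mate))
  other <- aln[idx, ]  # the mate's row (NA-padded if absent)
  other_mapped <- !is.na(other$mapped) & other$mapped
  flag <- 1L +
    ifelse(!aln$mapped, 4L, 0L) +
    ifelse(!other_mapped, 8L, 0L) +
    ifelse(aln$mapped & aln$strand == "-", 16L, 0L) +
    ifelse(other_mapped & other$strand == "-", 32L, 0L) +
    ifelse(aln$mate == 1L, 64L, 128L)
  rnext <- ifelse(is.na(aln$rnext), "*",
                  ifelse(!is.na(aln$rname) & aln$rnext == aln$rname, "=",
                         aln$rnext))
  lines <- paste(aln$qname, flag,
                 ifelse(aln$mapped, aln$rname, "*"),
                 ifelse(aln$mapped, aln$pos, 0L),
                 aln$mapq, aln$cigar, rnext,
                 ifelse(is.na(aln$pnext), 0L, aln$pnext),
                 aln$tlen, aln$seq, "*", sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a SAM file into an alignment table
#'
#' Parses the eleven mandatory SAM columns; optional tags are ignored.
#'
#' @param path Path to a SAM file.
#' @return A `bgc_alignments` data.frame with the same columns produced
#'   by [simulate_reads()] (minus simulation truth columns).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(empty_alignments()[, 1:12])
  f <- strsplit(lines, "\t")
  take <- function(i) vapply(f, `[[`, "", i)
  flag <- as.integer(take(2))
  mapped <- bitwAnd(flag, 4L) == 0L
  rname <- take(3); rname[rname == "*"] <- NA_character_
  rnext <- take(7)
  rnext <- ifelse(rnext == "=", rname, ifelse(rnext == "*", NA, rnext))
  out <- data.frame(
    qname = take(1),
    mate = ifelse(bitwAnd(flag, 64L) > 0L, 1L,
                  ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L)),
    rname = rname,
    pos = ifelse(mapped, as.integer(take(4)), NA_integer_),
    mapq = as.integer(take(5)),
    strand = ifelse(mapped, ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                    NA_character_),
    cigar = take(6),
    seq = take(10),
    rnext = rnext,
    pnext = as.integer(take(8)),
    tlen = as.integer(take(9)),
    mapped = mapped,
    stringsAsFactors = FALSE)
  out$pnext[is.na(out$rnext)] <- NA_integer_
  class(out) <- c("bgc_alignments", "data.frame")
  out
}

#' Write gene models to GFF3
#'
#' @param genes Gene table with columns `id`, `contig`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand,
    type = "gene", ID = genes$id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path Path to a GFF3 file.
#' @return A gene table with columns `id`, `contig`, `start`, `end`,
#'   `strand`, `length`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(id = if (!is.null(gr$ID)) as.character(gr$ID)
                  else sprintf("gene_%05d", seq_along(gr)),
             contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             length = GenomicRanges::width(gr),
             stringsAsFactors = FALSE)
}

#' Read a marker-hit table
#'
#' @param path TSV with columns `marker_id` and `count`.
#' @return Named integer vector of per-marker occurrence counts.
#' @export
read_marker_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("marker_id", "count") %in% names(tab)))
  if (anyDuplicated(tab$marker_id)) stop("marker ids must be unique")
  setNames(as.integer(tab$count), tab$marker_id)
}
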