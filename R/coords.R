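#' @include AllClasses.R
NULL

# Exon spans of a transcript in transcript coordinates (1-based, closed),
# paired with the exons in transcription (5'->3') order.
.txExonMap <- function(ann, txId) {
  ex <- exonsByTx(ann)
  if (!(txId %in% names(ex)))
    stop("unknown transcript: ", txId)
  e <- ex[[txId]]
  minus <- length(e) > 0L && as.character(strand(e)[1L]) == "-"
  if (minus) e <- rev(e)            # transcription order
  w <- width(e)
  txEnd <- cumsum(w)
  list(exons = e, txStart = txEnd - w + 1L, txEnd = txEnd,
       minus = minus, length = sum(w))
}

#' Transcript length (spliced)
#'
#' @param ann a [GenomeAnnotation].
#' @param txId transcript id.
#' @return integer, sum of exon widths.
#' @export
txLength <- function(ann, txId) {
  sum(width(exonsByTx(ann)[[txId]]))
}

#' Spliced transcript sequence
#'
#' Concatenates the exon sequences of a transcript in 5'->3' order,
#' reverse-complementing for minus-strand transcripts.
#'
#' @param genome a `DNAStringSet` (see [readGenome()]).
#' @param ann a [GenomeAnnotation].
#' @param txId transcript id.
#' @return a single character string.
#' @export
splicedSequence <- function(genome, ann, txId) {
  m <- .txExonMap(ann, txId)
  e <- m$exons
  chrom <- as.character(seqnames(e)[1L])
  if (!(chrom %in% names(genome)))
    stop("coordinate error: chromosome ", chrom, " absent from genome")
  chromSeq <- genome[[chrom]]
  if (max(end(e)) > length(chromSeq) || min(start(e)) < 1L)
    stop("coordinate error: exon out of chromosome bounds for ", txId)
  # genomic order for extraction, then orient
  eg <- if (m$minus) rev(e) else e
  parts <- as.character(Biostrings::extractAt(
    chromSeq, IRanges(start(eg), end(eg))))
  s <- paste(parts, collapse = "")
  if (m$minus) .revcomp(s) else s
}

#' Spliced transcript sequences for all transcripts
#'
#' @param genome a `DNAStringSet`.
#' @param ann a [GenomeAnnotation].
#' @return a named `DNAStringSet`, one element per transcript.
#' @export
transcriptSequences <- function(genome, ann) {
  txIds <- names(exonsByTx(ann))
  seqs <- vapply(txIds, function(tx) splicedSequence(genome, ann, tx),
                 character(1L))
  Biostrings::DNAStringSet(setNames(seqs, txIds))
}

#' Project transcript intervals onto the genome
#'
#' Maps closed 1-based transcript-coordinate intervals to genomic blocks,
#' splitting at exon junctions. The summed block width always equals the
#' interval length. Vectorised over `starts`/`ends`.
#'
#' @param ann a [GenomeAnnotation].
#' @param txId transcript id.
#' @param starts,ends integer vectors of transcript coordinates
#'   (1 = first transcribed base).
#' @return a `GRangesList` parallel to `starts`, each element the genomic
#'   blocks (sorted by genomic position) of one interval.
#' @export
txToGenome <- function(ann, txId, starts, ends) {
  m <- .txExonMap(ann, txId)
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (length(starts) != length(ends))
    stop("starts and ends must have equal length")
  if (!length(starts))
    return(GRangesList())
  if (any(starts < 1L) || any(ends > m$length) || any(starts > ends))
    stop("coordinate error: interval outside transcript ", txId)

  spans <- IRanges(m$txStart, m$txEnd)
  q <- IRanges(starts, ends)
  hits <- findOverlaps(q, spans)
  qi <- queryHits(hits); si <- subjectHits(hits)
  loTx <- pmax(starts[qi], m$txStart[si])
  hiTx <- pmin(ends[qi], m$txEnd[si])
  e <- m$exons[si]
  off1 <- loTx - m$txStart[si]           # offset of block start within exon
  off2 <- hiTx - m$txStart[si]
  if (m$minus) {
    gStart <- end(e) - off2
    gEnd <- end(e) - off1
  } else {
    gStart <- start(e) + off1
    gEnd <- start(e) + off2
  }
  blocks <- GRanges(seqnames(e), IRanges(gStart, gEnd), strand = strand(e))
  res <- GenomicRanges::split(blocks, factor(qi, levels = seq_along(starts)))
  BiocGenerics::sort(res)
}

#' Map genomic positions to transcript coordinates
#'
#' Inverse of [txToGenome()] for single bases. Positions not covered by the
#' transcript's exons yield `NA`.
#'
#' @param ann a [GenomeAnnotation].
#' @param txId transcript id.
#' @param gpos integer vector of genomic positions (1-based).
#' @return integer vector of transcript coordinates (NA where intronic or
#'   outside the transcript).
#' @export
genomeToTx <- function(ann, txId, gpos) {
  m <- .txExonMap(ann, txId)
  e <- m$exons
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_along(e)) {
    inEx <- gpos >= start(e)[i] & gpos <= end(e)[i]
    if (!any(inEx)) next
    out[inEx] <- if (m$minus)
      m$txStart[i] + (end(e)[i] - gpos[inEx])
    else
      m$txStart[i] + (gpos[inEx] - start(e)[i])
  }
  out
}
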