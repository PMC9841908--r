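#' @include AllClasses.R kozak.R
NULL

# Scan one oriented (5'->3') sequence string. Coordinates returned are
# 1-based, closed, on that oriented string; `end` includes the stop codon.
.scanOriented <- function(s, startSet, minNt, maxNt, allStarts) {
  n <- nchar(s)
  hits <- list()
  for (f in 0:2) {
    if (n - f < 3L) next
    cpos <- seq.int(f + 1L, n - 2L, by = 3L)
    cod <- substring(s, cpos, cpos + 2L)
    # codons containing N are neither starts nor stops
    isStop <- cod %in% .STOP_CODONS
    isStart <- cod %in% startSet
    stops <- which(isStop)
    startsIdx <- which(isStart)
    prev <- 0L
    for (k in stops) {
      cand <- startsIdx[startsIdx > prev & startsIdx < k]
      if (length(cand)) {
        sel <- if (allStarts) cand else cand[1L]
        ntLen <- (k - sel + 1L) * 3L
        keep <- ntLen >= minNt & ntLen <= maxNt
        if (any(keep)) {
          sel <- sel[keep]
          hits[[length(hits) + 1L]] <- data.frame(
            start = cpos[sel], end = cpos[k] + 2L, frame = f,
            startCodon = cod[sel], stringsAsFactors = FALSE)
        }
      }
      prev <- k
    }
  }
  if (!length(hits))
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      startCodon = character(), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Scan a sequence for small ORFs
#'
#' Enumerates ORFs running from an allowed start codon (default: ATG and its
#' nine near-cognate variants, see [kozakStartCodons()]) to the next in-frame
#' stop codon, per frame and strand. By default the most-upstream admissible
#' start is reported per (strand, frame, stop) -- the longest-ORF convention;
#' with `allStarts = TRUE` every admissible start is reported. Hits outside
#' the length bounds are removed after enumeration. Codons containing `N`
#' never act as start or stop codons.
#'
#' @param seq a character scalar or `DNAString` over A/C/G/T/N.
#' @param strandMode `"plus"` to scan the given strand only (used for
#'   transcript sequences), `"both"` to also scan the reverse complement
#'   (used for genomic conserved regions).
#' @param startCodons allowed start codons.
#' @param minNt,maxNt ORF length bounds in nucleotides, stop codon included.
#'   Defaults 9 (2 codons + stop) and 303 (100 codons + stop).
#' @param allStarts report every admissible start per stop instead of the
#'   most-upstream one.
#' @return data.frame with columns `start`, `end` (1-based, closed, on the
#'   input sequence's forward coordinates; for minus-strand hits the
#'   biological start is at `end`), `strand`, `frame` (0-2 on the scanned
#'   strand), `startCodon`, `peptide` (initiator rendered as M) and
#'   `ntLength`.
#' @examples
#' scanOrfs("ATGAAATAA")              # one hit, peptide "MK"
#' scanOrfs("TTGAAATAA")              # near-cognate TTG start
#' @export
scanOrfs <- function(seq, strandMode = c("plus", "both"),
                     startCodons = kozakStartCodons(),
                     minNt = 9L, maxNt = 303L, allStarts = FALSE) {
  strandMode <- match.arg(strandMode)
  s <- toupper(as.character(seq))
  if (length(s) != 1L)
    stop("seq must be a single sequence")
  if (minNt %% 3L != 0L || maxNt %% 3L != 0L || minNt > maxNt)
    stop("length bounds must be multiples of 3 with minNt <= maxNt")
  n <- nchar(s)
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      startCodon = character(), peptide = character(),
                      ntLength = integer(), stringsAsFactors = FALSE)
  if (n < 6L) return(empty)

  res <- list()
  plus <- .scanOriented(s, startCodons, minNt, maxNt, allStarts)
  if (nrow(plus)) {
    plus$strand <- "+"
    plus$nt <- substring(s, plus$start, plus$end)
    res[["+"]] <- plus
  }
  if (strandMode == "both") {
    rc <- .revcomp(s)
    minus <- .scanOriented(rc, startCodons, minNt, maxNt, allStarts)
    if (nrow(minus)) {
      minus$nt <- substring(rc, minus$start, minus$end)
      # convert to forward coordinates
      s2 <- n - minus$end + 1L
      e2 <- n - minus$start + 1L
      minus$start <- s2; minus$end <- e2
      minus$strand <- "-"
      res[["-"]] <- minus
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out$peptide <- .translateOrf(out$nt)
  out$ntLength <- out$end - out$start + 1L
  rownames(out) <- NULL
  out[, c("start", "end", "strand", "frame", "startCodon", "peptide",
          "ntLength")]
}

#' Conserved regions from multi-species alignment intervals
#'
#' Sweeps per-species genomic alignment intervals and extracts the maximal
#' regions where at least `minSpecies` distinct species align (per-base
#' species coverage, each species counted at most once per base). Regions
#' shorter than `minLen` are dropped. The recorded species count of a region
#' is the maximum per-base coverage within it.
#'
#' @param speciesIntervals named list (one element per species) of `GRanges`
#'   alignment intervals.
#' @param minSpecies minimum number of species covering a base (default 2).
#' @param minLen minimum region width in nt (default 30).
#' @return a `GRanges` with metadata column `speciesCount`.
#' @examples
#' library(GenomicRanges)
#' a <- GRanges("chr1", IRanges(1, 100))
#' b <- GRanges("chr1", IRanges(51, 150))
#' conservedRegions(list(spA = a, spB = b))   # chr1:51-100
#' @export
conservedRegions <- function(speciesIntervals, minSpecies = 2L, minLen = 30L) {
  if (!length(speciesIntervals))
    return(GRanges(seqnames = character(), ranges = IRanges(),
                   speciesCount = integer()))
  redd <- lapply(speciesIntervals, function(gr) {
    reduce(granges(gr), ignore.strand = TRUE)
  })
  allGr <- unlist(GRangesList(redd), use.names = FALSE)
  if (!length(allGr))
    return(GRanges(seqnames = character(), ranges = IRanges(),
                   speciesCount = integer()))
  chroms <- unique(as.character(seqnames(allGr)))
  maxEnd <- vapply(chroms, function(ch)
    max(end(allGr[seqnames(allGr) == ch])), integer(1L))

  out <- list()
  for (ch in chroms) {
    cov <- Rle(0L, maxEnd[[ch]])
    for (sp in redd) {
      spc <- sp[as.character(seqnames(sp)) == ch]
      if (!length(spc)) next
      cov <- cov + coverage(ranges(spc), width = maxEnd[[ch]])
    }
    v <- slice(cov, lower = minSpecies, rangesOnly = FALSE)
    if (!length(v)) next
    keep <- width(v) >= minLen
    if (!any(keep)) next
    v <- v[keep]
    out[[ch]] <- GRanges(ch, IRanges(start(v), end(v)),
                         speciesCount = as.integer(viewMaxs(v)))
  }
  if (!length(out))
    return(GRanges(seqnames = character(), ranges = IRanges(),
                   speciesCount = integer()))
  unlist(GRangesList(out), use.names = FALSE)
}
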