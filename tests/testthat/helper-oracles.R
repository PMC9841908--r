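# Independent oracles used across the suite. These deliberately take the
# most naive route available (per-base walks, exhaustive enumeration) so
# they share no code path with the implementation they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
  library(S4Vectors)
  library(IRanges)
})

revcompStr <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

# Exhaustive ORF enumeration: try every position as a start, walk codon by
# codon to the nearest in-frame stop.
bruteOrfs <- function(s, strandMode = "plus", startSet = kozakStartCodons(),
                      minNt = 9L, maxNt = 303L, allStarts = FALSE) {
  stops <- c("TAA", "TAG", "TGA")
  scanOne <- function(seq) {
    n <- nchar(seq)
    rows <- list()
    for (i in seq_len(max(0L, n - 5L))) {
      if (!(substr(seq, i, i + 2L) %in% startSet)) next
      j <- i + 3L
      found <- FALSE
      while (j + 2L <= n) {
        if (substr(seq, j, j + 2L) %in% stops) { found <- TRUE; break }
        j <- j + 3L
      }
      if (!found) next
      rows[[length(rows) + 1L]] <- data.frame(start = i, end = j + 2L)
    }
    df <- if (length(rows)) do.call(rbind, rows)
      else data.frame(start = integer(), end = integer())
    if (!allStarts && nrow(df)) {
      df <- df[order(df$end, df$start), , drop = FALSE]
      df <- df[!duplicated(df$end), , drop = FALSE]   # end determines frame
    }
    # length bounds apply after start selection (longest-per-stop first)
    if (nrow(df)) {
      len <- df$end - df$start + 1L
      df <- df[len >= minNt & len <= maxNt, , drop = FALSE]
    }
    df
  }
  out <- scanOne(s)
  out$strand <- rep("+", nrow(out))
  if (strandMode == "both") {
    n <- nchar(s)
    m <- scanOne(revcompStr(s))
    if (nrow(m)) {
      m2 <- data.frame(start = n - m$end + 1L, end = n - m$start + 1L,
                       strand = "-")
      out <- rbind(out, m2)
    }
  }
  out <- out[order(out$strand, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

orfKey <- function(df) {
  sort(paste(df$start, df$end, df$strand))
}

# Per-base species-coverage counting for the conserved-region sweep.
conservedOracle <- function(speciesIntervals, minSpecies = 2L, minLen = 30L) {
  chroms <- unique(unlist(lapply(speciesIntervals, function(gr)
    as.character(seqnames(gr)))))
  rows <- list()
  for (ch in chroms) {
    maxPos <- max(unlist(lapply(speciesIntervals, function(gr) {
      g <- gr[as.character(seqnames(gr)) == ch]
      if (length(g)) max(end(g)) else 0L
    })))
    cov <- integer(maxPos)
    for (gr in speciesIntervals) {
      g <- gr[as.character(seqnames(gr)) == ch]
      if (!length(g)) next
      seen <- logical(maxPos)
      for (k in seq_along(g))
        seen[seq(start(g)[k], end(g)[k])] <- TRUE
      cov <- cov + as.integer(seen)
    }
    r <- rle(cov >= minSpecies)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      if (r$lengths[k] < minLen) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = starts[k], end = ends[k],
        speciesCount = max(cov[starts[k]:ends[k]]))
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), speciesCount = integer()))
  df <- do.call(rbind, rows)
  df[order(df$chrom, df$start), , drop = FALSE]
}

# A small hand-buildable two-gene annotation on a 600-nt chromosome:
# gene A (+): exons 101-220 and 301-400, CDS 131-220 + 301-342 (132 nt)
# gene B (-): single exon 451-570, CDS 481-540
tinyAnnotation <- function() {
  genes <- GRanges("chrT", IRanges(c(101, 451), c(400, 570)),
                   strand = c("+", "-"))
  genes$gene_id <- c("gA", "gB")
  genes$biotype <- c("protein_coding", "protein_coding")
  exons <- GRangesList(
    txA = GRanges("chrT", IRanges(c(101, 301), c(220, 400)), strand = "+"),
    txB = GRanges("chrT", IRanges(451, 570), strand = "-"))
  cds <- list(
    txA = GRanges("chrT", IRanges(c(131, 301), c(220, 342)), strand = "+"),
    txB = GRanges("chrT", IRanges(481, 540), strand = "-"))
  makeGenomeAnnotation(genes, exons, cds,
                       c(txA = "gA", txB = "gB"))
}

tinyGenome <- function(seed = 42) {
  set.seed(seed)
  DNAStringSet(c(chrT = paste(sample(c("A", "C", "G", "T"), 600,
                                     replace = TRUE), collapse = "")))
}

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small, fast synthetic configuration for pipeline-level tests
smallConfig <- function(seed = 7L) {
  synthConfig(seed = seed, nChroms = 2L, chromLength = 15000L,
              nPerCategory = 2L, nExtraGenes = 2L,
              baseMeanRange = c(40, 90), nDEGenes = 2L)
}
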