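#' @include AllClasses.R discover.R
NULL

#' Confidence tiers and positional categories
#'
#' `smorfTiers()` returns the tier levels in decreasing credibility. HC4 is
#' reserved (named in the tier scheme but receiving no candidates under the
#' implemented evidence rules, which assign HC1-HC3 and LC1-LC2 only).
#' `smorfCategories()` returns the positional categories in priority order.
#'
#' @return character vector of levels.
#' @export
smorfTiers <- function() c("HC1", "HC2", "HC3", "HC4", "LC1", "LC2")

#' @rdname smorfTiers
#' @export
smorfCategories <- function() {
  c("InFrameORF", "OutFrameORF", "uORF", "dORF", "ncORF", "intronORF",
    "intergenicORF")
}

#' Assign confidence tiers from evidence flags
#'
#' Tier logic over the four evidence flags: coding potential together with a
#' homology hit gives HC1; homology without coding potential HC2; coding
#' potential without homology HC3. Candidates with neither line of evidence
#' fall to low confidence: LC1 when transcript-supported, otherwise LC2
#' (conservation-only). Every candidate must originate from at least one of
#' the transcript or conservation routes.
#'
#' @param smorfs a [SmorfSet] with evidence attached (see
#'   [attachEvidence()]), or a data.frame with logical columns
#'   `fromTranscript`, `fromConservation`, `coding`, `homology`.
#' @return the `SmorfSet` with `tier` filled in (or, for a data.frame input,
#'   a character vector of tiers).
#' @export
assignConfidence <- function(smorfs) {
  df <- if (is(smorfs, "SmorfSet")) as.data.frame(smorfs@info) else smorfs
  if (nrow(df) && !all(df$fromTranscript | df$fromConservation))
    stop("candidate(s) with empty evidence flag set: every candidate must ",
         "come from the transcript or the conservation route")
  tier <- ifelse(df$coding & df$homology, "HC1",
          ifelse(df$homology, "HC2",
          ifelse(df$coding, "HC3",
          ifelse(df$fromTranscript, "LC1", "LC2"))))
  if (!is(smorfs, "SmorfSet")) return(tier)
  smorfs@info$tier <- tier
  smorfs
}

# Pre-computed annotation footprints used by assignCategory.
.categoryIndex <- function(ann) {
  genes <- annGenes(ann)
  txg <- txGene(ann)
  biotypeOf <- setNames(genes$biotype, genes$gene_id)
  txBio <- biotypeOf[txg]
  coding <- names(txg)[txBio == "protein_coding" &
                       sum(width(cdsByTx(ann)))[names(txg)] > 0L]
  noncod <- setdiff(names(txg), coding)
  list(
    genes = genes,
    codingTx = coding,
    noncodingTx = noncod,
    exons = exonsByTx(ann),
    cds = cdsByTx(ann),
    utr5 = utr5ByTx(ann),
    utr3 = utr3ByTx(ann)
  )
}

# For each candidate, total overlap width with each transcript's footprint
# (same strand, same chromosome). Returns data.frame(cand, tx, ov).
.overlapByTx <- function(blocks, footprint, txIds, strands) {
  if (!length(txIds))
    return(data.frame(cand = integer(), tx = character(), ov = integer()))
  fp <- footprint[txIds]
  flatF <- unlist(fp, use.names = FALSE)
  txOf <- rep(txIds, lengths(fp))
  flatB <- unlist(blocks, use.names = FALSE)
  candOf <- rep(seq_along(blocks), lengths(blocks))
  hits <- findOverlaps(flatB, flatF, ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(cand = integer(), tx = character(), ov = integer()))
  qi <- queryHits(hits); si <- subjectHits(hits)
  sameStrand <- strands[candOf[qi]] ==
    as.character(strand(flatF))[si]
  qi <- qi[sameStrand]; si <- si[sameStrand]
  if (!length(qi))
    return(data.frame(cand = integer(), tx = character(), ov = integer()))
  ov <- width(pintersect(flatB[qi], flatF[si], ignore.strand = TRUE))
  agg <- stats::aggregate(ov,
    by = list(cand = candOf[qi], tx = txOf[si]), FUN = sum)
  data.frame(cand = agg$cand, tx = agg$tx, ov = agg$x,
             stringsAsFactors = FALSE)
}

# Frame test for a candidate fully contained in the CDS exonic footprint of
# a coding transcript: the candidate must project to a contiguous transcript
# interval whose start is in phase with the annotated CDS.
.inFrameWithTx <- function(ann, idx, blocks, txId) {
  b <- blocks
  minus <- as.character(strand(b)[1L]) == "-"
  gStart <- if (minus) max(end(b)) else min(start(b))
  gEnd <- if (minus) min(start(b)) else max(end(b))
  txs <- genomeToTx(ann, txId, c(gStart, gEnd))
  if (anyNA(txs)) return(FALSE)
  if (txs[2L] - txs[1L] + 1L != sum(width(b))) return(FALSE)  # not contiguous
  cd <- idx$cds[[txId]]
  cdsStartG <- if (as.character(strand(cd)[1L]) == "-") max(end(cd))
               else min(start(cd))
  cdsStartTx <- genomeToTx(ann, txId, cdsStartG)
  (txs[1L] - cdsStartTx) %% 3L == 0L
}

#' Assign positional categories against a gene annotation
#'
#' Places each candidate into exactly one category by the first matching
#' rule in priority order:
#' \enumerate{
#'   \item `InFrameORF`: all blocks within the CDS exonic footprint of a
#'     protein-coding transcript on the same strand, contiguous on that
#'     transcript and in the same codon phase as the annotated CDS.
#'   \item `OutFrameORF`: overlaps a coding transcript's CDS footprint on the
#'     same strand but fails the frame/containment test.
#'   \item `uORF`: all blocks within the exonic 5'UTR of an mRNA, same strand.
#'   \item `dORF`: all blocks within the exonic 3'UTR, same strand.
#'   \item `ncORF`: all blocks within the exons of a non-coding transcript,
#'     same strand.
#'   \item `intronORF`: overlaps the span of some gene (intronic or
#'     otherwise unplaced overlap with a gene).
#'   \item `intergenicORF`: no gene overlap at all.
#' }
#' A candidate matching several rules through different transcripts receives
#' the highest-priority achievable category.
#'
#' @param smorfs a [SmorfSet].
#' @param ann a [GenomeAnnotation].
#' @return the `SmorfSet` with `category` filled in; the `provenance` of the
#'   justifying transcript is recorded in the metadata column
#'   `categoryTx` (NA for intronic/intergenic).
#' @export
assignCategory <- function(smorfs, ann) {
  n <- length(smorfs)
  if (n == 0L) return(smorfs)
  idx <- .categoryIndex(ann)
  blocks <- smorfs@blocks
  strands <- as.character(smorfs@info$strand)
  ntLen <- smorfs@info$ntLength
  category <- rep(NA_character_, n)
  categoryTx <- rep(NA_character_, n)

  ## rules 1-2: CDS footprint
  ovCds <- .overlapByTx(blocks, idx$cds, idx$codingTx, strands)
  contained <- ovCds[ovCds$ov == ntLen[ovCds$cand], , drop = FALSE]
  if (nrow(contained)) {
    for (r in seq_len(nrow(contained))) {
      ci <- contained$cand[r]
      if (!is.na(category[ci])) next
      if (.inFrameWithTx(ann, idx, blocks[[ci]], contained$tx[r])) {
        category[ci] <- "InFrameORF"
        categoryTx[ci] <- contained$tx[r]
      }
    }
  }
  if (nrow(ovCds)) {
    firstTx <- tapply(ovCds$tx, ovCds$cand, function(z) z[[1L]])
    for (ci in unique(ovCds$cand)) {
      if (is.na(category[ci])) {
        category[ci] <- "OutFrameORF"
        categoryTx[ci] <- firstTx[[as.character(ci)]]
      }
    }
  }

  ## rules 3-5: containment in UTR / noncoding exon footprints
  applyContainment <- function(footprint, txIds, label) {
    open <- which(is.na(category))
    if (!length(open) || !length(txIds)) return()
    ov <- .overlapByTx(blocks[open], footprint, txIds, strands[open])
    ok <- ov[ov$ov == ntLen[open][ov$cand], , drop = FALSE]
    if (nrow(ok)) {
      for (r in seq_len(nrow(ok))) {
        ci <- open[ok$cand[r]]
        if (is.na(category[ci])) {
          category[ci] <<- label
          categoryTx[ci] <<- ok$tx[r]
        }
      }
    }
  }
  applyContainment(idx$utr5, idx$codingTx, "uORF")
  applyContainment(idx$utr3, idx$codingTx, "dORF")
  applyContainment(idx$exons, idx$noncodingTx, "ncORF")

  ## rules 6-7: gene-span overlap vs intergenic
  open <- which(is.na(category))
  if (length(open)) {
    spans <- unlist(range(blocks[open]))
    hit <- findOverlaps(spans, idx$genes, ignore.strand = TRUE)
    lab <- rep("intergenicORF", length(open))
    lab[unique(queryHits(hit))] <- "intronORF"
    category[open] <- lab
  }

  smorfs@info$category <- category
  smorfs@info$categoryTx <- categoryTx
  smorfs
}

#' Tier-by-category classification table
#'
#' Cross-tabulates candidates by confidence tier and positional category and
#' appends row, column and grand totals (see [addTableMargins()]).
#'
#' @param smorfs a [SmorfSet] with tiers and categories assigned, or a
#'   data.frame with `tier` and `category` columns.
#' @param tiers,categories level orderings for the table.
#' @return integer matrix with a `Total` row and column.
#' @export
tabulateSmorfs <- function(smorfs, tiers = setdiff(smorfTiers(), "HC4"),
                           categories = smorfCategories()) {
  df <- if (is(smorfs, "SmorfSet")) as.data.frame(smorfs@info) else smorfs
  if (nrow(df) && (anyNA(df$tier) || anyNA(df$category)))
    stop("every candidate needs an assigned tier and category")
  m <- table(factor(df$tier, levels = tiers),
             factor(df$category, levels = categories))
  m <- matrix(as.integer(m), nrow = length(tiers),
              dimnames = list(tiers, categories))
  addTableMargins(m)
}

#' Append marginal totals to a count matrix
#'
#' Adds a `Total` column (row sums), a `Total` row (column sums) and the
#' grand total in the corner. The grand total always equals both the sum of
#' row totals and the sum of column totals.
#'
#' @param m numeric/integer matrix of counts.
#' @return the matrix with margins appended.
#' @export
addTableMargins <- function(m) {
  if (!is.matrix(m)) stop("m must be a matrix")
  out <- rbind(cbind(m, Total = rowSums(m)),
               Total = c(colSums(m), sum(m)))
  out
}
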