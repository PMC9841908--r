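#' @include AllClasses.R
NULL

#' Union-mode fragment counting
#'
#' HTSeq-style union counting over exon features, unstranded: a fragment is
#' attributed to a feature group (gene) only when every feature any of its
#' blocks overlaps belongs to that one group. Fragments touching features of
#' two or more groups are ambiguous; fragments touching no feature are
#' no-feature; both are tallied but not counted.
#'
#' @param fragments a `GRangesList`, one element per fragment (blocks).
#' @param features a `GRanges` of exon features with metadata column
#'   `gene_id` (the feature group).
#' @return list with `counts` (named integer vector over all feature
#'   groups), `ambiguous`, `noFeature` and `total` tallies. Always
#'   `sum(counts) + ambiguous + noFeature == total`.
#' @export
countUnion <- function(fragments, features) {
  if (is.null(features$gene_id))
    stop("features must carry a gene_id metadata column")
  geneIds <- unique(features$gene_id)
  nFrag <- length(fragments)
  counts <- setNames(integer(length(geneIds)), geneIds)
  if (nFrag == 0L)
    return(list(counts = counts, ambiguous = 0L, noFeature = 0L, total = 0L))
  flat <- unlist(fragments, use.names = FALSE)
  fragOf <- rep(seq_len(nFrag), lengths(fragments))
  hits <- findOverlaps(flat, features, ignore.strand = TRUE)
  geneHit <- features$gene_id[subjectHits(hits)]
  fragHit <- fragOf[queryHits(hits)]
  # per fragment: number of distinct genes touched, and which gene if unique
  key <- paste(fragHit, geneHit, sep = "\r")
  dedup <- !duplicated(key)
  fragHit <- fragHit[dedup]; geneHit <- geneHit[dedup]
  nGenes <- tabulate(fragHit, nbins = nFrag)
  unambiguous <- nGenes == 1L
  assignedGene <- geneHit[match(which(unambiguous), fragHit)]
  tab <- table(factor(assignedGene, levels = geneIds))
  counts[] <- as.integer(tab)
  list(counts = counts,
       ambiguous = sum(nGenes > 1L),
       noFeature = sum(nGenes == 0L),
       total = nFrag)
}

#' Build a count matrix over samples with union counting
#'
#' @param sampleFragments named list of `GRangesList` objects, one per
#'   sample.
#' @param features exon features with `gene_id`, as in [countUnion()].
#' @return list with `counts` (feature-group x sample integer matrix) and
#'   `stats` (per-sample data.frame of ambiguous/no-feature/total tallies).
#' @export
buildCountMatrix <- function(sampleFragments, features) {
  samples <- names(sampleFragments)
  if (is.null(samples)) stop("sampleFragments must be named by sample")
  res <- lapply(sampleFragments, countUnion, features = features)
  counts <- vapply(res, `[[`, numeric(length(res[[1L]]$counts)), "counts")
  counts <- matrix(as.integer(counts), nrow = length(res[[1L]]$counts),
                   dimnames = list(names(res[[1L]]$counts), samples))
  stats <- data.frame(
    sample = samples,
    counted = vapply(res, function(r) sum(r$counts), numeric(1L)),
    ambiguous = vapply(res, `[[`, integer(1L), "ambiguous"),
    noFeature = vapply(res, `[[`, integer(1L), "noFeature"),
    total = vapply(res, `[[`, integer(1L), "total"),
    row.names = NULL)
  list(counts = counts, stats = stats)
}

#' Map smORF candidates to parent genes
#'
#' A candidate inherits the gene whose exonic footprint it overlaps by at
#' least 1 bp (either strand); with several genes the larger overlap wins,
#' ties broken by lexicographic gene id. Candidates overlapping no gene's
#' exons are orphans.
#'
#' @param smorfs a [SmorfSet].
#' @param ann a [GenomeAnnotation].
#' @return named character vector candidate id -> gene id, with `"orphan"`
#'   for unmapped candidates.
#' @export
smorfParentMap <- function(smorfs, ann) {
  ids <- names(smorfs)
  map <- setNames(rep("orphan", length(ids)), ids)
  if (!length(ids)) return(map)
  ex <- exonsByTx(ann)
  txg <- txGene(ann)
  flatEx <- unlist(ex, use.names = FALSE)
  geneOf <- rep(unname(txg[names(ex)]), lengths(ex))
  flatB <- unlist(smorfs@blocks, use.names = FALSE)
  candOf <- rep(seq_along(ids), lengths(smorfs@blocks))
  hits <- findOverlaps(flatB, flatEx, ignore.strand = TRUE)
  if (!length(hits)) return(map)
  qi <- queryHits(hits); si <- subjectHits(hits)
  ov <- width(pintersect(flatB[qi], flatEx[si], ignore.strand = TRUE))
  agg <- stats::aggregate(ov, by = list(cand = candOf[qi], gene = geneOf[si]),
                          FUN = sum)
  # larger overlap wins; ties by lexicographic gene id
  agg <- agg[order(agg$cand, -agg$x, agg$gene), ]
  best <- agg[!duplicated(agg$cand), ]
  map[ids[best$cand]] <- best$gene
  map
}

#' smORF expression from parent-gene inheritance
#'
#' A smORF overlapping a gene is quantified as that gene: its count row is
#' the parent gene's row, copied. Orphan smORFs (no gene overlap) are
#' quantified independently over their own genomic region.
#'
#' @param geneCounts feature-group x sample count matrix containing rows for
#'   all parent genes.
#' @param parentMap named character vector candidate -> gene or `"orphan"`
#'   (see [smorfParentMap()]).
#' @param orphanCounts count matrix with rows for orphan candidate ids
#'   (their independent region counts).
#' @return smORF x sample count matrix, rows ordered as `parentMap`.
#' @export
smorfCounts <- function(geneCounts, parentMap, orphanCounts = NULL) {
  ids <- names(parentMap)
  out <- matrix(0L, nrow = length(ids), ncol = ncol(geneCounts),
                dimnames = list(ids, colnames(geneCounts)))
  mapped <- parentMap != "orphan"
  if (any(mapped)) {
    missing <- setdiff(parentMap[mapped], rownames(geneCounts))
    if (length(missing))
      stop("parent gene row(s) missing from geneCounts: ",
           paste(missing, collapse = ", "))
    out[mapped, ] <- geneCounts[parentMap[mapped], , drop = FALSE]
  }
  if (any(!mapped)) {
    orphanIds <- ids[!mapped]
    if (is.null(orphanCounts) || !all(orphanIds %in% rownames(orphanCounts)))
      stop("orphanCounts must contain rows for all orphan candidates")
    out[!mapped, ] <- orphanCounts[orphanIds, , drop = FALSE]
  }
  out
}

#' Count fragments overlapping independent regions
#'
#' Per-region fragment counting for features quantified independently of the
#' gene model (orphan smORFs): a fragment counts for a region when any of
#' its blocks overlaps the region by at least 1 bp, irrespective of strand
#' and of other regions.
#'
#' @param fragments a `GRangesList` of fragments.
#' @param regions a named `GRangesList` of regions.
#' @return named integer vector of fragment counts per region.
#' @export
countRegionFragments <- function(fragments, regions) {
  out <- setNames(integer(length(regions)), names(regions))
  if (!length(fragments) || !length(regions)) return(out)
  flatF <- unlist(fragments, use.names = FALSE)
  fragOf <- rep(seq_along(fragments), lengths(fragments))
  flatR <- unlist(regions, use.names = FALSE)
  regOf <- rep(seq_along(regions), lengths(regions))
  hits <- findOverlaps(flatF, flatR, ignore.strand = TRUE)
  if (!length(hits)) return(out)
  key <- unique(paste(fragOf[queryHits(hits)], regOf[subjectHits(hits)]))
  regHit <- as.integer(sub(".* ", "", key))
  tab <- tabulate(regHit, nbins = length(regions))
  out[] <- tab
  out
}

#' FPKM and TPM normalisation
#'
#' `FPKM = 1e9 * c / (L * N)` with `N` the total counted fragments of the
#' sample; `TPM = 1e6 * (c/L) / sum(c/L)`. TPM columns sum to 1e6. For
#' orphan smORFs the effective length is the ORF length itself.
#'
#' @param counts feature x sample count matrix.
#' @param lengths named numeric vector of feature lengths in nt (exonic),
#'   covering all rows of `counts`.
#' @param librarySize optional per-sample total counted fragments `N`;
#'   defaults to the column sums of `counts`. Supply the gene-level library
#'   size when normalising smORF rows that inherit parent-gene counts.
#' @return list with matrices `fpkm` and `tpm`.
#' @export
normalizeExpression <- function(counts, lengths, librarySize = NULL) {
  if (!all(rownames(counts) %in% names(lengths)))
    stop("lengths missing for some features")
  L <- lengths[rownames(counts)]
  if (any(L <= 0)) stop("feature lengths must be positive")
  N <- if (is.null(librarySize)) colSums(counts) else librarySize[colnames(counts)]
  if (any(N == 0)) stop("normalization error: zero library size in sample(s) ",
                        paste(colnames(counts)[N == 0], collapse = ", "))
  fpkm <- 1e9 * sweep(counts / L, 2L, N, "/")
  rate <- counts / L
  tpm <- 1e6 * sweep(rate, 2L, colSums(rate), "/")
  list(fpkm = fpkm, tpm = tpm)
}

#' Average replicate samples per tissue
#'
#' @param mat feature x sample matrix.
#' @param design data.frame with `sample` and `tissue` columns covering all
#'   matrix columns.
#' @return feature x tissue matrix of arithmetic means.
#' @export
replicateMean <- function(mat, design) {
  if (!all(colnames(mat) %in% design$sample))
    stop("design error: sample(s) missing from design table")
  tissues <- unique(design$tissue)
  out <- vapply(tissues, function(t) {
    cols <- intersect(colnames(mat), design$sample[design$tissue == t])
    if (!length(cols))
      stop("design error: tissue ", t, " has no samples")
    rowMeans(mat[, cols, drop = FALSE])
  }, numeric(nrow(mat)))
  matrix(out, nrow = nrow(mat), dimnames = list(rownames(mat), tissues))
}

#' Sample-sample correlation of expression
#'
#' Correlation between samples on `log2(x + 1)` transformed values. Constant
#' columns (zero variance) get correlation 0 against everything, with a
#' warning; the diagonal is always 1.
#'
#' @param mat feature x sample matrix.
#' @param method `"pearson"` or `"spearman"`.
#' @return symmetric sample x sample correlation matrix.
#' @export
sampleCorrelation <- function(mat, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (ncol(mat) < 2L) stop("at least two samples are required")
  lx <- log2(mat + 1)
  sds <- apply(lx, 2L, stats::sd)
  cc <- suppressWarnings(stats::cor(lx, method = method))
  if (any(sds == 0)) {
    warning("constant sample(s): ",
            paste(colnames(mat)[sds == 0], collapse = ", "),
            "; correlations recorded as 0")
    cc[sds == 0, ] <- 0
    cc[, sds == 0] <- 0
  }
  diag(cc) <- 1
  cc
}
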