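#' @include AllClasses.R
NULL

# Vectorised two-sided Welch test on the rows of two matrices.
# Zero-variance rows: p = 1 when the group means agree, p = 0 otherwise.
.welchRows <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1L, stats::var); v2 <- apply(b, 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(-abs(tt), df)
  degenerate <- se2 == 0 | !is.finite(p)
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  p
}

#' Pairwise differential expression between tissues
#'
#' For every unordered tissue pair: counts are normalised to counts per
#' million (CPM) by library size; the fold change is
#' `log2((mean1 + 0.5) / (mean2 + 0.5))` over the tissue-mean CPM; p-values
#' come from a two-sided Welch test on `log2(CPM + 1)` replicate values,
#' adjusted by Benjamini-Hochberg within the pair. A feature is called
#' differential when `FDR <= fdrCutoff` and `|log2FC| >= lfcCutoff`
#' (defaults 0.05 and 2).
#'
#' @param counts feature x sample count matrix.
#' @param design data.frame with `sample` and `tissue` columns; every tissue
#'   needs at least 2 replicate samples.
#' @param fdrCutoff,lfcCutoff thresholds of the double gate.
#' @return named list (one element per pair, name `"A|B"`), each a
#'   data.frame with `feature`, `log2FC`, `pvalue`, `fdr`, `called`.
#' @export
pairwiseDE <- function(counts, design, fdrCutoff = 0.05, lfcCutoff = 2) {
  if (fdrCutoff <= 0 || fdrCutoff > 1) stop("fdrCutoff must be in (0, 1]")
  if (lfcCutoff < 0) stop("lfcCutoff must be non-negative")
  tissues <- unique(design$tissue)
  reps <- table(design$tissue)
  if (any(reps < 2L))
    stop("design error: tissue(s) with fewer than 2 replicates: ",
         paste(names(reps)[reps < 2L], collapse = ", "))
  cpm <- sweep(counts, 2L, colSums(counts), "/") * 1e6
  lcpm <- log2(cpm + 1)
  out <- list()
  for (i in seq_along(tissues)) {
    for (j in seq_along(tissues)) {
      if (j <= i) next
      s1 <- design$sample[design$tissue == tissues[i]]
      s2 <- design$sample[design$tissue == tissues[j]]
      m1 <- rowMeans(cpm[, s1, drop = FALSE])
      m2 <- rowMeans(cpm[, s2, drop = FALSE])
      lfc <- log2((m1 + 0.5) / (m2 + 0.5))
      p <- .welchRows(lcpm[, s1, drop = FALSE], lcpm[, s2, drop = FALSE])
      fdr <- stats::p.adjust(p, method = "BH")
      called <- fdr <= fdrCutoff & abs(lfc) >= lfcCutoff
      out[[paste(tissues[i], tissues[j], sep = "|")]] <- data.frame(
        feature = rownames(counts), log2FC = lfc, pvalue = p, fdr = fdr,
        called = called, row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  out
}

#' Tissue-by-tissue matrix of differential-feature counts
#'
#' @param calls result of [pairwiseDE()] (list over unordered pairs).
#' @param tissues tissue ordering for the matrix; inferred from the pair
#'   names when NULL.
#' @return symmetric integer matrix with zero diagonal.
#' @export
deCountMatrix <- function(calls, tissues = NULL) {
  pairs <- strsplit(names(calls), "|", fixed = TRUE)
  if (is.null(tissues))
    tissues <- unique(unlist(pairs))
  m <- matrix(NA_integer_, length(tissues), length(tissues),
              dimnames = list(tissues, tissues))
  diag(m) <- 0L
  for (k in seq_along(calls)) {
    a <- pairs[[k]][1L]; b <- pairs[[k]][2L]
    n <- sum(calls[[k]]$called)
    m[a, b] <- n
    m[b, a] <- n
  }
  if (anyNA(m))
    stop("completeness error: missing tissue pair(s) in calls")
  m
}

#' Summaries of a differential-count matrix
#'
#' Per-tissue mean (over that tissue's n-1 off-diagonal entries), the
#' overall mean over the n(n-1)/2 unordered pairs, and the largest and
#' smallest off-diagonal pair. The overall mean always equals the mean of
#' the per-tissue means.
#'
#' @param m symmetric tissue x tissue matrix with zero diagonal.
#' @return list with `perTissueMean` (named), `overallMean`, `max` and
#'   `min`, the latter two as `list(value, pair)`.
#' @export
summarizeDEMatrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m) || nrow(m) < 2L)
    stop("m must be a square matrix with at least 2 tissues")
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE)))
    stop("validation error: matrix is not symmetric")
  if (any(diag(m) != 0))
    stop("validation error: diagonal must be zero")
  n <- nrow(m)
  off <- m
  diag(off) <- NA
  perTissue <- rowMeans(off, na.rm = TRUE)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  vals <- m[upper.tri(m)]
  overall <- mean(vals)
  iMax <- which.max(vals)
  iMin <- which.min(vals)
  pairName <- function(k) {
    paste(rownames(m)[ut[k, "row"]], colnames(m)[ut[k, "col"]], sep = "|")
  }
  list(perTissueMean = perTissue,
       overallMean = overall,
       max = list(value = vals[iMax], pair = pairName(iMax)),
       min = list(value = vals[iMin], pair = pairName(iMin)))
}

#' Preprocess a tissue-level FPKM matrix for TSI
#'
#' The preprocessing applied before tissue-specificity scoring: (1) values
#' below 1 FPKM are set to 0 (a value of exactly 1 is retained); (2) rows
#' with no remaining expression are removed; (3) values are transformed
#' `log10(x + 1)` (zeros stay 0).
#'
#' @param mat feature x tissue FPKM matrix (replicates already averaged,
#'   see [replicateMean()]).
#' @return the filtered, transformed matrix.
#' @export
preprocessForTSI <- function(mat) {
  mat[mat < 1] <- 0
  keep <- rowSums(mat) > 0
  log10(mat[keep, , drop = FALSE] + 1)
}

#' Tissue-specificity index (TSI)
#'
#' `TSI = max(x) / sum(x)` per feature row. The value is 1 for exclusive
#' expression in one tissue and `1/n` for perfectly uniform expression over
#' `n` tissues.
#'
#' @param mat feature x tissue matrix with at least one positive entry per
#'   row (apply [preprocessForTSI()] first).
#' @return data.frame with `feature`, `tsi` and `tissue` (the argmax
#'   tissue, first in column order on ties).
#' @export
tsi <- function(mat) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1L)
  tot <- rowSums(mat)
  if (any(tot <= 0))
    stop("TSI undefined for all-zero rows; run preprocessForTSI() first")
  idx <- apply(mat, 1L, which.max)
  data.frame(feature = rownames(mat) %||% as.character(seq_len(nrow(mat))),
             tsi = apply(mat, 1L, max) / tot,
             tissue = colnames(mat)[idx] %||% as.character(idx),
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tissue-specific feature counts per TSI threshold
#'
#' A feature counts for its argmax tissue at a threshold when its TSI is at
#' least that threshold. Counts are non-increasing in the threshold.
#'
#' @param tsiResult result of [tsi()].
#' @param thresholds numeric thresholds in (0, 1].
#' @param tissues tissue ordering for the output rows; inferred when NULL.
#' @return tissue x threshold integer matrix.
#' @export
tissueSpecificCounts <- function(tsiResult,
                                 thresholds = c(0.8, 0.85, 0.9, 0.95, 1.0),
                                 tissues = NULL) {
  if (any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must lie in (0, 1]")
  if (is.null(tissues)) tissues <- unique(tsiResult$tissue)
  out <- vapply(thresholds, function(th) {
    hit <- tsiResult$tissue[tsiResult$tsi >= th]
    as.integer(table(factor(hit, levels = tissues)))
  }, integer(length(tissues)))
  matrix(out, nrow = length(tissues),
         dimnames = list(tissues, format(thresholds)))
}
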