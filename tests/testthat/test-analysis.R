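.deDesign <- function(reps = 3L, tissues = c("A", "B")) {
  data.frame(sample = c(sprintf("%s%d", tissues[1], 1:reps),
                        sprintf("%s%d", tissues[2], 1:reps)),
             tissue = rep(tissues, each = reps),
             replicate = rep(1:reps, 2))
}

test_that("identical expression in both tissues yields zero DE calls", {
  set.seed(4)
  base <- matrix(rpois(150, 80), nrow = 50)
  counts <- cbind(base, base)
  rownames(counts) <- sprintf("f%02d", 1:50)
  design <- .deDesign()
  colnames(counts) <- design$sample
  calls <- pairwiseDE(counts, design)
  expect_equal(sum(calls[["A|B"]]$called), 0L)
})

test_that("the fold-change gate blocks sub-threshold effects however significant", {
  # true log2FC = 1.5 with minuscule variance: significant but never called
  reps <- 3L
  counts <- matrix(c(rep(2000, reps), rep(round(2000 / 2^1.5), reps)),
                   nrow = 1, dimnames = list("f1", .deDesign(reps)$sample))
  counts <- rbind(counts, matrix(500, nrow = 30, ncol = 2 * reps,
                                 dimnames = list(sprintf("n%02d", 1:30),
                                                 colnames(counts))))
  calls <- pairwiseDE(counts, .deDesign(reps))[["A|B"]]
  f1 <- calls[calls$feature == "f1", ]
  expect_lt(abs(f1$log2FC), 2)
  expect_false(f1$called)
  expect_error(pairwiseDE(counts[, c(1, 4), drop = FALSE],
                          .deDesign(1L)), "fewer than 2")
})

test_that("planted 16-fold effects are recalled with controlled error", {
  sim <- simulateCountMatrix(nFeatures = 400L, nTrue = 40L, mean = 500,
                             dispersion = 0.05, log2fc = 4, seed = 8)
  calls <- pairwiseDE(sim$counts, sim$design)[["T1|T2"]]
  called <- calls$feature[calls$called]
  recall <- mean(sim$trueFeatures %in% called)
  fdr <- if (length(called))
    mean(!(called %in% sim$trueFeatures)) else 0
  expect_gte(recall, 0.9)
  expect_lte(fdr, 0.1)
})

test_that("the DE-count matrix is symmetric with a zero diagonal", {
  calls <- list(
    "A|B" = data.frame(feature = sprintf("f%d", 1:5), called = c(TRUE, TRUE,
      TRUE, TRUE, TRUE)),
    "A|C" = data.frame(feature = sprintf("f%d", 1:7), called = rep(TRUE, 7)),
    "B|C" = data.frame(feature = "f1", called = FALSE))
  m <- deCountMatrix(calls, tissues = c("A", "B", "C"))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), c(0L, 0L, 0L))
  expect_equal(unname(m["A", "B"]), 5L)
  expect_equal(unname(m["A", "C"]), 7L)
  expect_equal(unname(m["B", "C"]), 0L)
  expect_error(deCountMatrix(calls[1:2], tissues = c("A", "B", "C")),
               "completeness")
})

test_that("DE matrix summaries reproduce the published silkworm aggregates", {
  f <- system.file("extdata", "silkworm_de_counts.tsv",
                   package = "smorfscan")
  m <- as.matrix(read.delim(f, row.names = 1))
  s <- summarizeDEMatrix(m)
  expect_equal(unname(round(s$perTissueMean["ASG"], 1)), 5201.8)
  expect_equal(round(s$overallMean, 1), 5874.5)
  expect_equal(s$max$value, 12454)
  expect_setequal(strsplit(s$max$pair, "|", fixed = TRUE)[[1]],
                  c("SG", "TT"))
  expect_equal(s$min$value, 171)
  expect_setequal(strsplit(s$min$pair, "|", fixed = TRUE)[[1]],
                  c("MSG_M", "MSG_P"))
})

test_that("overall mean equals the mean of per-tissue means", {
  set.seed(6)
  for (n in c(3, 5, 8)) {
    m <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    vals <- sample.int(1000, n * (n - 1) / 2)
    m[upper.tri(m)] <- vals
    m <- m + t(m)
    s <- summarizeDEMatrix(m)
    expect_equal(s$overallMean, mean(s$perTissueMean))
    expect_equal(s$overallMean, mean(vals))
  }
  # constant off-diagonal: every summary equals the constant
  cm <- matrix(7, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(cm) <- 0
  sc <- summarizeDEMatrix(cm)
  expect_equal(unname(sc$perTissueMean), rep(7, 4))
  expect_equal(sc$overallMean, 7)
  expect_equal(sc$max$value, 7)
  # asymmetry is rejected
  bad <- cm; bad[1, 2] <- 9
  expect_error(summarizeDEMatrix(bad), "symmetric")
})

test_that("TSI preprocessing applies the sub-1 floor, drop, and log10 steps", {
  m <- rbind(low = c(0.5, 0.9, 0.99),
             keep1 = c(1, 0.2, 0.3),
             high = c(10, 0, 2))
  colnames(m) <- c("A", "B", "C")
  p <- preprocessForTSI(m)
  expect_false("low" %in% rownames(p))        # all sub-1: removed entirely
  expect_equal(unname(p["keep1", ]), c(log10(2), 0, 0))  # exactly 1 retained
  expect_equal(unname(p["high", "A"]), log10(11))
  expect_equal(unname(p["high", "B"]), 0)
})

test_that("TSI follows max/sum with its closed-form extremes", {
  expect_equal(tsi(matrix(c(5, 0, 0, 0), 1))$tsi, 1)
  for (n in c(2, 4, 10))
    expect_equal(tsi(matrix(rep(3, n), 1))$tsi, 1 / n)
  expect_equal(tsi(matrix(c(2, 1, 1), 1))$tsi, 0.5)
  # scale invariance
  set.seed(77)
  for (i in 1:20) {
    x <- matrix(runif(5, 0.1, 50), 1)
    expect_equal(tsi(x * runif(1, 0.01, 100))$tsi, tsi(x)$tsi)
  }
  # argmax tissue is recorded
  r <- tsi(matrix(c(1, 9, 2), 1, dimnames = list("f", c("A", "B", "C"))))
  expect_equal(r$tissue, "B")
  expect_error(tsi(matrix(0, 1, 3)), "all-zero")
})

test_that("tissue-specific counts are monotone in the threshold", {
  set.seed(55)
  mat <- matrix(runif(120, 0, 40), nrow = 30,
                dimnames = list(sprintf("f%02d", 1:30), c("A", "B", "C", "D")))
  mat[1:5, ] <- 0
  mat[1:5, 1] <- 20          # five exclusive to tissue A
  res <- tsi(preprocessForTSI(mat))
  counts <- tissueSpecificCounts(res)
  for (t in rownames(counts))
    expect_true(all(diff(counts[t, ]) <= 0))
  expect_gte(counts["A", "1.00"], 5)
  # no feature above 0.8 => all zero
  unif <- matrix(5, 4, 4, dimnames = list(letters[1:4], LETTERS[1:4]))
  resU <- tsi(preprocessForTSI(unif))
  expect_true(all(tissueSpecificCounts(resU, tissues = LETTERS[1:4]) == 0))
})

test_that("null simulations stay under a 1% call rate", {
  sim <- simulateCountMatrix(nFeatures = 2000L, nTrue = 0L, mean = 200,
                             dispersion = 0.05, replicates = 3L, seed = 12)
  calls <- pairwiseDE(sim$counts, sim$design)[["T1|T2"]]
  expect_lte(mean(calls$called), 0.01)
})
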