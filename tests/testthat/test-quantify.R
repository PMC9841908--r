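.twoGeneFeatures <- function() {
  f <- GRanges("c1", IRanges(c(101, 301, 601), c(260, 400, 760)),
               strand = "+")
  f$gene_id <- c("g1", "g1", "g2")
  f
}

test_that("union counting attributes, rejects ambiguity, conserves fragments", {
  feat <- .twoGeneFeatures()
  frags <- GRangesList(
    f1 = GRanges("c1", IRanges(120, 199)),              # inside g1 exon
    f2 = GRanges("c1", IRanges(c(240, 301), c(260, 350))), # junction, g1 only
    f3 = GRanges("c1", IRanges(390, 650)),              # spans g1 and g2
    f4 = GRanges("c1", IRanges(900, 979)),              # no feature
    f5 = GRanges("c1", IRanges(700, 759)))              # inside g2
  r <- countUnion(frags, feat)
  expect_equal(r$counts, c(g1 = 2L, g2 = 1L))
  expect_equal(r$ambiguous, 1L)
  expect_equal(r$noFeature, 1L)
  expect_equal(sum(r$counts) + r$ambiguous + r$noFeature, r$total)
  expect_equal(r$total, 5L)
})

test_that("union counting conserves fragments on random data", {
  set.seed(41)
  feat <- .twoGeneFeatures()
  st <- sample.int(1200, 300)
  frags <- GenomicRanges::split(
    GRanges("c1", IRanges(st, st + 79)), seq_along(st))
  r <- countUnion(frags, feat)
  expect_equal(sum(r$counts) + r$ambiguous + r$noFeature, 300L)
})

test_that("smORF rows inherit parent-gene counts bit-identically", {
  geneCounts <- matrix(c(50, 60, 70, 5, 6, 7), nrow = 2, byrow = TRUE,
                       dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  map <- c(smA = "g1", smB = "g1", smC = "orphan")
  orphan <- matrix(0L, nrow = 1, ncol = 3,
                   dimnames = list("smC", c("s1", "s2", "s3")))
  sc <- smorfCounts(geneCounts, map, orphan)
  expect_equal(sc["smA", ], geneCounts["g1", ])
  expect_identical(sc["smA", ], sc["smB", ])   # shared parent, shared row
  expect_equal(unname(sc["smC", ]), c(0, 0, 0))
  expect_error(smorfCounts(geneCounts, c(smX = "gMissing"), NULL), "missing")
})

test_that("parent mapping uses exon overlap with largest-overlap tie rules", {
  ann <- tinyAnnotation()
  sm <- rbind(
    data.frame(s = 150, e = 212),   # inside gA exon
    data.frame(s = 460, e = 504),   # inside gB exon (either strand counts)
    data.frame(s = 20, e = 79))     # no exon overlap: orphan
  blocks <- GRangesList(lapply(seq_len(nrow(sm)), function(i)
    GRanges("chrT", IRanges(sm$s[i], sm$e[i]), strand = "+")))
  ids <- smorfId(blocks)
  info <- data.frame(id = ids, chrom = "chrT", strand = "+",
                     startCodon = "ATG", peptide = "M",
                     ntLength = sm$e - sm$s + 1L,
                     fromTranscript = TRUE, fromConservation = FALSE,
                     coding = FALSE, homology = FALSE, tier = NA_character_,
                     category = NA_character_, provenance = "t",
                     stringsAsFactors = FALSE)
  smSet <- new("SmorfSet", blocks = setNames(blocks, ids),
               info = S4Vectors::DataFrame(info, row.names = ids))
  map <- smorfParentMap(smSet, ann)
  expect_equal(unname(map), c("gA", "gB", "orphan"))
})

test_that("FPKM and TPM follow their closed forms and identities", {
  counts <- matrix(10, nrow = 1, dimnames = list("f1", "s1"))
  n <- normalizeExpression(counts, c(f1 = 1000), librarySize = c(s1 = 1e6))
  expect_equal(unname(n$fpkm[1, 1]), 10)        # 1e9*10/(1000*1e6)
  expect_equal(unname(n$tpm[1, 1]), 1e6)        # single feature

  set.seed(13)
  counts <- matrix(rpois(60, 100), nrow = 10,
                   dimnames = list(sprintf("f%02d", 1:10),
                                   sprintf("s%d", 1:6)))
  lens <- setNames(sample(200:2000, 10), rownames(counts))
  n <- normalizeExpression(counts, lens)
  expect_true(all(abs(colSums(n$tpm) - 1e6) < 1e-3))
  # TPM equals FPKM rescaled to a million
  tpmFromFpkm <- sweep(n$fpkm, 2, colSums(n$fpkm), "/") * 1e6
  expect_equal(n$tpm, tpmFromFpkm, tolerance = 1e-9)
  expect_error(normalizeExpression(counts * 0, lens), "zero library")
})

test_that("replicate means group by tissue", {
  m <- matrix(c(1, 2, 3, 10, 20, 30), nrow = 1,
              dimnames = list("f", sprintf("s%d", 1:6)))
  design <- data.frame(sample = sprintf("s%d", 1:6),
                       tissue = rep(c("A", "B"), each = 3),
                       replicate = rep(1:3, 2))
  tm <- replicateMean(m, design)
  expect_equal(unname(tm[1, ]), c(2, 20))
  # single replicate passes through unchanged
  one <- replicateMean(m[, 1, drop = FALSE],
                       design[1, , drop = FALSE])
  expect_equal(unname(one[1, 1]), 1)
  # random design against a group-by oracle
  set.seed(9)
  mm <- matrix(runif(40), nrow = 5,
               dimnames = list(NULL, sprintf("s%d", 1:8)))
  dd <- data.frame(sample = sprintf("s%d", 1:8),
                   tissue = sample(c("X", "Y", "Z"), 8, replace = TRUE),
                   replicate = 1)
  dd$tissue[1:3] <- c("X", "Y", "Z")  # every tissue inhabited
  got <- replicateMean(mm, dd)
  for (t in unique(dd$tissue))
    expect_equal(got[, t],
                 rowMeans(mm[, dd$sample[dd$tissue == t], drop = FALSE]))
})

test_that("sample correlation is symmetric with unit diagonal", {
  set.seed(2)
  m <- matrix(rpois(300, 50), nrow = 50)
  colnames(m) <- sprintf("s%d", 1:6)
  m[, 2] <- m[, 1]                     # duplicated sample
  cc <- sampleCorrelation(m)
  expect_equal(cc, t(cc))
  expect_equal(unname(diag(cc)), rep(1, 6))
  expect_equal(unname(cc["s1", "s2"]), 1)

  # anti-correlated pair under spearman
  a <- 1:20
  m2 <- cbind(s1 = a, s2 = rev(a))
  expect_equal(unname(sampleCorrelation(m2, "spearman")["s1", "s2"]), -1)

  # constant sample: correlation recorded as 0 with a warning
  m3 <- cbind(s1 = c(1, 5, 9), s2 = c(0, 0, 0), s3 = c(2, 4, 8))
  expect_warning(c3 <- sampleCorrelation(m3), "constant")
  expect_equal(unname(c3["s2", "s1"]), 0)
  expect_equal(unname(c3["s2", "s2"]), 1)
})

test_that("independent region counting matches simple overlap", {
  regions <- GRangesList(r1 = GRanges("c1", IRanges(100, 199)),
                         r2 = GRanges("c1", IRanges(500, 599)))
  frags <- GRangesList(
    f1 = GRanges("c1", IRanges(90, 120)),
    f2 = GRanges("c1", IRanges(150, 180)),
    f3 = GRanges("c1", IRanges(300, 360)),
    f4 = GRanges("c1", IRanges(580, 640)))
  expect_equal(countRegionFragments(frags, regions), c(r1 = 2L, r2 = 1L))
})
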