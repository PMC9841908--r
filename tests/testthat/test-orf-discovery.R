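test_that("minimal ORFs are reported with start codon, peptide and length", {
  h <- scanOrfs("ATGAAATAA")
  expect_equal(nrow(h), 1L)
  expect_equal(h$peptide, "MK")
  expect_equal(h$ntLength, 9L)
  expect_equal(h$startCodon, "ATG")

  h2 <- scanOrfs("TTGAAATAA")
  expect_equal(h2$startCodon, "TTG")
  expect_equal(h2$peptide, "MK")   # near-cognate initiator decoded as Met

  expect_equal(nrow(scanOrfs("ATGAAAAAA")), 0L)   # no stop codon: no ORF
  expect_equal(nrow(scanOrfs("")), 0L)
  # codons containing N are never starts or stops
  expect_equal(nrow(scanOrfs("ANGAAATAA")), 0L)
  expect_equal(nrow(scanOrfs("ATGAAATNA")), 0L)
})

test_that("length bounds are applied after start selection", {
  # 303 nt (100 codons + stop) passes, 306 nt does not
  ok <- paste0("ATG", strrep("GCT", 99), "TAA")
  too <- paste0("ATG", strrep("GCT", 100), "TAA")
  expect_equal(scanOrfs(ok)$ntLength, 303L)
  expect_equal(nrow(scanOrfs(too)), 0L)
  # ...and an in-frame internal start does not rescue an over-long ORF in
  # longest-per-stop mode, but is reported with allStarts
  within <- paste0("ATG", strrep("GCT", 50), "ATG", strrep("GCT", 49), "TAA")
  expect_equal(nrow(scanOrfs(within)), 0L)
  expect_gt(nrow(scanOrfs(within, allStarts = TRUE)), 0L)
})

test_that("longest-per-stop picks the most-upstream admissible start", {
  s <- "TAAATGAAAACGAAATAG"   # stop, ATG, filler, ACG, filler, stop
  h <- scanOrfs(s)
  expect_equal(nrow(h), 1L)
  expect_equal(h$startCodon, "ATG")
  expect_equal(h$start, 4L)
  hAll <- scanOrfs(s, allStarts = TRUE)
  expect_equal(sort(hAll$startCodon), c("ACG", "ATG"))
})

test_that("scanner equals exhaustive enumeration on random sequences", {
  set.seed(17)
  for (rep in 1:12) {
    s <- randomSeq(800)
    for (mode in c(FALSE, TRUE)) {
      got <- scanOrfs(s, "both", allStarts = mode)
      want <- bruteOrfs(s, "both", allStarts = mode)
      expect_identical(orfKey(got), orfKey(want))
    }
  }
})

test_that("minus-strand coordinates convert correctly", {
  s <- revcompStr("ATGAAATAA")      # ORF only on the minus strand
  expect_equal(nrow(scanOrfs(s, "plus")), 0L)
  h <- scanOrfs(s, "both")
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "-")
  expect_equal(h$start, 1L)
  expect_equal(h$end, 9L)
  expect_equal(h$peptide, "MK")
})

test_that("conserved-region sweep: overlap, single species, min length", {
  a <- GRanges("chr1", IRanges(1, 100))
  b <- GRanges("chr1", IRanges(51, 150))
  r <- conservedRegions(list(spA = a, spB = b))
  expect_equal(start(r), 51)
  expect_equal(end(r), 100)
  expect_equal(r$speciesCount, 2L)

  expect_equal(length(conservedRegions(list(spA = a))), 0L)
  # 20-nt overlap is below the 30-nt floor
  short <- conservedRegions(list(spA = GRanges("chr1", IRanges(1, 50)),
                                 spB = GRanges("chr1", IRanges(31, 90))))
  expect_equal(length(short), 0L)
})

test_that("sweep is invariant to interval order and splitting", {
  a <- GRanges("chr1", IRanges(c(1, 200), c(120, 320)))
  b <- GRanges("chr1", IRanges(c(60, 250), c(180, 400)))
  cc <- GRanges("chr1", IRanges(90, 290))
  base <- conservedRegions(list(A = a, B = b, C = cc))
  shuf <- conservedRegions(list(C = cc, A = rev(a), B = b))
  expect_equal(as.data.frame(base), as.data.frame(shuf))
  # splitting one interval into adjacent pieces changes nothing
  aSplit <- GRanges("chr1", IRanges(c(1, 61, 200), c(60, 120, 320)))
  split <- conservedRegions(list(A = aSplit, B = b, C = cc))
  expect_equal(as.data.frame(base), as.data.frame(split))
})

test_that("sweep equals per-base coverage counting on random intervals", {
  set.seed(23)
  mk <- function() {
    n <- 60
    st <- sample.int(5000, n)
    GRanges(sample(c("c1", "c2"), n, replace = TRUE),
            IRanges(st, st + sample(20:200, n, replace = TRUE)))
  }
  sp <- list(s1 = mk(), s2 = mk(), s3 = mk(), s4 = mk())
  got <- conservedRegions(sp, minSpecies = 2L, minLen = 30L)
  gotDf <- data.frame(chrom = as.character(seqnames(got)),
                      start = start(got), end = end(got),
                      speciesCount = got$speciesCount)
  gotDf <- gotDf[order(gotDf$chrom, gotDf$start), ]
  rownames(gotDf) <- NULL
  want <- conservedOracle(sp, minSpecies = 2L, minLen = 30L)
  rownames(want) <- NULL
  expect_equal(gotDf, want)
})

test_that("evidence attachment follows the length-dependent homology rules", {
  blocks <- GRangesList(GRanges("c1", IRanges(1, 63), strand = "+"),
                        GRanges("c1", IRanges(101, 163), strand = "+"),
                        GRanges("c1", IRanges(201, 239), strand = "+"))
  info <- data.frame(
    id = smorfId(blocks), chrom = "c1", strand = "+",
    startCodon = "ATG",
    peptide = c(strrep("K", 20), strrep("R", 20), strrep("S", 12)),
    ntLength = c(63L, 63L, 39L), fromTranscript = TRUE,
    fromConservation = FALSE, coding = FALSE, homology = FALSE,
    tier = NA_character_, category = NA_character_, provenance = "t",
    stringsAsFactors = FALSE)
  sm <- new("SmorfSet",
            blocks = setNames(blocks, info$id),
            info = S4Vectors::DataFrame(info, row.names = info$id))
  hom <- data.frame(id = info$id[1:2], evalue = c(0.15, 0.2))
  sm2 <- attachEvidence(sm, homologyHits = hom,
                        shortCatalog = strrep("S", 12))
  expect_equal(unname(smorfInfo(sm2)$homology), c(TRUE, FALSE, TRUE))
  # unknown ids are skipped with a warning
  expect_warning(
    attachEvidence(sm, codingCalls = data.frame(id = "nope", coding = 1)),
    "unknown")
})

test_that("discovery merges transcript and conservation hits at one locus", {
  synth <- generateSyntheticData(smallConfig(19))
  sm <- discoverSmorfs(synth$genome, synth$annotation,
                       transcripts = synth$transcripts,
                       conservation = synth$conservation)
  info <- as.data.frame(sm)
  tr <- synth$truth$smorfs
  both <- tr[tr$fromTranscript & tr$conserved, ]
  expect_gt(nrow(both), 0L)
  m <- match(both$id, info$id)
  expect_false(anyNA(m))
  expect_true(all(info$fromTranscript[m]))
  expect_true(all(info$fromConservation[m]))

  # merging is idempotent: re-running discovery reproduces identical sets
  sm2 <- discoverSmorfs(synth$genome, synth$annotation,
                        transcripts = synth$transcripts,
                        conservation = synth$conservation)
  expect_identical(names(sm), names(sm2))
  expect_equal(as.data.frame(sm), as.data.frame(sm2))
})

test_that("every candidate's blocks re-extract and translate to its peptide", {
  synth <- generateSyntheticData(smallConfig(29))
  sm <- discoverSmorfs(synth$genome, synth$annotation,
                       transcripts = synth$transcripts,
                       conservation = synth$conservation)
  idx <- seq_len(min(length(sm), 80L))
  for (i in idx) {
    b <- smorfBlocks(sm)[[i]]
    chrom <- as.character(seqnames(b)[1])
    parts <- vapply(seq_along(b), function(k)
      as.character(Biostrings::subseq(synth$genome[[chrom]],
                                      start(b)[k], end(b)[k])),
      character(1))
    nt <- paste(parts, collapse = "")
    if (as.character(strand(b)[1]) == "-") nt <- revcompStr(nt)
    expect_equal(smorfscan:::.translateOrf(nt), smorfInfo(sm)$peptide[i])
    expect_true(substr(nt, nchar(nt) - 2, nchar(nt)) %in%
                  c("TAA", "TAG", "TGA"))
  }
})
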