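.mkSmorf <- function(blocks, peptide = "MKLV",
                     fromTx = TRUE, fromCons = FALSE) {
  if (is(blocks, "GRanges")) blocks <- GRangesList(blocks)
  ids <- smorfId(blocks)
  info <- data.frame(
    id = ids, chrom = vapply(blocks, function(b)
      as.character(seqnames(b)[1]), character(1)),
    strand = vapply(blocks, function(b)
      as.character(strand(b)[1]), character(1)),
    startCodon = "ATG", peptide = peptide,
    ntLength = sum(width(blocks)),
    fromTranscript = fromTx, fromConservation = fromCons,
    coding = FALSE, homology = FALSE,
    tier = NA_character_, category = NA_character_, provenance = "t",
    stringsAsFactors = FALSE)
  new("SmorfSet", blocks = setNames(blocks, ids),
      info = S4Vectors::DataFrame(info, row.names = ids))
}

test_that("confidence tiers follow the evidence logic", {
  df <- data.frame(
    fromTranscript  = c(TRUE,  TRUE,  TRUE,  TRUE,  FALSE, TRUE),
    fromConservation= c(FALSE, TRUE,  FALSE, FALSE, TRUE,  TRUE),
    coding          = c(TRUE,  FALSE, TRUE,  FALSE, FALSE, FALSE),
    homology        = c(TRUE,  TRUE,  FALSE, FALSE, FALSE, FALSE))
  expect_equal(assignConfidence(df),
               c("HC1", "HC2", "HC3", "LC1", "LC2", "LC1"))
  bad <- data.frame(fromTranscript = FALSE, fromConservation = FALSE,
                    coding = TRUE, homology = TRUE)
  expect_error(assignConfidence(bad), "empty evidence")
})

test_that("positional categories follow the priority rules", {
  ann <- tinyAnnotation()
  # txA (+): exons 101-220, 301-400; CDS 131-220 + 301-340
  # CDS transcript frame starts at tx position 31

  # fully inside CDS, in frame (codon-aligned with CDS start)
  inframe <- .mkSmorf(GRanges("chrT", IRanges(161, 220), strand = "+"))
  expect_equal(smorfInfo(assignCategory(inframe, ann))$category, "InFrameORF")

  # same region shifted by 1 nt: still inside CDS but out of frame
  outframe <- .mkSmorf(GRanges("chrT", IRanges(162, 218), strand = "+"))
  expect_equal(smorfInfo(assignCategory(outframe, ann))$category,
               "OutFrameORF")

  # spliced in-frame candidate spanning the CDS junction
  spliced <- .mkSmorf(GRangesList(GRanges("chrT",
    IRanges(c(158, 301), c(220, 321)), strand = "+")))
  expect_equal(smorfInfo(assignCategory(spliced, ann))$category, "InFrameORF")

  # within the 5'UTR (101-130) / 3'UTR (341-400) exonic footprints
  uorf <- .mkSmorf(GRanges("chrT", IRanges(104, 124), strand = "+"))
  expect_equal(smorfInfo(assignCategory(uorf, ann))$category, "uORF")
  dorf <- .mkSmorf(GRanges("chrT", IRanges(350, 379), strand = "+"))
  expect_equal(smorfInfo(assignCategory(dorf, ann))$category, "dORF")

  # antisense to the CDS: no same-strand rule fires, gene overlap remains
  anti <- .mkSmorf(GRanges("chrT", IRanges(161, 220), strand = "-"),
                   fromTx = FALSE, fromCons = TRUE)
  expect_equal(smorfInfo(assignCategory(anti, ann))$category, "intronORF")

  # inside the intron of txA (221-300)
  intr <- .mkSmorf(GRanges("chrT", IRanges(230, 259), strand = "+"),
                   fromTx = FALSE, fromCons = TRUE)
  expect_equal(smorfInfo(assignCategory(intr, ann))$category, "intronORF")

  # outside every gene
  inter <- .mkSmorf(GRanges("chrT", IRanges(20, 49), strand = "+"),
                    fromTx = FALSE, fromCons = TRUE)
  expect_equal(smorfInfo(assignCategory(inter, ann))$category,
               "intergenicORF")
})

test_that("a smORF on a lncRNA exon is an ncORF", {
  genes <- GRanges("c1", IRanges(c(1, 500), c(300, 800)), strand = "+",
                   gene_id = c("pc", "lnc"),
                   biotype = c("protein_coding", "lncRNA"))
  exons <- GRangesList(
    tPc = GRanges("c1", IRanges(1, 300), strand = "+"),
    tLnc = GRanges("c1", IRanges(500, 800), strand = "+"))
  cds <- list(tPc = GRanges("c1", IRanges(31, 270), strand = "+"))
  ann <- makeGenomeAnnotation(genes, exons, cds,
                              c(tPc = "pc", tLnc = "lnc"))
  nc <- .mkSmorf(GRanges("c1", IRanges(551, 601), strand = "+"))
  expect_equal(smorfInfo(assignCategory(nc, ann))$category, "ncORF")
})

test_that("priority: a uORF via one transcript beats intron via another", {
  genes <- GRanges("c1", IRanges(c(1, 1), c(400, 600)), strand = "+",
                   gene_id = c("gU", "gI"),
                   biotype = c("protein_coding", "protein_coding"))
  exons <- GRangesList(
    tU = GRanges("c1", IRanges(1, 400), strand = "+"),
    tI = GRanges("c1", IRanges(c(1, 501), c(40, 600)), strand = "+"))
  cds <- list(tU = GRanges("c1", IRanges(201, 380), strand = "+"),
              tI = GRanges("c1", IRanges(c(11, 501), c(40, 560)),
                           strand = "+"))
  ann <- makeGenomeAnnotation(genes, exons, cds, c(tU = "gU", tI = "gI"))
  # 101-131 is 5'UTR exon of tU and intron of tI
  cand <- .mkSmorf(GRanges("c1", IRanges(101, 130), strand = "+"))
  expect_equal(smorfInfo(assignCategory(cand, ann))$category, "uORF")
})

test_that("tier and category assignments partition synthetic candidates", {
  synth <- generateSyntheticData(smallConfig(31))
  sm <- discoverSmorfs(synth$genome, synth$annotation,
                       transcripts = synth$transcripts,
                       conservation = synth$conservation)
  sm <- attachEvidence(sm, synth$evidence$coding, synth$evidence$homology,
                       synth$evidence$shortCatalog)
  sm <- assignConfidence(sm)
  sm <- assignCategory(sm, synth$annotation)
  info <- as.data.frame(sm)
  expect_false(anyNA(info$tier))
  expect_false(anyNA(info$category))
  expect_true(all(info$tier %in% smorfTiers()))
  expect_true(all(info$category %in% smorfCategories()))
  tab <- tabulateSmorfs(sm)
  expect_equal(unname(tab["Total", "Total"]), nrow(info))
  expect_equal(unname(tab[, "Total"][-nrow(tab)]),
               unname(rowSums(tab[-nrow(tab), -ncol(tab)])))
})

test_that("classification table margins are consistent", {
  # published tier-by-category counts ship with the package
  f <- system.file("extdata", "silkworm_classification_counts.tsv",
                   package = "smorfscan")
  tab <- as.matrix(read.delim(f, row.names = 1))
  m <- addTableMargins(tab)
  expect_equal(unname(m["HC1", "Total"]), 738)
  expect_equal(unname(m["Total", "Total"]), sum(tab))

  # empty candidate set gives an all-zero table
  empty <- tabulateSmorfs(data.frame(tier = character(),
                                     category = character()))
  expect_true(all(empty == 0))
})
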