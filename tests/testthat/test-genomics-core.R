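test_that("FASTA reading normalises case and round-trips", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "acgtACGTnN", ">chr2", "TTTT"), fa)
  g <- readGenome(fa)
  expect_equal(length(g), 2L)
  expect_equal(as.character(g[["chr1"]]), "ACGTACGTNN")

  out <- withr::local_tempfile(fileext = ".fa")
  writeGenome(g, out)
  expect_equal(as.character(readGenome(out)), as.character(g))
})

test_that("FASTA reader rejects duplicate ids and missing files", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), fa)
  expect_error(readGenome(fa), "duplicated")
  expect_error(readGenome(file.path(tempdir(), "nope.fa")), "not found")
})

test_that("UTRs and introns are derived on the correct sides for both strands", {
  ann <- tinyAnnotation()
  # plus-strand gene: CDS 131-220 + 301-340 inside exons 101-220, 301-400
  u5 <- utr5ByTx(ann)[["txA"]]
  u3 <- utr3ByTx(ann)[["txA"]]
  expect_equal(start(u5), 101)
  expect_equal(end(u5), 130)
  expect_equal(start(u3), 343)
  expect_equal(end(u3), 400)
  intr <- intronsByTx(ann)[["txA"]]
  expect_equal(start(intr), 221)
  expect_equal(end(intr), 300)
  # minus-strand gene: 5'UTR is genomically downstream of the CDS
  expect_equal(start(utr5ByTx(ann)[["txB"]]), 541)
  expect_equal(end(utr5ByTx(ann)[["txB"]]), 570)
  expect_equal(start(utr3ByTx(ann)[["txB"]]), 451)
  expect_equal(end(utr3ByTx(ann)[["txB"]]), 480)
})

test_that("single-exon gene with CDS = exon has empty UTRs", {
  genes <- GRanges("c1", IRanges(1, 90), strand = "+",
                   gene_id = "g1", biotype = "protein_coding")
  exons <- GRangesList(t1 = GRanges("c1", IRanges(1, 90), strand = "+"))
  cds <- list(t1 = GRanges("c1", IRanges(1, 90), strand = "+"))
  ann <- makeGenomeAnnotation(genes, exons, cds, c(t1 = "g1"))
  expect_equal(length(utr5ByTx(ann)[["t1"]]), 0L)
  expect_equal(length(utr3ByTx(ann)[["t1"]]), 0L)
})

test_that("GFF3 write -> read round trip preserves the annotation model", {
  ann <- tinyAnnotation()
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeAnnotationGFF3(ann, gff)
  ann2 <- readAnnotation(gff)
  expect_equal(as.data.frame(annGenes(ann2))[, 1:5],
               as.data.frame(annGenes(ann))[, 1:5])
  expect_equal(annGenes(ann2)$biotype, annGenes(ann)$biotype)
  for (tx in names(exonsByTx(ann))) {
    expect_equal(as.data.frame(exonsByTx(ann2)[[tx]])[, 1:5],
                 as.data.frame(exonsByTx(ann)[[tx]])[, 1:5])
    expect_equal(as.data.frame(cdsByTx(ann2)[[tx]])[, 1:5],
                 as.data.frame(cdsByTx(ann)[[tx]])[, 1:5])
  }
  expect_equal(txGene(ann2), txGene(ann))
})

test_that("orphan features raise annotation errors naming the feature", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tx\tgene\t1\t100\t.\t+\t.\tID=g1",
               "c1\tx\tmRNA\t1\t100\t.\t+\t.\tID=t1;Parent=gMissing",
               "c1\tx\texon\t1\t100\t.\t+\t.\tParent=t1"), gff)
  expect_error(readAnnotation(gff), "t1")
})

test_that("spliced sequence matches substring / reverse-complement rules", {
  genome <- tinyGenome()
  ann <- tinyAnnotation()
  chr <- as.character(genome[["chrT"]])

  sA <- splicedSequence(genome, ann, "txA")
  expect_equal(sA, paste0(substr(chr, 101, 220), substr(chr, 301, 400)))

  sB <- splicedSequence(genome, ann, "txB")
  expect_equal(sB, revcompStr(substr(chr, 451, 570)))
})

test_that("two-exon minus-strand spliced sequence equals a per-base walk", {
  genes <- GRanges("chrT", IRanges(10, 120), strand = "-",
                   gene_id = "gM", biotype = "protein_coding")
  exons <- GRangesList(tM = GRanges("chrT", IRanges(c(10, 80), c(40, 120)),
                                    strand = "-"))
  ann <- makeGenomeAnnotation(genes, exons, NULL, c(tM = "gM"))
  genome <- tinyGenome(5)
  chr <- strsplit(as.character(genome[["chrT"]]), "")[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # walk transcript 5'->3': highest genomic position first, complemented
  walk <- c(vapply(120:80, function(p) comp[[chr[p]]], character(1)),
            vapply(40:10, function(p) comp[[chr[p]]], character(1)))
  expect_equal(splicedSequence(genome, ann, "tM"), paste(walk, collapse = ""))
  expect_equal(nchar(splicedSequence(genome, ann, "tM")),
               sum(width(exons[["tM"]])))
})

test_that("transcript intervals project to genomic blocks conserving length", {
  ann <- tinyAnnotation()
  # inside one exon -> single block
  b1 <- txToGenome(ann, "txA", 5, 20)[[1L]]
  expect_equal(length(b1), 1L)
  expect_equal(start(b1), 105)
  expect_equal(end(b1), 120)
  # spanning the junction -> two blocks, widths sum to interval length
  b2 <- txToGenome(ann, "txA", 115, 130)[[1L]]
  expect_equal(length(b2), 2L)
  expect_equal(sum(width(b2)), 16L)
  expect_error(txToGenome(ann, "txA", 200, 10000), "coordinate error")
})

test_that("projection agrees with a per-base oracle and inverts exactly", {
  set.seed(11)
  ann <- tinyAnnotation()
  for (tx in c("txA", "txB")) {
    L <- txLength(ann, tx)
    exTx <- exonsByTx(ann)[[tx]]
    minus <- as.character(strand(exTx)[1L]) == "-"
    # per-base genomic position of every transcript base
    gpos <- if (minus) {
      unlist(lapply(rev(seq_along(exTx)), function(i)
        seq(end(exTx)[i], start(exTx)[i])))
    } else {
      unlist(lapply(seq_along(exTx), function(i)
        seq(start(exTx)[i], end(exTx)[i])))
    }
    for (rep in 1:25) {
      s <- sample.int(L - 1L, 1L)
      e <- sample(s:L, 1L)
      blocks <- txToGenome(ann, tx, s, e)[[1L]]
      covered <- unlist(lapply(seq_along(blocks), function(i)
        seq(start(blocks)[i], end(blocks)[i])))
      expect_setequal(covered, gpos[s:e])
      # inverse mapping is the identity on every base
      expect_equal(sort(genomeToTx(ann, tx, gpos[s:e])), s:e)
    }
  }
})
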