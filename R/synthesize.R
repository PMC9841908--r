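#' @include AllClasses.R discover.R classify.R
NULL

#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions the generator emulates: a compact multi-gene
#' genome with UTRs, introns and non-coding genes; planted smORFs of every
#' positional category with in-frame stop codons and starts drawn from the
#' allowed 10-codon set; multi-species conservation evidence; and
#' negative-binomial expression (variance `mu + dispersion * mu^2`) over
#' `nTissues` tissues with `replicates` biological replicates each, planted
#' fold-changes and tissue-exclusive genes.
#'
#' @param seed integer seed; all generator output is a deterministic
#'   function of the configuration.
#' @param nChroms,chromLength genome shape (chromosomes are padded to
#'   `chromLength` nt).
#' @param nPerCategory planted smORFs per positional category.
#' @param nExtraGenes additional plain protein-coding genes (expression
#'   background, reliable-gene set, decoy hosts).
#' @param nTissues,replicates expression design (replicates per tissue,
#'   default 3).
#' @param dispersion negative-binomial dispersion phi.
#' @param baseMeanRange range of baseline per-gene fragment means.
#' @param plantedLog2FC planted log2 fold-change for differential genes.
#' @param nDEGenes number of genes with a planted fold-change.
#' @param exclusiveGenesPerTissue,exclusiveOrphansPerTissue number of
#'   tissue-exclusive host genes / orphan smORFs per tissue.
#' @param nSpecies number of aligned species for conservation evidence.
#' @param fragmentLength fragment (read-pair interval) length in nt.
#' @param conservedPerCategory how many single-exon planted smORFs per
#'   exonic category additionally receive conservation evidence.
#' @return a validated list of class `smorf_synth_config`.
#' @export
synthConfig <- function(seed = 1L, nChroms = 2L, chromLength = 40000L,
                        nPerCategory = 8L, nExtraGenes = 6L,
                        nTissues = 3L, replicates = 3L,
                        dispersion = 0.05, baseMeanRange = c(100, 250),
                        plantedLog2FC = 4, nDEGenes = 8L,
                        exclusiveGenesPerTissue = 1L,
                        exclusiveOrphansPerTissue = 1L,
                        nSpecies = 4L, fragmentLength = 80L,
                        conservedPerCategory = 2L) {
  cfg <- list(seed = as.integer(seed), nChroms = as.integer(nChroms),
              chromLength = as.integer(chromLength),
              nPerCategory = as.integer(nPerCategory),
              nExtraGenes = as.integer(nExtraGenes),
              nTissues = as.integer(nTissues),
              replicates = as.integer(replicates),
              dispersion = dispersion, baseMeanRange = baseMeanRange,
              plantedLog2FC = plantedLog2FC, nDEGenes = as.integer(nDEGenes),
              exclusiveGenesPerTissue = as.integer(exclusiveGenesPerTissue),
              exclusiveOrphansPerTissue = as.integer(exclusiveOrphansPerTissue),
              nSpecies = as.integer(nSpecies),
              fragmentLength = as.integer(fragmentLength),
              conservedPerCategory = as.integer(conservedPerCategory))
  stopifnot(cfg$nChroms >= 1L, cfg$chromLength >= 5000L,
            cfg$nPerCategory >= 1L, cfg$nExtraGenes >= 2L,
            cfg$nTissues >= 2L, cfg$replicates >= 2L, cfg$dispersion > 0,
            cfg$nSpecies >= 2L, cfg$fragmentLength >= 20L,
            cfg$nDEGenes >= 0L, cfg$conservedPerCategory >= 0L)
  class(cfg) <- "smorf_synth_config"
  cfg
}

.randStop <- function() sample(.STOP_CODONS, 1L)

# ORF string: allowed start + (nAa - 1) random non-stop codons + stop.
.makeOrf <- function(nAa, startCodon) {
  paste0(startCodon, .randCodons(nAa - 1L), .randStop())
}

.cycleStart <- function(i) kozakStartCodons()[(i - 1L) %% 10L + 1L]

## ---- host-gene plans ----------------------------------------------------

.planInFrame <- function(i) {
  nAa <- sample(30:60, 1L)
  orf <- .makeOrf(nAa, "ATG")
  u1 <- sample(15:25, 1L)
  utr5 <- paste0(.randDNA(u1), "TAA")
  utr3 <- .randDNA(sample(20:30, 1L))
  exonic <- paste0(utr5, orf, utr3)
  cdsS <- nchar(utr5) + 1L
  cdsE <- nchar(utr5) + nchar(orf)
  introns <- list()
  if (i %% 2L == 0L) {
    # intron splits the planted ORF itself: multi-block smORF
    introns <- list(list(after = cdsS + 29L,
                         seq = paste0("GT", .randDNA(40L), "AG"),
                         orfRel = NULL))
  }
  list(exonic = exonic, cdsTx = c(cdsS, cdsE),
       planted = list(list(txStart = cdsS, txEnd = cdsE,
                           category = "InFrameORF", startCodon = "ATG",
                           peptide = .translateOrf(orf))),
       introns = introns, biotype = "protein_coding")
}

.planOutFrame <- function(i) {
  startCodon <- .cycleStart(i)
  nCds <- 130L
  for (try in seq_len(400L)) {
    cds <- paste0("ATG", .randCodons(nCds - 1L), .randStop())
    nAa <- sample(15:35, 1L)
    orf <- .makeOrf(nAa, startCodon)
    seg <- paste0("TAA", orf)
    # embed at a codon-shifted offset inside the CDS, away from ends
    maxOff <- nchar(cds) - nchar(seg) - 9L
    offs <- seq.int(10L, maxOff, by = 3L)   # offset %% 3 == 1 (0-based)
    o <- sample(offs, 1L)
    cds2 <- paste0(substr(cds, 1L, o), seg,
                   substr(cds, o + nchar(seg) + 1L, nchar(cds)))
    # host frame must keep a single terminal stop
    cpos <- seq.int(1L, nchar(cds2) - 2L, by = 3L)
    cod <- substring(cds2, cpos, cpos + 2L)
    if (any(cod[-length(cod)] %in% .STOP_CODONS)) next
    utr5 <- .randDNA(sample(15:25, 1L))
    utr3 <- .randDNA(sample(20:30, 1L))
    exonic <- paste0(utr5, cds2, utr3)
    orfS <- nchar(utr5) + o + 4L            # after the 3-nt guard stop
    orfE <- orfS + nchar(orf) - 1L
    return(list(exonic = exonic,
                cdsTx = c(nchar(utr5) + 1L, nchar(utr5) + nchar(cds2)),
                planted = list(list(txStart = orfS, txEnd = orfE,
                                    category = "OutFrameORF",
                                    startCodon = startCodon,
                                    peptide = .translateOrf(orf))),
                introns = list(), biotype = "protein_coding"))
  }
  stop("failed to embed an out-of-frame ORF without disrupting the host CDS")
}

.planUtrHost <- function(i, side) {
  startCodon <- .cycleStart(i + 3L)
  nAa <- sample(8:25, 1L)
  orf <- .makeOrf(nAa, startCodon)
  cds <- paste0("ATG", .randCodons(119L), .randStop())
  if (side == "5") {
    u1 <- sample(10:20, 1L); u2 <- sample(6:12, 1L)
    utr5 <- paste0(.randDNA(u1), "TAA", orf, .randDNA(u2))
    utr3 <- .randDNA(sample(20:30, 1L))
    orfS <- u1 + 4L
    cat0 <- "uORF"
  } else {
    utr5 <- .randDNA(sample(15:25, 1L))
    u1 <- sample(8:14, 1L); u2 <- sample(8:14, 1L)
    utr3 <- paste0(.randDNA(u1), "TAA", orf, .randDNA(u2))
    orfS <- nchar(utr5) + nchar(cds) + u1 + 4L
    cat0 <- "dORF"
  }
  orfE <- orfS + nchar(orf) - 1L
  introns <- list()
  if (i %% 2L == 0L) {
    # intron inside the host CDS, away from the planted UTR element
    introns <- list(list(after = nchar(utr5) + 45L,
                         seq = paste0("GT", .randDNA(40L), "AG"),
                         orfRel = NULL))
  }
  list(exonic = paste0(utr5, cds, utr3),
       cdsTx = c(nchar(utr5) + 1L, nchar(utr5) + nchar(cds)),
       planted = list(list(txStart = orfS, txEnd = orfE, category = cat0,
                           startCodon = startCodon,
                           peptide = .translateOrf(orf))),
       introns = introns, biotype = "protein_coding")
}

.planNcHost <- function(i) {
  startCodon <- .cycleStart(i + 6L)
  nAa <- sample(10:30, 1L)
  orf <- .makeOrf(nAa, startCodon)
  left <- .randDNA(sample(25:40, 1L))
  right <- .randDNA(sample(25:40, 1L))
  exonic <- paste0(left, "TAA", orf, right)
  orfS <- nchar(left) + 4L
  list(exonic = exonic, cdsTx = NULL,
       planted = list(list(txStart = orfS, txEnd = orfS + nchar(orf) - 1L,
                           category = "ncORF", startCodon = startCodon,
                           peptide = .translateOrf(orf))),
       introns = list(), biotype = "lncRNA")
}

.planIntronHost <- function(i) {
  startCodon <- .cycleStart(i + 2L)
  nAa <- sample(10:30, 1L)
  orf <- .makeOrf(nAa, startCodon)
  intron <- paste0("GT", .randDNA(10L), "TAA", orf, .randDNA(10L), "AG")
  orfRel <- c(16L, 15L + nchar(orf))
  cds <- paste0("ATG", .randCodons(119L), .randStop())
  utr5 <- .randDNA(20L)
  utr3 <- .randDNA(20L)
  exonic <- paste0(utr5, cds, utr3)
  list(exonic = exonic, cdsTx = c(21L, 20L + nchar(cds)),
       planted = list(),
       introns = list(list(after = 20L + 60L, seq = intron, orfRel = orfRel,
                           startCodon = startCodon,
                           peptide = .translateOrf(orf),
                           category = "intronORF")),
       biotype = "protein_coding")
}

.planExtraGene <- function(i) {
  cds <- paste0("ATG", .randCodons(sample(100:150, 1L)), .randStop())
  list(exonic = paste0(.randDNA(20L), cds, .randDNA(20L)),
       cdsTx = c(21L, 20L + nchar(cds)),
       planted = list(), introns = list(), biotype = "protein_coding")
}

## ---- generator ----------------------------------------------------------

#' Generate a synthetic genome, annotation and ground-truth ledger
#'
#' Lays out protein-coding and lncRNA genes (with UTRs and introns) and
#' intergenic space over `nChroms` chromosomes, planting smORFs of all seven
#' positional categories. Every planted ORF starts with a codon from the
#' allowed set, has an in-frame stop, no internal stop, and an adjacent
#' upstream in-frame stop codon so that longest-per-stop scanning recovers
#' exactly the planted start. Intronic and intergenic smORFs carry
#' conservation evidence (they are invisible to the transcript route);
#' a subset of single-exon exonic smORFs is additionally conservation
#' flagged. Decoy elements (an over-long ORF and a start-less codon
#' stretch) exercise the scanner's filters.
#'
#' @param config a [synthConfig()].
#' @return list with `genome` (`DNAStringSet`), `annotation`
#'   ([GenomeAnnotation]) and `truth` (ledger: planted smORF table, planted
#'   expression means, DE/exclusive assignments, decoys).
#' @export
generateGenomeAndAnnotation <- function(config) {
  stopifnot(inherits(config, "smorf_synth_config"))
  set.seed(config$seed)
  nPC <- config$nPerCategory

  plans <- list()
  k <- 0L
  addPlan <- function(p, hostCategory) {
    k <<- k + 1L
    p$geneId <- sprintf("gene%03d", k)
    p$txId <- sprintf("tx%03d", k)
    p$strand <- if (k %% 2L == 0L) "-" else "+"
    p$hostCategory <- hostCategory
    plans[[k]] <<- p
  }
  for (i in seq_len(nPC)) addPlan(.planInFrame(i), "InFrameORF")
  for (i in seq_len(nPC)) addPlan(.planOutFrame(i), "OutFrameORF")
  for (i in seq_len(nPC)) addPlan(.planUtrHost(i, "5"), "uORF")
  for (i in seq_len(nPC)) addPlan(.planUtrHost(i, "3"), "dORF")
  for (i in seq_len(nPC)) addPlan(.planNcHost(i), "ncORF")
  for (i in seq_len(nPC)) addPlan(.planIntronHost(i), "intronORF")
  for (i in seq_len(config$nExtraGenes)) addPlan(.planExtraGene(i), "extra")

  # decoys live in the 3' UTRs of the first two extra genes (kept on +)
  extraIdx <- which(vapply(plans, `[[`, character(1L), "hostCategory") == "extra")
  decoyLong <- NULL; decoyStartless <- NULL
  p1 <- plans[[extraIdx[1L]]]
  longOrf <- .makeOrf(110L, "ATG")
  p1$strand <- "+"
  decoyLongTx <- c(nchar(p1$exonic) + 4L,
                   nchar(p1$exonic) + 3L + nchar(longOrf))
  p1$exonic <- paste0(p1$exonic, "TAA", longOrf, .randDNA(10L))
  plans[[extraIdx[1L]]] <- p1
  p2 <- plans[[extraIdx[2L]]]
  p2$strand <- "+"
  startless <- paste0("TAA", .randCodons(12L, excludeStarts = TRUE), "TGA")
  decoyStartlessTx <- c(nchar(p2$exonic) + 1L,
                        nchar(p2$exonic) + nchar(startless))
  p2$exonic <- paste0(p2$exonic, startless, .randDNA(10L))
  plans[[extraIdx[2L]]] <- p2

  # intergenic plantings (placed between genes, not annotated)
  gapPlants <- lapply(seq_len(nPC), function(i) {
    startCodon <- .cycleStart(i + 5L)
    nAa <- sample(10:30, 1L)
    orf <- .makeOrf(nAa, startCodon)
    sense <- paste0("TAA", orf)
    strand <- if (i %% 2L == 0L) "-" else "+"
    left <- .randDNA(60L)
    right <- .randDNA(60L)
    if (strand == "+") {
      seq <- paste0(left, sense, right)
      orfRel <- c(nchar(left) + 4L, nchar(left) + 3L + nchar(orf))
    } else {
      seq <- paste0(left, .revcomp(sense), right)
      # on the minus strand the ORF occupies the left part of revcomp(sense)
      orfRel <- c(nchar(left) + 1L, nchar(left) + nchar(orf))
    }
    list(seq = seq, orfRel = orfRel, strand = strand, startCodon = startCodon,
         peptide = .translateOrf(orf))
  })

  ## ---- layout ----------------------------------------------------------
  decoyZone <- 1500L
  chromNames <- sprintf("chr%02d", seq_len(config$nChroms))
  pieces <- setNames(vector("list", config$nChroms), chromNames)
  cursor <- setNames(integer(config$nChroms), chromNames)
  place <- function(chrom, s) {
    gstart <- cursor[[chrom]] + 1L
    pieces[[chrom]][[length(pieces[[chrom]]) + 1L]] <<- s
    cursor[[chrom]] <<- cursor[[chrom]] + nchar(s)
    if (cursor[[chrom]] > config$chromLength - decoyZone)
      stop("capacity error: chromLength too small for the requested gene count")
    gstart
  }
  for (ch in chromNames) place(ch, .randDNA(200L))

  geneRows <- list(); exonRows <- list(); cdsRows <- list()
  txGeneVec <- character()
  plantedRows <- list()
  orphanRows <- list()

  recPlanted <- function(category, startCodon, peptide, chrom, strand, blocks,
                         conserved, parentGene, txId) {
    gr <- BiocGenerics::sort(blocks)
    plantedRows[[length(plantedRows) + 1L]] <<- data.frame(
      id = smorfId(gr), category = category, startCodon = startCodon,
      peptide = peptide, chrom = chrom, strand = strand,
      blocks = paste(start(gr), end(gr), sep = "-", collapse = ","),
      ntLength = sum(width(gr)),
      fromTranscript = !(category %in% c("intronORF", "intergenicORF")),
      conserved = conserved, parentGene = parentGene, txId = txId,
      stringsAsFactors = FALSE)
  }

  for (gi in seq_along(plans)) {
    p <- plans[[gi]]
    chrom <- chromNames[(gi - 1L) %% config$nChroms + 1L]
    # intergenic gap, occasionally hosting a planted intergenic ORF
    gapIdx <- gi
    if (gapIdx <= length(gapPlants)) {
      gp <- gapPlants[[gapIdx]]
      place(chrom, .randDNA(sample(120:250, 1L)))
      gpStart <- place(chrom, gp$seq)
      blocks <- GRanges(chrom,
                        IRanges(gpStart + gp$orfRel[1L] - 1L,
                                gpStart + gp$orfRel[2L] - 1L),
                        strand = gp$strand)
      recPlanted("intergenicORF", gp$startCodon, gp$peptide, chrom,
                 gp$strand, blocks, conserved = TRUE,
                 parentGene = NA_character_, txId = NA_character_)
      place(chrom, .randDNA(sample(120:250, 1L)))
    } else {
      place(chrom, .randDNA(sample(250:500, 1L)))
    }

    ## assemble the gene: insert introns into the exonic (mRNA) sequence
    introns <- p$introns
    exonic <- p$exonic
    txLen <- nchar(exonic)
    afters <- vapply(introns, `[[`, numeric(1L), "after")
    o <- order(afters)
    introns <- introns[o]; afters <- afters[o]
    senseParts <- list(); senseExonStart <- integer(); exonTxStart <- integer()
    posTx <- 1L; senseLen <- 0L
    exonBounds <- c(afters, txLen)
    exonStartsTx <- c(1L, afters + 1L)
    senseStarts <- integer(length(exonStartsTx))
    senseSeq <- ""
    intronSense <- list()
    for (e in seq_along(exonStartsTx)) {
      s <- exonStartsTx[e]; eEnd <- exonBounds[e]
      senseStarts[e] <- nchar(senseSeq) + 1L
      senseSeq <- paste0(senseSeq, substr(exonic, s, eEnd))
      if (e <= length(introns)) {
        intronSense[[e]] <- c(nchar(senseSeq) + 1L,
                              nchar(senseSeq) + nchar(introns[[e]]$seq))
        senseSeq <- paste0(senseSeq, introns[[e]]$seq)
      }
    }
    senseLen <- nchar(senseSeq)
    gSeq <- if (p$strand == "+") senseSeq else .revcomp(senseSeq)
    gstart <- place(chrom, gSeq)
    gend <- gstart + senseLen - 1L
    senseToGenome <- function(sp) {
      if (p$strand == "+") gstart + sp - 1L else gend - sp + 1L
    }
    # exon genomic ranges
    exonG <- lapply(seq_along(exonStartsTx), function(e) {
      sS <- senseStarts[e]
      sE <- sS + (exonBounds[e] - exonStartsTx[e])
      g1 <- senseToGenome(sS); g2 <- senseToGenome(sE)
      IRanges(min(g1, g2), max(g1, g2))
    })
    exonGr <- GRanges(chrom, do.call(c, exonG), strand = p$strand)
    exonGr <- BiocGenerics::sort(exonGr)
    geneRows[[length(geneRows) + 1L]] <- GRanges(
      chrom, IRanges(gstart, gend), strand = p$strand,
      gene_id = p$geneId, biotype = p$biotype)
    exonRows[[p$txId]] <- exonGr
    txGeneVec[p$txId] <- p$geneId

    # transcript -> genomic mapping for CDS and exonic plantings
    mapTx <- function(s, e) {
      # split [s, e] (transcript coords) at exon boundaries
      res <- list()
      for (ei in seq_along(exonStartsTx)) {
        lo <- max(s, exonStartsTx[ei]); hi <- min(e, exonBounds[ei])
        if (lo > hi) next
        sp1 <- senseStarts[ei] + (lo - exonStartsTx[ei])
        sp2 <- senseStarts[ei] + (hi - exonStartsTx[ei])
        g1 <- senseToGenome(sp1); g2 <- senseToGenome(sp2)
        res[[length(res) + 1L]] <- IRanges(min(g1, g2), max(g1, g2))
      }
      GRanges(chrom, do.call(c, res), strand = p$strand)
    }
    if (!is.null(p$cdsTx))
      cdsRows[[p$txId]] <- BiocGenerics::sort(mapTx(p$cdsTx[1L], p$cdsTx[2L]))

    for (pl in p$planted) {
      blocks <- mapTx(pl$txStart, pl$txEnd)
      conserved <- isTRUE(pl$conserved)
      recPlanted(pl$category, pl$startCodon, pl$peptide, chrom, p$strand,
                 blocks, conserved = conserved, parentGene = p$geneId,
                 txId = p$txId)
    }
    for (ii in seq_along(introns)) {
      intr <- introns[[ii]]
      if (is.null(intr$orfRel)) next
      sp1 <- intronSense[[ii]][1L] + intr$orfRel[1L] - 1L
      sp2 <- intronSense[[ii]][1L] + intr$orfRel[2L] - 1L
      g1 <- senseToGenome(sp1); g2 <- senseToGenome(sp2)
      blocks <- GRanges(chrom, IRanges(min(g1, g2), max(g1, g2)),
                        strand = p$strand)
      recPlanted(intr$category, intr$startCodon, intr$peptide, chrom,
                 p$strand, blocks, conserved = TRUE, parentGene = p$geneId,
                 txId = NA_character_)
    }
    if (gi == extraIdx[1L]) {
      decoyLong <- list(txId = p$txId, tx = decoyLongTx,
                        blocks = mapTx(decoyLongTx[1L], decoyLongTx[2L]))
    }
    if (gi == extraIdx[2L]) {
      decoyStartless <- list(txId = p$txId,
                             blocks = mapTx(decoyStartlessTx[1L],
                                            decoyStartlessTx[2L]))
    }
  }

  # pad chromosomes to chromLength (tail doubles as the decoy zone for
  # single-species conservation intervals)
  genome <- Biostrings::DNAStringSet(vapply(chromNames, function(ch) {
    s <- paste(unlist(pieces[[ch]]), collapse = "")
    paste0(s, .randDNA(config$chromLength - nchar(s)))
  }, character(1L)))
  names(genome) <- chromNames

  genes <- unlist(GRangesList(geneRows))
  ann <- makeGenomeAnnotation(genes, GRangesList(exonRows),
                              cdsRows, txGeneVec)

  truthSmorfs <- do.call(rbind, plantedRows)
  rownames(truthSmorfs) <- NULL

  ## conservation flags for single-exon exonic plantings
  exonCats <- c("InFrameORF", "OutFrameORF", "uORF", "dORF", "ncORF")
  truthSmorfs$singleBlock <- !grepl(",", truthSmorfs$blocks, fixed = TRUE)
  for (cat0 in exonCats) {
    cand <- which(truthSmorfs$category == cat0 & truthSmorfs$singleBlock)
    take <- utils::head(cand, config$conservedPerCategory)
    truthSmorfs$conserved[take] <- TRUE
  }
  truthSmorfs$fromConservation <- truthSmorfs$conserved

  ## evidence-tier plan: cycle tiers within each category
  txTiers <- c("HC1", "HC2", "HC3", "LC1")
  consTiers <- c("HC1", "HC2", "HC3", "LC2")
  tier <- character(nrow(truthSmorfs))
  for (cat0 in unique(truthSmorfs$category)) {
    rows <- which(truthSmorfs$category == cat0)
    cyc <- if (cat0 %in% c("intronORF", "intergenicORF")) consTiers else txTiers
    tier[rows] <- cyc[(seq_along(rows) - 1L) %% length(cyc) + 1L]
  }
  truthSmorfs$tier <- tier
  truthSmorfs$coding <- tier %in% c("HC1", "HC3")
  truthSmorfs$homology <- tier %in% c("HC1", "HC2")

  ## expression plan
  geneIds <- genes$gene_id
  tissues <- sprintf("T%d", seq_len(config$nTissues))
  base <- stats::runif(length(geneIds), config$baseMeanRange[1L],
                       config$baseMeanRange[2L])
  geneMeans <- matrix(rep(base, config$nTissues), ncol = config$nTissues,
                      dimnames = list(geneIds, tissues))
  hostCat <- vapply(plans, `[[`, character(1L), "hostCategory")
  deHosts <- utils::head(geneIds[hostCat == "InFrameORF"], config$nDEGenes)
  deRows <- list()
  for (d in seq_along(deHosts)) {
    tUp <- tissues[(d - 1L) %% config$nTissues + 1L]
    geneMeans[deHosts[d], tUp] <-
      geneMeans[deHosts[d], tUp] * 2^config$plantedLog2FC
    deRows[[d]] <- data.frame(gene = deHosts[d], tissue = tUp,
                              log2fc = config$plantedLog2FC,
                              stringsAsFactors = FALSE)
  }
  exclGenes <- list()
  ncHostIds <- geneIds[hostCat == "ncORF"]
  gptr <- 0L
  for (t in tissues) {
    for (r in seq_len(config$exclusiveGenesPerTissue)) {
      gptr <- gptr + 1L
      if (gptr > length(ncHostIds)) break
      g <- ncHostIds[gptr]
      geneMeans[g, ] <- 0
      geneMeans[g, t] <- max(base[match(g, geneIds)], 150)
      exclGenes[[length(exclGenes) + 1L]] <-
        data.frame(gene = g, tissue = t, stringsAsFactors = FALSE)
    }
  }

  orphan <- truthSmorfs[truthSmorfs$category == "intergenicORF", ]
  orphanMeans <- matrix(rep(stats::runif(nrow(orphan),
                                         config$baseMeanRange[1L],
                                         config$baseMeanRange[2L]),
                            config$nTissues),
                        ncol = config$nTissues,
                        dimnames = list(orphan$id, tissues))
  exclOrphans <- list()
  optr <- 0L
  for (t in tissues) {
    for (r in seq_len(config$exclusiveOrphansPerTissue)) {
      optr <- optr + 1L
      if (optr > nrow(orphan)) break
      oid <- orphan$id[optr]
      orphanMeans[oid, ] <- 0
      orphanMeans[oid, t] <- 200
      exclOrphans[[length(exclOrphans) + 1L]] <-
        data.frame(id = oid, tissue = t, stringsAsFactors = FALSE)
    }
  }
  exclusiveTissue <- rep(NA_character_, nrow(truthSmorfs))
  exclG <- do.call(rbind, c(exclGenes, list(NULL)))
  if (!is.null(exclG)) {
    m <- match(truthSmorfs$parentGene, exclG$gene)
    exclusiveTissue[!is.na(m)] <- exclG$tissue[m[!is.na(m)]]
  }
  exclO <- do.call(rbind, c(exclOrphans, list(NULL)))
  if (!is.null(exclO)) {
    m <- match(truthSmorfs$id, exclO$id)
    exclusiveTissue[!is.na(m)] <- exclO$tissue[m[!is.na(m)]]
  }
  truthSmorfs$exclusiveTissue <- exclusiveTissue

  ## reliable-gene table (protein alignment identity/coverage)
  codingGenes <- geneIds[genes$biotype == "protein_coding"]
  nUnrel <- min(3L, length(codingGenes) - 1L)
  identity <- stats::runif(length(codingGenes), 35, 95)
  coverage <- stats::runif(length(codingGenes), 35, 95)
  unrel <- utils::tail(seq_along(codingGenes), nUnrel)
  identity[unrel] <- stats::runif(nUnrel, 5, 25)
  reliable <- data.frame(gene = codingGenes,
                         identity = round(identity, 1L),
                         coverage = round(coverage, 1L),
                         stringsAsFactors = FALSE)

  truth <- list(
    smorfs = truthSmorfs,
    geneMeans = geneMeans,
    orphanMeans = orphanMeans,
    deGenes = do.call(rbind, c(deRows, list(NULL))),
    exclusiveGenes = exclG,
    exclusiveOrphans = exclO,
    reliableGenes = reliable,
    tissues = tissues,
    decoys = list(
      longOrf = list(id = smorfId(decoyLong$blocks)),
      startless = list(chrom = as.character(seqnames(decoyStartless$blocks))[1L],
                       start = min(start(decoyStartless$blocks)),
                       end = max(end(decoyStartless$blocks)))))
  list(genome = genome, annotation = ann, truth = truth)
}

#' Generate per-species conservation intervals
#'
#' Every conservation-flagged planted smORF is covered (with 9 nt of
#' flanking context) by intervals from at least two species; decoy
#' single-species intervals are placed in the gene-free chromosome tails so
#' the >= 2-species sweep must reject them.
#'
#' @param synth result of [generateGenomeAndAnnotation()].
#' @param config the [synthConfig()] used to generate it.
#' @return named list (one `GRanges` per species).
#' @export
generateConservation <- function(synth, config) {
  set.seed(config$seed + 1L)
  species <- sprintf("species%02d", seq_len(config$nSpecies))
  rows <- setNames(rep(list(list()), length(species)), species)
  addRow <- function(sp, chrom, lo, hi) {
    rows[[sp]][[length(rows[[sp]]) + 1L]] <<-
      data.frame(chrom = chrom, lo = lo, hi = hi, stringsAsFactors = FALSE)
  }
  tr <- synth$truth$smorfs
  cons <- tr[tr$conserved, , drop = FALSE]
  for (i in seq_len(nrow(cons))) {
    b <- .parseBlocks(cons$blocks[i])
    lo <- max(1L, min(b[, 1L]) - 9L)
    hi <- max(b[, 2L]) + 9L
    nsp <- sample(2:min(4L, config$nSpecies), 1L)
    take <- sample(species, nsp)
    for (sp in take) addRow(sp, cons$chrom[i], lo, hi)
  }
  # single-species decoys in the gene-free chromosome tails
  chroms <- names(synth$genome)
  for (si in seq_along(species)) {
    ch <- chroms[(si - 1L) %% length(chroms) + 1L]
    zStart <- config$chromLength - 1400L + (si - 1L) * 320L
    addRow(species[si], ch, zStart, zStart + 99L)
  }
  lapply(rows, function(rr) {
    df <- do.call(rbind, rr)
    BiocGenerics::sort(GRanges(df$chrom, IRanges(df$lo, df$hi)))
  })
}

#' @noRd
.parseBlocks <- function(s) {
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
}

#' Generate per-sample read fragments and the design table
#'
#' Per-transcript fragment counts are drawn negative-binomially
#' (`variance = mu + dispersion * mu^2`) from the planted tissue-level
#' means, implementing the planted fold-changes and tissue-exclusive
#' expression (exclusive features have exactly zero fragments in the other
#' tissues). Fragments are placed uniformly along the spliced transcript and
#' projected to genomic blocks, so junction fragments appear as two blocks.
#' Orphan (intergenic) planted smORFs receive fragments over their own
#' genomic region.
#'
#' @param synth result of [generateGenomeAndAnnotation()].
#' @param config the corresponding [synthConfig()].
#' @return list with `fragments` (named list of `GRangesList`, one per
#'   sample) and `design` (data.frame sample/tissue/replicate).
#' @export
generateFragments <- function(synth, config) {
  set.seed(config$seed + 2L)
  ann <- synth$annotation
  truth <- synth$truth
  tissues <- truth$tissues
  design <- do.call(rbind, lapply(tissues, function(t) {
    data.frame(sample = sprintf("%s_rep%d", t, seq_len(config$replicates)),
               tissue = t, replicate = seq_len(config$replicates),
               stringsAsFactors = FALSE)
  }))
  txIds <- names(exonsByTx(ann))
  geneOfTx <- txGene(ann)
  txOfGene <- setNames(names(geneOfTx), geneOfTx)  # one tx per gene here
  fl <- config$fragmentLength
  size <- 1 / config$dispersion

  frags <- list()
  for (si in seq_len(nrow(design))) {
    smp <- design$sample[si]; tis <- design$tissue[si]
    blockChrom <- character(); blockStart <- integer(); blockEnd <- integer()
    fragOf <- integer()
    nFrag <- 0L
    for (g in rownames(truth$geneMeans)) {
      mu <- truth$geneMeans[g, tis]
      if (mu <= 0) next
      cnt <- stats::rnbinom(1L, mu = mu, size = size)
      if (cnt == 0L) next
      tx <- txOfGene[[g]]
      tl <- txLength(ann, tx)
      len <- min(fl, tl)
      starts <- sample.int(tl - len + 1L, cnt, replace = TRUE)
      proj <- txToGenome(ann, tx, starts, starts + len - 1L)
      flat <- unlist(proj, use.names = FALSE)
      nb <- lengths(proj)
      blockChrom <- c(blockChrom, as.character(seqnames(flat)))
      blockStart <- c(blockStart, start(flat))
      blockEnd <- c(blockEnd, end(flat))
      fragOf <- c(fragOf, nFrag + rep(seq_len(cnt), nb))
      nFrag <- nFrag + cnt
    }
    for (oid in rownames(truth$orphanMeans)) {
      mu <- truth$orphanMeans[oid, tis]
      if (mu <= 0) next
      cnt <- stats::rnbinom(1L, mu = mu, size = size)
      if (cnt == 0L) next
      row <- truth$smorfs[truth$smorfs$id == oid, ]
      b <- .parseBlocks(row$blocks)
      lo <- min(b[, 1L]); hi <- max(b[, 2L])
      len <- min(fl, hi - lo + 1L)
      starts <- lo + sample.int(hi - lo + 1L - len + 1L, cnt,
                                replace = TRUE) - 1L
      blockChrom <- c(blockChrom, rep(row$chrom, cnt))
      blockStart <- c(blockStart, starts)
      blockEnd <- c(blockEnd, starts + len - 1L)
      fragOf <- c(fragOf, nFrag + seq_len(cnt))
      nFrag <- nFrag + cnt
    }
    gr <- GRanges(blockChrom, IRanges(blockStart, blockEnd), strand = "*")
    ids <- sprintf("%s_frag%06d", smp, fragOf)
    grl <- GenomicRanges::split(gr, factor(ids, levels = unique(ids)))
    frags[[smp]] <- grl
  }
  list(fragments = frags, design = design)
}

#' Generate coding-potential and homology evidence tables
#'
#' Emits the external-evidence tables the classifier consumes, matching the
#' ground-truth flags: a coding-call table (id, call, score) and a homology
#' table (id, subject, E-value <= 0.15, peptide length) for peptides longer
#' than 15 aa, plus a short-peptide catalog for homology-flagged peptides of
#' at most 15 aa.
#'
#' @param synth result of [generateGenomeAndAnnotation()].
#' @param config the corresponding [synthConfig()].
#' @return list with `coding` (data.frame), `homology` (data.frame) and
#'   `shortCatalog` (character vector of peptides).
#' @export
generateEvidence <- function(synth, config) {
  set.seed(config$seed + 3L)
  tr <- synth$truth$smorfs
  codingRows <- tr[tr$coding, , drop = FALSE]
  coding <- data.frame(id = codingRows$id, coding = 1L,
                       score = round(stats::runif(nrow(codingRows), 0.6, 0.99), 3L),
                       stringsAsFactors = FALSE)
  hom <- tr[tr$homology, , drop = FALSE]
  pepLen <- nchar(hom$peptide)
  long <- hom[pepLen > 15L, , drop = FALSE]
  homology <- data.frame(
    id = long$id,
    subject = sprintf("refsmorf%04d", seq_len(nrow(long))),
    evalue = signif(10^stats::runif(nrow(long), -10, log10(0.15)), 3L),
    pepLength = nchar(long$peptide),
    stringsAsFactors = FALSE)
  shortCatalog <- hom$peptide[pepLen <= 15L]
  list(coding = coding, homology = homology, shortCatalog = shortCatalog)
}

#' Simulate a two-condition negative-binomial count matrix
#'
#' Direct count-level simulation for differential-expression calibration:
#' `nFeatures` features over two tissue groups with `replicates` samples
#' each, counts drawn from a negative binomial with variance
#' `mu + dispersion * mu^2`. The first `nTrue` features carry a planted
#' `log2fc` fold-change (up in the first group); the rest are null.
#'
#' @param nFeatures,nTrue feature counts (null features =
#'   `nFeatures - nTrue`).
#' @param mean baseline negative-binomial mean.
#' @param dispersion dispersion phi.
#' @param log2fc planted log2 fold-change for the true features.
#' @param replicates samples per group.
#' @param seed integer seed.
#' @param tissues names of the two groups.
#' @return list with `counts` (matrix), `design` (data.frame) and
#'   `trueFeatures` (character vector of planted feature ids).
#' @export
simulateCountMatrix <- function(nFeatures = 2000L, nTrue = 200L, mean = 500,
                                dispersion = 0.05, log2fc = 4,
                                replicates = 3L, seed = 1L,
                                tissues = c("T1", "T2")) {
  stopifnot(nTrue <= nFeatures, replicates >= 2L, dispersion > 0)
  set.seed(seed)
  features <- sprintf("feat%05d", seq_len(nFeatures))
  design <- data.frame(
    sample = c(sprintf("%s_rep%d", tissues[1L], seq_len(replicates)),
               sprintf("%s_rep%d", tissues[2L], seq_len(replicates))),
    tissue = rep(tissues, each = replicates),
    replicate = rep(seq_len(replicates), 2L),
    stringsAsFactors = FALSE)
  size <- 1 / dispersion
  mu <- matrix(mean, nrow = nFeatures, ncol = 2L * replicates)
  if (nTrue > 0L)
    mu[seq_len(nTrue), seq_len(replicates)] <- mean * 2^log2fc
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                   nrow = nFeatures,
                   dimnames = list(features, design$sample))
  list(counts = counts, design = design,
       trueFeatures = features[seq_len(nTrue)])
}

#' Generate a complete synthetic data set
#'
#' Convenience wrapper running [generateGenomeAndAnnotation()],
#' [generateConservation()], [generateFragments()] and
#' [generateEvidence()] for one configuration.
#'
#' @param config a [synthConfig()].
#' @return list with `genome`, `annotation`, `transcripts`, `conservation`,
#'   `fragments`, `design`, `evidence`, `reliableGenes`, `truth` and the
#'   `config`.
#' @export
generateSyntheticData <- function(config = synthConfig()) {
  synth <- generateGenomeAndAnnotation(config)
  conservation <- generateConservation(synth, config)
  fr <- generateFragments(synth, config)
  evidence <- generateEvidence(synth, config)
  list(genome = synth$genome, annotation = synth$annotation,
       transcripts = transcriptSequences(synth$genome, synth$annotation),
       conservation = conservation, fragments = fr$fragments,
       design = fr$design, evidence = evidence,
       reliableGenes = synth$truth$reliableGenes,
       truth = synth$truth, config = config)
}

#' Write a synthetic data set to a directory of standard-format files
#'
#' Writes genome and transcript FASTA, annotation GFF3, one BED file of
#' alignment intervals per species, one BED fragment file per sample, the
#' design TSV, evidence TSVs, the reliable-gene TSV and a JSON ground-truth
#' ledger.
#'
#' @param synthData result of [generateSyntheticData()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeSyntheticData <- function(synthData, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "conservation"), showWarnings = FALSE)
  dir.create(file.path(dir, "fragments"), showWarnings = FALSE)
  writeGenome(synthData$genome, file.path(dir, "genome.fa"))
  writeGenome(synthData$transcripts, file.path(dir, "transcripts.fa"))
  writeAnnotationGFF3(synthData$annotation, file.path(dir, "annotation.gff3"))
  for (sp in names(synthData$conservation))
    rtracklayer::export(synthData$conservation[[sp]],
                        file.path(dir, "conservation", paste0(sp, ".bed")),
                        format = "bed")
  for (smp in names(synthData$fragments))
    writeFragments(synthData$fragments[[smp]],
                   file.path(dir, "fragments", paste0(smp, ".bed")))
  writeDesign(synthData$design, file.path(dir, "design.tsv"))
  .writeTsv(synthData$evidence$coding, file.path(dir, "coding_calls.tsv"))
  .writeTsv(synthData$evidence$homology, file.path(dir, "homology_hits.tsv"))
  writeLines(synthData$evidence$shortCatalog,
             file.path(dir, "short_catalog.txt"))
  .writeTsv(synthData$reliableGenes, file.path(dir, "reliable_genes.tsv"))
  truth <- synthData$truth
  truth$geneMeans <- as.data.frame(truth$geneMeans)
  truth$orphanMeans <- as.data.frame(truth$orphanMeans)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
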