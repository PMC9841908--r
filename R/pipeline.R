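#' @include AllClasses.R discover.R classify.R quantify.R analysis.R synthesize.R
NULL

#' Pipeline tuning parameters
#'
#' Collects every tunable of the end-to-end pipeline with its default:
#' the allowed start-codon set, ORF length bounds (9-303 nt: 2-100 codons
#' plus stop), reliable-gene thresholds (identity/coverage >= 30%),
#' conserved-region sweep settings (>= 2 species, >= 30 nt), the homology
#' E-value cutoff (0.15), the differential-expression double gate
#' (FDR <= 0.05, |log2FC| >= 2) and the TSI thresholds
#' (0.8, 0.85, 0.9, 0.95, 1.0).
#'
#' @param ... overrides for any default named below.
#' @return a named list of parameters.
#' @export
smorfParams <- function(...) {
  p <- list(startCodons = kozakStartCodons(), minNt = 9L, maxNt = 303L,
            allStarts = FALSE, minSpecies = 2L, minConsLen = 30L,
            identityMin = 30, coverageMin = 30, maxEvalue = 0.15,
            fdrCutoff = 0.05, lfcCutoff = 2,
            tsiThresholds = c(0.8, 0.85, 0.9, 0.95, 1.0),
            corMethod = "pearson")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  p
}

# Gene-level exon features (union of transcript exons per gene) and their
# exonic lengths.
.geneFeatures <- function(ann) {
  ex <- exonsByTx(ann)
  txg <- txGene(ann)
  flat <- unlist(ex, use.names = FALSE)
  geneOf <- rep(unname(txg[names(ex)]), lengths(ex))
  byGene <- reduce(GenomicRanges::split(flat, geneOf), ignore.strand = TRUE)
  feat <- unlist(byGene, use.names = FALSE)
  feat$gene_id <- rep(names(byGene), lengths(byGene))
  list(features = feat, lengths = setNames(sum(width(byGene)), names(byGene)))
}

#' Run the full smORF pipeline on a directory of input files
#'
#' Orchestrates the stages Kozak-model -> discovery -> evidence tiering ->
#' positional classification -> quantification -> differential expression ->
#' tissue specificity, writing every stage output as a standard-format file
#' under `outDir` and returning all in-memory results plus a machine-readable
#' run manifest. With identical inputs and parameters the outputs are
#' identical.
#'
#' @param inputDir directory with the input files as laid out by
#'   [writeSyntheticData()]: `genome.fa`, `annotation.gff3`,
#'   `transcripts.fa` (optional), `conservation/*.bed`, `fragments/*.bed`,
#'   `design.tsv`, `coding_calls.tsv`, `homology_hits.tsv`,
#'   `short_catalog.txt`, `reliable_genes.tsv` (the last five optional).
#' @param outDir output directory (created).
#' @param params a [smorfParams()] list.
#' @return list with `smorfs` ([SmorfSet]), `kozak` ([KozakProfile] or
#'   NULL), `classification` (tier x category matrix with margins),
#'   `counts`, `smorfCountsMatrix`, `fpkm`, `tpm`, `correlation`,
#'   `deCalls`, `deMatrix`, `deSummary`, `tsi`, `tissueSpecific` and
#'   `manifest`.
#' @export
runSmorfPipeline <- function(inputDir, outDir, params = smorfParams()) {
  t0 <- Sys.time()
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(inputDir, ...)
  manifest <- list(params = params, inputDir = inputDir, outDir = outDir,
                   stages = list())
  stamp <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  ## inputs
  genome <- readGenome(pth("genome.fa"))
  ann <- readAnnotation(pth("annotation.gff3"))
  transcripts <- if (file.exists(pth("transcripts.fa")))
    readGenome(pth("transcripts.fa")) else NULL
  consFiles <- if (dir.exists(pth("conservation")))
    list.files(pth("conservation"), pattern = "\\.bed$", full.names = TRUE)
  else character()
  conservation <- if (length(consFiles)) {
    setNames(lapply(consFiles, rtracklayer::import, format = "bed"),
             sub("\\.bed$", "", basename(consFiles)))
  } else NULL

  ## Kozak model from reliable coding genes
  kozak <- NULL
  if (file.exists(pth("reliable_genes.tsv"))) {
    hits <- .readTsv(pth("reliable_genes.tsv"))
    reliable <- filterReliableGenes(hits, params$identityMin,
                                    params$coverageMin)
    txg <- txGene(ann)
    cds <- cdsByTx(ann)
    ctxs <- character()
    for (tx in names(txg)) {
      if (!(txg[[tx]] %in% reliable)) next
      cd <- cds[[tx]]
      if (!length(cd)) next
      cdsStartG <- if (as.character(strand(cd)[1L]) == "-") max(end(cd))
                   else min(start(cd))
      s <- if (!is.null(transcripts) && tx %in% names(transcripts))
        as.character(transcripts[[tx]]) else splicedSequence(genome, ann, tx)
      ctxs <- c(ctxs, extractKozakContext(s, genomeToTx(ann, tx, cdsStartG)))
    }
    if (length(ctxs)) {
      kozak <- buildKozakProfile(ctxs)
      writeKozakProfile(kozak, file.path(outDir, "kozak_profile.tsv"))
    }
    stamp("kozak", reliableGenes = length(reliable), contexts = length(ctxs))
  }

  ## discovery + evidence + classification
  smorfs <- discoverSmorfs(genome, ann, transcripts = transcripts,
                           conservation = conservation,
                           startCodons = params$startCodons,
                           minNt = params$minNt, maxNt = params$maxNt,
                           allStarts = params$allStarts,
                           minSpecies = params$minSpecies,
                           minConsLen = params$minConsLen)
  coding <- if (file.exists(pth("coding_calls.tsv")))
    .readTsv(pth("coding_calls.tsv")) else NULL
  homology <- if (file.exists(pth("homology_hits.tsv")))
    .readTsv(pth("homology_hits.tsv")) else NULL
  shortCatalog <- if (file.exists(pth("short_catalog.txt")))
    readLines(pth("short_catalog.txt")) else character()
  smorfs <- attachEvidence(smorfs, coding, homology, shortCatalog,
                           maxEvalue = params$maxEvalue)
  smorfs <- assignConfidence(smorfs)
  smorfs <- assignCategory(smorfs, ann)
  classification <- tabulateSmorfs(smorfs)
  writeSmorfGFF3(smorfs, file.path(outDir, "smorfs.gff3"))
  writeSmorfPeptides(smorfs, file.path(outDir, "smorf_peptides.fa"))
  writeSmorfTable(smorfs, file.path(outDir, "smorfs.tsv"))
  .writeTsv(as.data.frame(classification), file.path(outDir,
            "classification_table.tsv"), rowNames = TRUE)
  stamp("discover", candidates = length(smorfs),
        tiers = as.list(table(smorfs@info$tier)),
        categories = as.list(table(smorfs@info$category)))

  ## quantification
  out <- list(smorfs = smorfs, kozak = kozak,
              classification = classification, manifest = manifest)
  fragDir <- pth("fragments")
  if (dir.exists(fragDir) && file.exists(pth("design.tsv"))) {
    design <- readDesign(pth("design.tsv"))
    fragFiles <- list.files(fragDir, pattern = "\\.bed$", full.names = TRUE)
    sampleFragments <- setNames(lapply(fragFiles, readFragments),
                                sub("\\.bed$", "", basename(fragFiles)))
    sampleFragments <- sampleFragments[design$sample]
    gf <- .geneFeatures(ann)
    cm <- buildCountMatrix(sampleFragments, gf$features)
    parentMap <- smorfParentMap(smorfs, ann)
    orphanIds <- names(parentMap)[parentMap == "orphan"]
    orphanCounts <- vapply(sampleFragments, countRegionFragments,
                           integer(length(orphanIds)),
                           regions = smorfBlocks(smorfs)[orphanIds])
    orphanCounts <- matrix(orphanCounts, nrow = length(orphanIds),
                           dimnames = list(orphanIds, names(sampleFragments)))
    sc <- smorfCounts(cm$counts, parentMap, orphanCounts)
    smorfLengths <- ifelse(parentMap == "orphan",
                           smorfInfo(smorfs)$ntLength[match(names(parentMap),
                                                            names(smorfs))],
                           gf$lengths[parentMap])
    names(smorfLengths) <- names(parentMap)
    librarySize <- colSums(cm$counts)
    norm <- normalizeExpression(sc, smorfLengths, librarySize = librarySize)
    correlation <- sampleCorrelation(sc, method = params$corMethod)
    .writeTsv(as.data.frame(cm$counts), file.path(outDir, "gene_counts.tsv"),
              rowNames = TRUE)
    .writeTsv(as.data.frame(sc), file.path(outDir, "smorf_counts.tsv"),
              rowNames = TRUE)
    .writeTsv(as.data.frame(norm$fpkm), file.path(outDir, "smorf_fpkm.tsv"),
              rowNames = TRUE)
    .writeTsv(as.data.frame(norm$tpm), file.path(outDir, "smorf_tpm.tsv"),
              rowNames = TRUE)
    .writeTsv(as.data.frame(correlation),
              file.path(outDir, "sample_correlation.tsv"), rowNames = TRUE)
    .writeTsv(cm$stats, file.path(outDir, "count_stats.tsv"))
    stamp("quantify", samples = ncol(sc), orphans = length(orphanIds),
          counted = unname(colSums(cm$counts)))

    ## differential expression
    deCalls <- pairwiseDE(sc, design, fdrCutoff = params$fdrCutoff,
                          lfcCutoff = params$lfcCutoff)
    deMat <- deCountMatrix(deCalls, tissues = unique(design$tissue))
    deSummary <- summarizeDEMatrix(deMat)
    .writeTsv(as.data.frame(deMat), file.path(outDir, "de_matrix.tsv"),
              rowNames = TRUE)
    for (pair in names(deCalls)) {
      fn <- paste0("de_", gsub("[^A-Za-z0-9]", "_", pair), ".tsv")
      .writeTsv(deCalls[[pair]], file.path(outDir, fn))
    }
    stamp("de", pairs = length(deCalls),
          totalCalls = sum(vapply(deCalls, function(d) sum(d$called),
                                  integer(1L))))

    ## tissue specificity
    fpkmTissue <- replicateMean(norm$fpkm, design)
    pre <- preprocessForTSI(fpkmTissue)
    tsiRes <- tsi(pre)
    tsCounts <- tissueSpecificCounts(tsiRes, params$tsiThresholds,
                                     tissues = unique(design$tissue))
    .writeTsv(tsiRes, file.path(outDir, "tsi.tsv"))
    .writeTsv(as.data.frame(tsCounts),
              file.path(outDir, "tissue_specific_counts.tsv"),
              rowNames = TRUE)
    stamp("tsi", retained = nrow(tsiRes))

    out$counts <- cm$counts
    out$countStats <- cm$stats
    out$parentMap <- parentMap
    out$smorfCountsMatrix <- sc
    out$fpkm <- norm$fpkm
    out$tpm <- norm$tpm
    out$correlation <- correlation
    out$deCalls <- deCalls
    out$deMatrix <- deMat
    out$deSummary <- deSummary
    out$tsi <- tsiRes
    out$tissueSpecific <- tsCounts
    out$design <- design
  }

  manifest$elapsedSec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  out$manifest <- manifest
  jsonlite::write_json(
    list(params = lapply(params, function(x) x),
         stages = manifest$stages),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  out
}

#' One-command synthetic demonstration run with ground-truth recovery report
#'
#' Generates a synthetic data set, writes it to `file.path(dir, "data")`,
#' runs the full pipeline on those files into `file.path(dir, "results")`
#' and compares every pipeline output against the generator's ledger:
#' discovery, peptide, category and tier accuracy on the planted smORFs,
#' decoy rejection, TSI recovery of tissue-exclusive features and
#' differential-expression recall / empirical false discovery.
#'
#' @param dir working directory for the demo.
#' @param seed integer seed for the synthetic data.
#' @param config optional [synthConfig()] (its seed is used as-is when
#'   supplied).
#' @param params a [smorfParams()] list.
#' @return list with `pipeline` (see [runSmorfPipeline()]), `truth`,
#'   `report` (named list of recovery metrics) and `dir`.
#' @export
smorfDemo <- function(dir = tempfile("smorfdemo"), seed = 1L,
                      config = NULL, params = smorfParams()) {
  if (is.null(config)) config <- synthConfig(seed = seed)
  synthData <- generateSyntheticData(config)
  dataDir <- file.path(dir, "data")
  writeSyntheticData(synthData, dataDir)
  pipe <- runSmorfPipeline(dataDir, file.path(dir, "results"),
                           params = params)
  report <- recoveryReport(pipe, synthData$truth)
  jsonlite::write_json(report, file.path(dir, "recovery_report.json"),
                       auto_unbox = TRUE, digits = NA)
  list(pipeline = pipe, truth = synthData$truth, report = report, dir = dir)
}

#' Compare pipeline output with a ground-truth ledger
#'
#' @param pipe result of [runSmorfPipeline()].
#' @param truth ground-truth ledger from the synthetic generator.
#' @return named list of recovery metrics (rates in `[0, 1]`).
#' @export
recoveryReport <- function(pipe, truth) {
  sm <- pipe$smorfs
  info <- as.data.frame(sm)
  tr <- truth$smorfs
  m <- match(tr$id, info$id)
  found <- !is.na(m)
  discoveryRate <- mean(found)
  peptideRate <- mean(info$peptide[m[found]] == tr$peptide[found])
  categoryRate <- mean(info$category[m[found]] == tr$category[found])
  tierRate <- mean(info$tier[m[found]] == tr$tier[found])
  decoyAbsent <- !(truth$decoys$longOrf$id %in% info$id)

  report <- list(
    nPlanted = nrow(tr), nCandidates = nrow(info),
    discoveryRate = discoveryRate, peptideRate = peptideRate,
    categoryRate = categoryRate, tierRate = tierRate,
    decoyLongAbsent = decoyAbsent)

  if (!is.null(pipe$tsi)) {
    excl <- tr[!is.na(tr$exclusiveTissue), , drop = FALSE]
    tt <- pipe$tsi
    mm <- match(excl$id, tt$feature)
    ok <- !is.na(mm) & tt$tsi[mm] == 1 & tt$tissue[mm] == excl$exclusiveTissue
    report$tsiExclusiveRate <- mean(ok)
    report$nExclusive <- nrow(excl)
  }
  if (!is.null(pipe$deCalls) && !is.null(truth$deGenes)) {
    tissues <- truth$tissues
    parentMap <- pipe$parentMap
    # expected DE smORF-pair events: smORFs of planted-DE genes, in every
    # pair involving the up-tissue; exclusive features likewise
    expected <- character()
    for (d in seq_len(nrow(truth$deGenes))) {
      g <- truth$deGenes$gene[d]; tUp <- truth$deGenes$tissue[d]
      ids <- names(parentMap)[parentMap == g & names(parentMap) %in% tr$id]
      for (t2 in setdiff(tissues, tUp))
        expected <- c(expected, paste(ids, .pairKey(tUp, t2, tissues)))
    }
    # candidates whose counts derive from a planted-DE or tissue-exclusive
    # source (including unplanted spurious ORFs inside those genes/regions)
    # are genuinely differential and must not count as false positives
    exempt <- character()
    for (d in seq_len(nrow(truth$deGenes))) {
      g <- truth$deGenes$gene[d]; tUp <- truth$deGenes$tissue[d]
      ids <- names(parentMap)[parentMap == g]
      for (t2 in setdiff(tissues, tUp))
        exempt <- c(exempt, paste(ids, .pairKey(tUp, t2, tissues)))
    }
    exclRows <- list()
    if (!is.null(truth$exclusiveGenes) && nrow(truth$exclusiveGenes))
      for (d in seq_len(nrow(truth$exclusiveGenes)))
        exclRows[[length(exclRows) + 1L]] <- list(
          ids = names(parentMap)[parentMap == truth$exclusiveGenes$gene[d]],
          tissue = truth$exclusiveGenes$tissue[d])
    if (!is.null(truth$exclusiveOrphans) && nrow(truth$exclusiveOrphans)) {
      orphanBlocks <- smorfBlocks(sm)
      for (d in seq_len(nrow(truth$exclusiveOrphans))) {
        oid <- truth$exclusiveOrphans$id[d]
        oi <- match(oid, names(sm))
        ids <- oid
        if (!is.na(oi)) {
          ov <- findOverlaps(range(orphanBlocks[[oi]]),
                             unlist(range(orphanBlocks)),
                             ignore.strand = TRUE)
          ids <- unique(c(ids, names(sm)[subjectHits(ov)]))
        }
        exclRows[[length(exclRows) + 1L]] <- list(
          ids = ids, tissue = truth$exclusiveOrphans$tissue[d])
      }
    }
    for (er in exclRows)
      for (t2 in setdiff(tissues, er$tissue))
        exempt <- c(exempt, paste(er$ids, .pairKey(er$tissue, t2, tissues)))
    called <- character()
    for (pair in names(pipe$deCalls)) {
      d <- pipe$deCalls[[pair]]
      called <- c(called, paste(d$feature[d$called], pair))
    }
    truthSet <- unique(expected)
    report$deRecall <- if (length(truthSet))
      mean(truthSet %in% called) else NA_real_
    fp <- setdiff(called, union(truthSet, exempt))
    report$deEmpiricalFdr <- if (length(called))
      length(fp) / length(called) else 0
    report$deCalled <- length(called)
  }
  report
}

# canonical unordered pair key matching pairwiseDE's naming
.pairKey <- function(a, b, tissues) {
  if (match(a, tissues) < match(b, tissues)) paste(a, b, sep = "|")
  else paste(b, a, sep = "|")
}
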