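#' @include AllClasses.R scan.R coords.R
NULL

#' Canonical smORF candidate id
#'
#' The id is a pure function of the genomic location: chromosome, strand and
#' the sorted CDS blocks. Identical loci always receive identical ids, so
#' merging transcript- and conservation-derived hits, and re-running
#' discovery, is deterministic. Identical peptides at different loci remain
#' distinct candidates.
#'
#' @param blocks a `GRanges` of CDS blocks (single candidate) or a
#'   `GRangesList` (one id per element).
#' @return character vector of ids of the form
#'   `smORF:<chrom>:<strand>:<s1-e1[,s2-e2...]>`.
#' @export
smorfId <- function(blocks) {
  if (is(blocks, "GRanges"))
    blocks <- GRangesList(blocks)
  vapply(seq_along(blocks), function(i) {
    b <- BiocGenerics::sort(blocks[[i]])
    sprintf("smORF:%s:%s:%s",
            as.character(seqnames(b)[1L]),
            as.character(strand(b)[1L]),
            paste(start(b), end(b), sep = "-", collapse = ","))
  }, character(1L))
}

.newSmorfSet <- function(blocks, df) {
  info <- DataFrame(df)
  rownames(info) <- df$id
  names(blocks) <- df$id
  new("SmorfSet", blocks = blocks, info = info)
}

.emptySmorfInfo <- function(n = 0L) {
  data.frame(id = character(n), chrom = character(n), strand = character(n),
             startCodon = character(n), peptide = character(n),
             ntLength = integer(n), fromTranscript = logical(n),
             fromConservation = logical(n), coding = logical(n),
             homology = logical(n), tier = rep(NA_character_, n),
             category = rep(NA_character_, n),
             provenance = character(n), stringsAsFactors = FALSE)
}

#' Discover smORF candidates from transcripts and conserved regions
#'
#' Runs the ORF scanner over (i) every spliced transcript sequence on the
#' sense strand, projecting hits back to genomic blocks through the
#' transcript's exon structure, and (ii) every >= `minSpecies`-species
#' conserved genomic region on both strands (unspliced single-block hits).
#' Hits landing on the same genomic locus (chromosome, strand, identical
#' blocks) are merged into one candidate whose evidence flags are the union
#' of the sources. Coding-potential and homology flags start FALSE; attach
#' them afterwards with [attachEvidence()].
#'
#' @param genome a `DNAStringSet`.
#' @param ann a [GenomeAnnotation].
#' @param transcripts optional named `DNAStringSet` of spliced transcript
#'   sequences; computed from `genome` + `ann` when NULL.
#' @param conservation optional named list of per-species `GRanges`
#'   alignment intervals (see [conservedRegions()]); NULL skips the
#'   conserved-region route.
#' @param startCodons,minNt,maxNt,allStarts passed to [scanOrfs()].
#' @param minSpecies,minConsLen passed to [conservedRegions()].
#' @return a [SmorfSet].
#' @export
discoverSmorfs <- function(genome, ann, transcripts = NULL,
                           conservation = NULL,
                           startCodons = kozakStartCodons(),
                           minNt = 9L, maxNt = 303L, allStarts = FALSE,
                           minSpecies = 2L, minConsLen = 30L) {
  blockList <- list()
  rows <- list()

  addHit <- function(blocks, startCodon, peptide, ntLength, fromTx, fromCons,
                     prov) {
    id <- smorfId(blocks)
    if (!is.null(rows[[id]])) {
      r <- rows[[id]]
      r$fromTranscript <- r$fromTranscript || fromTx
      r$fromConservation <- r$fromConservation || fromCons
      if (!grepl(prov, r$provenance, fixed = TRUE))
        r$provenance <- paste(r$provenance, prov, sep = ";")
      rows[[id]] <<- r
    } else {
      blockList[[id]] <<- blocks
      rows[[id]] <<- data.frame(
        id = id, chrom = as.character(seqnames(blocks)[1L]),
        strand = as.character(strand(blocks)[1L]),
        startCodon = startCodon, peptide = peptide,
        ntLength = ntLength, fromTranscript = fromTx,
        fromConservation = fromCons, coding = FALSE, homology = FALSE,
        tier = NA_character_, category = NA_character_,
        provenance = prov, stringsAsFactors = FALSE)
    }
  }

  ## transcript route (sense strand only)
  txIds <- names(exonsByTx(ann))
  if (is.null(transcripts))
    transcripts <- transcriptSequences(genome, ann)
  for (tx in txIds) {
    if (!(tx %in% names(transcripts)))
      stop("transcript sequence missing for ", tx)
    hits <- scanOrfs(as.character(transcripts[[tx]]), "plus",
                     startCodons = startCodons, minNt = minNt, maxNt = maxNt,
                     allStarts = allStarts)
    if (!nrow(hits)) next
    proj <- tryCatch(
      txToGenome(ann, tx, hits$start, hits$end),
      error = function(e) stop("coordinate error projecting hits of ", tx,
                               ": ", conditionMessage(e), call. = FALSE))
    for (i in seq_len(nrow(hits))) {
      addHit(proj[[i]], hits$startCodon[i], hits$peptide[i], hits$ntLength[i],
             fromTx = TRUE, fromCons = FALSE, prov = tx)
    }
  }

  ## conserved-region route (both strands, unspliced)
  if (!is.null(conservation) && length(conservation)) {
    regions <- conservedRegions(conservation, minSpecies = minSpecies,
                                minLen = minConsLen)
    for (i in seq_along(regions)) {
      ch <- as.character(seqnames(regions)[i])
      if (!(ch %in% names(genome))) next
      lo <- max(1L, start(regions)[i])
      hi <- min(length(genome[[ch]]), end(regions)[i])
      if (hi - lo + 1L < 6L) next
      s <- as.character(Biostrings::subseq(genome[[ch]], lo, hi))
      hits <- scanOrfs(s, "both", startCodons = startCodons, minNt = minNt,
                       maxNt = maxNt, allStarts = allStarts)
      if (!nrow(hits)) next
      regId <- sprintf("consreg:%s:%d-%d", ch, lo, hi)
      for (j in seq_len(nrow(hits))) {
        blocks <- GRanges(ch,
                          IRanges(lo + hits$start[j] - 1L,
                                  lo + hits$end[j] - 1L),
                          strand = hits$strand[j])
        addHit(blocks, hits$startCodon[j], hits$peptide[j], hits$ntLength[j],
               fromTx = FALSE, fromCons = TRUE, prov = regId)
      }
    }
  }

  if (!length(rows))
    return(.newSmorfSet(GRangesList(), .emptySmorfInfo()))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  .newSmorfSet(GRangesList(blockList), df)
}

#' Attach coding-potential and homology evidence to candidates
#'
#' Sets the `coding` flag where an external coding-potential call is
#' positive, and the `homology` flag by peptide-length-dependent rules:
#' peptides longer than 15 aa need a database hit with E-value <= `maxEvalue`
#' (default 0.15); peptides of at most 15 aa are checked by direct membership
#' of a short-peptide catalog.
#'
#' @param smorfs a [SmorfSet].
#' @param codingCalls data.frame with columns `id` and `coding` (logical or
#'   0/1); rows for unknown ids are skipped with a warning.
#' @param homologyHits data.frame with columns `id` and `evalue` (one row
#'   per database hit); unknown ids skipped with a warning.
#' @param shortCatalog character vector of catalogued short peptides
#'   (<= 15 aa), matched against candidate peptides.
#' @param maxEvalue E-value cutoff for long-peptide homology.
#' @return the `SmorfSet` with updated `coding`/`homology` flags.
#' @export
attachEvidence <- function(smorfs, codingCalls = NULL, homologyHits = NULL,
                           shortCatalog = character(), maxEvalue = 0.15) {
  info <- smorfs@info
  ids <- as.character(info$id)
  if (!is.null(codingCalls) && nrow(codingCalls)) {
    unknown <- !(codingCalls$id %in% ids)
    if (any(unknown)) {
      warning(sum(unknown), " coding call(s) for unknown candidate ids skipped")
      codingCalls <- codingCalls[!unknown, , drop = FALSE]
    }
    pos <- codingCalls$id[as.logical(codingCalls$coding)]
    info$coding <- ids %in% pos
  }
  pepLen <- nchar(info$peptide)
  homology <- rep(FALSE, length(ids))
  if (!is.null(homologyHits) && nrow(homologyHits)) {
    unknown <- !(homologyHits$id %in% ids)
    if (any(unknown)) {
      warning(sum(unknown), " homology hit(s) for unknown candidate ids skipped")
      homologyHits <- homologyHits[!unknown, , drop = FALSE]
    }
    good <- homologyHits$id[homologyHits$evalue <= maxEvalue]
    homology <- ids %in% good & pepLen > 15L
  }
  if (length(shortCatalog))
    homology <- homology | (pepLen <= 15L & info$peptide %in% shortCatalog)
  info$homology <- homology
  smorfs@info <- info
  smorfs
}

#' Write smORF candidates as GFF3, peptides as FASTA, or a summary TSV
#'
#' The GFF3 uses a parent `smORF` feature with child `CDS` blocks and
#' attributes `tier`, `category`, `start_codon` and `evidence`.
#'
#' @param smorfs a [SmorfSet].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSmorfGFF3 <- function(smorfs, path) {
  info <- smorfs@info
  bl <- smorfs@blocks
  ev <- apply(cbind(transcript = info$fromTranscript,
                    conservation = info$fromConservation,
                    coding = info$coding, homology = info$homology), 1L,
              function(z) paste(names(z)[z], collapse = "+"))
  parent <- unlist(range(bl))
  parent$type <- "smORF"
  parent$ID <- info$id
  parent$Parent <- NA_character_
  parent$tier <- info$tier
  parent$category <- info$category
  parent$start_codon <- info$startCodon
  parent$evidence <- ev
  kids <- unlist(bl)
  names(kids) <- NULL
  kids$type <- "CDS"
  kids$ID <- NA_character_
  kids$Parent <- rep(info$id, lengths(bl))
  kids$tier <- NA_character_; kids$category <- NA_character_
  kids$start_codon <- NA_character_; kids$evidence <- NA_character_
  kids$phase <- unlist(.cdsPhases(bl), use.names = FALSE)
  parent$phase <- NA_integer_
  names(parent) <- NULL
  all <- c(parent, kids)
  all <- all[order(as.factor(seqnames(all)), start(all),
                   match(all$type, c("smORF", "CDS")))]
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' @rdname writeSmorfGFF3
#' @export
writeSmorfPeptides <- function(smorfs, path) {
  info <- smorfs@info
  aa <- Biostrings::AAStringSet(setNames(as.character(info$peptide),
                                         as.character(info$id)))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' @rdname writeSmorfGFF3
#' @export
writeSmorfTable <- function(smorfs, path) {
  .writeTsv(as.data.frame(smorfs), path)
}
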