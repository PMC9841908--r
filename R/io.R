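#' @include AllClasses.R
NULL

#' Read a genome (or transcript) FASTA file
#'
#' Loads all records of a FASTA file as a [Biostrings::DNAStringSet] with
#' sequences uppercased, so soft-masked (lowercase) stretches are treated as
#' ordinary sequence.
#'
#' @param path path to a FASTA file.
#' @return a `DNAStringSet`, one element per record.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (any(duplicated(names(seqs))))
    stop("duplicated sequence ids in ", path)
  if (any(width(seqs) == 0L))
    stop("empty sequence record in ", path)
  # uppercase normalisation (drops soft-masking)
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Write sequences to FASTA
#'
#' @param seqs a named `DNAStringSet` or named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenome <- function(seqs, path) {
  if (is.character(seqs))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Construct a GenomeAnnotation from its parts
#'
#' @param genes `GRanges` with `gene_id` and `biotype` metadata columns.
#' @param exonsByTx named `GRangesList` of exons per transcript.
#' @param cdsByTx named `GRangesList` of CDS segments per transcript; missing
#'   transcripts get an empty CDS.
#' @param txGene named character vector mapping transcript id to gene id.
#' @return a [GenomeAnnotation] object.
#' @export
makeGenomeAnnotation <- function(genes, exonsByTx, cdsByTx = NULL, txGene) {
  exonsByTx <- GRangesList(lapply(exonsByTx, BiocGenerics::sort))
  empty <- GRanges(seqnames = character(), ranges = IRanges(),
                   strand = character())
  full <- setNames(rep(list(empty), length(exonsByTx)), names(exonsByTx))
  if (!is.null(cdsByTx) && length(cdsByTx))
    full[names(cdsByTx)] <- lapply(cdsByTx, BiocGenerics::sort)
  new("GenomeAnnotation", genes = genes, exonsByTx = exonsByTx,
      cdsByTx = GRangesList(full), txGene = txGene[names(exonsByTx)])
}

.TX_TYPES <- c(mRNA = "protein_coding", transcript = "protein_coding",
               lncRNA = "lncRNA", lnc_RNA = "lncRNA", ncRNA = "other_ncRNA",
               miRNA = "miRNA", circRNA = "circRNA")

#' Read a GFF3 gene annotation
#'
#' Builds the gene -> transcript -> exon/CDS hierarchy from a GFF3 file with
#' `gene`, `mRNA`/`ncRNA`-type, `exon` and `CDS` features linked by `Parent`
#' attributes. Gene biotype is taken from a `biotype` attribute when present,
#' otherwise inferred from the transcript feature types (protein_coding if any
#' child transcript carries CDS). UTRs and introns are always derived from
#' the exon/CDS structure, not read from the file.
#'
#' @param path path to a GFF3 file.
#' @return a [GenomeAnnotation].
#' @export
readAnnotation <- function(path) {
  if (!file.exists(path))
    stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) p[[1L]] else NA_character_, character(1L))

  isGene <- type == "gene"
  isTx <- type %in% names(.TX_TYPES)
  isExon <- type == "exon"
  isCds <- type == "CDS"

  genesGr <- gr[isGene]
  geneIds <- as.character(genesGr$ID)
  txGr <- gr[isTx]
  txIds <- as.character(txGr$ID)
  txParent <- parent[isTx]
  orphanTx <- txIds[!(txParent %in% geneIds)]
  if (length(orphanTx))
    stop("annotation error: transcript(s) with missing Parent gene: ",
         paste(orphanTx, collapse = ", "))

  kidParent <- parent[isExon | isCds]
  orphanKid <- which(!(kidParent %in% txIds))
  if (length(orphanKid))
    stop("annotation error: exon/CDS feature(s) with missing Parent ",
         "transcript: ", paste(unique(kidParent[orphanKid]), collapse = ", "))

  exGr <- granges(gr[isExon])
  exParent <- factor(parent[isExon], levels = txIds)
  exonsByTx <- GenomicRanges::split(exGr, exParent)

  cdGr <- granges(gr[isCds])
  cdParent <- factor(parent[isCds], levels = txIds)
  cdsList <- GenomicRanges::split(cdGr, cdParent)

  txGene <- setNames(txParent, txIds)

  biotype <- genesGr$biotype
  if (is.null(biotype)) biotype <- rep(NA_character_, length(genesGr))
  txType <- setNames(.TX_TYPES[type[isTx]], txIds)
  hasCds <- tapply(sum(width(cdsList))[txIds] > 0L, txGene, any)
  for (i in which(is.na(biotype))) {
    gid <- geneIds[i]
    kids <- txIds[txGene == gid]
    biotype[i] <- if (isTRUE(hasCds[gid])) "protein_coding"
      else if (length(kids)) txType[kids[1L]] else "other_ncRNA"
  }
  genes <- granges(genesGr)
  genes$gene_id <- geneIds
  genes$biotype <- unname(biotype)

  makeGenomeAnnotation(genes, exonsByTx, as.list(cdsList), txGene)
}

#' Write a GenomeAnnotation to GFF3
#'
#' Emits gene, transcript (mRNA or the non-coding biotype), exon and CDS
#' features with `ID`/`Parent` links, a `biotype` attribute on genes, and CDS
#' phase computed from the cumulative coding length.
#'
#' @param ann a [GenomeAnnotation].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotationGFF3 <- function(ann, path) {
  genes <- annGenes(ann)
  ex <- exonsByTx(ann)
  cds <- cdsByTx(ann)
  txg <- txGene(ann)
  biotypeOf <- setNames(genes$biotype, genes$gene_id)

  rows <- list()
  gg <- granges(genes)
  gg$type <- "gene"; gg$ID <- genes$gene_id; gg$Parent <- NA_character_
  gg$biotype <- genes$biotype; gg$phase <- NA_integer_
  rows[[1L]] <- gg

  txIds <- names(ex)
  txSpan <- unlist(range(ex))
  txSpan$type <- ifelse(biotypeOf[txg[txIds]] == "protein_coding",
                        "mRNA",
                        ifelse(biotypeOf[txg[txIds]] == "lncRNA", "lncRNA",
                               "ncRNA"))
  txSpan$ID <- txIds; txSpan$Parent <- unname(txg[txIds])
  txSpan$biotype <- NA_character_; txSpan$phase <- NA_integer_
  rows[[2L]] <- txSpan

  exFlat <- unlist(ex)
  exFlat$type <- "exon"; exFlat$ID <- NA_character_
  exFlat$Parent <- rep(txIds, lengths(ex))
  exFlat$biotype <- NA_character_; exFlat$phase <- NA_integer_
  names(exFlat) <- NULL
  rows[[3L]] <- exFlat

  phases <- .cdsPhases(cds)
  cdFlat <- unlist(cds)
  if (length(cdFlat)) {
    cdFlat$type <- "CDS"; cdFlat$ID <- NA_character_
    cdFlat$Parent <- rep(names(cds), lengths(cds))
    cdFlat$biotype <- NA_character_; cdFlat$phase <- unlist(phases, use.names = FALSE)
    names(cdFlat) <- NULL
    rows[[4L]] <- cdFlat
  }
  all <- unlist(GRangesList(rows))
  all <- all[order(as.factor(seqnames(all)), start(all),
                   match(all$type, c("gene", "mRNA", "lncRNA", "ncRNA",
                                     "exon", "CDS")))]
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

# GFF3 phase per CDS segment: number of bases to skip at segment start to hit
# the next codon boundary, walking segments in translation (5'->3') order.
.cdsPhases <- function(cds) {
  lapply(seq_along(cds), function(i) {
    cd <- cds[[i]]
    if (!length(cd)) return(integer())
    minus <- as.character(strand(cd)[1L]) == "-"
    ord <- if (minus) rev(seq_along(cd)) else seq_along(cd)
    cum <- c(0L, cumsum(width(cd)[ord]))
    ph <- (3L - cum[seq_along(cd)] %% 3L) %% 3L
    out <- integer(length(cd))
    out[ord] <- ph
    out
  })
}

#' Read / write per-sample fragment files (BED)
#'
#' Fragments are alignment intervals standing in for aligned read pairs.
#' Multi-block (junction-spanning) fragments are stored as several BED6 rows
#' sharing the same `name`; reading groups rows by name back into one
#' fragment per element.
#'
#' @param path BED file path.
#' @return `readFragments`: a `GRangesList`, one element per fragment.
#' @export
readFragments <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$name) || anyNA(gr$name))
    stop("fragment BED must carry a name column")
  GenomicRanges::split(granges(gr), factor(gr$name, levels = unique(gr$name)))
}

#' @rdname readFragments
#' @param fragments a `GRangesList` of fragments.
#' @export
writeFragments <- function(fragments, path) {
  flat <- unlist(fragments, use.names = FALSE)
  flat$name <- rep(names(fragments), lengths(fragments))
  rtracklayer::export(flat, path, format = "bed")
  invisible(path)
}

#' Read / write a sample design table
#'
#' Tab-separated table with columns `sample`, `tissue`, `replicate`.
#'
#' @param path TSV path.
#' @return `readDesign`: a data.frame.
#' @export
readDesign <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "tissue", "replicate")
  if (!all(need %in% names(d)))
    stop("design table must have columns: ", paste(need, collapse = ", "))
  d
}

#' @rdname readDesign
#' @param design a data.frame with `sample`, `tissue`, `replicate`.
#' @export
writeDesign <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @noRd
.readTsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @noRd
.writeTsv <- function(df, path, rowNames = FALSE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = rowNames, col.names = TRUE)
  invisible(path)
}
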