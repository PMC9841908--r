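#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- queryHits subjectHits Rle runValue
#' @importFrom IRanges IRanges ranges width start end slice coverage Views viewMaxs
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand granges reduce
#'   findOverlaps pintersect gaps
#' @importFrom BiocGenerics unlist relist sort
NULL

#' Hierarchical gene annotation
#'
#' Container for a gene -> transcript -> exon/CDS hierarchy with gene
#' biotypes. Exons and CDS segments are held per transcript as
#' [GenomicRanges::GRangesList] objects in genomic order; 5'/3' UTRs and
#' introns are derived on demand (see [utr5ByTx()], [utr3ByTx()],
#' [intronsByTx()]). All coordinates follow the native GRanges convention
#' (1-based, closed intervals); GFF3 input/output needs no shifting.
#'
#' @slot genes `GRanges` with metadata columns `gene_id` and `biotype`
#'   (one of `protein_coding`, `lncRNA`, `miRNA`, `circRNA`, `other_ncRNA`).
#' @slot exonsByTx `GRangesList` of exons per transcript, names are
#'   transcript ids, elements sorted by genomic start.
#' @slot cdsByTx `GRangesList` of CDS segments per transcript (empty
#'   element for non-coding transcripts), names match `exonsByTx`.
#' @slot txGene named `character`, transcript id -> parent gene id.
#'
#' @seealso [readAnnotation()], [splicedSequence()], [txToGenome()]
#' @export
setClass("GenomeAnnotation",
  slots = c(
    genes = "GRanges",
    exonsByTx = "CompressedGRangesList",
    cdsByTx = "CompressedGRangesList",
    txGene = "character"
  )
)

setValidity("GenomeAnnotation", function(object) {
  msg <- character()
  g <- object@genes
  if (!all(c("gene_id", "biotype") %in% names(mcols(g))))
    msg <- c(msg, "genes must carry gene_id and biotype metadata columns")
  else {
    if (anyDuplicated(g$gene_id))
      msg <- c(msg, "duplicated gene ids")
    bad <- setdiff(unique(g$biotype),
                   c("protein_coding", "lncRNA", "miRNA", "circRNA", "other_ncRNA"))
    if (length(bad))
      msg <- c(msg, paste("unknown biotype(s):", paste(bad, collapse = ", ")))
  }
  ex <- object@exonsByTx
  cds <- object@cdsByTx
  if (is.null(names(ex)) || anyDuplicated(names(ex)))
    msg <- c(msg, "exonsByTx must have unique transcript names")
  if (!identical(names(ex), names(cds)))
    msg <- c(msg, "exonsByTx and cdsByTx names differ")
  if (!identical(BiocGenerics::sort(names(object@txGene)), BiocGenerics::sort(names(ex))))
    msg <- c(msg, "txGene names must match transcript names")
  if (length(msg) == 0L && length(ex)) {
    if (length(mcols(g)) && !all(object@txGene %in% g$gene_id))
      msg <- c(msg, "txGene refers to unknown gene ids")
    # exons per transcript non-overlapping and sorted
    red <- reduce(ex)
    if (!all(sum(width(red)) == sum(width(ex))))
      msg <- c(msg, "overlapping exons within a transcript")
    if (!all(vapply(start(ex), function(s) !is.unsorted(s), logical(1L))))
      msg <- c(msg, "exons not sorted by genomic start")
    # CDS contained in exons
    cw <- sum(width(cds))
    iw <- sum(width(GenomicRanges::intersect(cds, ex)))
    if (!all(cw == iw))
      msg <- c(msg, "CDS segments extend outside exons")
    # CDS length divisible by 3 for coding transcripts
    coding <- names(ex)[cw > 0L]
    if (length(coding) && any(cw[coding] %% 3L != 0L))
      msg <- c(msg, "CDS total length not divisible by 3")
  }
  if (length(msg)) msg else TRUE
})

#' Kozak translation-initiation context profile
#'
#' Position-frequency model of the 14-nt context around a translation start:
#' 9 nt upstream (positions -9..-1), the 3-nt start codon (+1..+3) and 2 nt
#' downstream (+4..+5). Frequencies at each position are computed over
#' observed contexts ignoring `N`; a position observed only as `N` falls back
#' to the uniform distribution.
#'
#' @slot freq 4 x 14 numeric matrix (rows A, C, G, T), columns sum to 1.
#' @slot nSeq number of contexts the profile was built from.
#' @slot consensus length-14 consensus string (per-position argmax, ties
#'   broken alphabetically).
#'
#' @seealso [buildKozakProfile()], [scoreKozakContext()]
#' @export
setClass("KozakProfile",
  slots = c(freq = "matrix", nSeq = "integer", consensus = "character")
)

setValidity("KozakProfile", function(object) {
  f <- object@freq
  msg <- character()
  if (!identical(dim(f), c(4L, 14L)))
    msg <- c(msg, "freq must be a 4 x 14 matrix")
  else {
    if (!identical(rownames(f), .BASES))
      msg <- c(msg, "freq rows must be named A, C, G, T")
    if (any(abs(colSums(f) - 1) > 1e-9))
      msg <- c(msg, "freq columns must each sum to 1")
  }
  if (nchar(object@consensus) != 14L)
    msg <- c(msg, "consensus must have 14 characters")
  if (length(msg)) msg else TRUE
})

#' A set of smORF candidates
#'
#' Each candidate is a small ORF with its genomic CDS blocks (possibly
#' spliced), start codon, peptide, evidence flags, and (once assigned) a
#' confidence tier and positional category. Candidate ids are canonical
#' functions of (chromosome, strand, sorted blocks) -- see [smorfId()] --
#' so re-discovery on identical input reproduces identical ids.
#'
#' @slot blocks `GRangesList`, genomic CDS blocks per candidate, names are
#'   candidate ids, blocks sorted and non-overlapping.
#' @slot info `DataFrame` with one row per candidate: `id`, `chrom`,
#'   `strand`, `startCodon`, `peptide`, `ntLength`, logical evidence flags
#'   `fromTranscript`, `fromConservation`, `coding`, `homology`, plus
#'   `tier`, `category` (NA until assigned) and `provenance`.
#'
#' @seealso [discoverSmorfs()], [assignConfidence()], [assignCategory()]
#' @export
setClass("SmorfSet",
  slots = c(blocks = "CompressedGRangesList", info = "DataFrame")
)

.SMORF_INFO_COLS <- c("id", "chrom", "strand", "startCodon", "peptide",
                      "ntLength", "fromTranscript", "fromConservation",
                      "coding", "homology", "tier", "category", "provenance")

setValidity("SmorfSet", function(object) {
  msg <- character()
  if (length(object@blocks) != nrow(object@info))
    msg <- c(msg, "blocks and info lengths differ")
  if (!all(.SMORF_INFO_COLS %in% names(object@info)))
    msg <- c(msg, paste("info must have columns:",
                        paste(.SMORF_INFO_COLS, collapse = ", ")))
  else if (length(object@blocks)) {
    if (!identical(names(object@blocks), as.character(object@info$id)))
      msg <- c(msg, "blocks names must equal info$id")
    bl <- sum(width(object@blocks))
    if (!all(bl == object@info$ntLength))
      msg <- c(msg, "summed block length must equal ntLength")
    if (any(object@info$ntLength %% 3L != 0L))
      msg <- c(msg, "ntLength must be divisible by 3")
  }
  if (length(msg)) msg else TRUE
})
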