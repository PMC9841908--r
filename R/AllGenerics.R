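#' @include AllClasses.R
NULL

#' @rdname GenomeAnnotation-class
#' @param object,x a `GenomeAnnotation`
#' @export
setGeneric("annGenes", function(object) standardGeneric("annGenes"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("exonsByTx", function(object) standardGeneric("exonsByTx"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("cdsByTx", function(object) standardGeneric("cdsByTx"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("txGene", function(object) standardGeneric("txGene"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("utr5ByTx", function(object) standardGeneric("utr5ByTx"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("utr3ByTx", function(object) standardGeneric("utr3ByTx"))

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("intronsByTx", function(object) standardGeneric("intronsByTx"))

#' @rdname SmorfSet-class
#' @param object,x a `SmorfSet`
#' @export
setGeneric("smorfBlocks", function(object) standardGeneric("smorfBlocks"))

#' @rdname SmorfSet-class
#' @export
setGeneric("smorfInfo", function(object) standardGeneric("smorfInfo"))

#' @rdname KozakProfile-class
#' @param object a `KozakProfile`
#' @export
setGeneric("profileFreq", function(object) standardGeneric("profileFreq"))

#' @rdname KozakProfile-class
#' @export
setGeneric("consensus", function(object) standardGeneric("consensus"))

## ---- GenomeAnnotation methods ------------------------------------------

#' @rdname GenomeAnnotation-class
#' @export
setMethod("annGenes", "GenomeAnnotation", function(object) object@genes)

#' @rdname GenomeAnnotation-class
#' @export
setMethod("exonsByTx", "GenomeAnnotation", function(object) object@exonsByTx)

#' @rdname GenomeAnnotation-class
#' @export
setMethod("cdsByTx", "GenomeAnnotation", function(object) object@cdsByTx)

#' @rdname GenomeAnnotation-class
#' @export
setMethod("txGene", "GenomeAnnotation", function(object) object@txGene)

# Exonic footprint of the CDS per transcript is the CDS itself; the UTRs are
# the exonic parts 5' / 3' of the CDS on the transcript's strand.
.utrByTx <- function(object, side) {
  ex <- object@exonsByTx
  cds <- object@cdsByTx
  res <- vector("list", length(ex))
  names(res) <- names(ex)
  cw <- sum(width(cds))
  for (i in seq_along(ex)) {
    if (cw[i] == 0L) {
      res[[i]] <- GRanges(seqnames = character(), ranges = IRanges(),
                          strand = character())
      next
    }
    e <- ex[[i]]
    cd <- cds[[i]]
    minus <- as.character(strand(e)[1L]) == "-"
    cdsLo <- min(start(cd)); cdsHi <- max(end(cd))
    noncds <- GenomicRanges::setdiff(e, cd)
    left <- noncds[end(noncds) < cdsLo]
    right <- noncds[start(noncds) > cdsHi]
    res[[i]] <- if (xor(side == "5", minus)) left else right
  }
  GRangesList(res)
}

#' @rdname GenomeAnnotation-class
#' @export
setMethod("utr5ByTx", "GenomeAnnotation", function(object) .utrByTx(object, "5"))

#' @rdname GenomeAnnotation-class
#' @export
setMethod("utr3ByTx", "GenomeAnnotation", function(object) .utrByTx(object, "3"))

#' @rdname GenomeAnnotation-class
#' @export
setMethod("intronsByTx", "GenomeAnnotation", function(object) {
  ex <- object@exonsByTx
  res <- lapply(seq_along(ex), function(i) {
    e <- ex[[i]]
    if (length(e) < 2L)
      return(GRanges(seqnames = character(), ranges = IRanges(),
                     strand = character()))
    GRanges(seqnames(e)[1L],
            IRanges(utils::head(end(e), -1L) + 1L, utils::tail(start(e), -1L) - 1L),
            strand = strand(e)[1L])
  })
  names(res) <- names(ex)
  GRangesList(res)
})

setMethod("show", "GenomeAnnotation", function(object) {
  nb <- table(object@genes$biotype)
  cat("GenomeAnnotation with", length(object@genes), "genes,",
      length(object@exonsByTx), "transcripts\n")
  cat("  biotypes:", paste(names(nb), nb, sep = "=", collapse = ", "), "\n")
})

## ---- SmorfSet methods ---------------------------------------------------

#' @rdname SmorfSet-class
#' @export
setMethod("smorfBlocks", "SmorfSet", function(object) object@blocks)

#' @rdname SmorfSet-class
#' @export
setMethod("smorfInfo", "SmorfSet", function(object) object@info)

#' @rdname SmorfSet-class
#' @export
setMethod("length", "SmorfSet", function(x) length(x@blocks))

#' @rdname SmorfSet-class
#' @export
setMethod("names", "SmorfSet", function(x) names(x@blocks))

#' @rdname SmorfSet-class
#' @param i index
#' @param j,...,drop ignored
#' @export
setMethod("[", "SmorfSet", function(x, i, j, ..., drop = TRUE) {
  new("SmorfSet", blocks = x@blocks[i], info = x@info[i, , drop = FALSE])
})

setMethod("show", "SmorfSet", function(object) {
  cat("SmorfSet with", length(object), "candidates\n")
  if (length(object)) {
    inf <- object@info
    cat("  evidence: transcript=", sum(inf$fromTranscript),
        " conservation=", sum(inf$fromConservation),
        " coding=", sum(inf$coding, na.rm = TRUE),
        " homology=", sum(inf$homology, na.rm = TRUE), "\n", sep = "")
    if (!all(is.na(inf$tier))) {
      tt <- table(inf$tier)
      cat("  tiers:", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
    }
    if (!all(is.na(inf$category))) {
      tc <- table(inf$category)
      cat("  categories:", paste(names(tc), tc, sep = "=", collapse = ", "), "\n")
    }
  }
})

#' @rdname SmorfSet-class
#' @param row.names,optional passed on
#' @export
setMethod("as.data.frame", "SmorfSet",
  function(x, row.names = NULL, optional = FALSE, ...) {
    as.data.frame(x@info, row.names = row.names, optional = optional, ...)
  })

## ---- KozakProfile methods ----------------------------------------------

#' @rdname KozakProfile-class
#' @export
setMethod("profileFreq", "KozakProfile", function(object) object@freq)

#' @rdname KozakProfile-class
#' @export
setMethod("consensus", "KozakProfile", function(object) object@consensus)

setMethod("show", "KozakProfile", function(object) {
  cat("KozakProfile built from", object@nSeq, "contexts\n")
  cat("  window: -9..-1 | start codon +1..+3 | +4..+5\n")
  cat("  consensus:", object@consensus, "\n")
})
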