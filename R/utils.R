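# Internal helpers: codon tables, translation, random sequence.

.STOP_CODONS <- c("TAA", "TAG", "TGA")
.BASES <- c("A", "C", "G", "T")

.ALL_CODONS <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0))
.SENSE_CODONS <- setdiff(.ALL_CODONS, .STOP_CODONS)

.codonTable <- local({
  gc <- Biostrings::GENETIC_CODE
  tab <- as.character(gc)
  names(tab) <- names(gc)
  tab
})

#' @noRd
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Translate an ORF nucleotide sequence (start..stop inclusive). The initiator
# codon is rendered as M regardless of identity (near-cognate starts are
# decoded by initiator tRNA-Met); codons containing N translate to X; the
# terminal stop codon is dropped.
#' @noRd
.translateOrf <- function(nt) {
  vapply(nt, function(s) {
    n <- nchar(s)
    if (n < 6L || n %% 3L != 0L)
      stop("ORF length must be a multiple of 3 and at least 6 nt")
    pos <- seq.int(1L, n - 3L, by = 3L)
    cod <- substring(s, pos, pos + 2L)
    aa <- .codonTable[cod]
    aa[is.na(aa)] <- "X"
    aa[1L] <- "M"
    paste(aa, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' @noRd
.randDNA <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

# Random non-stop codons; optionally also excluding the allowed start codons
# (used to build start-less decoy stretches).
#' @noRd
.randCodons <- function(k, excludeStarts = FALSE) {
  pool <- if (excludeStarts) setdiff(.SENSE_CODONS, kozakStartCodons()) else .SENSE_CODONS
  paste(sample(pool, k, replace = TRUE), collapse = "")
}

#' @noRd
.checkScalarString <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(what, " must be a single character string")
  invisible(x)
}
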