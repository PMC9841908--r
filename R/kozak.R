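#' @include AllClasses.R
NULL

#' The allowed start-codon set
#'
#' ATG plus the nine near-cognate codons differing from ATG at exactly one
#' position: TTG, GTG, CTG (first base), AAG, ACG, AGG (second base), ATT,
#' ATC, ATA (third base). Equivalently: the codons within Hamming distance 1
#' of ATG.
#'
#' @return character vector of 10 codons.
#' @seealso [isKozakStart()]
#' @export
kozakStartCodons <- function() {
  c("ATG",
    "TTG", "GTG", "CTG",
    "AAG", "ACG", "AGG",
    "ATT", "ATC", "ATA")
}

#' @rdname kozakStartCodons
#' @param codon character vector of 3-mers.
#' @return `isKozakStart`: logical vector, TRUE where the codon is in the
#'   allowed set.
#' @export
isKozakStart <- function(codon) {
  codon %in% kozakStartCodons()
}

#' Filter reliable coding genes by alignment identity and coverage
#'
#' Keeps genes whose protein alignment passes both thresholds (boundary
#' inclusive), collapsing duplicate hits to one gene entry. Defaults are
#' identity >= 30% and coverage >= 30%.
#'
#' @param hits data.frame with columns `gene`, `identity`, `coverage`
#'   (percentages in 0-100).
#' @param identityMin,coverageMin thresholds in percent.
#' @return character vector of retained gene ids (unique, input order).
#' @export
filterReliableGenes <- function(hits, identityMin = 30, coverageMin = 30) {
  need <- c("gene", "identity", "coverage")
  if (!all(need %in% names(hits)))
    stop("hits must have columns: ", paste(need, collapse = ", "))
  if (any(hits$identity < 0 | hits$coverage < 0, na.rm = TRUE))
    stop("identity and coverage must be non-negative percentages")
  if (any(hits$identity > 100 | hits$coverage > 100, na.rm = TRUE))
    stop("identity and coverage must be at most 100")
  keep <- hits$identity >= identityMin & hits$coverage >= coverageMin
  unique(as.character(hits$gene[keep]))
}

#' Extract the 14-nt Kozak context around a start codon
#'
#' The window covers positions -9..-1 (upstream), +1..+3 (the start codon)
#' and +4..+5 (downstream): 14 nt in total. Positions falling outside the
#' transcript are padded with `N`, so starts near the 5' end (e.g. uORFs)
#' keep a full-width context.
#'
#' @param txSeq transcript sequence (character scalar).
#' @param startPos 1-based position of the first base of the start codon.
#' @return a 14-character string.
#' @export
extractKozakContext <- function(txSeq, startPos) {
  .checkScalarString(txSeq, "txSeq")
  n <- nchar(txSeq)
  if (startPos < 1L || startPos > n)
    stop("startPos outside transcript")
  pos <- seq.int(startPos - 9L, startPos + 4L)
  chars <- rep("N", 14L)
  ok <- pos >= 1L & pos <= n
  if (any(ok))
    chars[ok] <- substring(txSeq, pos[ok], pos[ok])
  paste(chars, collapse = "")
}

#' Build a Kozak position-frequency profile
#'
#' Tallies base frequencies at each of the 14 window positions over a set of
#' contexts. `N` characters are ignored (frequencies renormalised over
#' observed bases); a position with no observed base falls back to uniform.
#' The consensus is the per-position argmax, ties broken alphabetically.
#'
#' @param contexts character vector of 14-nt context strings
#'   (see [extractKozakContext()]).
#' @return a [KozakProfile].
#' @export
buildKozakProfile <- function(contexts) {
  if (length(contexts) == 0L)
    stop("at least one context is required")
  if (any(nchar(contexts) != 14L))
    stop("all contexts must be 14 nt long")
  mat <- matrix(unlist(strsplit(toupper(contexts), "")), nrow = 14L)
  freq <- matrix(0, nrow = 4L, ncol = 14L,
                 dimnames = list(.BASES, NULL))
  for (p in seq_len(14L)) {
    tab <- table(factor(mat[p, ], levels = .BASES))
    tot <- sum(tab)
    freq[, p] <- if (tot > 0L) as.numeric(tab) / tot else rep(0.25, 4L)
  }
  cons <- paste(.BASES[apply(freq, 2L, which.max)], collapse = "")
  new("KozakProfile", freq = freq, nSeq = length(contexts), consensus = cons)
}

#' Score a context against a Kozak profile
#'
#' Log-odds score in bits against a uniform background: the sum over window
#' positions of `log2(freq / 0.25)`, with zero frequencies floored at 1e-3
#' and `N` positions contributing 0. Intended for ranking candidate starts;
#' it is not used as a discovery filter.
#'
#' @param profile a [KozakProfile].
#' @param context a 14-nt context string.
#' @return numeric score in bits.
#' @export
scoreKozakContext <- function(profile, context) {
  .checkScalarString(context, "context")
  if (nchar(context) != 14L)
    stop("context must be 14 nt long")
  chars <- strsplit(toupper(context), "")[[1L]]
  f <- profileFreq(profile)
  score <- 0
  for (p in seq_len(14L)) {
    b <- chars[p]
    if (!(b %in% .BASES)) next
    score <- score + log2(max(f[b, p], 1e-3) / 0.25)
  }
  score
}

#' Write / read a Kozak profile as a TSV matrix
#'
#' @param profile a [KozakProfile].
#' @param path TSV path (position columns P-9..P+5, base rows).
#' @return `path` invisibly, or a [KozakProfile] for the reader.
#' @export
writeKozakProfile <- function(profile, path) {
  f <- profileFreq(profile)
  colnames(f) <- c(paste0("m", 9:1), paste0("p", 1:5))
  df <- data.frame(base = rownames(f), f, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat("# nSeq=", profile@nSeq, " consensus=", consensus(profile), "\n",
      sep = "", file = path, append = TRUE)
  invisible(path)
}
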