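## Read-level barcode extraction, validation and exact-match assignment.

#' Mean-quality acceptance over the barcode bases
#'
#' The filter averages phred scores over the barcode bases
#' only; the threshold is inclusive (a mean of exactly 30 passes a
#' threshold of 30).
#'
#' @param qualities integer phred scores of the barcode bases.
#' @param threshold minimum mean quality.
#' @return logical scalar.
#' @export
meanQualityPass <- function(qualities, threshold = 30) {
  if (!length(qualities)) stop("empty quality vector")
  mean(qualities) >= threshold
}

#' Extract candidate barcodes downstream of the constant region
#'
#' For every read, searches the forward strand for the first exact
#' occurrence of the constant region and takes the
#' \code{nRepeats * nchar(repeatUnit)} bases immediately 3' of it,
#' together with their qualities. Reads are then screened in the fixed
#' order: constant region present, enough downstream bases, pattern
#' valid (which also excludes any literal \code{N}), mean barcode
#' quality at least \code{meanQualityMin}. With
#' \code{config@searchRevcomp} the reverse complement is searched when
#' the forward search fails.
#'
#' @param reads a \code{QualityScaledDNAStringSet} from
#'   \code{\link{readFastq}}.
#' @param config a \code{\link{FilterConfig}}.
#' @return \code{DataFrame} with one row per read: \code{barcode}
#'   (character, \code{NA} unless accepted), \code{meanQuality}, and
#'   \code{status} (\code{"ok"}, \code{"no_constant_region"},
#'   \code{"truncated"}, \code{"pattern_mismatch"},
#'   \code{"low_quality"}).
#' @export
extractBarcodes <- function(reads, config = FilterConfig()) {
  stopifnot(is(config, "FilterConfig"))
  n <- length(reads)
  bcLen <- nchar(config@repeatUnit) * config@nRepeats
  out <- S4Vectors::DataFrame(
    barcode = rep(NA_character_, n),
    meanQuality = rep(NA_real_, n),
    status = rep("no_constant_region", n),
    row.names = if (is.null(names(reads))) NULL else names(reads))
  if (n == 0L) return(out)

  seqChar <- as.character(reads)
  qualChar <- as.character(Biostrings::quality(reads))

  if (config@searchRevcomp) {
    hit <- .firstMatchEnd(seqChar, config@constantRegion)
    rc <- is.na(hit)
    if (any(rc)) {
      rcReads <- Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqChar[rc]))
      seqChar[rc] <- as.character(rcReads)
      qualChar[rc] <- vapply(strsplit(qualChar[rc], ""), function(ch)
        paste(rev(ch), collapse = ""), "")
    }
  }
  matchEnd <- .firstMatchEnd(seqChar, config@constantRegion)

  found <- !is.na(matchEnd)
  start <- matchEnd + 1L
  end <- matchEnd + bcLen
  truncated <- found & end > nchar(seqChar)
  out$status[truncated] <- "truncated"

  sel <- found & !truncated
  bc <- substr(seqChar[sel], start[sel], end[sel])
  mq <- .phredMeans(substr(qualChar[sel], start[sel], end[sel]), bcLen)
  out$meanQuality[sel] <- mq

  okPattern <- validPattern(bc, config@repeatUnit, config@nRepeats)
  okQual <- mq >= config@meanQualityMin
  status <- ifelse(!okPattern, "pattern_mismatch",
                   ifelse(!okQual, "low_quality", "ok"))
  out$status[sel] <- status
  keep <- which(sel)[status == "ok"]
  out$barcode[keep] <- bc[status == "ok"]
  out
}

## end position of the first exact forward occurrence of `pattern`
## in each sequence, NA when absent (literal grep semantics)
.firstMatchEnd <- function(seqChar, pattern) {
  at <- regexpr(pattern, seqChar, fixed = TRUE, useBytes = TRUE)
  out <- as.integer(at) + nchar(pattern) - 1L
  out[at < 0L] <- NA_integer_
  out
}

## mean phred score of equal-length phred+33 strings
.phredMeans <- function(qualStrings, len) {
  if (!length(qualStrings)) return(numeric())
  ints <- utf8ToInt(paste(qualStrings, collapse = "")) - 33L
  colMeans(matrix(ints, nrow = len))
}

#' Exact-match assignment of barcodes to a reference library
#'
#' Hash-lookup equivalent of exact-match-only alignment: a query is
#' assigned the unique reference id whose sequence it equals; any
#' mismatch, even a single base, leaves it unmapped.
#'
#' @param barcodes character vector (or \code{DNAStringSet}) of
#'   extracted barcodes; \code{NA} stays unmapped.
#' @param reference named \code{DNAStringSet} with unique sequences.
#' @return character vector of reference ids, \code{NA} for unmapped.
#' @export
mapExact <- function(barcodes, reference) {
  refChar <- as.character(reference)
  if (anyDuplicated(refChar))
    stop("duplicate sequences in the reference library at index ",
         anyDuplicated(refChar))
  names(reference)[match(as.character(barcodes), refChar)]
}
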