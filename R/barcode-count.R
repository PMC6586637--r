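## Per-sample tallies, cumulative top-fraction sets, baseline filter and
## serial retention.

.REJECTION_REASONS <- c("no_constant_region", "truncated",
                        "pattern_mismatch", "low_quality", "unmapped")

#' Tally barcode assignments into a BarcodeCountTable
#'
#' @param assignments named list, one element per sample: a character
#'   vector of assigned reference barcode ids, one per read, with
#'   \code{NA} for unmapped reads.
#' @param reference named \code{DNAStringSet}; its names define the rows.
#' @param sampleInfo data.frame with columns \code{sample}, \code{arm},
#'   \code{plating}, \code{dose}, \code{isBaseline} (one row per element
#'   of \code{assignments}). Defaults to a single-arm sheet in list
#'   order.
#' @param rejections optional reasons-by-samples matrix of reads
#'   rejected before assignment; the \code{"unmapped"} row is filled in
#'   from the \code{NA} assignments.
#' @return a \code{\link{BarcodeCountTable}}.
#' @export
countBarcodes <- function(assignments, reference, sampleInfo = NULL,
                          rejections = NULL) {
  if (is.null(names(assignments)))
    stop("every assignment vector must carry a sample name")
  samples <- names(assignments)
  lev <- names(reference)
  cnt <- vapply(assignments, function(ids)
    as.integer(table(factor(ids, levels = lev))), integer(length(lev)))
  cnt <- matrix(cnt, nrow = length(lev),
                dimnames = list(lev, samples))
  rej <- matrix(0L, length(.REJECTION_REASONS), length(samples),
                dimnames = list(.REJECTION_REASONS, samples))
  if (!is.null(rejections))
    rej[rownames(rejections), colnames(rejections)] <- rejections
  rej["unmapped", ] <- rej["unmapped", ] +
    vapply(assignments, function(ids) sum(is.na(ids)), integer(1))
  if (is.null(sampleInfo))
    sampleInfo <- data.frame(sample = samples, arm = "pooled",
                             plating = seq_along(samples), dose = 0,
                             isBaseline = seq_along(samples) == 1L)
  stopifnot(nrow(sampleInfo) == length(samples))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt),
    colData = S4Vectors::DataFrame(sampleInfo, row.names = samples),
    metadata = list(rejections = rej))
  new("BarcodeCountTable", se)
}

#' Barcodes comprising a cumulative fraction of a sample's reads
#'
#' Ranks barcodes by descending count and returns the minimal top set
#' whose cumulative read proportion reaches \code{fraction}. With
#' \code{tieRule = "group"} (default) barcodes tied in count with the
#' last-included one are included as a block, so the result depends only
#' on the multiset of counts, not on barcode labels; \code{"lexical"}
#' breaks ties by barcode id and returns a minimal prefix.
#'
#' @param counts named non-negative counts for one sample; at least one
#'   must be positive.
#' @param fraction target cumulative proportion in (0, 1].
#' @param tieRule \code{"group"} or \code{"lexical"}.
#' @return character vector of barcode ids in rank order.
#' @examples
#' cumulativeFractionSet(c(A = 50, B = 30, C = 15, D = 5), 0.9)
#' @export
cumulativeFractionSet <- function(counts, fraction = 0.9,
                                  tieRule = c("group", "lexical")) {
  tieRule <- match.arg(tieRule)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (any(counts < 0)) stop("counts must be non-negative")
  counts <- counts[counts > 0]
  if (!length(counts)) stop("sample has no positive counts")
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  target <- fraction * sum(counts) - 1e-9 * sum(counts)
  if (tieRule == "lexical") {
    k <- which(cumsum(counts) >= target)[1L]
    return(names(counts)[seq_len(k)])
  }
  grpTot <- tapply(counts, -counts, sum) # ordered by descending count
  kGrp <- which(cumsum(grpTot) >= target)[1L]
  cutCount <- sort(unique(counts), decreasing = TRUE)[kGrp]
  names(counts)[counts >= cutCount]
}

#' Filter candidate barcodes on baseline representation
#'
#' Retains candidates whose count at the baseline time point is strictly
#' above \code{minCount} ("a representation above 20" is read as > 20).
#' Candidates absent from the baseline have count 0.
#'
#' @param candidates character vector of barcode ids.
#' @param baselineCounts named counts at the baseline sample.
#' @param minCount strict lower bound.
#' @return filtered character vector, order preserved.
#' @export
baselineRepresentationFilter <- function(candidates, baselineCounts,
                                         minCount = 20L) {
  if (is.null(names(baselineCounts)))
    stop("baselineCounts must be named by barcode id")
  bl <- baselineCounts[candidates]
  bl[is.na(bl)] <- 0
  candidates[bl > minCount]
}

#' Serial retention of barcode sets across platings
#'
#' Chains per-plating retained sets by intersection with the previous
#' plating's chain: the first set is taken as-is, each later set keeps
#' only barcodes already retained at the previous plating. Reports the
#' nested sets and the resistant-clone fraction estimate
#' |final| / |first|.
#'
#' @param sets list of character vectors, one per plating, in plating
#'   order.
#' @param platingIndices integer plating indices (defaults to
#'   \code{seq_along(sets)}).
#' @param arm arm label carried through to the result.
#' @return a \code{\link{RetentionResult}}.
#' @examples
#' r <- sequentialRetention(list(c("A","B","C"), c("A","B","D"), c("A","D")))
#' retainedCounts(r)
#' @export
sequentialRetention <- function(sets, platingIndices = seq_along(sets),
                                arm = "drug") {
  if (!length(sets)) stop("at least one plating set is required")
  chain <- vector("list", length(sets))
  chain[[1L]] <- as.character(sets[[1L]])
  for (i in seq_along(sets)[-1L])
    chain[[i]] <- intersect(as.character(sets[[i]]), chain[[i - 1L]])
  frac <- if (length(chain[[1L]]) == 0L) NA_real_
          else length(chain[[length(chain)]]) / length(chain[[1L]])
  new("RetentionResult", arm = arm,
      platings = as.integer(platingIndices),
      retained = IRanges::CharacterList(chain),
      resistantFraction = frac)
}

#' Per-arm retention analysis of a barcode count table
#'
#' For each plating of the arm (in plating order), computes the
#' cumulative top-\code{fraction} set, applies the baseline
#' representation filter against the arm's baseline sample, and chains
#' the per-plating sets with \code{\link{sequentialRetention}}. Samples
#' with no mapped reads contribute an empty set.
#'
#' @param counts a \code{\link{BarcodeCountTable}}.
#' @param arm arm label to analyse.
#' @param config a \code{\link{FilterConfig}} (cumulative fraction,
#'   baseline threshold, tie rule).
#' @return a \code{\link{RetentionResult}}.
#' @export
retentionAnalysis <- function(counts, arm, config = FilterConfig()) {
  stopifnot(is(counts, "BarcodeCountTable"), is(config, "FilterConfig"))
  cd <- SummarizedExperiment::colData(counts)
  sel <- which(cd$arm == arm)
  if (!length(sel)) stop("no samples for arm '", arm, "'")
  sel <- sel[order(cd$plating[sel])]
  cnt <- barcodeCounts(counts)
  blSel <- sel[cd$isBaseline[sel]]
  if (!length(blSel))
    stop("no baseline sample designated for arm '", arm, "'")
  baseline <- cnt[, blSel[1L]]
  sets <- lapply(sel, function(j) {
    v <- cnt[, j]
    if (all(v == 0)) return(character())
    top <- cumulativeFractionSet(v, config@cumulativeFraction,
                                 config@tieRule)
    baselineRepresentationFilter(top, baseline, config@baselineMinCount)
  })
  sequentialRetention(sets, platingIndices = cd$plating[sel], arm = arm)
}
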