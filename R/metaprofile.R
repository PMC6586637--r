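#' Summit-centred coverage metaprofile
#'
#' Computes, for a set of sites with summits, the mean coverage in
#' \code{nBins} equal bins across the window
#' [summit - flank, summit + flank), plus the across-site average
#' profile. Bins that fall outside the covered span of the track (sites
#' truncated by contig edges) are \code{NA} and excluded from the
#' averages.
#'
#' @param track a \code{\link{CoverageTrack}}.
#' @param sites \code{GRanges} with a \code{summit} metadata column
#'   (midpoints used when absent); must be non-empty.
#' @param flank half-window in bp.
#' @param nBins number of bins across the 2*flank window.
#' @param normalize per-million scale the values.
#' @return list with \code{matrix} (sites x bins), \code{profile}
#'   (per-bin across-site means) and \code{positions} (bin centres
#'   relative to the summit).
#' @export
metaprofile <- function(track, sites, flank = 5000L, nBins = 100L,
                        normalize = FALSE) {
  stopifnot(is(track, "CoverageTrack"))
  if (!length(sites)) stop("empty site set")
  if (flank <= 0) stop("flank must be > 0")
  nBins <- as.integer(nBins)
  flank <- as.integer(flank)
  summit <- if (!is.null(sites$summit)) sites$summit
            else (GenomicRanges::start(sites) +
                  GenomicRanges::end(sites)) %/% 2L
  edges <- round(seq(-flank, flank, length.out = nBins + 1L))
  n <- length(sites)

  starts <- rep(summit, each = nBins) + rep(edges[-(nBins + 1L)], n)
  ends <- rep(summit, each = nBins) + rep(edges[-1L] - 1L, n)
  binGr <- GenomicRanges::GRanges(
    rep(GenomicRanges::seqnames(sites), each = nBins),
    IRanges::IRanges(starts, ends))

  bins <- trackBins(track)
  covered <- unlist(range(S4Vectors::split(
    bins, GenomicRanges::seqnames(bins))))
  inside <- IRanges::overlapsAny(binGr, covered, type = "within")
  vals <- rep(NA_real_, length(binGr))
  if (any(inside))
    vals[inside] <- .intervalMean(track, binGr[inside], normalize)

  mat <- matrix(vals, nrow = n, ncol = nBins, byrow = TRUE,
                dimnames = list(
                  if (!is.null(sites$name)) sites$name else names(sites),
                  NULL))
  list(matrix = mat,
       profile = colMeans(mat, na.rm = TRUE),
       positions = (edges[-(nBins + 1L)] + edges[-1L]) / 2)
}
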