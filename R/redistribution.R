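#' Coactivator redistribution between pre-existing and new enhancers
#'
#' Quantifies the change in occupancy (e.g. Brd4) at two enhancer
#' classes between conditions: per site, the log2 fold change of mean
#' interval coverage (after vs before, with the configured pseudocount
#' and normalisation); per class, its mean and median; and the
#' redistribution contrast
#' \code{mean(delta at new sites) - mean(delta at pre-existing sites)},
#' positive when signal moves from pre-existing onto new enhancers.
#' Sites belonging to both classes are permitted but their count is
#' reported.
#'
#' @param sitesPre,sitesNew non-empty \code{GRanges} of pre-existing and
#'   new enhancer intervals.
#' @param trackBefore,trackAfter \code{\link{CoverageTrack}}s of the
#'   occupancy signal in the two conditions.
#' @param config an \code{\link{EnhancerConfig}} (pseudocount,
#'   normalisation).
#' @return list with \code{perSite} (data.frame: class, site, delta),
#'   \code{summary} (per-class n, mean, median), \code{contrast} and
#'   \code{nOverlap}.
#' @export
redistributionScore <- function(sitesPre, sitesNew, trackBefore,
                                trackAfter, config = EnhancerConfig()) {
  if (!length(sitesPre) || !length(sitesNew))
    stop("both site classes must be non-empty")
  delta <- function(sites) {
    a <- .intervalMean(trackAfter, sites, config@normalize)
    b <- .intervalMean(trackBefore, sites, config@normalize)
    log2((a + config@pseudocount) / (b + config@pseudocount))
  }
  dPre <- delta(sitesPre)
  dNew <- delta(sitesNew)
  siteName <- function(s, prefix) {
    if (!is.null(s$name)) s$name
    else if (!is.null(names(s))) names(s)
    else paste0(prefix, seq_along(s))
  }
  perSite <- rbind(
    data.frame(class = "pre_existing",
               site = siteName(sitesPre, "pre_"), delta = dPre),
    data.frame(class = "new", site = siteName(sitesNew, "new_"),
               delta = dNew))
  summary <- data.frame(
    class = c("pre_existing", "new"),
    n = c(length(dPre), length(dNew)),
    meanDelta = c(mean(dPre), mean(dNew)),
    medianDelta = c(median(dPre), median(dNew)))
  list(perSite = perSite, summary = summary,
       contrast = mean(dNew) - mean(dPre),
       nOverlap = sum(IRanges::overlapsAny(sitesNew, sitesPre)))
}
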