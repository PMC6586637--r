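## Enhancer classification from per-condition coverage fold changes, and
## linking to drug-responsive genes within a TSS window.

## mean (optionally per-million normalised) coverage of each interval
.intervalMean <- function(track, intervals, normalize = TRUE) {
  bins <- trackBins(track)
  covered <- unlist(range(S4Vectors::split(
    bins, GenomicRanges::seqnames(bins))))
  out <- GenomicRanges::findOverlaps(intervals, covered, type = "within")
  if (length(unique(S4Vectors::queryHits(out))) < length(intervals))
    stop("interval(s) outside the covered span of track '",
         condition(track), "'")
  hits <- GenomicRanges::findOverlaps(intervals, bins)
  ov <- GenomicRanges::width(IRanges::pintersect(
    intervals[S4Vectors::queryHits(hits)],
    bins[S4Vectors::subjectHits(hits)]))
  sig <- bins$score[S4Vectors::subjectHits(hits)] * ov
  tot <- rep(0, length(intervals))
  agg <- tapply(sig, S4Vectors::queryHits(hits), sum)
  tot[as.integer(names(agg))] <- agg
  m <- tot / GenomicRanges::width(intervals)
  if (normalize) m <- m / librarySize(track) * 1e6
  m
}

#' Coverage fold change of intervals between two conditions
#'
#' fold = (mean coverage in \code{after} + pseudocount) /
#' (mean coverage in \code{before} + pseudocount), with means taken over
#' the interval and, when \code{config@normalize} is on, scaled
#' per-million of each track's library size first.
#'
#' @param intervals \code{GRanges}.
#' @param after,before \code{\link{CoverageTrack}}s sharing the binning.
#' @param config an \code{\link{EnhancerConfig}} (pseudocount,
#'   normalisation).
#' @return numeric fold change per interval.
#' @export
coverageFoldChange <- function(intervals, after, before,
                               config = EnhancerConfig()) {
  ma <- .intervalMean(after, intervals, config@normalize)
  mb <- .intervalMean(before, intervals, config@normalize)
  (ma + config@pseudocount) / (mb + config@pseudocount)
}

#' Drug-responsive genes from a differential-expression table
#'
#' Responsive genes are downregulated with a linear fold-change
#' magnitude strictly above \code{config@deFcMin} and a significance
#' value (column \code{p} or \code{fdr}, per \code{config@sigField})
#' strictly below \code{config@dePMax}.
#'
#' @param deTable data.frame with \code{gene}, \code{log2fc} and the
#'   significance column.
#' @param config an \code{\link{EnhancerConfig}}.
#' @return character vector of gene ids.
#' @export
ibetResponsiveGenes <- function(deTable, config = EnhancerConfig()) {
  if (!all(c("gene", "log2fc") %in% names(deTable)))
    stop("DE table needs columns gene, log2fc")
  if (!config@sigField %in% names(deTable))
    stop("DE table lacks the significance column '", config@sigField, "'")
  sig <- deTable[[config@sigField]]
  down <- deTable$log2fc < 0 & 2^(-deTable$log2fc) > config@deFcMin
  deTable$gene[down & sig < config@dePMax]
}

#' Classify enhancer peaks and link them to responsive genes
#'
#' Implements the rule set of the enhancer-switching analysis. Per peak:
#' \itemize{
#'   \item \code{new}: H3K27ac coverage fold change (after vs before
#'     treatment) strictly above \code{config@foldThreshold};
#'   \item \code{pre_existing}: at least 1 bp overlap with a peak of the
#'     before-condition H3K27ac peak set (\code{preExistingPeaks});
#'   \item \code{new_pu1}: Pu.1 occupancy fold change above threshold;
#'   \item \code{new_pu1_active}: both Pu.1 and H3K27ac above threshold.
#' }
#' All applicable class flags are reported. Each peak is linked to every
#' responsive gene whose TSS lies within \code{config@tssWindow} of the
#' peak summit (or nearest edge with \code{distanceMode = "edge"});
#' peaks with no linked gene get primary class \code{"unlinked"}, peaks
#' with a linked gene get the most specific applicable class
#' (\code{new_pu1_active} > \code{new_pu1} > \code{new} >
#' \code{pre_existing}), or \code{"none"} when no rule fires.
#'
#' @param peaks \code{GRanges} with \code{summit} metadata column
#'   (midpoint used when absent).
#' @param tracks named list of \code{\link{CoverageTrack}}s:
#'   \code{k27acBefore}, \code{k27acAfter} and optionally
#'   \code{pu1Before}, \code{pu1After}.
#' @param genes width-1 \code{GRanges} of TSS positions, named by gene.
#' @param deTable differential-expression data.frame (see
#'   \code{\link{ibetResponsiveGenes}}).
#' @param preExistingPeaks optional \code{GRanges} of before-condition
#'   H3K27ac peaks.
#' @param config an \code{\link{EnhancerConfig}}.
#' @return the input \code{GRanges} with metadata columns
#'   \code{foldK27ac}, \code{foldPu1}, the four class flags,
#'   \code{linkedGenes}, \code{linkedDistances} (signed TSS - summit),
#'   and \code{class}.
#' @export
classifyEnhancers <- function(peaks, tracks, genes, deTable,
                              preExistingPeaks = NULL,
                              config = EnhancerConfig()) {
  stopifnot(is(config, "EnhancerConfig"))
  if (!all(c("k27acBefore", "k27acAfter") %in% names(tracks)))
    stop("tracks must include k27acBefore and k27acAfter")
  n <- length(peaks)
  foldK27 <- coverageFoldChange(peaks, tracks$k27acAfter,
                                tracks$k27acBefore, config)
  hasPu1 <- all(c("pu1Before", "pu1After") %in% names(tracks))
  foldPu1 <- if (hasPu1)
    coverageFoldChange(peaks, tracks$pu1After, tracks$pu1Before, config)
  else rep(NA_real_, n)

  isNew <- foldK27 > config@foldThreshold
  isNewPu1 <- !is.na(foldPu1) & foldPu1 > config@foldThreshold
  isNewPu1Active <- isNew & isNewPu1
  isPreExisting <- if (!is.null(preExistingPeaks))
    IRanges::overlapsAny(peaks, preExistingPeaks)
  else rep(FALSE, n)

  responsive <- ibetResponsiveGenes(deTable, config)
  missing <- setdiff(responsive, names(genes))
  if (length(missing))
    stop("no TSS for responsive gene(s): ",
         paste(head(missing, 3), collapse = ", "))
  rg <- genes[responsive]

  summit <- if (!is.null(peaks$summit)) peaks$summit
            else (GenomicRanges::start(peaks) +
                  GenomicRanges::end(peaks)) %/% 2L
  anchor <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                   IRanges::IRanges(summit, width = 1L))
  query <- if (config@distanceMode == "summit") anchor
           else GenomicRanges::granges(peaks)
  win <- suppressWarnings(GenomicRanges::resize(
    query, GenomicRanges::width(query) + 2L * config@tssWindow,
    fix = "center"))
  hits <- GenomicRanges::findOverlaps(win, rg, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  dist <- GenomicRanges::start(rg)[sh] - summit[qh]

  linkedGenes <- IRanges::CharacterList(split(
    names(rg)[sh], factor(qh, levels = seq_len(n))))
  linkedDistances <- IRanges::IntegerList(split(
    as.integer(dist), factor(qh, levels = seq_len(n))))

  cls <- unname(ifelse(lengths(linkedGenes) == 0L, "unlinked",
         ifelse(isNewPu1Active, "new_pu1_active",
         ifelse(isNewPu1, "new_pu1",
         ifelse(isNew, "new",
         ifelse(isPreExisting, "pre_existing", "none"))))))

  out <- peaks
  out$foldK27ac <- foldK27
  out$foldPu1 <- foldPu1
  out$isNew <- isNew
  out$isPreExisting <- isPreExisting
  out$isNewPu1 <- isNewPu1
  out$isNewPu1Active <- isNewPu1Active
  out$linkedGenes <- unname(linkedGenes)
  out$linkedDistances <- unname(linkedDistances)
  out$class <- cls
  out
}
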