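#' Simulate clone dynamics through a serial replating course
#'
#' Generates ground-truth clone trajectories for a barcoded pool carried
#' through weekly methylcellulose replatings in a vehicle arm and a
#' drug-escalation arm. Each clone carries a \code{clonogenic} flag
#' (can it re-form colonies at all) and, among clonogenic clones, a
#' \code{resistant} flag (can it adapt to doses beyond the starting
#' dose). Clone flags are shared between arms: the same barcoded pool is
#' split across both.
#'
#' The tolerance model is deterministic: resistant clones survive every
#' dose; all other clones survive doses up to \code{naiveTolerance}
#' (default 400 nM, the dose of the first drug plating, which drug-naive
#' cells tolerate) and are eliminated once the escalation exceeds it.
#' Non-clonogenic clones fail to form colonies: they carry a residual
#' abundance at the first plating (\code{residualGrowth}-fold) and zero
#' abundance afterwards.
#'
#' At each plating, surviving clones expand \code{growthRate}-fold with
#' per-clone lognormal noise (\code{growthNoiseSd}); the harvest is then
#' bottlenecked to \code{bottleneckSize} cells, emulating replating a
#' fixed cell number. With \code{sampling = "multinomial"} (default) the
#' bottleneck is a multinomial draw; \code{sampling = "expected"}
#' propagates expected values instead, giving fully deterministic
#' trajectories in which exactly tied clones stay exactly tied — the
#' configuration used, together with \code{growthNoiseSd = 0}, for
#' noise-free parameter-recovery checks.
#'
#' @param nClones number of barcoded clones in the pool.
#' @param clonogenicFraction probability a clone is clonogenic.
#' @param resistantFraction probability a clonogenic clone is resistant.
#' @param growthRate weekly fold-expansion of surviving clones.
#' @param residualGrowth fold-change of non-clonogenic clones over the
#'   first week (they persist as aborted colonies, then vanish).
#' @param growthNoiseSd sd of the per-clone lognormal growth noise.
#' @param bottleneckSize cells replated at each passage.
#' @param naiveTolerance highest dose (nM) non-resistant clones survive.
#' @param schedule a \code{\link{PlatingSchedule}}.
#' @param sampling \code{"multinomial"} or \code{"expected"} bottleneck.
#' @param seed integer seed.
#' @return a \code{\link{CloneGroundTruth}} (rows = clones, columns =
#'   (arm, plating) samples).
#' @examples
#' truth <- simulatePlatingTimecourse(nClones = 50, seed = 1)
#' table(SummarizedExperiment::rowData(truth)$resistant)
#' @export
simulatePlatingTimecourse <- function(nClones = 3000,
                                      clonogenicFraction = 0.3,
                                      resistantFraction = 0.1,
                                      growthRate = 20,
                                      residualGrowth = 0.25,
                                      growthNoiseSd = 0.5,
                                      bottleneckSize = 6e5,
                                      naiveTolerance = 400,
                                      schedule = PlatingSchedule(),
                                      sampling = c("multinomial", "expected"),
                                      seed) {
  sampling <- match.arg(sampling)
  stopifnot(is(schedule, "PlatingSchedule"))
  validObject(schedule)
  if (clonogenicFraction < 0 || clonogenicFraction > 1 ||
      resistantFraction < 0 || resistantFraction > 1)
    stop("fractions must lie in [0, 1]")
  if (bottleneckSize <= 0) stop("bottleneckSize must be > 0")
  sc <- platings(schedule)
  if (nrow(sc) == 0L) stop("empty plating schedule")
  set.seed(seed)

  ids <- sprintf("BC_%06d", seq_len(nClones))
  clonogenic <- runif(nClones) < clonogenicFraction
  resistant <- clonogenic & (runif(nClones) < resistantFraction)
  tolerance <- ifelse(resistant, Inf, naiveTolerance)

  ## pool composition after the pre-plating liquid expansion
  w0 <- if (growthNoiseSd > 0) exp(rnorm(nClones, 0, growthNoiseSd))
        else rep(1, nClones)

  arms <- unique(sc$arm)
  pIdx <- sort(unique(sc$plating))
  ab <- matrix(0, nClones, length(arms) * length(pIdx),
               dimnames = list(ids, NULL))
  cd <- data.frame(arm = character(), plating = integer(), dose = numeric())

  col <- 0L
  for (a in arms) {
    doses <- sc$dose[sc$arm == a][order(sc$plating[sc$arm == a])]
    prev <- w0
    for (t in seq_along(pIdx)) {
      col <- col + 1L
      surv <- if (t == 1L) rep(TRUE, nClones) else clonogenic
      surv <- surv & (doses[t] <= tolerance)
      base <- ifelse(clonogenic, growthRate, residualGrowth)
      if (t > 1L) base <- ifelse(clonogenic, growthRate, 0)
      noise <- if (growthNoiseSd > 0) exp(rnorm(nClones, 0, growthNoiseSd))
               else 1
      expanded <- prev * ifelse(surv, base, 0) * noise
      tot <- sum(expanded)
      ab[, col] <- if (tot == 0) 0
        else if (sampling == "multinomial")
          as.numeric(rmultinom(1L, bottleneckSize, expanded))
        else bottleneckSize * expanded / tot
      cd <- rbind(cd, data.frame(arm = a, plating = pIdx[t],
                                 dose = doses[t]))
      prev <- ab[, col]
    }
  }
  colnames(ab) <- paste0(cd$arm, "_p", cd$plating)
  rownames(cd) <- colnames(ab)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = ab),
    rowData = S4Vectors::DataFrame(clonogenic = clonogenic,
                                   resistant = resistant,
                                   tolerance = tolerance,
                                   row.names = ids),
    colData = S4Vectors::DataFrame(cd))
  new("CloneGroundTruth", se)
}
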