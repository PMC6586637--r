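## Synthetic cohort variant tables with planted artifacts, for
## exercising the targeted-amplicon filter.

#' Generate a cohort variant table with planted artifacts
#'
#' Emits a duplicate-replicate variant table for \code{nSamples}
#' patients. True variants satisfy every retention rule (depth >= 20,
#' >= 5 supporting reads, VAF > 1\%, carried by under half the cohort,
#' population allele frequency <= 0.4\%, concordant across replicates);
#' each artifact class violates exactly one rule:
#' \itemize{
#'   \item \code{recurrent}: present in over half the samples;
#'   \item \code{common_population}: population AF above 0.4\%;
#'   \item \code{low_depth}: depth below 20;
#'   \item \code{low_alt}: fewer than 5 supporting reads;
#'   \item \code{boundary_vaf}: VAF exactly 1\% (fails the strict rule);
#'   \item \code{discordant}: passes in one replicate only.
#' }
#'
#' @param nSamples cohort size (each analysed in duplicate).
#' @param nTrue number of true somatic variants.
#' @param nArtifactRecurrent,nCommonPopulation,nLowDepth,nLowAlt
#'   artifact counts per class.
#' @param nBoundaryVaf,nDiscordant artifact counts per class.
#' @param depthModel list with \code{meanDepth}, \code{sdDepth}.
#' @param seed integer seed.
#' @return list with \code{variants} (long data.frame: \code{sample},
#'   \code{replicate}, \code{contig}, \code{pos}, \code{ref},
#'   \code{alt}, \code{depth}, \code{alt_reads}, \code{vaf},
#'   \code{population_af}, \code{annotation}) and \code{truth}
#'   (variant key, class, \code{isTrue}).
#' @export
generateVariantFixture <- function(nSamples = 10L, nTrue = 5L,
                                   nArtifactRecurrent = 1L,
                                   nCommonPopulation = 1L,
                                   nLowDepth = 1L, nLowAlt = 1L,
                                   nBoundaryVaf = 1L, nDiscordant = 1L,
                                   depthModel = list(meanDepth = 500,
                                                     sdDepth = 80),
                                   seed) {
  counts <- c(nTrue, nArtifactRecurrent, nCommonPopulation, nLowDepth,
              nLowAlt, nBoundaryVaf, nDiscordant)
  if (any(counts < 0) || nSamples < 1L) stop("counts must be >= 0")
  set.seed(seed)
  samples <- sprintf("S%02d", seq_len(nSamples))
  bases <- c("A", "C", "G", "T")
  nVar <- sum(counts)
  classes <- rep(c("true", "recurrent", "common_population", "low_depth",
                   "low_alt", "boundary_vaf", "discordant"), counts)
  pos <- 1000L * seq_len(nVar)
  ref <- sample(bases, nVar, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  key <- sprintf("chr17:%d:%s>%s", pos, ref, alt)

  rdepth <- function(n, lo = 20L)
    pmax(lo, round(rnorm(n, depthModel$meanDepth, depthModel$sdDepth)))

  rows <- list()
  emit <- function(i, sample, replicate, depth, altReads, popAf = 0) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sample = sample, replicate = replicate, contig = "chr17",
      pos = pos[i], ref = ref[i], alt = alt[i], depth = depth,
      alt_reads = altReads, vaf = altReads / depth,
      population_af = popAf,
      annotation = if (classes[i] == "true") "curated" else ".")
  }
  for (i in seq_len(nVar)) {
    carriers <- switch(classes[i],
      recurrent = samples[seq_len(floor(nSamples / 2) + 1L)],
      sample(samples, 1L))
    for (s in carriers) for (rep in c("R1", "R2")) {
      switch(classes[i],
        true = ,
        recurrent = {
          d <- rdepth(1L)
          emit(i, s, rep, d, max(5L, round(d * runif(1L, 0.05, 0.4))))
        },
        common_population = {
          d <- rdepth(1L)
          emit(i, s, rep, d, max(5L, round(d * runif(1L, 0.05, 0.4))),
               popAf = 0.01)
        },
        low_depth = emit(i, s, rep, 15L, 6L),
        low_alt = emit(i, s, rep, 300L, 4L),
        boundary_vaf = emit(i, s, rep, 2000L, 20L),
        discordant = if (rep == "R1") {
          d <- rdepth(1L)
          emit(i, s, rep, d, max(5L, round(d * 0.2)))
        } else emit(i, s, rep, rdepth(1L), 0L))
    }
  }
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL
  list(variants = variants,
       truth = data.frame(key = key, class = classes,
                          isTrue = classes == "true"))
}
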