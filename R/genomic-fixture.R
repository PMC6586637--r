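## Synthetic genomic fixture with planted enhancer classes: genes, a DE
## table with a designated down-regulated subset, peaks with summits,
## and per-condition binned coverage tracks in which the intended fold
## changes are planted by construction.

.addBump <- function(score, summit, halfWidth, height, binSize) {
  lo <- (summit - halfWidth - 1L) %/% binSize + 1L
  hi <- (summit + halfWidth - 1L - 1L) %/% binSize + 1L
  idx <- lo:hi
  centers <- (idx - 1L) * binSize + (binSize + 1) / 2
  score[idx] <- score[idx] +
    height * pmax(0, 1 - abs(centers - summit) / halfWidth)
  score
}

.scaleInterval <- function(score, start, end, factor, binSize) {
  lo <- (start - 1L) %/% binSize + 1L
  hi <- (end - 1L) %/% binSize + 1L
  score[lo:hi] <- score[lo:hi] * factor
  score
}

#' Generate a genomic fixture with planted enhancer classes
#'
#' Builds a single synthetic contig carrying evenly spaced genes (every
#' other one designated drug-responsive: 2-fold down-regulated,
#' p = 1e-4), peaks of six planted classes, and binned coverage tracks
#' (H3K27ac, Pu.1, ATAC, Brd4; before/after treatment) in which each
#' class's fold changes hold by construction:
#' \itemize{
#'   \item \code{new}: H3K27ac scaled by \code{plantedFold} after
#'     treatment, within the TSS window of a responsive gene;
#'   \item \code{pre_existing}: H3K27ac bump in both conditions, member
#'     of the before-condition peak set, near a responsive gene;
#'   \item \code{new_pu1}: Pu.1 scaled by \code{plantedFold} only;
#'   \item \code{new_pu1_active}: both marks scaled;
#'   \item \code{none}: background peak near a responsive gene, all
#'     folds at \code{backgroundFold};
#'   \item \code{unlinked}: H3K27ac scaled by \code{plantedFold} but
#'     placed in a gene desert beyond the TSS window of every gene.
#' }
#' Brd4 is additionally doubled at \code{new} peaks and halved at
#' \code{pre_existing} peaks after treatment, modelling coactivator
#' redistribution.
#'
#' @param nGenes number of genes (every other one responsive).
#' @param nPeaksPerClass planted peaks per class.
#' @param tssWindow linking window the layout is built around (bp).
#' @param plantedFold coverage scale factor at planted-gain peaks.
#' @param backgroundFold scale factor at background peaks (default 1).
#' @param binSize track bin width (bp).
#' @param peakWidth planted peak width (bp, bin-aligned).
#' @param baseCoverage background track value per bin.
#' @param bumpHeight peak bump height over background.
#' @param noiseSd sd of optional Gaussian track noise (default 0 keeps
#'   planted folds exact).
#' @param seed integer seed.
#' @return list with \code{genes} (TSS \code{GRanges}), \code{peaks}
#'   (all planted peaks, with \code{name}, \code{summit},
#'   \code{plantedClass}), \code{beforePeaks}, \code{tracks} (named
#'   list of \code{\link{CoverageTrack}}s: \code{k27acBefore/After},
#'   \code{pu1Before/After}, \code{atac}, \code{brd4Before/After}),
#'   \code{deTable}, \code{plantedTruth} and \code{contigLength}.
#' @export
generateGenomicFixture <- function(nGenes = 20L, nPeaksPerClass = 5L,
                                   tssWindow = 50000L, plantedFold = 8,
                                   backgroundFold = 1, binSize = 50L,
                                   peakWidth = 1000L, baseCoverage = 10,
                                   bumpHeight = 40, noiseSd = 0, seed = 1) {
  set.seed(seed)
  contig <- "chrF"
  spacing <- 100000L
  desert0 <- nGenes * spacing + 3L * tssWindow
  L <- desert0 + nPeaksPerClass * 20000L + tssWindow
  if (tssWindow >= L) stop("TSS window larger than the contig")
  halfW <- peakWidth %/% 2L

  ## genes: TSS every `spacing`, alternating strand; odd ones responsive
  tss <- seq_len(nGenes) * spacing
  geneIds <- sprintf("gene_%02d", seq_len(nGenes))
  responsive <- geneIds[seq(1L, nGenes, 2L)]
  genes <- GenomicRanges::GRanges(contig, IRanges::IRanges(tss, width = 1L),
                                  strand = rep(c("+", "-"),
                                               length.out = nGenes))
  names(genes) <- geneIds

  deTable <- data.frame(
    gene = geneIds,
    log2fc = ifelse(geneIds %in% responsive, -1,
                    rep(c(0.8, -0.3), length.out = nGenes)),
    p = ifelse(geneIds %in% responsive, 1e-4,
               rep(c(1e-3, 0.5), length.out = nGenes)),
    fdr = ifelse(geneIds %in% responsive, 1e-3, 0.9))

  ## planted peaks: linked classes sit at class-specific summit offsets
  ## from responsive TSSs; "unlinked" sits in the gene desert
  offsets <- c(new = 10000L, pre_existing = -12000L, new_pu1 = 18000L,
               new_pu1_active = -22000L, none = 30000L)
  rTss <- tss[match(responsive, geneIds)]
  mkClass <- function(class) {
    k <- seq_len(nPeaksPerClass)
    g <- rTss[(k - 1L) %% length(rTss) + 1L]
    shift <- 2000L * ((k - 1L) %/% length(rTss))
    summit <- g + offsets[[class]] + shift
    data.frame(name = sprintf("%s_%d", class, k), class = class,
               summit = summit)
  }
  planted <- do.call(rbind, lapply(names(offsets), mkClass))
  planted <- rbind(planted, data.frame(
    name = sprintf("unlinked_%d", seq_len(nPeaksPerClass)),
    class = "unlinked",
    summit = desert0 + (seq_len(nPeaksPerClass) - 1L) * 20000L))

  peaks <- GenomicRanges::GRanges(
    contig, IRanges::IRanges(planted$summit - halfW,
                             planted$summit + halfW - 1L))
  peaks$name <- planted$name
  peaks$summit <- planted$summit
  peaks$plantedClass <- planted$class
  names(peaks) <- planted$name

  nbins <- as.integer(ceiling(L / binSize))
  base <- rep(baseCoverage, nbins)
  if (noiseSd > 0)
    base <- pmax(0, base + rnorm(nbins, 0, noiseSd))

  bump <- function(score, classes, height = bumpHeight) {
    for (i in which(planted$class %in% classes))
      score <- .addBump(score, planted$summit[i], halfW, height, binSize)
    score
  }
  scale <- function(score, classes, factor) {
    if (factor == 1) return(score)
    for (i in which(planted$class %in% classes))
      score <- .scaleInterval(score, planted$summit[i] - halfW,
                              planted$summit[i] + halfW - 1L, factor,
                              binSize)
    score
  }

  k27Before <- bump(base, c("pre_existing", "none"))
  k27After <- scale(k27Before, c("new", "new_pu1_active", "unlinked"),
                    plantedFold)
  k27After <- scale(k27After, c("none", "pre_existing"), backgroundFold)
  pu1Before <- bump(base, "none")
  pu1After <- scale(pu1Before, c("new_pu1", "new_pu1_active"), plantedFold)
  atac <- bump(base, unique(planted$class))
  brd4Before <- bump(base, c("pre_existing", "new"))
  brd4After <- scale(scale(brd4Before, "new", 2), "pre_existing", 0.5)

  ## library size as a read count (75 bp nominal reads), so per-million
  ## normalised bin values sit on the usual RPM scale
  mkTrack <- function(score, label) {
    starts <- seq(1L, nbins * binSize, binSize)
    bins <- GenomicRanges::GRanges(
      contig, IRanges::IRanges(starts, width = binSize))
    bins$score <- score
    CoverageTrack(bins, condition = label,
                  librarySize = sum(score * binSize) / 75)
  }
  tracks <- list(
    k27acBefore = mkTrack(k27Before, "H3K27ac_resistant"),
    k27acAfter = mkTrack(k27After, "H3K27ac_LSD1i"),
    pu1Before = mkTrack(pu1Before, "Pu.1_resistant"),
    pu1After = mkTrack(pu1After, "Pu.1_LSD1i"),
    atac = mkTrack(atac, "ATAC"),
    brd4Before = mkTrack(brd4Before, "Brd4_resistant"),
    brd4After = mkTrack(brd4After, "Brd4_LSD1i"))

  list(genes = genes, peaks = peaks,
       beforePeaks = peaks[peaks$plantedClass == "pre_existing"],
       tracks = tracks, deTable = deTable,
       plantedTruth = planted[, c("name", "class")],
       contigLength = L, binSize = as.integer(binSize))
}
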