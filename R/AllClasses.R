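## Central S4 classes. Count-like objects extend SummarizedExperiment so the
## usual assay()/rowData()/colData() accessors apply; interval-like objects
## are plain GRanges with documented metadata columns.

.CONSTANT_REGION <- "CGGATCCTGACCATGTACGATTGACTA"
.SGRNA_CONSTANT <- "TTGTGGAAAGGACGAAACACCG"

## Allowed degeneracy classes for barcode repeat units. S and W are the
## strong/weak two-fold codes; N is fully degenerate.
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  S = c("C", "G"), W = c("A", "T"),
  N = c("A", "C", "G", "T")
)

#' LibraryDesign: layout of a degenerate barcode library
#'
#' Describes a semi-random barcode library: a repeating IUPAC unit
#' (default \code{"NNSWSNNWSW"}, repeated six times for a 60-base barcode)
#' downstream of a fixed constant region used to anchor extraction.
#'
#' @slot repeatUnit single IUPAC string; only codes A/C/G/T/S/W/N allowed.
#' @slot nRepeats number of unit repeats making up the full barcode.
#' @slot constantRegion fixed DNA sequence immediately 5' of the barcode.
#' @slot librarySize number of distinct barcodes in the reference library.
#'
#' @examples
#' d <- LibraryDesign(librarySize = 100L)
#' barcodeLength(d)
#' @aliases LibraryDesign-class
#' @exportClass LibraryDesign
setClass("LibraryDesign", representation(
  repeatUnit = "character",
  nRepeats = "integer",
  constantRegion = "character",
  librarySize = "integer"
))

setValidity("LibraryDesign", function(object) {
  msg <- character()
  unit <- strsplit(object@repeatUnit, "")[[1]]
  if (!length(unit) || !all(unit %in% names(.IUPAC_SETS)))
    msg <- c(msg, "repeatUnit may only contain IUPAC codes A, C, G, T, S, W, N")
  if (length(object@nRepeats) != 1L || is.na(object@nRepeats) ||
      object@nRepeats < 1L)
    msg <- c(msg, "nRepeats must be a single integer >= 1")
  cr <- strsplit(object@constantRegion, "")[[1]]
  if (!length(cr) || !all(cr %in% c("A", "C", "G", "T")))
    msg <- c(msg, "constantRegion must be a non-empty A/C/G/T string")
  if (length(object@librarySize) != 1L || is.na(object@librarySize) ||
      object@librarySize < 1L)
    msg <- c(msg, "librarySize must be a single integer >= 1")
  if (!length(msg) &&
      log(object@librarySize) > .logPatternDiversity(object@repeatUnit) *
        object@nRepeats)
    msg <- c(msg, sprintf(
      "librarySize %d exceeds the diversity of the pattern %d(%s)",
      object@librarySize, object@nRepeats, object@repeatUnit))
  if (length(msg)) msg else TRUE
})

#' @param repeatUnit,nRepeats,constantRegion,librarySize see slot
#'   descriptions.
#' @rdname LibraryDesign-class
#' @export
LibraryDesign <- function(repeatUnit = "NNSWSNNWSW", nRepeats = 6L,
                          constantRegion = .CONSTANT_REGION,
                          librarySize = 3000L) {
  new("LibraryDesign", repeatUnit = toupper(repeatUnit),
      nRepeats = as.integer(nRepeats),
      constantRegion = toupper(constantRegion),
      librarySize = as.integer(librarySize))
}

#' PlatingSchedule: arms, platings and doses of a serial replating course
#'
#' An ordered series of weekly methylcellulose platings for a control arm
#' (vehicle throughout) and a drug arm with non-decreasing doses. The
#' default mirrors an escalation course: first plating at 400 nM, then
#' 600, 800 and 1000 nM, with 1000 nM maintained for four further weekly
#' platings.
#'
#' @slot schedule data.frame with columns \code{arm}, \code{plating},
#'   \code{dose} (nM; 0 in the control arm).
#' @slot baselineIndex plating index used as the baseline time point for
#'   the representation filter (the first plating).
#'
#' @aliases PlatingSchedule-class
#' @exportClass PlatingSchedule
setClass("PlatingSchedule", representation(
  schedule = "data.frame",
  baselineIndex = "integer"
))

setValidity("PlatingSchedule", function(object) {
  sc <- object@schedule
  msg <- character()
  if (!all(c("arm", "plating", "dose") %in% names(sc)))
    msg <- c(msg, "schedule needs columns arm, plating, dose")
  else {
    if (nrow(sc) == 0L) msg <- c(msg, "schedule is empty")
    if (any(sc$dose < 0)) msg <- c(msg, "doses must be non-negative")
    for (a in unique(sc$arm)) {
      d <- sc$dose[sc$arm == a][order(sc$plating[sc$arm == a])]
      if (is.unsorted(d))
        msg <- c(msg, sprintf("doses must be non-decreasing within arm '%s'", a))
    }
    if (length(object@baselineIndex) != 1L ||
        object@baselineIndex != min(sc$plating))
      msg <- c(msg, "baselineIndex must be the first plating index")
  }
  if (length(msg)) msg else TRUE
})

#' @param drugDoses dose (nM) at each plating of the drug arm.
#' @param arms labels for the control and drug arms.
#' @rdname PlatingSchedule-class
#' @export
PlatingSchedule <- function(drugDoses = c(400, 600, 800, 1000, 1000, 1000,
                                          1000, 1000),
                            arms = c(control = "DMSO", drug = "IBET")) {
  if (!length(drugDoses)) stop("empty plating schedule")
  p <- seq_along(drugDoses)
  sc <- rbind(
    data.frame(arm = arms[["control"]], plating = p, dose = 0),
    data.frame(arm = arms[["drug"]], plating = p, dose = as.numeric(drugDoses))
  )
  new("PlatingSchedule", schedule = sc, baselineIndex = 1L)
}

#' CloneGroundTruth: simulated clone flags and abundance trajectories
#'
#' A \linkS4class{SummarizedExperiment} with one row per clone and one
#' column per (arm, plating) sample. \code{assay(x, "abundance")} holds
#' non-negative clone abundances (cells at harvest); \code{rowData} holds
#' the per-clone \code{clonogenic} and \code{resistant} flags;
#' \code{colData} holds \code{arm}, \code{plating} and \code{dose}.
#'
#' @aliases CloneGroundTruth-class
#' @exportClass CloneGroundTruth
setClass("CloneGroundTruth", contains = "SummarizedExperiment")

setValidity("CloneGroundTruth", function(object) {
  msg <- character()
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    return("assay 'abundance' is required")
  ab <- SummarizedExperiment::assay(object, "abundance")
  if (any(ab < 0)) msg <- c(msg, "abundances must be non-negative")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("clonogenic", "resistant") %in% names(rd)))
    msg <- c(msg, "rowData needs logical columns clonogenic, resistant")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("arm", "plating", "dose") %in% names(cd)))
    msg <- c(msg, "colData needs columns arm, plating, dose")
  if (!length(msg)) {
    late <- cd$plating > min(cd$plating)
    if (any(ab[!rd$clonogenic, late, drop = FALSE] > 0))
      msg <- c(msg, "non-clonogenic clones must have zero abundance after the first plating")
  }
  if (length(msg)) msg else TRUE
})

#' BarcodeCountTable: per-sample, per-barcode read tallies
#'
#' A \linkS4class{SummarizedExperiment} with one row per reference barcode
#' and one column per sequenced sample. \code{assay(x, "counts")} holds
#' integer read tallies; \code{colData} carries \code{sample}, \code{arm},
#' \code{plating}, \code{dose} and \code{isBaseline};
#' \code{metadata(x)$rejections} is a reasons-by-samples matrix of reads
#' that were not assigned, partitioned by rejection reason.
#'
#' @aliases BarcodeCountTable-class
#' @exportClass BarcodeCountTable
setClass("BarcodeCountTable", contains = "SummarizedExperiment")

setValidity("BarcodeCountTable", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample", "arm", "plating", "isBaseline")
  if (!all(need %in% names(cd)))
    msg <- c(msg, paste("colData needs columns", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' CoverageTrack: binned per-condition genomic signal
#'
#' Fixed-width binned coverage for one condition (e.g. H3K27ac in
#' resistant cells), stored as a disjoint \linkS4class{GRanges} with a
#' \code{score} column, plus the library size used for per-million
#' normalisation.
#'
#' @slot condition condition label.
#' @slot bins disjoint GRanges tiling of the covered contigs, with
#'   numeric non-negative \code{score}.
#' @slot binSize bin width in bp.
#' @slot librarySize total signal (sum of score times width) used for
#'   per-million scaling.
#'
#' @aliases CoverageTrack-class
#' @exportClass CoverageTrack
setClass("CoverageTrack", representation(
  condition = "character",
  bins = "GRanges",
  binSize = "integer",
  librarySize = "numeric"
))

setValidity("CoverageTrack", function(object) {
  msg <- character()
  if (is.null(object@bins$score))
    return("bins must carry a numeric 'score' column")
  if (any(object@bins$score < 0)) msg <- c(msg, "scores must be non-negative")
  if (!GenomicRanges::isDisjoint(object@bins))
    msg <- c(msg, "bins must not overlap")
  if (length(object@librarySize) != 1L || object@librarySize <= 0)
    msg <- c(msg, "librarySize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' RetentionResult: serially retained barcode sets across platings
#'
#' Result of \code{\link{sequentialRetention}}: for one arm, the chain of
#' retained barcode sets (each nested within the previous), their sizes,
#' and the resistant-clone fraction estimate, i.e. the fraction of
#' first-plating barcodes still retained at the final plating.
#'
#' @slot arm arm label the chain was computed for.
#' @slot platings ordered plating indices.
#' @slot retained \code{CharacterList} of retained barcode ids per plating.
#' @slot resistantFraction size of the final set over the size of the
#'   first set.
#'
#' @aliases RetentionResult-class
#' @exportClass RetentionResult
setClass("RetentionResult", representation(
  arm = "character",
  platings = "integer",
  retained = "CharacterList",
  resistantFraction = "numeric"
))

setValidity("RetentionResult", function(object) {
  sets <- object@retained
  if (length(sets) != length(object@platings))
    return("one retained set per plating required")
  if (length(sets) > 1L)
    for (i in 2:length(sets))
      if (!all(sets[[i]] %in% sets[[i - 1L]]))
        return("retained sets must be nested across platings")
  TRUE
})

#' FilterConfig: thresholds for barcode read filtering and retention
#'
#' @slot constantRegion anchor sequence searched on the forward strand.
#' @slot repeatUnit,nRepeats expected barcode pattern.
#' @slot meanQualityMin minimum mean phred over the barcode bases
#'   (inclusive; default 30).
#' @slot cumulativeFraction cumulative read fraction defining the
#'   retained top set per sample (default 0.90).
#' @slot baselineMinCount strict lower bound on baseline representation
#'   (default 20: barcodes need a baseline count above 20).
#' @slot tieRule \code{"group"} (default) includes the whole tied count
#'   group at the cumulative boundary; \code{"lexical"} breaks ties by
#'   barcode id.
#' @slot searchRevcomp also search the reverse-complement strand for the
#'   constant region when the forward search fails.
#'
#' @aliases FilterConfig-class
#' @exportClass FilterConfig
setClass("FilterConfig", representation(
  constantRegion = "character",
  repeatUnit = "character",
  nRepeats = "integer",
  meanQualityMin = "numeric",
  cumulativeFraction = "numeric",
  baselineMinCount = "integer",
  tieRule = "character",
  searchRevcomp = "logical"
))

setValidity("FilterConfig", function(object) {
  msg <- character()
  if (object@cumulativeFraction <= 0 || object@cumulativeFraction > 1)
    msg <- c(msg, "cumulativeFraction must be in (0, 1]")
  if (object@meanQualityMin < 0)
    msg <- c(msg, "meanQualityMin must be >= 0")
  if (!object@tieRule %in% c("group", "lexical"))
    msg <- c(msg, "tieRule must be 'group' or 'lexical'")
  if (length(msg)) msg else TRUE
})

#' @param constantRegion,repeatUnit,nRepeats,meanQualityMin see slots.
#' @param cumulativeFraction,baselineMinCount,tieRule,searchRevcomp see
#'   slots.
#' @rdname FilterConfig-class
#' @export
FilterConfig <- function(constantRegion = .CONSTANT_REGION,
                         repeatUnit = "NNSWSNNWSW", nRepeats = 6L,
                         meanQualityMin = 30, cumulativeFraction = 0.9,
                         baselineMinCount = 20L,
                         tieRule = c("group", "lexical"),
                         searchRevcomp = FALSE) {
  new("FilterConfig", constantRegion = toupper(constantRegion),
      repeatUnit = toupper(repeatUnit), nRepeats = as.integer(nRepeats),
      meanQualityMin = meanQualityMin,
      cumulativeFraction = cumulativeFraction,
      baselineMinCount = as.integer(baselineMinCount),
      tieRule = match.arg(tieRule), searchRevcomp = searchRevcomp)
}

#' EnhancerConfig: thresholds for enhancer classification and linking
#'
#' @slot foldThreshold coverage fold change (after vs before) above which
#'   a mark is called increased (strict; default 4).
#' @slot tssWindow maximum |summit - TSS| distance in bp for linking a
#'   peak to a responsive gene (default 50000).
#' @slot deFcMin minimum linear fold-change magnitude for a gene to count
#'   as drug-responsive (strict; default 1.5).
#' @slot dePMax significance cutoff for responsive genes (strict;
#'   default 0.01).
#' @slot flank half-width of metaprofile windows around summits (bp,
#'   default 5000).
#' @slot nBins number of metaprofile bins across the window.
#' @slot pseudocount added to normalised mean coverages before folds.
#' @slot normalize per-million library-size scaling before folds.
#' @slot sigField DE column used for significance: \code{"p"} or
#'   \code{"fdr"}.
#' @slot distanceMode \code{"summit"} measures summit-to-TSS,
#'   \code{"edge"} measures nearest interval edge to TSS.
#'
#' @aliases EnhancerConfig-class
#' @exportClass EnhancerConfig
setClass("EnhancerConfig", representation(
  foldThreshold = "numeric",
  tssWindow = "integer",
  deFcMin = "numeric",
  dePMax = "numeric",
  flank = "integer",
  nBins = "integer",
  pseudocount = "numeric",
  normalize = "logical",
  sigField = "character",
  distanceMode = "character"
))

setValidity("EnhancerConfig", function(object) {
  msg <- character()
  if (object@foldThreshold <= 1) msg <- c(msg, "foldThreshold must be > 1")
  if (object@tssWindow <= 0) msg <- c(msg, "tssWindow must be > 0")
  if (object@flank <= 0) msg <- c(msg, "flank must be > 0")
  if (object@nBins < 1) msg <- c(msg, "nBins must be >= 1")
  if (object@pseudocount < 0) msg <- c(msg, "pseudocount must be >= 0")
  if (!object@sigField %in% c("p", "fdr"))
    msg <- c(msg, "sigField must be 'p' or 'fdr'")
  if (!object@distanceMode %in% c("summit", "edge"))
    msg <- c(msg, "distanceMode must be 'summit' or 'edge'")
  if (length(msg)) msg else TRUE
})

#' @param foldThreshold,tssWindow,deFcMin,dePMax,flank,nBins see slots.
#' @param pseudocount,normalize,sigField,distanceMode see slots.
#' @rdname EnhancerConfig-class
#' @export
EnhancerConfig <- function(foldThreshold = 4, tssWindow = 50000L,
                           deFcMin = 1.5, dePMax = 0.01, flank = 5000L,
                           nBins = 100L, pseudocount = 1, normalize = TRUE,
                           sigField = c("p", "fdr"),
                           distanceMode = c("summit", "edge")) {
  new("EnhancerConfig", foldThreshold = foldThreshold,
      tssWindow = as.integer(tssWindow), deFcMin = deFcMin, dePMax = dePMax,
      flank = as.integer(flank), nBins = as.integer(nBins),
      pseudocount = pseudocount, normalize = normalize,
      sigField = match.arg(sigField), distanceMode = match.arg(distanceMode))
}

#' VariantFilterConfig: targeted-amplicon variant retention thresholds
#'
#' Per-record retention requires depth >= \code{minDepth}, supporting
#' reads >= \code{minAltReads} and VAF strictly above \code{minVaf}.
#' Cohort exclusions drop variants seen in strictly more than
#' \code{recurrenceFraction} of samples or with population allele
#' frequency strictly above \code{maxPopulationAf}.
#'
#' @slot minDepth,minAltReads,minVaf per-record thresholds.
#' @slot recurrenceFraction,maxPopulationAf cohort-level exclusions.
#' @slot requireDuplicateConcordance keep a variant only when it passes
#'   the per-record stage in both replicates of a sample.
#'
#' @aliases VariantFilterConfig-class
#' @exportClass VariantFilterConfig
setClass("VariantFilterConfig", representation(
  minDepth = "integer",
  minAltReads = "integer",
  minVaf = "numeric",
  recurrenceFraction = "numeric",
  maxPopulationAf = "numeric",
  requireDuplicateConcordance = "logical"
))

setValidity("VariantFilterConfig", function(object) {
  vals <- c(object@minDepth, object@minAltReads, object@minVaf,
            object@recurrenceFraction, object@maxPopulationAf)
  if (any(vals < 0)) "all thresholds must be >= 0" else TRUE
})

#' @param minDepth,minAltReads,minVaf,recurrenceFraction see slots.
#' @param maxPopulationAf,requireDuplicateConcordance see slots.
#' @rdname VariantFilterConfig-class
#' @export
VariantFilterConfig <- function(minDepth = 20L, minAltReads = 5L,
                                minVaf = 0.01, recurrenceFraction = 0.5,
                                maxPopulationAf = 0.004,
                                requireDuplicateConcordance = TRUE) {
  new("VariantFilterConfig", minDepth = as.integer(minDepth),
      minAltReads = as.integer(minAltReads), minVaf = minVaf,
      recurrenceFraction = recurrenceFraction,
      maxPopulationAf = maxPopulationAf,
      requireDuplicateConcordance = requireDuplicateConcordance)
}
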