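#' @rdname LibraryDesign-class
#' @param x a \code{LibraryDesign}.
#' @export
setGeneric("barcodeLength", function(x) standardGeneric("barcodeLength"))

#' @rdname PlatingSchedule-class
#' @param x a \code{PlatingSchedule}.
#' @export
setGeneric("platings", function(x) standardGeneric("platings"))

#' @rdname BarcodeCountTable-class
#' @param x a \code{BarcodeCountTable}.
#' @export
setGeneric("barcodeCounts", function(x) standardGeneric("barcodeCounts"))

#' @rdname BarcodeCountTable-class
#' @export
setGeneric("rejectionSummary", function(x) standardGeneric("rejectionSummary"))

#' @rdname CoverageTrack-class
#' @param x a \code{CoverageTrack}.
#' @export
setGeneric("trackBins", function(x) standardGeneric("trackBins"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))

#' @rdname RetentionResult-class
#' @param x a \code{RetentionResult}.
#' @export
setGeneric("retainedSets", function(x) standardGeneric("retainedSets"))

#' @rdname RetentionResult-class
#' @export
setGeneric("retainedCounts", function(x) standardGeneric("retainedCounts"))

#' @rdname RetentionResult-class
#' @export
setGeneric("resistantFraction", function(x) standardGeneric("resistantFraction"))
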