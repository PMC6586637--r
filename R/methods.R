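## Accessors and show() methods.

#' @rdname LibraryDesign-class
#' @export
setMethod("barcodeLength", "LibraryDesign", function(x)
  nchar(x@repeatUnit) * x@nRepeats)

setMethod("show", "LibraryDesign", function(object) {
  cat("LibraryDesign:", object@nRepeats, "x", object@repeatUnit,
      sprintf("(%d bp barcode)\n", barcodeLength(object)))
  cat("  constant region:", object@constantRegion, "\n")
  cat("  library size:", object@librarySize, "\n")
})

#' @rdname PlatingSchedule-class
#' @export
setMethod("platings", "PlatingSchedule", function(x) x@schedule)

setMethod("show", "PlatingSchedule", function(object) {
  sc <- object@schedule
  arms <- unique(sc$arm)
  cat("PlatingSchedule:", length(unique(sc$plating)), "platings,",
      length(arms), "arms\n")
  for (a in arms) {
    d <- sc$dose[sc$arm == a][order(sc$plating[sc$arm == a])]
    cat(sprintf("  %s: %s nM\n", a, paste(d, collapse = ", ")))
  }
})

#' @rdname BarcodeCountTable-class
#' @export
setMethod("barcodeCounts", "BarcodeCountTable", function(x)
  SummarizedExperiment::assay(x, "counts"))

#' @rdname BarcodeCountTable-class
#' @export
setMethod("rejectionSummary", "BarcodeCountTable", function(x)
  S4Vectors::metadata(x)$rejections)

#' @rdname CoverageTrack-class
#' @export
setMethod("trackBins", "CoverageTrack", function(x) x@bins)

#' @rdname CoverageTrack-class
#' @export
setMethod("condition", "CoverageTrack", function(x) x@condition)

#' @rdname CoverageTrack-class
#' @export
setMethod("binSize", "CoverageTrack", function(x) x@binSize)

#' @rdname CoverageTrack-class
#' @export
setMethod("librarySize", "CoverageTrack", function(x) x@librarySize)

setMethod("show", "CoverageTrack", function(object) {
  cat("CoverageTrack:", object@condition, "\n")
  cat(sprintf("  %d bins of %d bp on %d contig(s); library size %.4g\n",
              length(object@bins), object@binSize,
              length(GenomeInfoDb::seqlevels(object@bins)),
              object@librarySize))
})

#' @rdname RetentionResult-class
#' @export
setMethod("retainedSets", "RetentionResult", function(x) x@retained)

#' @rdname RetentionResult-class
#' @export
setMethod("retainedCounts", "RetentionResult", function(x)
  setNames(lengths(x@retained), paste0("p", x@platings)))

#' @rdname RetentionResult-class
#' @export
setMethod("resistantFraction", "RetentionResult", function(x)
  x@resistantFraction)

setMethod("show", "RetentionResult", function(object) {
  cat("RetentionResult (", object@arm, " arm)\n", sep = "")
  cnt <- retainedCounts(object)
  cat("  retained:", paste(cnt, collapse = " -> "), "\n")
  cat(sprintf("  resistant fraction estimate: %.4g\n",
              object@resistantFraction))
})
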