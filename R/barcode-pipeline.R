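#' Run the full barcode quantification and retention pipeline
#'
#' FASTQ to retention statistics in one call: reads each sample's FASTQ,
#' extracts and screens candidate barcodes (constant region, pattern,
#' no-N, mean quality), assigns them to the reference by exact match,
#' tallies counts and rejection reasons per sample, and runs the
#' per-arm serial-retention analysis.
#'
#' The drug-arm \code{resistantFraction} of the returned retention
#' results estimates the fraction of clonogenic clones able to adapt to
#' the escalated drug; because the cumulative-fraction and baseline
#' filters deliberately discard low-frequency signal, it is an
#' underestimate of the true resistant fraction.
#'
#' @param sampleSheet data.frame with columns \code{sample}, \code{arm},
#'   \code{plating}, \code{dose}, \code{isBaseline}, \code{fastq} (as
#'   written by \code{\link{emitBarcodeReads}}), or the path of such a
#'   TSV.
#' @param reference named \code{DNAStringSet} or path of a reference
#'   TSV (\code{id}, \code{sequence}).
#' @param config a \code{\link{FilterConfig}}.
#' @return list with \code{counts} (a
#'   \code{\link{BarcodeCountTable}}), \code{retention} (named list of
#'   \code{\link{RetentionResult}}, one per arm), and
#'   \code{resistantFraction} (drug-arm estimate, taken from the arm
#'   with a non-zero final dose when present).
#' @export
runBarcodePipeline <- function(sampleSheet, reference,
                               config = FilterConfig()) {
  if (is.character(sampleSheet) && length(sampleSheet) == 1L)
    sampleSheet <- read.delim(sampleSheet, stringsAsFactors = FALSE)
  need <- c("sample", "arm", "plating", "dose", "isBaseline", "fastq")
  if (!all(need %in% names(sampleSheet)))
    stop("sample sheet needs columns ", paste(need, collapse = ", "))
  if (is.character(reference) && length(reference) == 1L)
    reference <- readReferenceLibrary(reference)

  assignments <- list()
  rejections <- matrix(0L, length(.REJECTION_REASONS),
                       nrow(sampleSheet),
                       dimnames = list(.REJECTION_REASONS,
                                       sampleSheet$sample))
  for (i in seq_len(nrow(sampleSheet))) {
    reads <- readFastq(sampleSheet$fastq[i])
    ext <- extractBarcodes(reads, config)
    ids <- mapExact(ext$barcode[ext$status == "ok"], reference)
    assignments[[sampleSheet$sample[i]]] <- ids
    rj <- table(factor(ext$status, levels = c("ok", .REJECTION_REASONS)))
    rejections[, i] <- as.integer(rj[.REJECTION_REASONS])
  }

  counts <- countBarcodes(assignments, reference,
                          sampleInfo = sampleSheet[, need[-6L]],
                          rejections = rejections)
  arms <- unique(sampleSheet$arm)
  retention <- lapply(setNames(arms, arms), function(a)
    retentionAnalysis(counts, a, config))

  finalDose <- vapply(arms, function(a) {
    d <- sampleSheet$dose[sampleSheet$arm == a]
    d[which.max(sampleSheet$plating[sampleSheet$arm == a])]
  }, numeric(1))
  drugArm <- if (any(finalDose > 0)) arms[which.max(finalDose)]
             else arms[length(arms)]
  list(counts = counts, retention = retention,
       resistantFraction = resistantFraction(retention[[drugArm]]))
}

#' Write a JSON run report for a pipeline result
#'
#' Serialises per-sample read accounting (mapped and per-reason
#' rejections), per-arm retained counts and the resistant-fraction
#' estimate.
#'
#' @param result list returned by \code{\link{runBarcodePipeline}}.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeRunReport <- function(result, path) {
  cnt <- barcodeCounts(result$counts)
  rep <- list(
    samples = colnames(cnt),
    mapped_reads = as.list(setNames(colSums(cnt), colnames(cnt))),
    rejections = apply(rejectionSummary(result$counts), 2L, as.list),
    retained = lapply(result$retention, function(r)
      as.list(retainedCounts(r))),
    resistant_fraction = result$resistantFraction)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
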