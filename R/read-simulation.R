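## Synthetic amplicon read emission for the barcoding experiment.

.randomDNA <- function(totalChars) {
  if (totalChars <= 0) return("")
  rawToChar(as.raw(c(65L, 67L, 71L, 84L)[sample.int(4L, totalChars,
                                                    replace = TRUE)]))
}

## chop one long string into fixed-width pieces
.chop <- function(long, width, n) {
  if (n == 0L) return(character())
  substring(long, seq(1L, by = width, length.out = n),
            seq(width, by = width, length.out = n))
}

#' Emit synthetic barcode amplicon reads per sample
#'
#' Writes one FASTQ file per (arm, plating) sample of a simulated
#' timecourse, plus a sample sheet TSV. Each read is a uniform random
#' stagger prefix (0 to \code{staggerMax} bases), the design's constant
#' region, the clone's barcode, and random filler up to
#' \code{readLength}; per-base substitution errors occur at
#' \code{errorRate} and phred qualities are Gaussian
#' (\code{qualityModel}), rounded and clipped to [2, 41].
#'
#' Per-barcode read counts are a multinomial draw of
#' \code{readsPerSample} reads on the sample's clone abundances
#' (\code{sampling = "multinomial"}, under which per-sample counts sum
#' exactly to \code{readsPerSample}); \code{sampling = "expected"}
#' rounds the expected counts instead, keeping exactly tied clones tied
#' at the cost of an approximate total.
#'
#' @param truth a \code{\link{CloneGroundTruth}}.
#' @param reference named \code{DNAStringSet}; must contain every clone
#'   id of \code{truth}.
#' @param design the \code{\link{LibraryDesign}} used for the library.
#' @param dir output directory (created if needed).
#' @param readsPerSample reads emitted per sample.
#' @param errorRate per-base substitution probability in [0, 1).
#' @param qualityModel list with \code{meanQ} and \code{sdQ}.
#' @param staggerMax maximum stagger prefix length.
#' @param readLength total read length in bases.
#' @param sampling read-count sampling mode, see Details.
#' @param compress write gzipped FASTQ.
#' @param seed integer seed.
#' @return the sample sheet as a data.frame (columns \code{sample},
#'   \code{arm}, \code{plating}, \code{dose}, \code{isBaseline},
#'   \code{fastq}), also written to \code{file.path(dir, "samples.tsv")}.
#' @export
emitBarcodeReads <- function(truth, reference, design = LibraryDesign(),
                             dir, readsPerSample = 2e5, errorRate = 0.002,
                             qualityModel = list(meanQ = 37, sdQ = 3),
                             staggerMax = 6L, readLength = 110L,
                             sampling = c("multinomial", "expected"),
                             compress = FALSE, seed) {
  sampling <- match.arg(sampling)
  stopifnot(is(truth, "CloneGroundTruth"), is(design, "LibraryDesign"))
  if (errorRate < 0 || errorRate >= 1) stop("errorRate must be in [0, 1)")
  missing <- setdiff(rownames(truth), names(reference))
  if (length(missing))
    stop("clone ids absent from the reference library: ",
         paste(head(missing, 3), collapse = ", "),
         if (length(missing) > 3) " ...")
  bcLen <- barcodeLength(design)
  minLen <- staggerMax + nchar(design@constantRegion) + bcLen
  if (readLength < minLen)
    stop("readLength must be at least ", minLen)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  ab <- SummarizedExperiment::assay(truth, "abundance")
  cd <- as.data.frame(SummarizedExperiment::colData(truth))
  refChar <- as.character(reference)
  ext <- if (compress) ".fastq.gz" else ".fastq"

  sheet <- data.frame(sample = colnames(ab), arm = cd$arm,
                      plating = cd$plating, dose = cd$dose,
                      isBaseline = cd$plating == min(cd$plating),
                      fastq = file.path(dir, paste0(colnames(ab), ext)),
                      stringsAsFactors = FALSE)

  for (j in seq_len(ncol(ab))) {
    tot <- sum(ab[, j])
    counts <- if (tot == 0) integer(length(refChar[rownames(ab)]))
      else if (sampling == "multinomial")
        as.integer(rmultinom(1L, readsPerSample, ab[, j]))
      else as.integer(round(readsPerSample * ab[, j] / tot))
    pos <- counts > 0L
    bc <- rep(refChar[rownames(ab)][pos], counts[pos])
    n <- length(bc)
    if (n == 0L) {
      writeFastq(Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(), Biostrings::PhredQuality(character())),
        sheet$fastq[j], compress = compress)
      next
    }
    sLen <- sample.int(staggerMax + 1L, n, replace = TRUE) - 1L
    stagger <- substring(.chop(.randomDNA(n * staggerMax), staggerMax, n),
                         1L, sLen)
    core <- paste0(stagger, design@constantRegion, bc)
    maxFill <- readLength - nchar(design@constantRegion) - bcLen
    fill <- substring(.chop(.randomDNA(n * maxFill), maxFill, n),
                      1L, readLength - nchar(core))
    reads <- paste0(core, fill)

    if (errorRate > 0) {
      nBase <- n * readLength
      nErr <- rbinom(1L, nBase, errorRate)
      if (nErr > 0L) {
        at <- sample.int(nBase, nErr)
        ri <- (at - 1L) %/% readLength + 1L
        pj <- (at - 1L) %% readLength + 1L
        sub <- sample(c("A", "C", "G", "T"), nErr, replace = TRUE)
        for (k in seq_len(nErr))
          substr(reads[ri[k]], pj[k], pj[k]) <- sub[k]
      }
    }

    if (qualityModel$sdQ == 0) {
      q0 <- min(max(round(qualityModel$meanQ), 2L), 41L)
      qual <- rep(strrep(rawToChar(as.raw(33L + q0)), readLength), n)
    } else {
      q <- round(rnorm(n * readLength, qualityModel$meanQ,
                       qualityModel$sdQ))
      q <- pmin(pmax(q, 2L), 41L)
      qual <- .chop(rawToChar(as.raw(33L + q)), readLength, n)
    }

    fq <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(
        setNames(reads, sprintf("%s:%06d", colnames(ab)[j], seq_len(n)))),
      Biostrings::PhredQuality(qual))
    writeFastq(fq, sheet$fastq[j], compress = compress)
  }

  write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  sheet
}
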