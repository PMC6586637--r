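## Readers and writers for peaks (BED6 + summit), binned coverage
## (bedGraph), gene TSS tables and differential-expression tables.
## BED and bedGraph are 0-based half-open on disk; in memory everything
## is 1-based GRanges.

.scanBedCoords <- function(path, what = "BED") {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#")
  if (ncol(tab) < 3L)
    stop(what, " file '", path, "' needs at least 3 columns")
  start <- suppressWarnings(as.numeric(tab[[2L]]))
  end <- suppressWarnings(as.numeric(tab[[3L]]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop(sprintf("%s file '%s': invalid coordinates at line %d", what,
                 path, bad[1L]))
  tab
}

#' Read peak intervals from a BED file
#'
#' Accepts BED3/BED6 and the extended BED6+summit layout written by
#' \code{\link{writePeaks}} (column 7: absolute 0-based summit
#' coordinate). Without a summit column the interval midpoint is used.
#' Coordinate violations (start >= end, negative start) are reported
#' with their line number.
#'
#' @param path BED file path.
#' @return \code{GRanges} with metadata columns \code{name} and
#'   \code{summit} (1-based absolute position).
#' @export
readPeaks <- function(path) {
  tab <- .scanBedCoords(path, "BED")
  strand <- if (ncol(tab) >= 6L) sub("^\\.$", "*", tab[[6L]]) else "*"
  gr <- GenomicRanges::GRanges(
    tab[[1L]],
    IRanges::IRanges(start = as.integer(tab[[2L]]) + 1L,
                     end = as.integer(tab[[3L]])),
    strand = strand)
  gr$name <- if (ncol(tab) >= 4L) as.character(tab[[4L]])
             else paste0("peak_", seq_along(gr))
  ## default summit: 0-based midpoint of the half-open interval
  summit <- if (ncol(tab) >= 7L) as.integer(tab[[7L]]) + 1L
            else as.integer((GenomicRanges::start(gr) - 1L +
                             GenomicRanges::end(gr)) %/% 2L) + 1L
  if (any(summit < GenomicRanges::start(gr) |
          summit > GenomicRanges::end(gr)))
    stop("summit outside its interval in '", path, "'")
  gr$summit <- summit
  names(gr) <- gr$name
  gr
}

#' @param peaks \code{GRanges} with \code{name} and \code{summit}
#'   columns (defaults are filled in).
#' @rdname readPeaks
#' @export
writePeaks <- function(peaks, path) {
  name <- if (!is.null(peaks$name)) peaks$name
          else paste0("peak_", seq_along(peaks))
  summit <- if (!is.null(peaks$summit)) peaks$summit
            else (GenomicRanges::start(peaks) +
                  GenomicRanges::end(peaks)) %/% 2L
  strand <- as.character(GenomicRanges::strand(peaks))
  strand[strand == "*"] <- "."
  write.table(
    data.frame(as.character(GenomicRanges::seqnames(peaks)),
               GenomicRanges::start(peaks) - 1L,
               GenomicRanges::end(peaks),
               name, 0L, strand, summit - 1L),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read binned coverage from a bedGraph file
#'
#' Parsing is delegated to \code{rtracklayer}; a cheap coordinate
#' pre-scan first reports malformed lines by number. The library size
#' defaults to the track's total signal (sum of value times width),
#' the quantity used for per-million normalisation.
#'
#' @param path bedGraph file path.
#' @param condition condition label for the track.
#' @param librarySize total-signal override.
#' @return a \code{\link{CoverageTrack}}.
#' @export
readCoverageTrack <- function(path, condition = basename(path),
                              librarySize = NULL) {
  .scanBedCoords(path, "bedGraph")
  bins <- rtracklayer::import(path, format = "bedGraph")
  CoverageTrack(bins, condition = condition, librarySize = librarySize)
}

#' @param track a \code{\link{CoverageTrack}}.
#' @rdname readCoverageTrack
#' @export
writeCoverageTrack <- function(track, path) {
  rtracklayer::export(trackBins(track), path, format = "bedGraph")
  invisible(path)
}

#' Construct a CoverageTrack from a binned GRanges
#'
#' @param bins disjoint \code{GRanges} with a numeric \code{score}.
#' @param condition condition label.
#' @param librarySize total signal; defaults to
#'   \code{sum(score * width)}.
#' @return a \code{\link{CoverageTrack}}.
#' @rdname CoverageTrack-class
#' @export
CoverageTrack <- function(bins, condition = "track", librarySize = NULL) {
  if (is.null(librarySize)) {
    librarySize <- sum(bins$score * GenomicRanges::width(bins))
    ## all-zero tracks are legal inputs; unit library size keeps the
    ## per-million scaling defined
    if (librarySize <= 0) librarySize <- 1
  }
  new("CoverageTrack", condition = condition, bins = bins,
      binSize = as.integer(max(GenomicRanges::width(bins))),
      librarySize = as.numeric(librarySize))
}

#' Read a gene TSS table
#'
#' Tab-separated with columns \code{gene}, \code{contig}, \code{tss}
#' (1-based), \code{strand}. Multiple TSS rows per gene are resolved to
#' the 5'-most (smallest coordinate on +, largest on -).
#'
#' @param path TSV path.
#' @return width-1 \code{GRanges} named by gene.
#' @export
readGenes <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "contig", "tss", "strand")
  if (!all(need %in% names(tab)))
    stop("gene table needs columns ", paste(need, collapse = ", "))
  sp <- split(tab, tab$gene)
  tab <- do.call(rbind, lapply(sp, function(g) {
    if (nrow(g) == 1L) return(g)
    pick <- if (g$strand[1L] == "-") which.max(g$tss) else which.min(g$tss)
    g[pick, ]
  }))
  gr <- GenomicRanges::GRanges(tab$contig,
                               IRanges::IRanges(tab$tss, width = 1L),
                               strand = tab$strand)
  names(gr) <- tab$gene
  gr
}

#' Read a differential-expression results table
#'
#' Tab-separated with columns \code{gene}, \code{log2fc}, \code{p} and
#' optionally \code{fdr}.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readDETable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "log2fc", "p") %in% names(tab)))
    stop("DE table needs columns gene, log2fc, p")
  tab
}
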