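#' Read a FASTQ file into a QualityScaledDNAStringSet
#'
#' Strict 4-line-record FASTQ reader (phred+33). Gzip-compressed files
#' are decompressed transparently. Structural problems are reported with
#' the 1-based index of the offending record: a record count not
#' divisible by four, a header not starting with \code{@}, a separator
#' not starting with \code{+}, or sequence and quality strings of
#' different lengths.
#'
#' @param path FASTQ file, optionally gzipped.
#' @return a \code{Biostrings::QualityScaledDNAStringSet}; empty input
#'   yields an empty set.
#' @seealso \code{\link{writeFastq}}
#' @export
readFastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L)
    return(Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(), Biostrings::PhredQuality(character())))
  if (n %% 4L != 0L)
    stop(sprintf("malformed FASTQ '%s': truncated record %d", path,
                 n %/% 4L + 1L))
  hd <- lines[seq(1L, n, 4L)]
  sq <- lines[seq(2L, n, 4L)]
  pl <- lines[seq(3L, n, 4L)]
  ql <- lines[seq(4L, n, 4L)]
  bad <- which(!startsWith(hd, "@") | !startsWith(pl, "+"))
  if (length(bad))
    stop(sprintf("malformed FASTQ '%s': bad record markers at record %d",
                 path, bad[1L]))
  bad <- which(nchar(sq) != nchar(ql))
  if (length(bad))
    stop(sprintf(
      "malformed FASTQ '%s': sequence/quality length mismatch at record %d",
      path, bad[1L]))
  ids <- sub("^@", "", hd)
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(sq, ids)),
    Biostrings::PhredQuality(ql))
}

#' Write a QualityScaledDNAStringSet as FASTQ
#'
#' @param x a \code{QualityScaledDNAStringSet}.
#' @param path output path; a \code{.gz} suffix (or \code{compress =
#'   TRUE}) writes gzip.
#' @param compress write gzip-compressed output.
#' @return the path, invisibly.
#' @export
writeFastq <- function(x, path, compress = grepl("\\.gz$", path)) {
  Biostrings::writeQualityScaledXStringSet(x, path, compress = compress)
  invisible(path)
}

## integer phred scores per read
.qualityInts <- function(reads)
  as(Biostrings::quality(reads), "IntegerList")
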