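## Degenerate barcode pattern utilities and reference-library generation.

.unitLetters <- function(unit) {
  letters <- strsplit(unit, "")[[1]]
  bad <- setdiff(letters, names(.IUPAC_SETS))
  if (length(bad))
    stop("unsupported IUPAC code(s) in repeat unit: ",
         paste(unique(bad), collapse = ", "))
  letters
}

.logPatternDiversity <- function(unit)
  sum(log(lengths(.IUPAC_SETS[.unitLetters(unit)])))

#' Number of distinct sequences a degenerate pattern admits
#'
#' Closed-form diversity of a repeated IUPAC unit: the product of the
#' per-position degeneracies, raised to the number of repeats. For the
#' default unit \code{"NNSWSNNWSW"} a single repeat admits
#' 4^4 * 2^3 * 2^3 = 16384 sequences.
#'
#' @param unit IUPAC repeat unit (codes A/C/G/T/S/W/N).
#' @param nRepeats number of repeats (default 1).
#' @return numeric count (may be \code{Inf} past double range).
#' @examples
#' patternDiversity("NNSWSNNWSW")
#' @export
patternDiversity <- function(unit, nRepeats = 1L) {
  prod(lengths(.IUPAC_SETS[.unitLetters(unit)]))^nRepeats
}

#' Validate sequences against a repeated degenerate pattern
#'
#' A sequence is pattern-valid iff its length equals
#' \code{nRepeats * nchar(unit)}, it contains only A/C/G/T (a literal
#' \code{N} base always fails), and every position belongs to the
#' degeneracy class of the corresponding unit position (S = G/C,
#' W = A/T, N = any base).
#'
#' @param seqs character vector or \code{DNAStringSet} of candidate
#'   barcodes.
#' @param unit IUPAC repeat unit.
#' @param nRepeats number of repeats the full barcode must contain.
#' @return logical vector, one element per input sequence.
#' @examples
#' validPattern(strrep("AAGTCAATGA", 6))         # TRUE
#' validPattern(strrep("AAATCAATGA", 6))         # FALSE: pos 3 not S
#' @export
validPattern <- function(seqs, unit = "NNSWSNNWSW", nRepeats = 6L) {
  seqs <- as.character(seqs)
  letters <- rep(.unitLetters(unit), nRepeats)
  ok <- !is.na(seqs) & nchar(seqs) == length(letters)
  if (!any(ok)) return(ok)
  m <- matrix(utf8ToInt(paste(seqs[ok], collapse = "")),
              nrow = length(letters))
  valid <- rep(TRUE, ncol(m))
  for (j in seq_along(letters)) {
    codes <- utf8ToInt(paste(.IUPAC_SETS[[letters[j]]], collapse = ""))
    valid <- valid & (m[j, ] %in% codes)
  }
  ok[ok] <- valid
  ok
}

#' Generate a reference library of degenerate barcodes
#'
#' Draws \code{librarySize} distinct barcodes matching the design's
#' repeated pattern, by sampling each position uniformly from its
#' degeneracy class and resampling collisions. Deterministic for a given
#' seed.
#'
#' @param design a \code{\link{LibraryDesign}}.
#' @param seed integer seed.
#' @return named \code{DNAStringSet} (names \code{BC_000001}, ...) of
#'   \code{librarySize} distinct pattern-valid barcodes.
#' @examples
#' ref <- generateReferenceLibrary(LibraryDesign(librarySize = 10L), seed = 1)
#' @export
generateReferenceLibrary <- function(design = LibraryDesign(), seed) {
  stopifnot(is(design, "LibraryDesign"))
  validObject(design)
  set.seed(seed)
  letters <- rep(.unitLetters(design@repeatUnit), design@nRepeats)
  n <- design@librarySize

  draw <- function(k) {
    cols <- lapply(letters, function(l)
      sample(.IUPAC_SETS[[l]], k, replace = TRUE))
    do.call(paste0, cols)
  }
  seqs <- unique(draw(n))
  while (length(seqs) < n)
    seqs <- unique(c(seqs, draw(n - length(seqs))))
  seqs <- seqs[seq_len(n)]
  names(seqs) <- sprintf("BC_%06d", seq_len(n))
  Biostrings::DNAStringSet(seqs)
}

#' Write / read a barcode reference library as TSV
#'
#' Two-column tab-separated format: \code{id}, \code{sequence}.
#'
#' @param reference named \code{DNAStringSet}.
#' @param path file path.
#' @return \code{readReferenceLibrary} returns a named
#'   \code{DNAStringSet}.
#' @export
writeReferenceLibrary <- function(reference, path) {
  write.table(
    data.frame(id = names(reference), sequence = as.character(reference)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeReferenceLibrary
#' @export
readReferenceLibrary <- function(path) {
  tab <- read.delim(path, colClasses = "character")
  if (!all(c("id", "sequence") %in% names(tab)))
    stop("reference TSV needs columns 'id' and 'sequence'")
  Biostrings::DNAStringSet(setNames(tab$sequence, tab$id))
}
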