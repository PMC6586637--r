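## sgRNA counting from a vector constant region, and guide depletion
## scoring for a sorted-population screen.

#' Count sgRNA sequences downstream of the vector constant region
#'
#' Greps each read for the first exact occurrence of the vector sequence
#' immediately 5' of the sgRNA and counts the fixed-length guide that
#' follows it. Reads without the constant region, or with fewer than
#' \code{guideLength} bases after it, are dropped.
#'
#' @param reads a \code{QualityScaledDNAStringSet} or
#'   \code{DNAStringSet}.
#' @param guides optional named character vector / \code{DNAStringSet}
#'   of library guides; when given, counts are returned for every
#'   library guide (zeros included) and off-library extractions are
#'   dropped.
#' @param vectorConstant constant region 5' of the guide.
#' @param guideLength guide length in bases.
#' @return named integer vector of counts.
#' @export
countGuides <- function(reads, guides = NULL,
                        vectorConstant = .SGRNA_CONSTANT,
                        guideLength = 20L) {
  seqChar <- as.character(reads)
  matchEnd <- .firstMatchEnd(seqChar, vectorConstant)
  ok <- !is.na(matchEnd) & matchEnd + guideLength <= nchar(seqChar)
  g <- substr(seqChar[ok], matchEnd[ok] + 1L, matchEnd[ok] + guideLength)
  if (is.null(guides)) {
    tab <- table(g)
    return(setNames(as.integer(tab), names(tab)))
  }
  gseq <- setNames(as.character(guides), names(guides))
  if (is.null(names(gseq))) names(gseq) <- gseq
  hit <- names(gseq)[match(g, gseq)]
  tab <- table(factor(hit, levels = names(gseq)))
  setNames(as.integer(tab), names(gseq))
}

#' Guide depletion scores relative to a library control
#'
#' For each guide and each sorted population, the depletion score is
#' \code{log2((control proportion + pc) / (population proportion + pc))},
#' so guides under-represented in the sorted population relative to the
#' library control score positive.
#'
#' @param counts guides-by-samples matrix of integer counts (or a named
#'   list of per-sample count vectors over the same guides).
#' @param control column name of the library control sample.
#' @param pc pseudocount added to both proportions.
#' @return guides-by-populations matrix of depletion scores (control
#'   column excluded).
#' @examples
#' m <- cbind(library = c(g1 = 40, g2 = 10), sorted = c(g1 = 10, g2 = 40))
#' guideDepletion(m, control = "library", pc = 0)
#' @export
guideDepletion <- function(counts, control = "library", pc = 0.5) {
  if (is.list(counts)) counts <- do.call(cbind, counts)
  if (!control %in% colnames(counts))
    stop("control sample '", control, "' not found")
  prop <- sweep(counts, 2L, colSums(counts), "/")
  ctrl <- prop[, control]
  pops <- setdiff(colnames(counts), control)
  score <- vapply(pops, function(s) log2((ctrl + pc) / (prop[, s] + pc)),
                  numeric(nrow(counts)))
  matrix(score, nrow = nrow(counts),
         dimnames = list(rownames(counts), pops))
}
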