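## Shared helpers: tiny in-code fixtures for reads, truth objects and
## coverage tracks.

CONSTANT <- "CGGATCCTGACCATGTACGATTGACTA"

## a pattern-valid 60-mer (unit AAGTCAATGA: pos 3,5,9 in {G,C}; 4,8,10
## in {A,T})
VALID_UNIT <- "AAGTCAATGA"
VALID_BARCODE <- strrep(VALID_UNIT, 6)

## build a QualityScaledDNAStringSet from sequences and one quality char
makeReads <- function(seqs, qualChar = "I", quals = NULL) {
  if (is.null(quals)) quals <- strrep(qualChar, nchar(seqs))
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(seqs, sprintf("r%d", seq_along(seqs)))),
    Biostrings::PhredQuality(quals))
}

## minimal CloneGroundTruth: abundance matrix + flags
makeTruth <- function(ab, clonogenic, resistant,
                      arm = rep("IBET", ncol(ab)),
                      plating = seq_len(ncol(ab)),
                      dose = rep(0, ncol(ab))) {
  colnames(ab) <- paste0(arm, "_p", plating)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = ab),
    rowData = S4Vectors::DataFrame(clonogenic = clonogenic,
                                   resistant = resistant,
                                   row.names = rownames(ab)),
    colData = S4Vectors::DataFrame(arm = arm, plating = plating,
                                   dose = dose,
                                   row.names = colnames(ab)))
  new("CloneGroundTruth", se)
}

## constant-value coverage track on one contig
makeUniformTrack <- function(value, contigLength = 10000L, binSize = 50L,
                             condition = "uniform", contig = "chrT") {
  starts <- seq(1L, contigLength, binSize)
  bins <- GenomicRanges::GRanges(
    contig, IRanges::IRanges(starts, width = binSize))
  bins$score <- rep(value, length(bins))
  CoverageTrack(bins, condition = condition)
}

## independent closed-form oracle for the cumulative top-fraction set:
## group rule: b is retained iff the reads of strictly larger counts do
## not already reach the target; lexical rule: same with the strict
## (-count, id) rank order.
oracleCumulativeSet <- function(counts, fraction, tieRule = "group") {
  counts <- counts[counts > 0]
  total <- sum(counts)
  target <- fraction * total - 1e-9 * total
  keep <- vapply(seq_along(counts), function(i) {
    before <- if (tieRule == "group") counts[counts > counts[i]]
      else counts[order(-counts, names(counts))][
        seq_len(which(order(-counts, names(counts)) == i) - 1L)]
    sum(before) < target
  }, logical(1))
  names(counts)[keep]
}

## one concordant duplicate-pair record set for a single variant
pairRecord <- function(sample = "S01", pos = 1000L, depth = 100L,
                       alt = 10L, vaf = alt / depth, popAf = 0) {
  do.call(rbind, lapply(c("R1", "R2"), function(r)
    data.frame(sample = sample, replicate = r, contig = "chr17",
               pos = pos, ref = "C", alt = "T", depth = depth,
               alt_reads = alt, vaf = vaf, population_af = popAf,
               annotation = ".")))
}
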