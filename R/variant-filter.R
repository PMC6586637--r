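#' Filter a cohort variant table with the targeted-amplicon rules
#'
#' Three stages, mirroring a deep-amplicon resequencing workflow:
#' \enumerate{
#'   \item per-record retention: depth >= \code{minDepth}, supporting
#'     reads >= \code{minAltReads}, and VAF strictly greater than
#'     \code{minVaf} (a VAF of exactly 1\% is rejected);
#'   \item duplicate concordance (PCR-artifact control): a variant is
#'     kept only when it passes stage 1 in every replicate of its
#'     sample; replicates are then merged (summed depth and supporting
#'     reads, mean VAF);
#'   \item cohort exclusions on merged records: variants carried by
#'     strictly more than \code{recurrenceFraction} of the distinct
#'     samples (likely sequencing/PCR artifacts), or with population
#'     allele frequency strictly above \code{maxPopulationAf}, are
#'     removed. A missing population AF counts as 0.
#' }
#' Each rejected record is flagged with the first failing rule.
#'
#' @param records data.frame with columns \code{sample},
#'   \code{replicate}, \code{contig}, \code{pos}, \code{ref},
#'   \code{alt}, \code{depth}, \code{alt_reads}, \code{vaf},
#'   \code{population_af} (optional), \code{annotation} (optional).
#' @param config a \code{\link{VariantFilterConfig}}.
#' @return list with \code{retained} (merged per-sample records),
#'   \code{rejected} (records with a \code{reason} column) and
#'   \code{summary} (named counts).
#' @examples
#' fx <- generateVariantFixture(seed = 1)
#' res <- filterVariants(fx$variants)
#' res$summary
#' @export
filterVariants <- function(records, config = VariantFilterConfig()) {
  stopifnot(is(config, "VariantFilterConfig"))
  need <- c("sample", "replicate", "contig", "pos", "ref", "alt",
            "depth", "alt_reads", "vaf")
  if (!all(need %in% names(records)))
    stop("variant table needs columns ", paste(need, collapse = ", "))
  if (any(records$alt_reads > records$depth))
    stop("alt_reads exceeds depth in some records")
  if (is.null(records$population_af)) records$population_af <- 0
  records$population_af[is.na(records$population_af)] <- 0
  if (is.null(records$annotation)) records$annotation <- "."

  key <- sprintf("%s:%d:%s>%s", records$contig, records$pos,
                 records$ref, records$alt)
  records$.key <- key
  cohortSamples <- unique(records$sample)

  ## stage 1: per-record rules, first failing rule recorded
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(reason) & records$depth < config@minDepth] <- "depth"
  reason[is.na(reason) & records$alt_reads < config@minAltReads] <-
    "alt_reads"
  reason[is.na(reason) & !(records$vaf > config@minVaf)] <- "vaf"
  pass1 <- is.na(reason)

  ## stage 2: duplicate concordance, then replicate merge
  sk <- paste(records$sample, key, sep = "|")
  if (config@requireDuplicateConcordance) {
    nRep <- tapply(records$replicate, records$sample,
                   function(r) length(unique(r)))
    solo <- names(nRep)[nRep < 2L]
    if (length(solo))
      stop("duplicate concordance requires >= 2 replicates; single-",
           "replicate sample(s): ", paste(solo, collapse = ", "))
    passCount <- tapply(pass1, sk, sum)
    seen <- tapply(rep(TRUE, length(sk)), sk, length)
    concordant <- names(passCount)[
      passCount == nRep[sub("\\|.*", "", names(passCount))] &
      seen == passCount]
    discord <- pass1 & !(sk %in% concordant)
    reason[discord] <- "discordant_replicate"
    pass1 <- is.na(reason)
  }

  keep <- records[pass1, , drop = FALSE]
  merged <- if (nrow(keep)) {
    sp <- split(keep, paste(keep$sample, keep$.key, sep = "|"))
    do.call(rbind, lapply(sp, function(g) data.frame(
      sample = g$sample[1L], contig = g$contig[1L], pos = g$pos[1L],
      ref = g$ref[1L], alt = g$alt[1L], depth = sum(g$depth),
      alt_reads = sum(g$alt_reads), vaf = mean(g$vaf),
      population_af = g$population_af[1L],
      annotation = g$annotation[1L], nReplicates = nrow(g),
      .key = g$.key[1L])))
  } else keep[, c(need[-2L], "population_af", "annotation", ".key")]

  ## stage 3: cohort exclusions on merged samples
  mReason <- rep(NA_character_, nrow(merged))
  if (nrow(merged)) {
    nCarrier <- tapply(merged$sample, merged$.key,
                       function(s) length(unique(s)))
    recur <- names(nCarrier)[
      nCarrier / length(cohortSamples) > config@recurrenceFraction]
    mReason[merged$.key %in% recur] <- "recurrent"
    mReason[is.na(mReason) &
              merged$population_af > config@maxPopulationAf] <-
      "population_af"
  }

  retained <- merged[is.na(mReason), , drop = FALSE]
  rejectedMerged <- merged[!is.na(mReason), , drop = FALSE]
  rejectedMerged$reason <- mReason[!is.na(mReason)]
  rejectedRecords <- records[!pass1, , drop = FALSE]
  rejectedRecords$reason <- reason[!pass1]

  cols <- c("sample", "contig", "pos", "ref", "alt", "reason")
  rejected <- rbind(rejectedRecords[, cols], rejectedMerged[, cols])
  rownames(retained) <- rownames(rejected) <- NULL
  retained$.key <- NULL

  list(retained = retained, rejected = rejected,
       summary = c(input_records = nrow(records),
                   retained_sample_variants = nrow(retained),
                   retained_distinct_variants =
                     length(unique(paste(retained$contig, retained$pos,
                                         retained$ref, retained$alt))),
                   table(factor(rejected$reason,
                                levels = c("depth", "alt_reads", "vaf",
                                           "discordant_replicate",
                                           "recurrent",
                                           "population_af")))))
}

#' Read / write a cohort variant TSV
#'
#' @param path TSV path with the columns of
#'   \code{\link{filterVariants}}.
#' @return \code{readVariantTable} returns a data.frame.
#' @export
readVariantTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "replicate", "contig", "pos", "ref", "alt",
            "depth", "alt_reads", "vaf")
  if (!all(need %in% names(tab)))
    stop("variant table needs columns ", paste(need, collapse = ", "))
  tab
}

#' @param records variant data.frame.
#' @rdname readVariantTable
#' @export
writeVariantTable <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
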