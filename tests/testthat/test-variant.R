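## pad the cohort with an unrelated sample carrying a private variant,
## so the >50% recurrence rule sees a cohort larger than one
padCohort <- function(rec) rbind(rec, pairRecord("S99", pos = 999000L))

test_that("clean variants pass and each strict boundary rejects", {
  res <- filterVariants(padCohort(pairRecord()))
  got <- res$retained[res$retained$pos == 1000L, ]
  expect_equal(nrow(got), 1L)
  expect_equal(got$depth, 200L)     # replicates merged
  expect_equal(got$vaf, 0.1)

  ## VAF exactly 1% fails the strictly-greater rule
  vaf1 <- pairRecord(depth = 2000L, alt = 20L)
  resV <- filterVariants(padCohort(vaf1))
  expect_false(1000L %in% resV$retained$pos)
  expect_true(all(resV$rejected$reason[resV$rejected$pos == 1000L] ==
                    "vaf"))

  ## depth 19 and 4 supporting reads each fail their own rule
  byPos <- function(res) res$rejected$reason[res$rejected$pos == 1000L]
  expect_true(all(byPos(filterVariants(padCohort(
    pairRecord(depth = 19L, alt = 6L, vaf = 6 / 19)))) == "depth"))
  expect_true(all(byPos(filterVariants(padCohort(
    pairRecord(depth = 300L, alt = 4L)))) == "alt_reads"))

  ## population AF above 0.4% is excluded, at 0.4% it is kept
  expect_false(1000L %in% filterVariants(padCohort(
    pairRecord(popAf = 0.0041)))$retained$pos)
  expect_true(1000L %in% filterVariants(padCohort(
    pairRecord(popAf = 0.004)))$retained$pos)
})

test_that("recurrence is strict: over half the cohort excludes, exactly half keeps", {
  cohort <- function(nCarrier, nSamples = 10L) {
    carriers <- do.call(rbind, lapply(sprintf("S%02d", seq_len(nCarrier)),
                                      function(s) pairRecord(s)))
    ## remaining samples carry an unrelated private variant so the
    ## cohort size is visible to the filter
    others <- do.call(rbind, lapply(
      sprintf("S%02d", seq(nCarrier + 1L, nSamples)),
      function(s) pairRecord(s, pos = 9000L)))
    rbind(carriers, others)
  }
  res6 <- filterVariants(cohort(6L))
  expect_false(1000L %in% res6$retained$pos)
  expect_true(any(res6$rejected$reason == "recurrent"))
  res5 <- filterVariants(cohort(5L))
  expect_true(1000L %in% res5$retained$pos)
})

test_that("duplicate concordance drops single-replicate detections", {
  rec <- pairRecord()
  discord <- rec[rec$replicate == "R1", ]
  discord$pos <- 2000L
  ## second replicate exists for the sample but lacks the variant
  tab <- padCohort(rbind(rec, discord))
  res <- filterVariants(tab)
  expect_true(1000L %in% res$retained$pos)
  expect_false(2000L %in% res$retained$pos)
  expect_true("discordant_replicate" %in% res$rejected$reason)
  ## with concordance off the solo detection is kept
  resOff <- filterVariants(tab, VariantFilterConfig(
    requireDuplicateConcordance = FALSE))
  expect_setequal(resOff$retained$pos, c(1000L, 2000L, 999000L))
  ## a sample sequenced without a duplicate is an error
  solo <- pairRecord()[1, ]
  expect_error(filterVariants(solo), "single-replicate")
})

test_that("the filter recovers exactly the planted true variants", {
  fx <- generateVariantFixture(nSamples = 12L, nTrue = 6L, seed = 31)
  res <- filterVariants(fx$variants)
  gotKeys <- unique(sprintf("%s:%d:%s>%s", res$retained$contig,
                            res$retained$pos, res$retained$ref,
                            res$retained$alt))
  expect_setequal(gotKeys, fx$truth$key[fx$truth$isTrue])
  ## every planted artifact class is rejected for its own reason
  expect_true(all(c("depth", "alt_reads", "vaf", "discordant_replicate",
                    "recurrent", "population_af") %in%
                    res$rejected$reason))
})

test_that("filter results are invariant to row order and monotone in thresholds", {
  fx <- generateVariantFixture(nSamples = 8L, nTrue = 5L, seed = 17)
  res <- filterVariants(fx$variants)
  set.seed(1)
  shuffled <- fx$variants[sample(nrow(fx$variants)), ]
  resS <- filterVariants(shuffled)
  key <- function(r) sort(sprintf("%s|%s:%d", r$sample, r$contig, r$pos))
  expect_identical(key(resS$retained), key(res$retained))

  ## tightening any threshold never grows the retained set
  base <- VariantFilterConfig()
  tighter <- list(VariantFilterConfig(minDepth = 50L),
                  VariantFilterConfig(minAltReads = 20L),
                  VariantFilterConfig(minVaf = 0.05),
                  VariantFilterConfig(recurrenceFraction = 0.2),
                  VariantFilterConfig(maxPopulationAf = 0))
  for (cfg in tighter) {
    r2 <- filterVariants(fx$variants, cfg)
    expect_true(all(key(r2$retained) %in% key(res$retained)))
  }
})

test_that("variant tables round-trip through TSV", {
  fx <- generateVariantFixture(nSamples = 4L, nTrue = 2L, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeVariantTable(fx$variants, path)
  back <- readVariantTable(path)
  expect_equal(back$vaf, fx$variants$vaf)
  expect_identical(back$sample, fx$variants$sample)
  expect_error(readVariantTable(
    writeVariantTable(fx$variants[, 1:4], path)), "needs columns")
})
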