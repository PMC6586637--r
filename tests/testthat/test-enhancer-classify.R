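cfgRaw <- EnhancerConfig(normalize = FALSE)

test_that("responsive genes require strict down-regulation and significance", {
  de <- data.frame(
    gene = c("down_sig", "down_nonsig", "up_sig", "weak_down"),
    log2fc = c(-log2(1.6), -log2(1.6), log2(2), -log2(1.2)),
    p = c(0.005, 0.02, 0.001, 0.001),
    fdr = c(0.02, 0.2, 0.01, 0.01))
  expect_identical(ibetResponsiveGenes(de), "down_sig")
  ## the significance field is selectable; fdr 0.02 fails the 0.01 cut
  expect_identical(ibetResponsiveGenes(de, EnhancerConfig(sigField = "fdr")),
                   character())
  ## exactly 1.5-fold is not "greater than 1.5-fold"
  boundary <- data.frame(gene = "b", log2fc = -log2(1.5), p = 1e-5)
  expect_identical(ibetResponsiveGenes(boundary), character())
  expect_error(ibetResponsiveGenes(de[, 1:2, drop = FALSE]),
               "significance column")
})

test_that("coverage fold changes follow the pseudocount arithmetic", {
  t10 <- makeUniformTrack(10, condition = "before")
  t50 <- makeUniformTrack(50, condition = "after")
  iv <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1001, 2000))
  ## identical tracks give fold 1 whatever the config
  expect_equal(coverageFoldChange(iv, t10, t10, EnhancerConfig()), 1)
  expect_equal(coverageFoldChange(iv, t50, t50, cfgRaw), 1)
  ## raw means 50 vs 10 with pseudocount 1: 51/11
  expect_equal(coverageFoldChange(iv, t50, t10, cfgRaw), 51 / 11)
  ## reciprocal symmetry at pseudocount 0
  cfg0 <- EnhancerConfig(pseudocount = 0, normalize = FALSE)
  expect_equal(coverageFoldChange(iv, t50, t10, cfg0) *
                 coverageFoldChange(iv, t10, t50, cfg0), 1)
  outside <- GenomicRanges::GRanges("chrT", IRanges::IRanges(9990, 10500))
  expect_error(coverageFoldChange(outside, t50, t10), "outside")
})

test_that("the classifier recovers every planted class exactly", {
  fx <- generateGenomicFixture(nGenes = 12, nPeaksPerClass = 4,
                               plantedFold = 8, seed = 7)
  calls <- classifyEnhancers(fx$peaks, fx$tracks, fx$genes, fx$deTable,
                             preExistingPeaks = fx$beforePeaks)
  expect_identical(calls$class,
                   fx$plantedTruth$class[match(calls$name,
                                               fx$plantedTruth$name)])
  ## per-class precision and recall are both 1
  for (cl in unique(fx$plantedTruth$class)) {
    called <- calls$name[calls$class == cl]
    planted <- fx$plantedTruth$name[fx$plantedTruth$class == cl]
    expect_setequal(called, planted)
  }
  ## planted fold holds in the emitted tracks
  newPeaks <- fx$peaks[fx$peaks$plantedClass == "new"]
  raw <- coverageFoldChange(newPeaks, fx$tracks$k27acAfter,
                            fx$tracks$k27acBefore,
                            EnhancerConfig(pseudocount = 0,
                                           normalize = FALSE))
  expect_true(all(raw >= 8 - 1e-9))
})

test_that("gene linking agrees with a brute-force all-pairs distance scan", {
  fx <- generateGenomicFixture(nGenes = 10, nPeaksPerClass = 3, seed = 3)
  cfg <- EnhancerConfig()
  calls <- classifyEnhancers(fx$peaks, fx$tracks, fx$genes, fx$deTable,
                             preExistingPeaks = fx$beforePeaks,
                             config = cfg)
  responsive <- ibetResponsiveGenes(fx$deTable, cfg)
  tss <- GenomicRanges::start(fx$genes[responsive])
  for (i in seq_along(calls)) {
    wanted <- names(fx$genes[responsive])[
      abs(tss - calls$summit[i]) <= cfg@tssWindow]
    expect_setequal(calls$linkedGenes[[i]], wanted)
    ## signed distances are TSS minus summit
    expect_setequal(calls$linkedDistances[[i]],
                    (tss - calls$summit[i])[
                      abs(tss - calls$summit[i]) <= cfg@tssWindow])
  }
  ## desert peaks link to nothing
  expect_true(all(lengths(
    calls$linkedGenes[calls$plantedClass == "unlinked"]) == 0))
})

test_that("calls shrink monotonically in threshold and grow with the window", {
  fx <- generateGenomicFixture(nGenes = 10, nPeaksPerClass = 3,
                               plantedFold = 6, seed = 11)
  call4 <- classifyEnhancers(fx$peaks, fx$tracks, fx$genes, fx$deTable,
                             preExistingPeaks = fx$beforePeaks,
                             config = EnhancerConfig(foldThreshold = 4))
  call8 <- classifyEnhancers(fx$peaks, fx$tracks, fx$genes, fx$deTable,
                             preExistingPeaks = fx$beforePeaks,
                             config = EnhancerConfig(foldThreshold = 8))
  for (flag in c("isNew", "isNewPu1", "isNewPu1Active"))
    expect_true(all(!S4Vectors::mcols(call8)[[flag]] |
                      S4Vectors::mcols(call4)[[flag]]))

  narrow <- classifyEnhancers(fx$peaks, fx$tracks, fx$genes, fx$deTable,
                              config = EnhancerConfig(tssWindow = 20000L))
  wide <- classifyEnhancers(fx$peaks, fx$tracks, fx$genes, fx$deTable,
                            config = EnhancerConfig(tssWindow = 60000L))
  for (i in seq_along(narrow))
    expect_true(all(narrow$linkedGenes[[i]] %in% wide$linkedGenes[[i]]))
})

test_that("missing tracks or TSSs are errors", {
  fx <- generateGenomicFixture(nGenes = 6, nPeaksPerClass = 2, seed = 5)
  expect_error(classifyEnhancers(fx$peaks, fx$tracks["k27acBefore"],
                                 fx$genes, fx$deTable),
               "k27acBefore and k27acAfter")
  expect_error(classifyEnhancers(fx$peaks, fx$tracks, fx$genes[-1],
                                 fx$deTable), "no TSS")
})
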