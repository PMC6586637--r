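test_that("tallies, proportions and rejection accounting are conserved", {
  ref <- Biostrings::DNAStringSet(setNames(c("AAAA", "CCCC", "GGGG"),
                                           c("A", "B", "C")))
  assignments <- list(
    s1 = c("A", "A", "A", "B"),
    s2 = c(NA, NA, NA))  # zero mapped reads
  tab <- countBarcodes(assignments, ref)
  cnt <- barcodeCounts(tab)
  expect_identical(cnt[, "s1"], c(A = 3L, B = 1L, C = 0L))
  expect_equal(cnt[, "s1"] / sum(cnt[, "s1"]),
               c(A = 0.75, B = 0.25, C = 0))
  expect_true(all(cnt[, "s2"] == 0L))
  rej <- rejectionSummary(tab)
  expect_identical(rej["unmapped", "s2"], 3L)
  ## conservation: assigned + rejected = input reads per sample
  expect_equal(colSums(cnt) + colSums(rej),
               c(s1 = 4, s2 = 3))
  expect_error(countBarcodes(list(c("A", "B")), ref), "sample name")
})

test_that("cumulative top-fraction sets take the minimal covering prefix", {
  expect_identical(cumulativeFractionSet(c(A = 50, B = 30, C = 15, D = 5),
                                         0.9),
                   c("A", "B", "C"))
  expect_identical(cumulativeFractionSet(c(A = 10), 0.9), "A")
  ## fraction 1 keeps every positive barcode, zeros never enter
  expect_setequal(cumulativeFractionSet(c(A = 5, B = 1, C = 0), 1),
                  c("A", "B"))
  expect_error(cumulativeFractionSet(c(A = 0, B = 0), 0.9), "positive")
  expect_error(cumulativeFractionSet(c(A = 5), 1.5), "fraction")
})

test_that("boundary ties are grouped by default and split lexically on request", {
  tied <- c(D = 10, C = 10, B = 10, A = 10)
  ## group rule: the cut falls inside the tie, the whole group is kept
  expect_setequal(cumulativeFractionSet(tied, 0.5, tieRule = "group"),
                  c("A", "B", "C", "D"))
  expect_identical(cumulativeFractionSet(tied, 0.5, tieRule = "lexical"),
                   c("A", "B"))
  ## relabeling invariance of the group rule
  relabeled <- setNames(tied, c("A", "B", "C", "D"))
  expect_length(cumulativeFractionSet(relabeled, 0.5, "group"), 4L)
})

test_that("baseline representation is a strict above-threshold filter", {
  base <- c(A = 25, B = 20, C = 100)
  expect_identical(
    baselineRepresentationFilter(c("A", "B", "C"), base, 20L),
    c("A", "C"))
  ## absent from baseline counts as zero
  expect_identical(
    baselineRepresentationFilter(c("A", "Z"), base, 20L), "A")
  expect_identical(
    baselineRepresentationFilter(c("A", "B", "C"), base, 0L),
    c("A", "B", "C"))
  expect_identical(baselineRepresentationFilter(character(), base, 20L),
                   character())
  expect_error(baselineRepresentationFilter("A", unname(base), 20L),
               "named")
})

test_that("sequential retention chains nested intersections", {
  r <- sequentialRetention(list(c("A", "B", "C"), c("A", "B", "D"),
                                c("A", "D")))
  sets <- retainedSets(r)
  expect_identical(as.list(sets),
                   list(c("A", "B", "C"), c("A", "B"), "A"))
  expect_identical(unname(retainedCounts(r)), c(3L, 2L, 1L))
  expect_equal(resistantFraction(r), 1 / 3)

  same <- sequentialRetention(rep(list(c("X", "Y")), 4))
  expect_true(all(retainedCounts(same) == 2L))
  expect_equal(resistantFraction(same), 1)

  empty <- sequentialRetention(list(character(), c("A")))
  expect_true(is.na(resistantFraction(empty)))
  expect_error(sequentialRetention(list()), "at least one")
})
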