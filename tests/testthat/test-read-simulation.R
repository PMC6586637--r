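test_that("error-free reads carry the exact constant region and a library barcode", {
  design <- LibraryDesign(librarySize = 20L)
  ref <- generateReferenceLibrary(design, seed = 2)
  ab <- matrix(c(5, 3, 2, 0, 0, 4, 6, 0), nrow = 4,
               dimnames = list(names(ref)[1:4], NULL))
  truth <- makeTruth(ab, clonogenic = rep(TRUE, 4),
                     resistant = rep(TRUE, 4), arm = c("IBET", "IBET"),
                     plating = 1:2, dose = c(400, 600))
  dir <- withr::local_tempdir()
  sheet <- emitBarcodeReads(truth, ref, design, dir = dir,
                            readsPerSample = 500, errorRate = 0,
                            qualityModel = list(meanQ = 40, sdQ = 0),
                            seed = 9)
  reads <- readFastq(sheet$fastq[1])
  expect_length(reads, 500L)  # conservation under multinomial sampling
  seqs <- as.character(reads)
  expect_true(all(grepl(CONSTANT, seqs, fixed = TRUE)))
  at <- regexpr(CONSTANT, seqs, fixed = TRUE)
  bc <- substr(seqs, at + nchar(CONSTANT), at + nchar(CONSTANT) + 59)
  expect_true(all(bc %in% as.character(ref)))
  ## only clones with positive abundance in that sample are represented
  expect_true(all(bc %in% as.character(ref[c("BC_000001", "BC_000002",
                                             "BC_000003")])))
})

test_that("read counts follow the abundance ratios in expectation", {
  design <- LibraryDesign(librarySize = 2L)
  ref <- generateReferenceLibrary(design, seed = 4)
  ab <- matrix(c(3, 1), nrow = 2, dimnames = list(names(ref), NULL))
  truth <- makeTruth(ab, clonogenic = c(TRUE, TRUE),
                     resistant = c(TRUE, TRUE))
  dir <- withr::local_tempdir()
  sheet <- emitBarcodeReads(truth, ref, design, dir = dir,
                            readsPerSample = 40000, errorRate = 0,
                            qualityModel = list(meanQ = 40, sdQ = 0),
                            seed = 10)
  reads <- readFastq(sheet$fastq[1])
  bc <- substr(as.character(reads),
               regexpr(CONSTANT, as.character(reads), fixed = TRUE) +
                 nchar(CONSTANT), nchar(as.character(reads)))
  n1 <- sum(startsWith(bc, as.character(ref[[1]])))
  ## multinomial expectation 3:1, generous sampling tolerance
  expect_equal(n1 / length(reads), 0.75, tolerance = 0.02)
  ## deterministic mode hits the expectation exactly
  sheet2 <- emitBarcodeReads(truth, ref, design, dir = dir,
                             readsPerSample = 40000, errorRate = 0,
                             qualityModel = list(meanQ = 40, sdQ = 0),
                             sampling = "expected", seed = 10)
  expect_length(readFastq(sheet2$fastq[1]), 40000L)
})

test_that("emitted FASTQ round-trips with identical sequences and qualities", {
  design <- LibraryDesign(librarySize = 5L)
  ref <- generateReferenceLibrary(design, seed = 6)
  ab <- matrix(rep(1, 5), nrow = 5, dimnames = list(names(ref), NULL))
  truth <- makeTruth(ab, clonogenic = rep(TRUE, 5),
                     resistant = rep(TRUE, 5))
  dir <- withr::local_tempdir()
  sheet <- emitBarcodeReads(truth, ref, design, dir = dir,
                            readsPerSample = 100, errorRate = 0.01,
                            qualityModel = list(meanQ = 35, sdQ = 4),
                            compress = TRUE, seed = 3)
  expect_match(sheet$fastq[1], "\\.gz$")
  reads <- readFastq(sheet$fastq[1])
  path2 <- withr::local_tempfile(fileext = ".fastq")
  writeFastq(reads, path2)
  back <- readFastq(path2)
  expect_identical(as.character(back), as.character(reads))
  expect_identical(as.character(Biostrings::quality(back)),
                   as.character(Biostrings::quality(reads)))
})

test_that("truth clones missing from the reference are an error", {
  design <- LibraryDesign(librarySize = 3L)
  ref <- generateReferenceLibrary(design, seed = 8)
  ab <- matrix(1, 1, 1, dimnames = list("BC_UNKNOWN", NULL))
  truth <- makeTruth(ab, clonogenic = TRUE, resistant = TRUE)
  expect_error(
    emitBarcodeReads(truth, ref, design, dir = withr::local_tempdir(),
                     readsPerSample = 10, seed = 1),
    "absent from the reference")
})
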