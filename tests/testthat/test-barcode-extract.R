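test_that("barcodes are the 60 bases 3' of the constant region", {
  reads <- makeReads(c(
    paste0("ACGT", CONSTANT, VALID_BARCODE, "TT"),   # ok, staggered
    paste0("TTTTTTTTTT", strrep("ACGT", 20)),        # no constant region
    paste0(CONSTANT, substr(VALID_BARCODE, 1, 59))), # 59 bases: truncated
    qualChar = "I")
  ext <- extractBarcodes(reads, FilterConfig())
  expect_identical(ext$status,
                   c("ok", "no_constant_region", "truncated"))
  expect_identical(ext$barcode[1], VALID_BARCODE)
  expect_true(is.na(ext$barcode[2]) && is.na(ext$barcode[3]))
})

test_that("pattern violations and N residues are rejected after extraction", {
  badPattern <- strrep("AAATCAATGA", 6)  # pos 3 violates S
  withN <- paste0("NAGTCAATGA", strrep("AAGTCAATGA", 5))
  reads <- makeReads(c(paste0(CONSTANT, VALID_BARCODE),
                       paste0(CONSTANT, badPattern),
                       paste0(CONSTANT, withN)), qualChar = "I")
  ext <- extractBarcodes(reads)
  expect_identical(ext$status, c("ok", "pattern_mismatch",
                                 "pattern_mismatch"))
})

test_that("mean barcode quality is averaged over barcode bases only, inclusive", {
  ## barcode bases alternate Q20/Q40 (mean exactly 30); the leading
  ## read bases are terrible and must not count
  q2040 <- strrep(paste0(rawToChar(as.raw(33 + 20)),
                         rawToChar(as.raw(33 + 40))), 30)
  lowPrefix <- strrep(rawToChar(as.raw(33 + 2)), nchar(CONSTANT))
  reads <- makeReads(paste0(CONSTANT, VALID_BARCODE),
                     quals = paste0(lowPrefix, q2040))
  ext <- extractBarcodes(reads, FilterConfig(meanQualityMin = 30))
  expect_identical(ext$status, "ok")
  expect_equal(ext$meanQuality, 30)
  ## all-29 fails a threshold of 30
  q29 <- strrep(rawToChar(as.raw(33 + 29)), 60)
  reads29 <- makeReads(paste0(CONSTANT, VALID_BARCODE),
                       quals = paste0(lowPrefix, q29))
  expect_identical(extractBarcodes(reads29)$status, "low_quality")

  expect_true(meanQualityPass(rep(40, 60), 30))
  expect_true(meanQualityPass(rep(c(20, 40), 30), 30))
  expect_false(meanQualityPass(rep(29, 60), 30))
  expect_error(meanQualityPass(numeric(), 30), "empty")
})

test_that("reverse-complement search is off by default and opt-in", {
  fwd <- paste0("AA", CONSTANT, VALID_BARCODE, "CC")
  rcRead <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(fwd)))
  reads <- makeReads(rcRead, qualChar = "I")
  expect_identical(extractBarcodes(reads)$status, "no_constant_region")
  ext <- extractBarcodes(reads, FilterConfig(searchRevcomp = TRUE))
  expect_identical(ext$status, "ok")
  expect_identical(ext$barcode, VALID_BARCODE)
})

test_that("the three read filters commute: any order accepts the same reads", {
  set.seed(71)
  design <- LibraryDesign(librarySize = 30L)
  ref <- generateReferenceLibrary(design, seed = 30)
  n <- 200
  bc <- sample(as.character(ref), n, replace = TRUE)
  ## corrupt some barcodes and some qualities
  mutate <- sample(n, 50)
  substr(bc[mutate], 3, 3) <- "A"   # position 3 must be S: now invalid
  qual <- ifelse(seq_len(n) %% 3 == 0, strrep("(", 60), strrep("I", 60))
  reads <- makeReads(paste0(CONSTANT, bc),
                     quals = paste0(strrep("I", nchar(CONSTANT)), qual))
  ext <- extractBarcodes(reads)
  ## independent predicate evaluation, conjunction is order-free
  passPattern <- validPattern(bc)
  passQual <- vapply(strsplit(qual, ""), function(ch)
    mean(utf8ToInt(paste(ch, collapse = "")) - 33), numeric(1)) >= 30
  for (ord in list(c(1, 2), c(2, 1))) {
    acc <- rep(TRUE, n)
    for (f in ord) acc <- acc & list(passPattern, passQual)[[f]]
    expect_identical(ext$status == "ok", acc)
  }
})

test_that("exact mapping equals a brute-force linear scan and rejects near-misses", {
  design <- LibraryDesign(librarySize = 100L)
  ref <- generateReferenceLibrary(design, seed = 20)
  expect_identical(mapExact(as.character(ref[["BC_000042"]]), ref),
                   "BC_000042")
  ## Hamming distance 1 from a reference entry: unmapped
  near <- as.character(ref[["BC_000001"]])
  substr(near, 1, 1) <- setdiff(c("A", "C", "G", "T"),
                                substr(near, 1, 1))[1]
  expect_true(is.na(mapExact(near, ref)))

  set.seed(21)
  queries <- c(as.character(generateReferenceLibrary(
    LibraryDesign(librarySize = 5000L), seed = 22)),
    sample(as.character(ref), 5000, replace = TRUE))
  got <- mapExact(queries, ref)
  bruteForce <- vapply(queries, function(q) {
    hit <- which(vapply(as.character(ref), identical, TRUE, y = q))
    if (length(hit)) names(ref)[hit[1]] else NA_character_
  }, character(1), USE.NAMES = FALSE)
  expect_identical(got, bruteForce)

  dup <- Biostrings::DNAStringSet(setNames(c("ACGT", "ACGT"),
                                           c("a", "b")))
  expect_error(mapExact("ACGT", dup), "duplicate")
})
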