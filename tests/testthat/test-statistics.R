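test_that("substitution classifier agrees with exhaustive enumeration", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]          # 12 ordered pairs
  cls <- classifySubstitution(pairs$ref, pairs$alt)
  expect_equal(sum(cls == "transition"), 4L)
  expect_equal(sum(cls == "transversion"), 8L)
  # the four transitions are exactly the purine-purine/pyrimidine-pyrimidine
  expect_setequal(paste(pairs$ref, pairs$alt)[cls == "transition"],
                  c("A G", "G A", "C T", "T C"))
  expect_identical(classifySubstitution("C", "TT"), "not_snv")
  expect_identical(classifySubstitution("CA", "C"), "not_snv")
})

test_that("spectrum summary reproduces the published Ti/Tv rendering", {
  # 1676 transitions to 857 transversions truncates to 1.9
  ref <- c(rep("C", 1676), rep("C", 857))
  alt <- c(rep("T", 1676), rep("A", 857))
  s <- spectrumSummary(ref, alt)
  expect_equal(s@tiCount, 1676L)
  expect_equal(s@tvCount, 857L)
  expect_equal(s@ratio, 1676 / 857)
  expect_equal(s@ratioTruncated, 1.9)
  expect_equal(s@tiCount + s@tvCount, length(ref))

  # equal counts give 1.0; zero transversions are flagged
  expect_equal(spectrumSummary(c("C", "C"), c("T", "A"))@ratio, 1)
  z <- spectrumSummary(c("C", "T"), c("T", "C"))
  expect_true(z@tvZero)
  expect_true(is.nan(z@ratio))

  # purine-reference classes collapse onto the pyrimidine strand
  s2 <- spectrumSummary(c("G", "C", "A"), c("A", "T", "C"))
  expect_equal(unname(s2@sixClass[c("C>T", "T>G")]), c(2L, 1L))
  expect_equal(s2@gcTargetedFraction, 2 / 3)
})

test_that("mutation burden yields the published medians on a toy cohort", {
  calls <- data.frame(
    sample_id = rep(c("S1", "S2", "S3"), c(6, 135, 204)),
    effect = "missense")
  bu <- mutationBurden(calls, exomeMb = 54)
  expect_equal(bu$medianCount, 135)
  expect_equal(bu$rangeCount, c(6L, 204L))
  expect_equal(bu$medianRate, 2.5)
  # single sample: median is the count
  expect_equal(mutationBurden(data.frame(sample_id = rep("S1", 10),
                                         effect = "missense"),
                              54)$medianCount, 10)
  # synonymous calls are excluded; absent samples count zero
  calls2 <- data.frame(sample_id = c("S1", "S1", "S2"),
                       effect = c("missense", "synonymous", "stop_gain"))
  bu2 <- mutationBurden(calls2, 1, samples = c("S1", "S2", "S3"))
  expect_equal(bu2$perSample$count, c(1L, 1L, 0L))
  expect_error(mutationBurden(calls[0, ], 54), "empty cohort")
  expect_error(mutationBurden(calls, 0), "positive")
})

test_that("recurrence collapses multiple hits per sample to one", {
  calls <- data.frame(
    sample_id = c("S1", "S1", "S1", "S2", "S3"),
    gene = c("FAT1", "FAT1", "FAT1", "FAT1", "TET2"),
    effect = "missense")
  rec <- recurrenceMatrix(calls, samples = c("S1", "S2", "S3"))
  expect_equal(unname(rec@counts["FAT1"]), 2L)  # 3 variants, 1 sample
  expect_equal(unname(rec@counts["TET2"]), 1L)
  expect_true(all(rec@counts <= 3L))
  rg <- recurrentGenes(rec)
  expect_identical(rg$gene, "FAT1")
  # collapsing is idempotent: recurrence of the collapsed pairs is equal
  collapsed <- unique(calls[, c("sample_id", "gene")])
  rec2 <- recurrenceMatrix(collapsed, samples = c("S1", "S2", "S3"))
  expect_identical(rec@mat, rec2@mat)
  # empty input
  expect_equal(dim(recurrenceMatrix(calls[0, ])), c(0L, 0L))
})

test_that("panel construction enforces disjointness and sizes", {
  expect_length(buildPanel(paste0("W", 1:92), paste0("L", 1:45)), 137L)
  expect_error(buildPanel(c("TET2", "FAT1"), c("TET2", "RHOA")), "TET2")
  expect_length(buildPanel(character(), character()), 0L)
  p <- referenceProfile()
  expect_length(buildPanel(p@wesGenes, p@litGenes), 137L)
})

test_that("H-score is the positivity-intensity product on [0, 300]", {
  expect_equal(hScore(100, 3), 300)
  expect_equal(hScore(0, 3), 0)
  expect_equal(hScore(50, 2), 100)
  expect_error(hScore(101, 2), "0, 100")
  expect_error(hScore(50, 3.5), "0, 3")
  expect_error(hScore(-1, 1), "0, 100")
})
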