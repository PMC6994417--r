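test_that("panel-of-normals membership matches a brute-force union oracle", {
  set.seed(11)
  tables <- lapply(1:5, function(i) {
    n <- 8L
    makeVariantTable(sample_id = sprintf("N%02d", i), chrom = "chr1",
                     pos = sample(100:140, n), ref = "C", alt = "T",
                     depth = sample(10:60, n, replace = TRUE),
                     alt_reads = sample(0:5, n, replace = TRUE))
  })
  for (minReads in 1:3) {
    pon <- buildPon(tables, minReads = minReads)
    expect_setequal(ponKeys(pon), bruteForcePon(tables, minReads))
  }
  # threshold semantics: 1 supporting read is below the default threshold
  one <- makeVariantTable("N1", "chr2", 500, "G", "A", 30, 1)
  three <- makeVariantTable("N2", "chr2", 600, "G", "A", 30, 3)
  pon <- buildPon(list(one, three))
  expect_false(variantKey("chr2", 500, "G", "A") %in% ponKeys(pon))
  expect_true(variantKey("chr2", 600, "G", "A") %in% ponKeys(pon))
  expect_true(variantKey("chr2", 500, "G", "A") %in%
                ponKeys(buildPon(list(one), minReads = 1)))

  # order-invariant and idempotent
  ponRev <- buildPon(rev(tables))
  pon1 <- buildPon(tables)
  expect_identical(ponKeys(pon1), ponKeys(ponRev))
  expect_identical(pon1@provenance, ponRev@provenance)
  expect_error(buildPon(list()), "at least one")
})

test_that("WES cascade applies the published strict thresholds in order", {
  ann <- rbind(annotRow(100), annotRow(200, gene = "TET2"),
               annotRow(300, gene = "TP53"), annotRow(400, gene = "ATM"))
  emptyPon <- buildPon(list(makeVariantTable("N1", "chr9", 1, "A", "G",
                                             30, 5)))

  # paired call: depth 50/40, VAF 0.30/0.00, COSMIC+, PoN-, unique -> retained
  tumor <- callRow(100, depth = 50L, alt_reads = 15L)
  normal <- makeVariantTable("SAL_S1", "chr1", 100, "C", "T", 40, 0)
  res <- wesDiscoveryFilter(tumor, ann, emptyPon, matchedNormal = normal)
  expect_identical(res@calls$verdict, "retained")

  # tumor depth 9 fails the depth gate (9 < 10)
  res <- wesDiscoveryFilter(callRow(200, depth = 9L, alt_reads = 3L),
                            ann, emptyPon)
  expect_identical(res@calls$verdict, "rejected")
  expect_identical(res@calls$rejecting_gate, "depth")

  # unpaired: depth 20 at VAF 0.30 fails (depth strictly > 20 required)
  res <- wesDiscoveryFilter(callRow(300, depth = 20L, alt_reads = 6L),
                            ann, emptyPon)
  expect_identical(res@calls$rejecting_gate, "vaf")
  # ... depth 21 at VAF > 0.25 passes the same gate
  res <- wesDiscoveryFilter(callRow(300, depth = 21L, alt_reads = 6L),
                            ann, emptyPon)
  expect_identical(res@calls$verdict, "retained")
  # ... VAF exactly 0.25 fails (strict >)
  res <- wesDiscoveryFilter(callRow(300, depth = 40L, alt_reads = 10L),
                            ann, emptyPon)
  expect_identical(res@calls$rejecting_gate, "vaf")

  # paired: matched-normal VAF at 3% is not below 3% -> rejected
  normalHot <- makeVariantTable("SAL_S1", "chr1", 400, "C", "T", 100, 3)
  res <- wesDiscoveryFilter(callRow(400, depth = 50L, alt_reads = 15L),
                            ann, emptyPon, matchedNormal = normalHot)
  expect_identical(res@calls$rejecting_gate, "vaf")

  # site absent from the matched-normal evidence: normal depth counts as 0
  res <- wesDiscoveryFilter(callRow(100, depth = 50L, alt_reads = 15L),
                            ann, emptyPon,
                            matchedNormal = makeVariantTable(
                              "SAL_S1", "chr1", 999, "C", "T", 40, 0))
  expect_identical(res@calls$rejecting_gate, "depth")

  # dbSNP membership rejects unless COSMIC-listed
  annDb <- rbind(annotRow(100, in_dbsnp = TRUE, in_cosmic = FALSE),
                 annotRow(200, in_dbsnp = TRUE, in_cosmic = TRUE))
  res <- wesDiscoveryFilter(callRow(100, depth = 50L, alt_reads = 20L),
                            annDb, emptyPon)
  expect_identical(res@calls$rejecting_gate, "germline_db")
  res <- wesDiscoveryFilter(callRow(200, depth = 50L, alt_reads = 20L),
                            annDb, emptyPon)
  expect_identical(res@calls$verdict, "retained")

  # missing annotation cannot be adjudicated
  expect_error(wesDiscoveryFilter(callRow(777), ann, emptyPon),
               "missing annotation")
})

test_that("targeted cascade uses inclusive thresholds and effect rules", {
  ctrl <- buildPon(list(makeVariantTable("H1", "chr9", 1, "A", "G",
                                         300, 50)))
  ann <- rbind(
    annotRow(100),
    annotRow(150, gene = "TET2"),
    annotRow(200, gene = "TP53", effect = "intronic", dist_to_cds = 3L),
    annotRow(250, gene = "TP53", effect = "intronic", dist_to_cds = 2L),
    annotRow(300, gene = "ATM", effect = "synonymous"),
    annotRow(350, gene = "ATM", kg_af = 0.02))

  # VAF exactly 10% with exactly 3 reads is retained (inclusive bounds)
  res <- targetedFilter(callRow(100, depth = 30L, alt_reads = 3L),
                        ann, ctrl)
  expect_identical(res@calls$verdict, "retained")
  # 2 supporting reads fail even at 10% VAF
  res <- targetedFilter(callRow(150, depth = 20L, alt_reads = 2L),
                        ann, ctrl)
  expect_identical(res@calls$rejecting_gate, "alt_reads")
  # intronic 3 bp from the CDS is excluded; 2 bp is kept
  res <- targetedFilter(callRow(200, depth = 100L, alt_reads = 30L),
                        ann, ctrl)
  expect_identical(res@calls$rejecting_gate, "effect")
  res <- targetedFilter(callRow(250, depth = 100L, alt_reads = 30L),
                        ann, ctrl)
  expect_identical(res@calls$verdict, "retained")
  # synonymous COSMIC variants are still excluded
  res <- targetedFilter(callRow(300, depth = 100L, alt_reads = 30L),
                        ann, ctrl)
  expect_identical(res@calls$rejecting_gate, "effect")
  # 1000 Genomes prevalence above 1% is excluded
  res <- targetedFilter(callRow(350, depth = 100L, alt_reads = 30L),
                        ann, ctrl)
  expect_identical(res@calls$rejecting_gate, "kg_af")
  # caller-quality flag is the first gate
  res <- targetedFilter(callRow(100, depth = 30L, alt_reads = 3L,
                                quality_ok = FALSE), ann, ctrl)
  expect_identical(res@calls$rejecting_gate, "quality")
  # control subtraction
  inCtrl <- makeVariantTable("S1", "chr9", 1, "A", "G", 200, 60)
  annC <- annotRow(1, chrom = "chr9", ref = "A", alt = "G", gene = "ATM")
  res <- targetedFilter(inCtrl, annC, ctrl)
  expect_identical(res@calls$rejecting_gate, "controls")
})

test_that("RNA concordance requires two supporting reads by default", {
  rna <- data.frame(key = c("chr1:100:C:T", "chr1:200:C:T"),
                    reads = c(5L, 1L))
  expect_true(rnaConcordant("chr1:100:C:T", rna))
  expect_false(rnaConcordant("chr1:200:C:T", rna))        # 1 read
  expect_true(rnaConcordant("chr1:200:C:T", rna, minReads = 1))
  expect_false(rnaConcordant("chr1:999:C:T", rna))        # absent
  expect_false(rnaConcordant("chr1:100:C:T", rna[0, ]))   # empty table
})

test_that("context uniqueness counts forward and reverse-complement hits", {
  set.seed(3)
  base <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                collapse = "")
  ctxU <- substring(base, 101, 141)      # occurs once
  dup <- paste0(base, substring(base, 501, 700))  # duplicate a block
  ctxD <- substring(base, 551, 591)      # now occurs twice
  rcomp <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(
      substring(base, 901, 941))))
  withRC <- paste0(dup, rcomp)           # forward + RC occurrence
  ctxRC <- substring(base, 901, 941)

  expect_true(contextIsUnique(ctxU, dup))
  expect_false(contextIsUnique(ctxD, dup))
  expect_false(contextIsUnique(ctxRC, withRC))
  expect_error(contextIsUnique("ACGT", dup), "41 bases")
  expect_true(is.na(contextIsUnique(NA_character_, dup)))

  # agreement with the brute-force character-scan oracle
  short <- substring(dup, 1, 1200)
  for (start in c(101, 401, 551, 701)) {
    ctx <- substring(short, start, start + 40)
    expect_identical(unname(contextIsUnique(ctx, short)),
                     bruteForceContextUnique(ctx, short),
                     label = paste("context at", start))
  }
})

test_that("cascades are monotone and traces replay to the verdicts", {
  b <- smallBundle()
  tgt <- targetedFilterCohort(b)
  for (s in names(tgt$results)[1:4]) {
    res <- tgt$results[[s]]
    calls <- res@calls
    # monotone: retained is a subset of the input
    expect_true(all(retainedCalls(res)$key %in% b@targeted[[s]]$key))
    # replay the documented gate predicates from the adjudicated calls
    th <- filterThresholds()
    replay <- cbind(
      quality = calls$quality_ok,
      vaf = calls$vaf >= th$targeted_min_vaf,
      alt_reads = calls$alt_reads >= th$targeted_min_alt,
      kg_af = calls$kg_af <= th$targeted_max_kg,
      cosmic = calls$in_cosmic,
      dbsnp = !(calls$in_dbsnp & !calls$dbsnp_pathogenic &
                  !calls$in_cosmic),
      effect = calls$effect != "synonymous" &
        (calls$effect != "intronic" |
           calls$dist_to_cds <= th$intronic_max_dist),
      controls = !(calls$key %in% ponKeys(tgt$controls)))
    expect_identical(ifelse(rowSums(!replay) == 0, "retained",
                            "rejected"),
                     calls$verdict)
    # the trace stores the same gate outcomes
    tr <- filterTrace(res)
    for (g in colnames(replay))
      expect_identical(tr$passed[tr$gate == g], unname(replay[, g]),
                       label = paste("gate", g))
    # verdict = retained iff all gates passed
    agg <- tapply(tr$passed, tr$key, all)
    expect_identical(as.logical(agg[calls$key]),
                     calls$verdict == "retained")
  }
})

test_that("full-recovery: cascades retain exactly the planted somatic set", {
  b <- smallBundle()
  cls <- setNames(b@truth$classes$class, b@truth$classes$key)

  wes <- wesFilterCohort(b)
  expect_true(all(cls[wes$retained$key] == "somatic"))
  plantedWes <- unlist(lapply(names(b@wes), function(s)
    paste(s, b@truth$perSampleSomatic[[s]])))
  expect_setequal(paste(wes$retained$sample_id, wes$retained$key),
                  plantedWes)

  tgt <- targetedFilterCohort(b)
  expect_true(all(cls[tgt$retained$key] == "somatic"))
  plantedPanel <- unlist(lapply(names(b@targeted), function(s)
    if (length(b@truth$perSamplePanel[[s]]))
      paste(s, b@truth$perSamplePanel[[s]])))
  expect_setequal(paste(tgt$retained$sample_id, tgt$retained$key),
                  plantedPanel)
})
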