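test_that("generation is deterministic: same seed, identical bundle", {
  b1 <- smallBundle()
  b2 <- generateCohort(smallProfile(), seed = 7)
  expect_identical(b1@targeted, b2@targeted)
  expect_identical(b1@wes, b2@wes)
  expect_identical(b1@pon, b2@pon)
  expect_identical(b1@annotations, b2@annotations)
  expect_identical(b1@truth, b2@truth)
  expect_identical(b1@clinical, b2@clinical)
  expect_identical(as.character(b1@reference), as.character(b2@reference))
  # a different seed changes the bundle
  b3 <- generateCohort(smallProfile(), seed = 8)
  expect_false(identical(b1@annotations, b3@annotations))
})

test_that("bundle honours the profiled sample counts and roles", {
  b <- smallBundle()
  p <- smallProfile()
  roles <- table(b@samples$role)
  expect_equal(as.integer(roles[["tumor_discovery"]]), p@nDiscovery)
  expect_equal(as.integer(roles[["tumor_extension"]]), p@nExtension)
  expect_equal(as.integer(roles[["pon_normal"]]), p@nPon)
  expect_equal(as.integer(roles[["hyperplastic_control"]]),
               p@nHyperplastic)
  expect_equal(as.integer(roles[["matched_normal"]]),
               p@nMatchedDiscovery + p@nMatchedExtension)
  expect_length(b@wes, p@nDiscovery)
  expect_length(b@targeted, nTumors(p))
  expect_length(b@rna, p@nRna)
  expect_length(b@saliva, p@nMatchedDiscovery + p@nMatchedExtension)
  # neoplastic-cell fraction above the inclusion threshold for tumors
  tf <- b@samples$tumor_fraction[grepl("^tumor", b@samples$role)]
  expect_true(all(tf > 0.75))
})

test_that("planted truth matches the profile: gene sets and burden", {
  b <- smallBundle()
  p <- smallProfile()
  gf <- geneFreqs(p)
  for (g in names(gf))
    expect_length(b@truth$geneSamples[[g]], gf[[g]])
  # every emitted tumor variant has exactly one truth label
  expect_false(anyDuplicated(b@truth$classes$key) > 0)
  # per-discovery-sample planted nonsynonymous counts equal the burden list
  counts <- lengths(b@truth$perSampleSomatic[names(b@wes)])
  expect_equal(unname(counts), as.integer(perSampleBurden(p)))
})

test_that("every generated table satisfies the VAF/count invariants", {
  b <- smallBundle()
  for (tbl in c(b@wes, b@targeted, b@pon, b@hyperplastic, b@saliva,
                b@wesMatchedNormals)) {
    expect_true(all(tbl$alt_reads <= tbl$depth))
    expect_true(all(abs(tbl$vaf - ifelse(tbl$depth > 0,
                                         tbl$alt_reads / tbl$depth, 0))
                    < 1e-9))
  }
})

test_that("substitution sampler hits the requested Ti/Tv ratio and G/C bias", {
  expect_error(sampleSubstitution(-1, 0.5), "positive")
  expect_error(sampleSubstitution(2, 1.5), "0, 1")

  # limiting cases
  set.seed(1)
  allTi <- sampleSubstitution(Inf, 0.5, 500)
  expect_true(all(classifySubstitution(allTi$ref, allTi$alt) ==
                    "transition"))
  noGC <- sampleSubstitution(2, 0, 500)
  expect_false(any(noGC$ref %in% c("G", "C")))
  allGC <- sampleSubstitution(2, 1, 500)
  expect_true(all(allGC$ref %in% c("G", "C")))

  # empirical ratio within 3 binomial SEs of the target
  titv <- 1676 / 857
  n <- 100000L
  set.seed(42)
  draws <- sampleSubstitution(titv, 0.6, n)
  ti <- sum(classifySubstitution(draws$ref, draws$alt) == "transition")
  pTi <- titv / (1 + titv)
  se <- sqrt(n * pTi * (1 - pTi))
  expect_lt(abs(ti - n * pTi), 3 * se)
  # implied ratio close to the target
  expect_lt(abs(ti / (n - ti) - titv), 3 * se / (n - ti) * (1 + titv))
})

test_that("clinical layer plants the survival landmarks exactly", {
  b <- smallBundle()
  p <- smallProfile()
  ss <- survivalSpec(p)
  cl <- b@clinical
  expect_equal(nrow(cl), ss$n_clinical)
  expect_true(all(cl$os_months >= ss$followup_range[1] &
                    cl$os_months <= ss$followup_range[2]))
  # group medians are planted as uncensored events at the defining rank
  kmM <- kmEstimate(cl[cl$group == "mutated", ])
  kmW <- kmEstimate(cl[cl$group == "wildtype", ])
  expect_equal(kmMedian(kmM), ss$median_mutated)
  expect_equal(kmMedian(kmW), ss$median_wildtype)
  expect_equal(survivalAt(kmEstimate(cl), 36), ss$survival_at_36m)
})

test_that("infeasible survival constraints are rejected with an error", {
  p <- smallProfile()
  p@survivalSpec$median_mutated <- 39   # beyond the 36-month landmark
  b <- smallBundle()
  expect_error(generateSurvival(p, b@truth, seed = 1), "infeasible")
  p2 <- smallProfile()
  p2@survivalSpec$survival_at_36m <- 1 / 7   # unattainable at n = 9
  expect_error(generateSurvival(p2, b@truth, seed = 1), "infeasible")
})

test_that("product-limit construction agrees with the closed form on a toy", {
  # four patients, all events at months 1..4
  km <- kmEstimate(1:4, rep(TRUE, 4))
  expect_equal(km@surv, c(0.75, 0.5, 0.25, 0))
  # the smallest time with S(t) <= 0.5 is month 2
  expect_equal(kmMedian(km), 2)
})
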