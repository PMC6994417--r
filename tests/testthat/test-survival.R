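test_that("product-limit estimate matches hand computation on toys", {
  # all events at 1..4: S = 3/4, 1/2, 1/4, 0
  km <- kmEstimate(1:4, rep(TRUE, 4))
  expect_equal(km@surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km@nRisk, c(4, 3, 2, 1))

  # mixed 6-patient toy {(1,E),(2,C),(3,E),(4,E),(5,C),(6,E)}
  # hand product-limit: 5/6, then 5/6*3/4 = 5/8, 5/8*2/3 = 5/12, then 0
  km <- kmEstimate(1:6, c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(km@time, c(1, 3, 4, 6))
  expect_equal(km@surv, c(5/6, 5/8, 5/12, 0))

  # all censored: S identically 1, median undefined
  km <- kmEstimate(1:5, rep(FALSE, 5))
  expect_length(km@time, 0L)
  expect_equal(survivalAt(km, c(0, 3, 100)), c(1, 1, 1))
  expect_true(is.na(kmMedian(km)))

  # ties: a censoring at an event time stays at risk for that event
  km <- kmEstimate(c(2, 2, 5), c(TRUE, FALSE, TRUE))
  expect_equal(km@nRisk, c(3, 1))
  expect_equal(km@surv, c(2/3, 0))

  expect_error(kmEstimate(numeric(0), logical(0)), "at least one")
  expect_error(kmEstimate(c(-1, 2), c(TRUE, TRUE)), "nonnegative")
})

test_that("survival evaluation is right-continuous with S(0) = 1", {
  km <- kmEstimate(c(1, 2, 3, 4), rep(TRUE, 4))
  expect_equal(survivalAt(km, 0), 1)
  expect_equal(survivalAt(km, 0.99), 1)
  expect_equal(survivalAt(km, 2), 0.5)     # right-continuous at the step
  expect_equal(survivalAt(km, 2.5), 0.5)
  expect_equal(survivalAt(km, 100), 0)     # beyond last event, all events
  expect_equal(kmMedian(km), 2)            # smallest t with S(t) <= 0.5
})

test_that("estimator agrees with the survival package on random fixtures", {
  skip_if_not_installed("survival")
  set.seed(9)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    time <- sample(1:10, n, replace = TRUE)
    ev <- runif(n) < 0.7
    if (!any(ev)) ev[1] <- TRUE
    km <- kmEstimate(time, ev)
    sf <- survival::survfit(survival::Surv(time, ev) ~ 1)
    sfSurv <- summary(sf, times = km@time)$surv
    expect_equal(km@surv, sfSurv, tolerance = 1e-12,
                 label = paste("fixture", i))
  }
})

test_that("log-rank statistic matches the hand hypergeometric computation", {
  # A: events at 1 and 3; B: event at 2, censored at 4. Hand sums over the
  # three event times (n, n_A, d) = (4,2,1), (3,1,1), (2,1,1):
  #   E_A = 2/4 + 1/3 + 1/2 = 4/3
  #   V   = (2*2*3)/(16*3) + (1*2*2)/(9*2) + (1*1*1)/(4*1) = 13/18
  #   chisq = (2 - 4/3)^2 / (13/18) = 8/13
  a <- data.frame(os_months = c(1, 3), event = c(TRUE, TRUE))
  b <- data.frame(os_months = c(2, 4), event = c(TRUE, FALSE))
  lr <- logrankTest(a, b)
  expect_equal(lr@observed, c(2, 1))
  expect_equal(lr@expected[1], 4/3)
  expect_equal(lr@variance, 13/18)
  expect_equal(lr@chisq, 8/13)
  expect_equal(lr@pValue, pchisq(8/13, 1, lower.tail = FALSE))

  # identical groups: statistic 0, p = 1
  g <- data.frame(os_months = c(1, 2, 3), event = c(TRUE, TRUE, FALSE))
  lr0 <- logrankTest(g, g)
  expect_equal(lr0@chisq, 0)
  expect_equal(lr0@pValue, 1)

  # label swap leaves the statistic unchanged
  lrSwap <- logrankTest(b, a)
  expect_equal(lrSwap@chisq, lr@chisq)
  expect_equal(lrSwap@expected, rev(lr@expected))

  expect_error(logrankTest(
    data.frame(os_months = 1, event = FALSE),
    data.frame(os_months = 2, event = FALSE)), "no events")
})

test_that("log-rank agrees with survival::survdiff on random fixtures", {
  skip_if_not_installed("survival")
  set.seed(13)
  for (i in 1:20) {
    nA <- sample(3:10, 1); nB <- sample(3:10, 1)
    da <- data.frame(os_months = sample(1:15, nA, replace = TRUE),
                     event = runif(nA) < 0.7)
    db <- data.frame(os_months = sample(1:15, nB, replace = TRUE),
                     event = runif(nB) < 0.7)
    if (!any(da$event) && !any(db$event)) da$event[1] <- TRUE
    lr <- logrankTest(da, db)
    pooled <- rbind(cbind(da, g = "A"), cbind(db, g = "B"))
    sd <- survival::survdiff(
      survival::Surv(os_months, event) ~ g, data = pooled)
    expect_equal(lr@chisq, unname(sd$chisq), tolerance = 1e-10,
                 label = paste("fixture", i))
    expect_equal(lr@expected, unname(sd$exp), tolerance = 1e-10)
  }
})

test_that("gene stratification partitions the clinical table", {
  calls <- data.frame(
    sample_id = c("P1", "P1", "P2", "P9"),
    gene = c("FAT1", "TET2", "FAT1", "FAT1"),
    effect = c("missense", "missense", "stop_gain", "missense"))
  clinical <- data.frame(patient_id = paste0("P", 1:5),
                         os_months = c(5, 10, 15, 20, 25),
                         event = c(TRUE, TRUE, FALSE, TRUE, FALSE))
  expect_message(st <- stratifyByGene(calls, clinical, "FAT1"), "P9")
  expect_setequal(st$mutated$patient_id, c("P1", "P2"))
  expect_setequal(st$wildtype$patient_id, c("P3", "P4", "P5"))
  # exhaustive and disjoint over clinical records
  expect_equal(nrow(st$mutated) + nrow(st$wildtype), nrow(clinical))
  expect_length(intersect(st$mutated$patient_id,
                          st$wildtype$patient_id), 0L)
  # a gene with no mutated samples puts everyone in wild-type
  st2 <- stratifyByGene(calls, clinical, "TET2")
  expect_setequal(st2$mutated$patient_id, "P1")
  st3 <- stratifyByGene(calls, clinical, "FAT1",
                        knownGenes = c("FAT1", "EZH2"))
  expect_equal(nrow(st3$mutated), 2L)
  expect_error(stratifyByGene(calls, clinical, "NOPE"), "unknown gene")
})
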