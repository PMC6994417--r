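test_that("damaging vote requires four of nine predictors", {
  expect_true(damagingVote(c(rep("D", 4), rep("T", 5))))
  expect_false(damagingVote(c(rep("D", 3), rep(".", 6))))  # missing != damaging
  expect_true(damagingVote(rep("D", 9)))
  expect_false(damagingVote(rep("T", 9)))
  expect_error(damagingVote(rep("D", 8)), "9 predictor")
  expect_error(damagingVote(matrix("D", 2, 10)), "9 predictor")
  expect_error(damagingVote(c(rep("D", 4), rep("X", 5))), "D, T or")
  # matrix input is vectorised
  m <- rbind(rep("D", 9), c(rep("D", 3), rep("T", 6)))
  expect_identical(damagingVote(m), c(TRUE, FALSE))
})

test_that("damaging vote is monotone in damaging calls", {
  set.seed(5)
  for (i in 1:50) {
    calls <- sample(c("D", "T", "."), 9, replace = TRUE)
    v0 <- damagingVote(calls)
    flip <- which(calls != "D")
    for (j in flip) {
      up <- calls; up[j] <- "D"
      expect_true(damagingVote(up) >= v0)
    }
  }
})

test_that("stability classification applies a strict -0.5 kcal/mol cut", {
  expect_identical(classifyStability(-1.2), "destabilizing")
  expect_identical(classifyStability(-0.5), "non_destabilizing")  # boundary
  expect_identical(classifyStability(-0.5000001), "destabilizing")
  expect_identical(classifyStability(NA), "not_applicable")
  expect_identical(classifyStability(c(-1, 0, NA)),
                   c("destabilizing", "non_destabilizing",
                     "not_applicable"))
})

test_that("destabilizing fractions equal brute-force counts", {
  expect_equal(destabilizingFraction(c(-1, -0.6, 0.2)), c(k = 2, n = 3))
  expect_equal(destabilizingFraction(numeric(0)), c(k = 0, n = 0))
  expect_equal(destabilizingFraction(c(NA, NA)), c(k = 0, n = 0))
  # data.frame input restricts to the gene's missense variants
  df <- data.frame(gene = c("ATM", "ATM", "ATM", "TP53"),
                   effect = c("missense", "missense", "stop_gain",
                              "missense"),
                   ddg = c(-2, 0.1, -3, -1))
  expect_equal(destabilizingFraction(df, "ATM"), c(k = 1, n = 2))
  # property: k <= n on random inputs
  set.seed(6)
  for (i in 1:20) {
    x <- runif(sample(0:10, 1), -3, 2)
    kn <- destabilizingFraction(x)
    expect_lte(kn[["k"]], kn[["n"]])
    expect_equal(kn[["k"]], sum(x < -0.5))
  }
})

test_that("consequence step votes missense calls and keeps truncating ones", {
  calls <- rbind(
    cbind(callRow(100), annotRow(100)[-(1:4)]),
    cbind(callRow(200), annotRow(200, effect = "stop_gain",
                                 preds = rep(".", 9))[-(1:4)]),
    cbind(callRow(300), annotRow(300, preds = c(rep("D", 3),
                                                rep("T", 6)))[-(1:4)]))
  out <- consequenceFilter(calls)
  expect_setequal(out$pos, c(100L, 200L))  # weak missense vote dropped
  expect_identical(consequenceFilter(calls[0, ]), calls[0, ])
})
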