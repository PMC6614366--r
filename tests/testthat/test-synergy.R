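test_that("noise-free logistic curves are recovered to optimizer precision", {
  doses <- c(10, 30, 100, 300, 1000, 3000, 10000)
  truth <- c(L = 0, U = 100, slope = 1, ec50 = 100)
  fit <- fit4PL(doses, logistic4(truth, doses))
  expect_false(fit$fallback)
  expect_equal(fit$L, 0, tolerance = 1e-5)
  expect_equal(fit$U, 100, tolerance = 1e-6)
  expect_equal(fit$slope, 1, tolerance = 1e-6)
  expect_equal(fit$ec50, 100, tolerance = 1e-6)
})

test_that("degenerate dose-response data falls back to interpolation", {
  doses <- c(10, 100, 1000, 10000)
  expect_warning(fit <- fit4PL(doses, rep(42, 4)), "degenerate")
  expect_true(fit$fallback)
  expect_equal(predict4PL(fit, c(50, 5000)), c(42, 42))
})

test_that("EC50 is typically recovered from noisy 7-dose curves", {
  doses <- c(10, 30, 100, 300, 1000, 3000, 10000)
  truth <- c(L = 0, U = 100, slope = 1, ec50 = 100)
  set.seed(21)
  errs <- replicate(100, {
    y <- logistic4(truth, doses) + rnorm(7, sd = 3)
    fit <- suppressWarnings(fit4PL(doses, y))
    if (fit$fallback) NA_real_ else abs(fit$ec50 - 100) / 100
  })
  expect_lt(median(errs, na.rm = TRUE), 0.25)
})

test_that("a surface equal to the Bliss expectation scores zero", {
  m <- genSurface(delta = 0, sigma = 0)
  expect_equal(blissScore(m, useFittedMargins = FALSE)$score, 0)
  expect_equal(blissScore(m)$score, 0, tolerance = 1e-6)
})

test_that("a uniform planted excess is recovered linearly", {
  m5 <- genSurface(delta = 5, sigma = 0)
  expect_equal(blissScore(m5, useFittedMargins = FALSE)$score, 5)
  m0 <- genSurface(delta = 0, sigma = 0)
  m0@inhibition[-1, -1] <- m0@inhibition[-1, -1] + 7.5
  expect_equal(blissScore(m0, useFittedMargins = FALSE)$score, 7.5)
})

test_that("the Bliss score is invariant to swapping the two drugs", {
  for (seed in 1:5) {
    m <- genSurface(delta = 3, sigma = 4, seed = seed)
    mt <- DoseResponseMatrix(m@drug2, m@drug1, m@conc2, m@conc1,
                             t(m@inhibition))
    expect_equal(blissScore(mt, useFittedMargins = FALSE)$score,
                 blissScore(m, useFittedMargins = FALSE)$score)
    expect_equal(blissScore(mt)$score, blissScore(m)$score,
                 tolerance = 1e-8)
  }
})

test_that("the literal product expectation differs and is gated by flag", {
  m <- genSurface(delta = 0, sigma = 0)
  lit <- blissScore(m, useFittedMargins = FALSE, literalProduct = TRUE)$score
  # on a Bliss-null surface the product expectation undershoots, so the
  # literal mode reports spurious positive synergy
  expect_gt(lit, 0)
})

test_that("HSA score is the gain over the better single agent", {
  expect_equal(hsaScore(80, 50, 60), 20)
  expect_equal(hsaScore(60, 50, 60), 0)
  expect_equal(hsaScore(40, 50, 60), -20)
  expect_equal(hsaScore(c(80, 40), c(50, 50), c(60, 60)), c(20, -20))
})

test_that("siRNA multiplicative synergy averages pair excesses", {
  expect_equal(sirnaPairSynergy(0.3, 0.5, 0.6), 0)
  expect_equal(sirnaPairSynergy(c(0.9, 0.3), c(0.5, 0.5), c(0.6, 0.6)), 30)
  expect_error(sirnaPairSynergy(numeric(0), numeric(0), numeric(0)), "empty")
  set.seed(13)
  for (i in 1:20) {
    n <- sample(1:12, 1)
    yp <- runif(n); y1 <- runif(n); y2 <- runif(n)
    manual <- 0
    for (k in seq_len(n)) manual <- manual + (yp[k] - y1[k] * y2[k])
    expect_equal(sirnaPairSynergy(yp, y1, y2), manual / n * 100)
    expect_lte(abs(sirnaPairSynergy(yp, y1, y2)), 100)
  }
})

test_that("qPCR percent expression matches the cross-point formula", {
  expect_equal(qpcrPercentExpression(20, 20, 18, 18), 100)
  expect_equal(qpcrPercentExpression(21, 20, 18, 18), 50)
  expect_equal(qpcrPercentExpression(21, 20, 19, 18), 100)
  expect_error(qpcrPercentExpression(NA, 20, 18, 18))
})

test_that("CRISPR viability and cytotoxicity ratios match hand arithmetic", {
  r <- crisprViabilityCytotoxicity(100, 100, 30)
  expect_equal(r$viability, 1)
  expect_equal(crisprViabilityCytotoxicity(100, 400, 0)$cytotoxicity, 0)
  r2 <- crisprViabilityCytotoxicity(100, 400, 80)
  expect_equal(r2$viability, 4)
  expect_equal(r2$cytotoxicity, 20)
  expect_error(crisprViabilityCytotoxicity(0, 100, 10), "positive")
  r3 <- crisprViabilityCytotoxicity(100, 300, 10, negCtrl = 4, posCtrl = 0.5)
  expect_equal(r3$percent_inhibition, 100 * (4 - 3) / 3.5)
})

test_that("batch scoring emits per-replicate scores and pair means", {
  ms <- list(genSurface(delta = 4, sigma = 0),
             genSurface(delta = 6, sigma = 0),
             genSurface(delta = 0, sigma = 0))
  out <- scoreDoseMatrices(ms, useFittedMargins = FALSE)
  expect_equal(nrow(out), 3)
  expect_equal(out$replicate, c(1, 2, 3))
  expect_equal(out$bliss, c(4, 6, 0))
  expect_equal(attr(out, "pairMeans")$bliss, mean(c(4, 6, 0)))
})
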