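test_that("target binarization follows the fold-of-minimum rule", {
  kd <- KdMatrix(matrix(c(10, 400, 600), 1,
                        dimnames = list("d", c("k1", "k2", "k3"))))
  expect_setequal(binarizeTargets(kd, 50)$d, c("k1", "k2"))  # threshold 500
  expect_setequal(binarizeTargets(kd, 100)$d, c("k1", "k2", "k3"))
  expect_identical(binarizeTargets(kd, 10)$d, "k1")          # threshold 100
  expect_identical(binarizeTargets(kd, 1)$d, "k1")           # argmin only
  expect_error(binarizeTargets(kd, 0.5))
  kdNA <- KdMatrix(matrix(c(10, NA), 1, dimnames = list("d", c("k1", "k2"))))
  expect_identical(binarizeTargets(kdNA, 50)$d, "k1")        # missing never hits
})

test_that("DSS normalization is a min-max map preserving order", {
  expect_equal(unname(normalizeDss(c(a = 0, b = 5, c = 10))), c(0, 0.5, 1))
  set.seed(7)
  for (i in 1:20) {
    x <- stats::setNames(runif(8, 0, 40), letters[1:8])
    y <- normalizeDss(x)
    expect_equal(unname(y[which.min(x)]), 0)
    expect_equal(unname(y[which.max(x)]), 1)
    expect_identical(order(y), order(x))
  }
  expect_error(normalizeDss(c(a = 3, b = 3)), "degenerate")
})

test_that("identical-profile queries average the matching sensitivities", {
  profiles <- list(d1 = c("t1", "t2"), d2 = c("t1", "t2"), d3 = "t3")
  y <- c(0.2, 0.4, 0.9)
  expect_equal(predictSensitivity(c("t1", "t2"), profiles, y,
                                  universe = paste0("t", 1:3)), 0.3)
})

test_that("queries with no set relation fall back to the 0/1 anchors", {
  profiles <- list(d1 = "t1", d2 = "t2")
  y <- c(0.3, 0.8)
  expect_equal(predictSensitivity("t3", profiles, y,
                                  universe = paste0("t", 1:3)), 0.5)
})

test_that("nested-profile query matches hand enumeration", {
  profiles <- list(dA = "t1", dB = c("t1", "t2"), dC = c("t1", "t2", "t3"))
  y <- c(0.1, 0.5, 0.9)
  # subsets of {t1,t2,t4}: dA, dB; h = dB (y = 0.5), no qualifying j below
  # it -> y_min = 0.5; no superset -> y_max = 1; prediction 0.75
  expect_equal(predictSensitivity(c("t1", "t2", "t4"), profiles, y,
                                  universe = paste0("t", 1:4)), 0.75)
  expect_equal(bruteForceTimma(c("t1", "t2", "t4"), profiles, y), 0.75)
})

test_that("predictor agrees with the brute-force set enumerator", {
  set.seed(42)
  for (i in 1:400) {
    inst <- randomTimmaInstance()
    expect_equal(
      predictSensitivity(inst$d, inst$profiles, inst$y,
                         universe = inst$universe),
      bruteForceTimma(inst$d, inst$profiles, inst$y))
  }
})

test_that("predictions stay in [0, 1] and respect monotone data edits", {
  set.seed(11)
  for (i in 1:100) {
    inst <- randomTimmaInstance()
    p <- predictSensitivity(inst$d, inst$profiles, inst$y,
                            universe = inst$universe)
    expect_gte(p, 0)
    expect_lte(p, 1)
    # raising the anchor subset drug's sensitivity never lowers the
    # prediction (the anchor stays argmax, so the minimization average
    # can only move up)
    isSub <- vapply(inst$profiles, function(pr)
      all(pr %in% inst$d) && !setequal(pr, inst$d), logical(1))
    if (any(isSub)) {
      y2 <- inst$y
      j <- which(isSub)[which.max(inst$y[isSub])]
      y2[j] <- min(1, y2[j] + 0.3)
      p2 <- predictSensitivity(inst$d, inst$profiles, y2,
                               universe = inst$universe)
      if (!any(vapply(inst$profiles, setequal, logical(1), inst$d)))
        expect_gte(p2 + 1e-12, p)
    }
  }
})

test_that("a perfect single-target signal is recovered exactly", {
  set.seed(5)
  kinases <- paste0("k", 1:6)
  kd <- matrix(NA_real_, 12, 6, dimnames = list(paste0("d", 1:12), kinases))
  hit <- rep(c(TRUE, FALSE), 6)
  kd[cbind(1:12, sample(c(1, 2, 4, 5, 6), 12, TRUE))] <- 50  # background
  kd[hit, "k3"] <- 10                     # planted target, hit drugs only
  for (i in 1:12) if (!any(is.finite(kd[i, ]))) kd[i, 1] <- 30
  y <- stats::setNames(as.numeric(hit), rownames(kd))
  model <- selectEssentialTargets(binarizeTargets(KdMatrix(kd), 50), y)
  expect_identical(selectedTargets(model), "k3")
  expect_equal(looError(model), 0)
})

test_that("a constant all-drugs target is never the first pick", {
  set.seed(8)
  for (rep in 1:5) {
    scr <- genScreen(nDrugs = 15, nKinases = 8, nEssential = 2, sigma = 0.05,
                     seed = rep)
    kd <- kdValues(scr$kd)
    # bound by every drug at its own minimal Kd, so it joins every
    # profile without evicting the real targets
    kd <- cbind(kd, CONST = apply(kd, 1, min, na.rm = TRUE))
    model <- selectEssentialTargets(binarizeTargets(KdMatrix(kd), 50), scr$y)
    expect_false(selectedTargets(model)[1] == "CONST")
  }
})

test_that("essential-target selection is deterministic", {
  scr <- genScreen(nDrugs = 25, nKinases = 12, nEssential = 3, seed = 6)
  prof <- binarizeTargets(scr$kd)
  m1 <- selectEssentialTargets(prof, scr$y, seed = 1)
  m2 <- selectEssentialTargets(prof, scr$y, seed = 99)
  expect_identical(selectedTargets(m1), selectedTargets(m2))
  expect_identical(looError(m1), looError(m2))
})

test_that("combining a drug with itself predicts zero synergy", {
  scr <- genScreen(nDrugs = 15, nKinases = 10, nEssential = 2, seed = 2)
  model <- fitTimmaModel(scr$kd, scr$dss, maxSize = 5)
  d <- drugNames(model)[1]
  pred <- predictCombination(model, d, d)
  expect_equal(pred$synergy, 0)
  expect_equal(pred$y_combination, pred$yhat1)
})

test_that("an AND-type planted interaction yields positive synergy", {
  # sensitive only when both planted targets are hit: single-target drugs
  # score low, the combination recovers the planted effect
  scr <- genScreen(nDrugs = 30, nKinases = 12, nEssential = 2, rule = "AND",
                   sigma = 0, seed = 5)
  model <- fitTimmaModel(scr$kd, scr$dss, maxSize = 6)
  prof <- binarizeTargets(scr$kd)
  oneEach <- vapply(prof, function(t) sum(scr$essential %in% t) == 1,
                    logical(1))
  t1only <- names(prof)[oneEach &
    vapply(prof, function(t) scr$essential[1] %in% t, logical(1))]
  t2only <- names(prof)[oneEach &
    vapply(prof, function(t) scr$essential[2] %in% t, logical(1))]
  expect_gt(length(t1only), 0)
  expect_gt(length(t2only), 0)
  pred <- predictCombination(model, t1only[1], t2only[1])
  expect_gt(pred$synergy, 0.2)
  expect_error(predictCombination(model, "nonsense", t2only[1]), "unknown drug")
})

test_that("kinases with identical binding patterns merge into one node", {
  P <- matrix(c(TRUE, FALSE, TRUE,
                TRUE, FALSE, TRUE,
                FALSE, TRUE, TRUE), 3,
              dimnames = list(c("d1", "d2", "d3"), c("kA", "kB", "kC")))
  y <- stats::setNames(c(0.1, 0.6, 0.9), rownames(P))
  model <- methods::new("TimmaModel", targets = colnames(P), profiles = P,
                        projected = P, y = y, looError = 0.1, fold = 50)
  net <- buildCombinationNetwork(model)
  expect_equal(length(net@nodes), 2)        # kA+kB identical, kC separate
  merged <- net@nodes[["kA|kB"]]
  expect_setequal(merged$kinases, c("kA", "kB"))
  expect_setequal(merged$drugs, c("d1", "d3"))
  # partition property: every selected kinase in exactly one node
  allK <- unlist(lapply(net@nodes, `[[`, "kinases"))
  expect_setequal(allK, colnames(P))
  expect_equal(anyDuplicated(allK), 0)
})

test_that("cut inference flags combinations that disconnect the network", {
  # path A - B - C built from drug co-binding: dAB hits A,B; dBC hits B,C
  P <- matrix(c(TRUE, FALSE,
                TRUE, TRUE,
                FALSE, TRUE), 2,
              dimnames = list(c("dAB", "dBC"), c("A", "B", "C")))
  y <- stats::setNames(c(0.4, 0.6), rownames(P))
  model <- methods::new("TimmaModel", targets = colnames(P), profiles = P,
                        projected = P, y = y, looError = 0.1, fold = 50)
  net <- buildCombinationNetwork(model)
  expect_equal(length(net@nodes), 3)
  # both drugs together remove everything -> effective by emptiness
  res <- networkCutInference(net, "dAB", "dBC")
  expect_true(res$predicted_effective)
  expect_equal(res$components_after, 0)
  # one drug removes A and B, leaving {C}: 1 component, not effective
  res2 <- networkCutInference(net, "dAB", "dAB")
  expect_false(res2$predicted_effective)
  expect_equal(res2$components_after, 1)
})
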