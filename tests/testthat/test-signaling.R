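# small helper: an isolated birth-death gene (constant source + first-order
# degradation), built through the same compiler as full networks
isolatedGene <- function(kp = 10, kd = 0.1, gene = "G") {
  net <- SignedNetwork(data.frame(source = "A", target = "B",
                                  sign = "activation"))
  suppressWarnings(compileReactions(net, gene, keep = character(0),
                                    kp = kp, kd = kd))
}

test_that("differential-expression selection uses D > 1 strictly", {
  self <- c(g1 = 10, g2 = 30, g3 = 20, g4 = 0)
  panel <- c(g1 = 10, g2 = 10, g3 = 10, g4 = 10)
  out <- selectNetworkGenes(self, panel)
  expect_equal(out$D, c(0, 2, 1, 1))
  expect_identical(out$included, c(FALSE, TRUE, FALSE, FALSE))  # D = 1 excluded
  expect_error(selectNetworkGenes(c(g = 1), c(g = 0)), "zero")
})

test_that("edge compilation produces the source-consuming reaction scheme", {
  net <- SignedNetwork(data.frame(source = "A", target = "B",
                                  sign = "activation"))
  sys <- compileReactions(net, c("A", "B"), keep = character(0),
                          sources = "none")
  expect_equal(reactionCount(sys), 3)     # 1 conversion + 2 degradations
  conv <- which(sys@kref == "kp:B")
  expect_equal(sys@stoich[conv, ], c(A = -1, B = 1))

  # catalytic variant leaves the activator untouched
  sysc <- compileReactions(net, c("A", "B"), keep = character(0),
                           sources = "none", form = "catalytic")
  convc <- which(sysc@kref == "kp:B")
  expect_equal(sysc@stoich[convc, ], c(A = 0, B = 1))

  # default adds constant sources for input-less genes only
  sysr <- compileReactions(net, c("A", "B"), keep = character(0))
  expect_equal(reactionCount(sysr), 4)
  expect_equal(sum(sysr@type == 0L), 1)

  # inhibition propensity is mass-action bimolecular: kd(C) * X_B * X_C
  neti <- SignedNetwork(data.frame(source = "B", target = "C",
                                   sign = "inhibition"))
  sysi <- compileReactions(neti, c("B", "C"), keep = character(0),
                           kd = c(B = 0.2, C = 0.1), sources = "none")
  r <- which(sysi@type == 2L)
  x <- c(B = 2, C = 3)
  expect_equal(sys@k[1] * 0 + sysi@k[r] * x[sysi@a[r]] * x[sysi@b[r]],
               c(B = 0.6))               # 0.1/h * 2 * 3
  expect_equal(sysi@stoich[r, ], c(B = -1, C = -1))

  # edges touching unselected genes are dropped with a warning
  expect_warning(compileReactions(neti, "B", keep = character(0)), "dropped")
})

test_that("an isolated gene calibrates to the closed-form steady state", {
  sys <- isolatedGene(kp = 3, kd = 0.15)
  expect_equal(odeTwin(sys), c(G = 20))            # kp / kd exactly
  cal <- calibrateRates(sys, c(G = 120), tol = 0.01)
  expect_equal(productionRates(cal)[["G"]], 0.15 * 120)  # kp = kd * target
  expect_equal(odeTwin(cal), c(G = 120), tolerance = 1e-6)
})

test_that("a 3-gene activation chain calibrates within tolerance", {
  net <- SignedNetwork(data.frame(source = c("A", "B"),
                                  target = c("B", "C"),
                                  sign = "activation"))
  sys <- compileReactions(net, c("A", "B", "C"), keep = character(0),
                          kd = c(A = 0.1, B = 0.2, C = 0.25))
  target <- c(A = 100, B = 50, C = 20)
  cal <- calibrateRates(sys, target, tol = 0.05)
  ss <- odeTwin(cal)
  expect_true(all(abs(ss - target) / target < 0.05))
  # idempotence: a second pass changes the rates by less than tol
  cal2 <- calibrateRates(cal, target, tol = 0.05)
  expect_true(all(abs(productionRates(cal2) - productionRates(cal)) /
                    productionRates(cal) < 0.05))
})

test_that("the ODE twin matches linear-cascade closed forms", {
  net <- SignedNetwork(data.frame(source = c("A", "B"),
                                  target = c("B", "C"),
                                  sign = "activation"))
  kp <- c(A = 20, B = 0.5, C = 0.4)
  kd <- c(A = 0.1, B = 0.2, C = 0.25)
  sys <- compileReactions(net, c("A", "B", "C"), keep = character(0),
                          kp = kp, kd = kd)
  # consuming form: A* = kpA/(kdA+kpB); B* = kpB A*/(kdB+kpC); C* = kpC B*/kdC
  A <- 20 / 0.6; B <- 0.5 * A / 0.6; C <- 0.4 * B / 0.25
  expect_equal(odeTwin(sys), c(A = A, B = B, C = C), tolerance = 1e-6)
})

test_that("SSA birth-death moments match the Poisson closed form", {
  sys <- isolatedGene(kp = 10, kd = 0.1)
  res <- ssaSimulate(sys, init = c(G = 100), nCells = 1, tEnd = 20000,
                     recordDt = 1, seed = 424)
  x <- res$meanExpr[res$time > 500, "G"]
  nEff <- length(x) / 20          # ~2 x 1/kd autocorrelation spacing
  se <- sqrt(100) / sqrt(nEff)
  expect_lt(abs(mean(x) - 100), 3 * se)
  expect_gt(var(x) / mean(x), 0.9)
  expect_lt(var(x) / mean(x), 1.1)
})

test_that("simulations are reproducible for a fixed seed", {
  sys <- isolatedGene()
  r1 <- ssaSimulate(sys, init = c(G = 50), nCells = 2, tEnd = 200, seed = 7)
  r2 <- ssaSimulate(sys, init = c(G = 50), nCells = 2, tEnd = 200, seed = 7)
  expect_identical(r1$meanExpr, r2$meanExpr)
  expect_identical(r1$cellCount, r2$cellCount)
  r3 <- ssaSimulate(sys, init = c(G = 50), nCells = 2, tEnd = 200, seed = 8)
  expect_false(identical(r1$meanExpr, r3$meanExpr))
})

test_that("division partitions every species exactly between daughters", {
  sys <- addGrowthModule(isolatedGene(kp = 8, kd = 0.1), tdiv = 20,
                         tp53 = NA)
  res <- ssaSimulate(sys, init = c(G = 80), nCells = 4, tEnd = 150,
                     cap = 4000, seed = 31, maxDivLog = 1000)
  ns <- length(res$species)
  d <- res$divisions
  expect_gt(nrow(d), 20)
  mother <- d[, 1:ns, drop = FALSE]
  d1 <- d[, ns + (1:ns), drop = FALSE]
  d2 <- d[, 2 * ns + (1:ns), drop = FALSE]
  expect_identical(mother, d1 + d2)      # exact conservation, every event
  expect_true(all(d1 >= 0) && all(d2 >= 0))
})

test_that("ungated growth doubles the population every t_div", {
  sys <- addGrowthModule(isolatedGene(kp = 5, kd = 0.1), tdiv = 38,
                         tp53 = NA)
  dbl <- sapply(1:10, function(r) {
    res <- ssaSimulate(sys, init = c(G = 50), nCells = 10, tEnd = 152,
                       cap = 400, seed = 500 + r)
    n1 <- res$cellCount[res$time == 38]
    n2 <- res$cellCount[res$time == 152]
    (152 - 38) / log2(n2 / n1)
  })
  expect_lt(abs(mean(dbl) - 38) / 38, 0.10)
})

test_that("growth halves at the TP53 Hill midpoint", {
  # TP53 held near Q = 65 (kp/kd = 65): the Hill gate f should average 0.5
  net <- SignedNetwork(data.frame(source = "A", target = "B",
                                  sign = "activation"))
  sys <- suppressWarnings(compileReactions(net, "TP53", keep = character(0),
                                           kp = 65 * 0.5, kd = 0.5))
  sys <- addGrowthModule(sys, tdiv = 38, theta = 1e9)   # no division
  res <- ssaSimulate(sys, init = c(TP53 = 65), nCells = 1, tEnd = 400,
                     seed = 12)
  pg <- res$meanExpr[, "pGrowth"]
  rate <- log(pg[res$time == 400] / pg[res$time == 50]) / 350
  fHat <- rate / (log(2) / 38)
  expect_gt(fHat, 0.3)
  expect_lt(fHat, 0.7)
})

test_that("silencing removes production and respects knockdown efficiency", {
  sys <- isolatedGene(kp = 10, kd = 0.1)
  ko <- silenceGenes(sys, "G", mode = "knockout")
  expect_equal(sum(ko@kref == "kp:G"), 0)
  kdn <- silenceGenes(sys, "G", mode = "knockdown", eff = 0.8)
  expect_equal(kdn@k[kdn@kref == "kp:G"], 10 * 0.2)
  expect_equal(odeTwin(kdn), c(G = 20))
  expect_error(silenceGenes(sys, "NOPE"), "absent")
})

test_that("silencing a bystander gene leaves viability at one", {
  sys <- demoSignalingModel()
  kx <- knockoutExperiment(sys, "PARP1", nRuns = 3, tEnd = 120, window = 40,
                           nCells = 6, cap = 80, seed = 3)
  expect_lt(abs(kx$viability - 1), 0.1)
  # the control arm normalizes to exactly 1 by construction
  kx0 <- knockoutExperiment(sys, "PARP1", nRuns = 2, tEnd = 60, window = 20,
                            nCells = 4, cap = 50, seed = 5,
                            control = c(10, 10))
  expect_equal(mean(kx0$perturbed_counts) / mean(kx0$control_counts),
               kx0$viability)
})

test_that("self-sensitivity of a birth-death gene's degradation rate is -1", {
  sys <- isolatedGene(kp = 12, kd = 0.15)
  rep <- parameterSensitivity(sys)
  kdRow <- rep$mean_abs_sensitivity[rep$parameter == "kd:G"]
  kpRow <- rep$mean_abs_sensitivity[rep$parameter == "kp:G"]
  expect_equal(kdRow, 1, tolerance = 1e-3)
  expect_equal(kpRow, 1, tolerance = 1e-3)
  S <- attr(rep, "matrix")
  expect_equal(S["G", "kd:G"], -1, tolerance = 1e-3)   # power law X* = c/kd
})

test_that("parameters of sink genes have no off-target influence", {
  sys <- demoSignalingModel()
  rep <- parameterSensitivity(sys)
  S <- attr(rep, "matrix")
  # PARP1 has no outgoing edges: its rates influence only itself
  others <- setdiff(rownames(S), "PARP1")
  expect_lt(max(abs(S[others, c("kp:PARP1", "kd:PARP1")])), 1e-4)
  # ranking is stable across perturbation step sizes
  repSmall <- parameterSensitivity(sys, perturbation = 0.005)
  repBig <- parameterSensitivity(sys, perturbation = 0.02)
  o <- match(rep$parameter, repSmall$parameter)
  rho <- cor(rank(repSmall$mean_abs_sensitivity[o]),
             rank(repBig$mean_abs_sensitivity[match(rep$parameter,
                                                    repBig$parameter)]),
             method = "spearman")
  expect_gte(rho, 0.95)
})
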