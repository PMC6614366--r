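#' Generate a synthetic kinome drug screen with planted essential targets
#'
#' Emulates a kinome-wide binding screen (drugs x kinases Kd matrix with a
#' heavy no-bind mass and log-normal affinities) together with single-drug
#' sensitivities generated from a planted Boolean rule over an essential
#' target set T*: a drug's noiseless sensitivity is 1 if it hits any
#' planted target (\code{rule = "OR"}), 1 only if it hits all
#' (\code{"AND"}), or the fraction hit (\code{"weighted"}). Gaussian noise
#' of sd \code{sigma} is added and clipped to [0, 1]. Planted kinases are
#' bound more often than background kinases so the planted signal has
#' realistic coverage across the screen. Fixed seeds reproduce identical
#' tables.
#'
#' @param nDrugs,nKinases screen dimensions (defaults 41 x 385, a
#'   kinome-scan-sized panel).
#' @param nEssential size of the planted set T*.
#' @param rule Boolean sensitivity rule over T*.
#' @param sigma Gaussian noise sd on sensitivities.
#' @param seed RNG seed.
#' @param bindProb background per-cell binding probability.
#' @param essentialBindProb binding probability for planted kinases.
#' @param fold binarization fold used to define "hits" in the ground
#'   truth (default 50, matching model fitting).
#' @return list of class \code{PlantedScreen}: \code{kd}
#'   (\code{\link{KdMatrix-class}}), \code{essential} (T*), \code{y}
#'   (noisy sensitivities in [0, 1]), \code{dss} (raw scores on a
#'   DSS-like 0-50 scale), \code{rule}, \code{sigma}.
#' @export
genScreen <- function(nDrugs = 41, nKinases = 385, nEssential = 3,
                      rule = c("OR", "AND", "weighted"), sigma = 0.05,
                      seed = 1, bindProb = 0.12, essentialBindProb = 0.25,
                      fold = 50) {
  rule <- match.arg(rule)
  stopifnot(nEssential <= nKinases)
  set.seed(seed)
  drugs <- sprintf("drug%02d", seq_len(nDrugs))
  kinases <- sprintf("KIN%03d", seq_len(nKinases))
  essential <- sort(sample(kinases, nEssential))
  p <- ifelse(kinases %in% essential, essentialBindProb, bindProb)
  bound <- matrix(stats::runif(nDrugs * nKinases), nDrugs, nKinases) <=
    matrix(p, nDrugs, nKinases, byrow = TRUE)
  kd <- matrix(NA_real_, nDrugs, nKinases, dimnames = list(drugs, kinases))
  kd[bound] <- stats::rlnorm(sum(bound), meanlog = log(100), sdlog = 1.5)
  for (i in seq_len(nDrugs))                     # every drug binds something
    if (!any(bound[i, ])) {
      j <- sample.int(nKinases, 1)
      kd[i, j] <- stats::rlnorm(1, log(100), 1.5)
    }
  km <- KdMatrix(kd)
  prof <- binarizeTargets(km, fold = fold)
  hits <- vapply(prof, function(t) sum(essential %in% t), numeric(1))
  y0 <- switch(rule,
    OR = as.numeric(hits >= 1),
    AND = as.numeric(hits == nEssential),
    weighted = hits / nEssential)
  y <- pmin(pmax(y0 + stats::rnorm(nDrugs, sd = sigma), 0), 1)
  names(y) <- drugs
  structure(list(kd = km, essential = essential, y = y, dss = y * 50,
                 rule = rule, sigma = sigma, seed = seed),
            class = "PlantedScreen")
}

#' @export
print.PlantedScreen <- function(x, ...) {
  cat("PlantedScreen:", length(drugNames(x$kd)), "drugs x",
      length(kinaseNames(x$kd)), "kinases; planted targets:",
      paste(x$essential, collapse = ", "),
      sprintf("(rule %s, sigma %.3g)\n", x$rule, x$sigma))
  invisible(x)
}

#' Generate a dose-response surface with planted Bliss excess
#'
#' Single-agent margins follow exact four-parameter logistic curves; each
#' combination cell is the Bliss independence expectation of the margins
#' plus a planted excess \code{delta} (percentage points) and Gaussian
#' noise. With \code{sigma = 0} the Bliss score of the surface (raw
#' margins) equals \code{delta} exactly.
#'
#' @param params1,params2 4PL parameters \code{c(L, U, slope, ec50)} of
#'   the two drugs.
#' @param delta planted uniform Bliss excess in percentage points.
#' @param sigma Gaussian noise sd (percentage points) on all cells.
#' @param n grid size including the zero dose (default 8, i.e. 7 nonzero
#'   doses).
#' @param doseRange nonzero dose range in nM (log-spaced).
#' @param seed RNG seed.
#' @return a \code{\link{DoseResponseMatrix-class}} with attributes
#'   \code{"delta"} and \code{"params"}.
#' @export
genSurface <- function(params1 = c(L = 0, U = 100, slope = 1, ec50 = 100),
                       params2 = c(L = 0, U = 90, slope = 1.2, ec50 = 300),
                       delta = 0, sigma = 0, n = 8,
                       doseRange = c(10, 10000), seed = 1) {
  set.seed(seed)
  doses <- c(0, exp(seq(log(doseRange[1]), log(doseRange[2]),
                        length.out = n - 1)))
  curve <- function(p, x)
    p[1] + (p[2] - p[1]) / (1 + (p[4] / x)^p[3])
  m1 <- c(0, curve(params1, doses[-1]))
  m2 <- c(0, curve(params2, doses[-1]))
  f1 <- m1 / 100
  f2 <- m2 / 100
  inh <- outer(f1, f2, function(a, b) a + b - a * b) * 100
  inh[-1, -1] <- inh[-1, -1] + delta
  inh[1, ] <- m2
  inh[, 1] <- m1
  if (sigma > 0)
    inh <- inh + matrix(stats::rnorm(length(inh), sd = sigma), nrow(inh))
  out <- DoseResponseMatrix("synthA", "synthB", doses, doses, inh)
  attr(out, "delta") <- delta
  attr(out, "params") <- list(params1, params2)
  out
}

demoEdges <- function() {
  data.frame(
    source = c("AURKB", "ZAK", "MAP2K3", "MAPK14", "CSF1R", "TGFB1"),
    target = c("TP53", "MAP2K3", "MAPK14", "TP53", "TGFB1", "TP53"),
    sign = c("inhibition", "activation", "activation", "inhibition",
             "activation", "activation"),
    stringsAsFactors = FALSE)
}

demoTargets <- function() {
  c(AURKB = 60, ZAK = 60, CSF1R = 50, MAP2K3 = 40, MAPK14 = 30,
    TGFB1 = 40, TP53 = 10, PKN1 = 80, PARP1 = 90)
}

#' Generate a signed signaling network (demo motif or random)
#'
#' The \code{"aurkb_zak_csf1r_demo"} motif is a fixed nine-gene network
#' engineered around a TP53 growth gate: AURKB inhibits TP53 directly; a
#' ZAK -> MAP2K3 -> MAPK14 (p38-like) branch provides a second TP53 sink,
#' so silencing AURKB and ZAK together de-represses TP53 super-additively;
#' CSF1R supports TP53 through a TGFB1 (TGF-beta-like) branch, so
#' silencing CSF1R starves TP53 and rescues growth; PKN1 and PARP1 are
#' input-less bystanders. \code{"random"} samples activation/inhibition
#' edges with bounded in-degree.
#'
#' @param motif \code{"aurkb_zak_csf1r_demo"} or \code{"random"}.
#' @param nGenes gene count for random mode.
#' @param seed RNG seed (random mode).
#' @param maxInDegree in-degree bound (random mode).
#' @return list: \code{network} (\code{\link{SignedNetwork-class}}),
#'   \code{targets} (named steady-state copy-number targets), \code{kd}
#'   (named degradation constants, per hour).
#' @export
genNetwork <- function(motif = c("aurkb_zak_csf1r_demo", "random"),
                       nGenes = 10, seed = 1, maxInDegree = 2) {
  motif <- match.arg(motif)
  if (motif == "aurkb_zak_csf1r_demo") {
    kd <- c(AURKB = 0.1, ZAK = 0.1, CSF1R = 0.1, MAP2K3 = 0.05,
            MAPK14 = 0.31, TGFB1 = 0.05, TP53 = 0.01, PKN1 = 0.1,
            PARP1 = 0.1)
    return(list(network = SignedNetwork(demoEdges()),
                targets = demoTargets(), kd = kd))
  }
  set.seed(seed)
  genes <- sprintf("G%02d", seq_len(nGenes))
  rows <- list()
  for (g in genes) {
    nIn <- sample(0:maxInDegree, 1)
    regs <- sample(setdiff(genes, g), nIn)
    for (r in regs)
      rows[[length(rows) + 1]] <- data.frame(
        source = r, target = g,
        sign = sample(c("activation", "inhibition"), 1),
        stringsAsFactors = FALSE)
  }
  ed <- if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(source = genes[1], target = genes[2], sign = "activation",
               stringsAsFactors = FALSE)
  targets <- stats::setNames(round(stats::runif(nGenes, 20, 120)), genes)
  kd <- stats::setNames(stats::runif(nGenes, 0.05, 0.3), genes)
  list(network = SignedNetwork(ed), targets = targets, kd = kd)
}

#' Build the calibrated demo signaling model
#'
#' Compiles the demo motif from \code{\link{genNetwork}}, attaches the
#' TP53-gated growth module, and calibrates production rates so the ODE
#' steady state matches the motif's expression targets.
#'
#' @param calibrate run \code{\link{calibrateRates}} (default TRUE).
#' @param tol calibration tolerance.
#' @param tdiv doubling time (hours).
#' @return a calibrated \code{\link{ReactionSystem-class}} with growth
#'   attached; attribute \code{"targets"} holds the expression targets.
#' @export
demoSignalingModel <- function(calibrate = TRUE, tol = 0.02, tdiv = 38) {
  gn <- genNetwork("aurkb_zak_csf1r_demo")
  genes <- names(gn$targets)
  sys <- compileReactions(gn$network, genes, kp = 5, kd = gn$kd,
                          sources = "roots")
  sys <- addGrowthModule(sys, tdiv = tdiv)
  if (calibrate) sys <- calibrateRates(sys, gn$targets, tol = tol)
  attr(sys, "targets") <- gn$targets
  sys
}
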