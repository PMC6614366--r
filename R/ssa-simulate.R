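#' Stochastic simulation of a growing, dividing cell population
#'
#' Exact Gillespie simulation of the compiled reaction system in every
#' cell of a population. When the growth module is attached, a cell
#' divides the instant its pGrowth count reaches the threshold; all
#' species (pGrowth included) are partitioned binomially between the two
#' daughters, and simultaneous-event ties are resolved division-first.
#' The population is capped by uniform random subsampling, with the
#' cumulative subsampling factor folded back into the reported cell
#' counts. Runs are bitwise reproducible for a fixed seed.
#'
#' @param sys a \code{\link{ReactionSystem-class}}.
#' @param init named initial per-cell counts; defaults to the rounded ODE
#'   steady state (and \code{pGrowth0} for pGrowth).
#' @param nCells initial number of cells.
#' @param tEnd simulated time (hours).
#' @param recordDt sampling interval of the output time series (hours).
#' @param cap population cap (cells) before subsampling.
#' @param seed optional RNG seed (\code{set.seed} is called when given).
#' @param maxDivLog number of division events to log for partitioning
#'   audits (0 = none).
#' @return object of class \code{SimulationResult}: \code{time},
#'   \code{cellCount} (subsampling-corrected), \code{meanExpr}
#'   (time x species per-cell means), \code{factor}, \code{nDivisions},
#'   \code{divisions} (mother / daughter1 / daughter2 counts).
#' @export
ssaSimulate <- function(sys, init = NULL, nCells = 1, tEnd = 250,
                        recordDt = 1, cap = 2000, seed = NULL,
                        maxDivLog = 0) {
  stopifnot(methods::is(sys, "ReactionSystem"), tEnd > 0, nCells >= 1)
  hasGrowth <- !is.na(sys@growth$tdiv)
  genes <- setdiff(sys@species, "pGrowth")
  if (is.null(init)) {
    ss <- odeTwin(sys)
    init <- round(ss[genes])
  }
  x0 <- integer(length(sys@species))
  names(x0) <- sys@species
  x0[names(init)] <- as.integer(round(init))
  if (hasGrowth) x0["pGrowth"] <- as.integer(sys@growth$pGrowth0)
  if (any(x0 < 0)) stop("negative initial counts")
  if (!is.null(seed)) set.seed(seed)
  growthIdx <- if (hasGrowth) match("pGrowth", sys@species) else 0L
  tp53Idx <- if (hasGrowth && !is.na(sys@growth$tp53))
    match(sys@growth$tp53, sys@species) else 0L
  aa <- sys@a; aa[is.na(aa)] <- 0L
  bb <- sys@b; bb[is.na(bb)] <- 0L
  res <- .ssaPopulationCpp(sys@stoich, sys@type, sys@k, aa, bb,
                           x0, as.integer(nCells), tEnd, recordDt,
                           as.integer(cap), growthIdx, tp53Idx,
                           if (hasGrowth) sys@growth$Q else 0,
                           if (hasGrowth) sys@growth$beta else 1,
                           if (hasGrowth) sys@growth$theta else Inf,
                           as.integer(maxDivLog))
  colnames(res$meanExpr) <- sys@species
  res$species <- sys@species
  res$tEnd <- tEnd
  class(res) <- "SimulationResult"
  res
}

#' @export
print.SimulationResult <- function(x, ...) {
  cat("SimulationResult:", length(x$time), "samples to t =", x$tEnd, "h;",
      "final cell count", format(round(x$cellCount[length(x$cellCount)], 1)),
      "(", x$nDivisions, "divisions )\n")
  invisible(x)
}

#' Viability readout of a simulation
#'
#' Mean (subsampling-corrected) cell count over the last \code{window}
#' hours of the run.
#'
#' @param res a \code{SimulationResult}.
#' @param window trailing window in hours (default 50).
#' @return mean cell count.
#' @export
viabilitySummary <- function(res, window = 50) {
  sel <- res$time >= max(res$time) - window
  mean(res$cellCount[sel])
}

#' Per-gene long-run mean expression of a simulation
#'
#' Per-cell mean copy numbers averaged over the last \code{window} hours.
#'
#' @inheritParams viabilitySummary
#' @return named numeric vector over species.
#' @export
longRunMeans <- function(res, window = 50) {
  sel <- res$time >= max(res$time) - window
  colMeans(res$meanExpr[sel, , drop = FALSE])
}

#' Simulated gene-silencing experiment with normalized viability
#'
#' Runs the perturbed system (\code{\link{silenceGenes}}; silenced genes
#' start at zero copies) and the unperturbed control with paired seeds,
#' and reports the ratio of mean viable-cell counts over the trailing
#' window (perturbed / control), averaged over \code{nRuns} replicate
#' runs. The control normalizes to 1 by construction.
#'
#' @param sys the calibrated, growth-enabled
#'   \code{\link{ReactionSystem-class}}.
#' @param genes genes to silence.
#' @param mode \code{"knockout"} (remove production) or
#'   \code{"knockdown"} (scale production by \code{1 - eff}).
#' @param eff knock-down efficiency.
#' @param nRuns replicate runs (default 10).
#' @param tEnd,window simulation horizon and viability window (hours).
#' @param nCells,cap initial cells and population cap per run.
#' @param seed base seed; run r uses \code{seed + r} for both arms.
#' @param init named initial counts (defaults to the ODE steady state of
#'   the control).
#' @param control optional precomputed per-run control counts (from a
#'   previous call's \code{control_counts}) to avoid re-simulating.
#' @return list: \code{viability} (normalized), \code{perturbed_counts},
#'   \code{control_counts} (per-run viability summaries), \code{se}
#'   (standard error of the normalized viability over runs).
#' @export
knockoutExperiment <- function(sys, genes, mode = c("knockout", "knockdown"),
                               eff = 0.8, nRuns = 10, tEnd = 250,
                               window = 50, nCells = 8, cap = 150,
                               seed = 1, init = NULL, control = NULL) {
  mode <- match.arg(mode)
  pert <- silenceGenes(sys, genes, mode = mode, eff = eff)
  if (is.null(init)) {
    ss <- odeTwin(sys)
    init <- round(ss)
  }
  initPert <- init
  if (mode == "knockout") initPert[intersect(genes, names(initPert))] <- 0
  runArm <- function(s, arm, armInit, sd)
    viabilitySummary(ssaSimulate(s, init = armInit, nCells = nCells,
                                 tEnd = tEnd, cap = cap, seed = sd),
                     window = window)
  pc <- numeric(nRuns)
  cc <- if (is.null(control)) numeric(nRuns) else control
  for (r in seq_len(nRuns)) {
    pc[r] <- runArm(pert, "perturbed", initPert, seed + r)
    if (is.null(control)) cc[r] <- runArm(sys, "control", init, seed + r)
  }
  ratio <- pc / cc
  list(viability = mean(pc) / mean(cc),
       perturbed_counts = pc, control_counts = cc,
       se = stats::sd(ratio) / sqrt(nRuns))
}
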