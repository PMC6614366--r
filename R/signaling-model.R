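#' Select differentially expressed genes for network construction
#'
#' Normalized deviation of a cell line's expression from the panel mean,
#' \code{D = |expr_self - mean| / mean}; genes with \code{D > 1}
#' (strictly) are flagged for inclusion in the signaling network.
#'
#' @param exprSelf named expression vector for the modeled cell line.
#' @param exprPanelMean named per-gene mean expression over the cell-line
#'   panel (> 0).
#' @param threshold inclusion threshold on D (default 1, strict).
#' @return data.frame with columns gene, D, included.
#' @export
selectNetworkGenes <- function(exprSelf, exprPanelMean, threshold = 1) {
  genes <- intersect(names(exprSelf), names(exprPanelMean))
  m <- exprPanelMean[genes]
  if (any(m <= 0)) stop("zero or negative panel mean for: ",
                        paste(genes[m <= 0], collapse = ", "))
  D <- abs(exprSelf[genes] - m) / m
  data.frame(gene = genes, D = unname(D), included = unname(D > threshold),
             stringsAsFactors = FALSE)
}

emptyGrowth <- function() {
  list(tdiv = NA_real_, Q = NA_real_, beta = NA_real_,
       pGrowth0 = NA_real_, theta = NA_real_, tp53 = NA_character_)
}

#' Compile a signed network into a stochastic reaction system
#'
#' Each activation edge A -> B becomes a production reaction for B driven
#' by A's copy number (the source-consuming conversion \code{A -> B} with
#' propensity \code{kp(B) * X_A} by default, or the catalytic
#' \code{A -> A + B} via \code{form = "catalytic"}); each inhibition edge
#' B -| C becomes the annihilation \code{B + C -> 0} with propensity
#' \code{kd(C) * X_B * X_C}; every gene gets the self-degradation
#' \code{A -> 0} at \code{kd(A) * X_A}. Because the interaction scheme
#' itself has no production term, constant sources \code{0 -> A} at rate
#' \code{kp(A)} are added for genes without an activating input by
#' default (\code{sources = "roots"}) so the system has a nontrivial
#' steady state; \code{"all"}/\code{"none"} are available. Edges touching
#' genes outside the selected set are dropped with a warning; genes
#' listed in \code{keep} are retained regardless of selection.
#'
#' @param net a \code{\link{SignedNetwork-class}}.
#' @param genes character vector of selected genes.
#' @param keep hub genes always kept when present in the network
#'   (default AURKB, ZAK, CSF1R, TP53).
#' @param kp,kd per-gene production and degradation rate constants
#'   (per hour); scalar or named vector.
#' @param form reaction form for activation edges.
#' @param sources which genes receive a constant production source.
#' @return a \code{\link{ReactionSystem-class}} (growth module off; see
#'   \code{\link{addGrowthModule}}).
#' @export
compileReactions <- function(net, genes,
                             keep = c("AURKB", "ZAK", "CSF1R", "TP53"),
                             kp = 10, kd = 0.1,
                             form = c("consuming", "catalytic"),
                             sources = c("roots", "all", "none")) {
  form <- match.arg(form)
  sources <- match.arg(sources)
  ed <- networkEdges(net)
  netGenes <- unique(c(ed$source, ed$target))
  species <- sort(unique(c(genes, intersect(keep, netGenes))))
  if (length(species) == 0) stop("no genes selected")
  drop <- !(ed$source %in% species & ed$target %in% species)
  if (any(drop)) {
    warning(sum(drop), " edge(s) referencing unselected genes dropped")
    ed <- ed[!drop, , drop = FALSE]
  }
  expand <- function(v) {
    if (length(v) == 1 && is.null(names(v)))
      return(stats::setNames(rep(v, length(species)), species))
    if (!all(species %in% names(v)))
      stop("named rate vector must cover all species")
    v[species]
  }
  kp <- expand(kp)
  kd <- expand(kd)
  ns <- length(species)
  rows <- list()
  addRx <- function(stoich, type, k, a, b, kref) {
    rows[[length(rows) + 1]] <<- list(stoich = stoich, type = type, k = k,
                                      a = a, b = b, kref = kref)
  }
  idx <- function(g) match(g, species)
  for (i in seq_len(nrow(ed))) {
    s <- idx(ed$source[i]); tg <- idx(ed$target[i])
    st <- integer(ns)
    if (ed$sign[i] == "activation") {
      st[tg] <- st[tg] + 1L
      if (form == "consuming") st[s] <- st[s] - 1L
      addRx(st, 1L, kp[tg], s, NA_integer_, paste0("kp:", species[tg]))
    } else {
      st[s] <- -1L; st[tg] <- st[tg] - 1L
      addRx(st, 2L, kd[tg], s, tg, paste0("kd:", species[tg]))
    }
  }
  for (g in seq_len(ns)) {
    st <- integer(ns); st[g] <- -1L
    addRx(st, 1L, kd[g], g, NA_integer_, paste0("kd:", species[g]))
  }
  hasInput <- species %in% ed$target[ed$sign == "activation"]
  srcGenes <- switch(sources, roots = which(!hasInput),
                     all = seq_len(ns), none = integer(0))
  for (g in srcGenes) {
    st <- integer(ns); st[g] <- 1L
    addRx(st, 0L, kp[g], NA_integer_, NA_integer_, paste0("kp:", species[g]))
  }
  stoich <- do.call(rbind, lapply(rows, `[[`, "stoich"))
  colnames(stoich) <- species
  methods::new("ReactionSystem",
    species = species,
    stoich = stoich,
    type = vapply(rows, `[[`, integer(1), "type"),
    k = vapply(rows, `[[`, numeric(1), "k"),
    a = vapply(rows, `[[`, integer(1), "a"),
    b = vapply(rows, `[[`, integer(1), "b"),
    kref = vapply(rows, `[[`, character(1), "kref"),
    kp = kp, kd = kd, growth = emptyGrowth())
}

#' Attach the TP53-gated growth and division module
#'
#' Adds the pGrowth species whose birth reaction has propensity
#' \code{pGrowth * (ln2 / tdiv) * f(TP53)}, with the decreasing Hill gate
#' \code{f(x) = 1 / (1 + (x / Q)^beta)} (\code{f(0) = 1},
#' \code{f(Q) = 0.5}). A cell divides instantly once pGrowth reaches
#' \code{theta}; at division every species (pGrowth included) is split
#' binomially between the daughters. With \code{theta = 2 * pGrowth0}
#' and low TP53, the population doubling time is \code{tdiv}.
#'
#' @param sys a \code{\link{ReactionSystem-class}}.
#' @param tdiv doubling time in hours (default 38, an MDA-MB-231-like
#'   value).
#' @param Q Hill threshold in molecules (default 65).
#' @param beta Hill exponent (default 7).
#' @param pGrowth0 pGrowth copies at birth (default 100).
#' @param theta division threshold (default \code{2 * pGrowth0}).
#' @param tp53 species gating growth (\code{NA} for ungated growth).
#' @return the extended \code{ReactionSystem}.
#' @export
addGrowthModule <- function(sys, tdiv = 38, Q = 65, beta = 7,
                            pGrowth0 = 100, theta = 2 * pGrowth0,
                            tp53 = "TP53") {
  stopifnot(methods::is(sys, "ReactionSystem"))
  if ("pGrowth" %in% sys@species) stop("growth module already attached")
  if (!is.na(tp53) && !tp53 %in% sys@species)
    tp53 <- NA_character_
  species <- c(sys@species, "pGrowth")
  ns <- length(species)
  stoich <- cbind(sys@stoich, 0L)
  gRow <- integer(ns); gRow[ns] <- 1L
  stoich <- rbind(stoich, gRow)
  dimnames(stoich) <- list(NULL, species)
  methods::new("ReactionSystem",
    species = species, stoich = stoich,
    type = c(sys@type, 3L), k = c(sys@k, log(2) / tdiv),
    a = c(sys@a, ns), b = c(sys@b, NA_integer_),
    kref = c(sys@kref, "growth"),
    kp = sys@kp, kd = sys@kd,
    growth = list(tdiv = tdiv, Q = Q, beta = beta, pGrowth0 = pGrowth0,
                  theta = theta, tp53 = tp53))
}

# Rebuild per-reaction rate constants from the named kp/kd parameters.
syncRates <- function(sys) {
  for (r in seq_along(sys@k)) {
    ref <- sys@kref[r]
    if (ref == "growth") next
    parts <- strsplit(ref, ":", fixed = TRUE)[[1]]
    sys@k[r] <- if (parts[1] == "kp") sys@kp[parts[2]] else sys@kd[parts[2]]
  }
  sys
}

#' Calibrate production rates to target steady-state expression
#'
#' Automates the manual tuning of per-gene degradation-to-production
#' ratios: iteratively rescales each gene's production constant kp by the
#' ratio of its target to its current ODE steady-state level (computed by
#' \code{\link{odeTwin}}, including growth dilution when the growth
#' module is attached) until every gene is within \code{tol} relative
#' error. A second pass on a calibrated system changes rates by less than
#' \code{tol} (idempotence).
#'
#' @param sys a \code{\link{ReactionSystem-class}}.
#' @param target named positive steady-state copy-number targets (one per
#'   gene).
#' @param tol relative-error tolerance (default 0.05).
#' @param maxIter iteration cap.
#' @return the calibrated system, with attribute \code{"achieved"}
#'   holding the relative errors.
#' @export
calibrateRates <- function(sys, target, tol = 0.05, maxIter = 50) {
  genes <- setdiff(sys@species, "pGrowth")
  if (!all(genes %in% names(target)))
    stop("targets required for all genes")
  target <- target[genes]
  if (any(target <= 0)) stop("targets must be positive")
  # Flux balance at the target state is linear in the kp vector (each
  # gene's production is kp_g times known activator levels; each
  # source-consuming activation edge drains its source at kp_target *
  # X_source), so the exact kp solving steady state = target is obtained
  # directly, then verified by the ODE twin.
  sys@kp[genes] <- solveProductionRates(sys, target)
  sys <- syncRates(sys)
  ss <- NULL
  for (it in seq_len(maxIter)) {
    ss <- odeTwin(sys, init = if (is.null(ss)) target else ss)
    relErr <- abs(ss[genes] - target) / target
    if (all(relErr <= tol)) {
      attr(sys, "achieved") <- relErr
      return(sys)
    }
    ratio <- sqrt(target / pmax(ss[genes], 1e-9))   # damped refinement
    sys@kp[genes] <- sys@kp[genes] * pmin(pmax(ratio, 0.5), 2)
    sys <- syncRates(sys)
  }
  stop("calibration did not converge for: ",
       paste(genes[relErr > tol], collapse = ", "))
}

# Solve the per-gene production constants that balance fluxes exactly at
# the target state. Rows: gene balance; unknowns: kp per gene.
solveProductionRates <- function(sys, target) {
  genes <- names(target)
  n <- length(genes)
  A <- matrix(0, n, n, dimnames = list(genes, genes))
  L <- numeric(n)
  hasGrowth <- !is.na(sys@growth$tdiv)
  mu <- 0
  if (hasGrowth) {
    f <- if (is.na(sys@growth$tp53)) 1 else
      1 / (1 + (target[sys@growth$tp53] / sys@growth$Q)^sys@growth$beta)
    mu <- log(2) / sys@growth$tdiv * f
  }
  for (r in seq_along(sys@type)) {
    ref <- strsplit(sys@kref[r], ":", fixed = TRUE)[[1]]
    if (ref[1] == "growth") next
    st <- sys@stoich[r, ]
    touched <- which(st != 0L)
    if (ref[1] == "kp") {
      g <- ref[2]
      # propensity = kp_g * X_a (activation) or kp_g (source)
      lvl <- if (sys@type[r] == 0L) 1 else target[sys@species[sys@a[r]]]
      for (s in touched) {
        gs <- sys@species[s]
        A[gs, g] <- A[gs, g] + st[s] * lvl
      }
    } else {
      # degradation / inhibition propensities are fully known at target
      prop <- switch(as.character(sys@type[r]),
        "1" = sys@kd[ref[2]] * target[sys@species[sys@a[r]]],
        "2" = sys@kd[ref[2]] * target[sys@species[sys@a[r]]] *
              target[sys@species[sys@b[r]]])
      for (s in touched)
        L[match(sys@species[s], genes)] <-
          L[match(sys@species[s], genes)] - st[s] * prop
    }
  }
  L <- L + mu * target
  kp <- tryCatch(solve(A, L), error = function(e)
    stop("target state infeasible: ", conditionMessage(e)))
  if (any(!is.finite(kp)) || any(kp <= 0))
    stop("target state infeasible: requires non-positive production for ",
         paste(genes[kp <= 0], collapse = ", "))
  stats::setNames(kp, genes)
}

#' Silence genes in a reaction system
#'
#' Knock-out removes the gene's production reactions entirely (CRISPR-
#' like); knock-down scales their rate constants by \code{1 - eff}
#' (siRNA-like, default efficiency 0.8). Degradation and outgoing
#' interaction reactions are untouched.
#'
#' @param sys a \code{\link{ReactionSystem-class}}.
#' @param genes genes to silence (must be in the system).
#' @param mode \code{"knockout"} or \code{"knockdown"}.
#' @param eff knock-down efficiency in (0, 1].
#' @return the perturbed system.
#' @export
silenceGenes <- function(sys, genes, mode = c("knockout", "knockdown"),
                         eff = 0.8) {
  mode <- match.arg(mode)
  missing <- setdiff(genes, sys@species)
  if (length(missing))
    stop("gene(s) absent from the system: ", paste(missing, collapse = ", "))
  prodRefs <- paste0("kp:", genes)
  hit <- sys@kref %in% prodRefs
  if (mode == "knockout") {
    keepRows <- !hit
    methods::new("ReactionSystem",
      species = sys@species, stoich = sys@stoich[keepRows, , drop = FALSE],
      type = sys@type[keepRows], k = sys@k[keepRows],
      a = sys@a[keepRows], b = sys@b[keepRows], kref = sys@kref[keepRows],
      kp = sys@kp, kd = sys@kd, growth = sys@growth)
  } else {
    sys@k[hit] <- sys@k[hit] * (1 - eff)
    sys
  }
}
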