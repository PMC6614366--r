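#' Deterministic (ODE) twin of a reaction system
#'
#' Mass-action rate equations for the same reaction set, integrated to
#' steady state with \code{deSolve::lsoda} and verified by the residual
#' of the rate equations at the final state. Gene counts are continuous;
#' when the growth module is attached, cell division enters only through
#' a dilution term \code{mu * X} with
#' \code{mu = (ln2 / tdiv) * f(TP53)} (division halves per-cell counts
#' on average, so the twin would overestimate the stochastic per-cell
#' means without it). Systems without a growth module have no dilution,
#' so closed-form birth-death steady states hold exactly.
#'
#' @param sys a \code{\link{ReactionSystem-class}}.
#' @param init named initial gene levels; defaults to \code{kp / kd}.
#' @param tMax integration horizon (hours) before giving up.
#' @param tol convergence tolerance on \code{max |dX| / max(1, max X)}.
#' @return named numeric vector of per-gene steady-state levels.
#' @export
odeTwin <- function(sys, init = NULL, tMax = 50000, tol = 1e-7) {
  genes <- setdiff(sys@species, "pGrowth")
  gi <- match(genes, sys@species)
  keep <- sys@type != 3L
  S <- sys@stoich[keep, gi, drop = FALSE]
  type <- sys@type[keep]; k <- sys@k[keep]
  a <- match(sys@species[sys@a[keep]], genes)
  b <- match(sys@species[sys@b[keep]], genes)
  hasGrowth <- !is.na(sys@growth$tdiv)
  tp53i <- if (hasGrowth && !is.na(sys@growth$tp53))
    match(sys@growth$tp53, genes) else NA_integer_
  deriv <- function(t, x, p) {
    props <- ifelse(type == 0L, k,
             ifelse(type == 1L, k * x[a], k * x[a] * x[b]))
    dx <- as.vector(crossprod(S, props))
    if (hasGrowth) {
      f <- if (is.na(tp53i)) 1 else
        1 / (1 + (max(x[tp53i], 0) / sys@growth$Q)^sys@growth$beta)
      dx <- dx - (log(2) / sys@growth$tdiv) * f * x
    }
    list(dx)
  }
  x <- if (is.null(init)) (sys@kp / sys@kd)[genes] else {
    stopifnot(all(genes %in% names(init)))
    pmax(as.numeric(init[genes]), 0)
  }
  names(x) <- genes
  t0 <- 0
  chunk <- 200
  repeat {
    sol <- deSolve::lsoda(x, c(0, chunk), deriv, NULL,
                          rtol = 1e-8, atol = 1e-8, maxsteps = 50000)
    x <- pmax(sol[nrow(sol), -1], 0)
    names(x) <- genes
    t0 <- t0 + chunk
    res <- max(abs(unlist(deriv(0, x, NULL))))
    if (res < tol * max(1, max(x))) break
    if (t0 >= tMax)
      stop("no steady state within horizon; residual = ", format(res),
           " at state ", paste(round(x, 3), collapse = ","))
    chunk <- min(chunk * 2, 5000)
  }
  x
}

#' Scaled parameter sensitivities at the ODE steady state
#'
#' For every per-gene production (kp) and degradation (kd) constant, the
#' scaled sensitivity of each gene's steady-state level,
#' \code{S(i, p) = (p / X_i) * dX_i / dp}, is estimated by central finite
#' differences (default +/- 1 percent); the report carries the mean of
#' \code{|S(i, p)|} over all genes per parameter, ranked. Parameters for
#' which a perturbed steady state cannot be found are marked undefined
#' (NA).
#'
#' @param sys a calibrated \code{\link{ReactionSystem-class}}.
#' @param perturbation relative perturbation h (default 0.01).
#' @return data.frame: parameter, gene, type (kp/kd),
#'   mean_abs_sensitivity, sorted decreasing; attribute
#'   \code{"matrix"} holds the full genes x parameters sensitivity
#'   matrix.
#' @export
parameterSensitivity <- function(sys, perturbation = 0.01) {
  genes <- setdiff(sys@species, "pGrowth")
  base <- odeTwin(sys)
  params <- expand.grid(type = c("kp", "kd"), gene = genes,
                        stringsAsFactors = FALSE)
  h <- perturbation
  sens <- matrix(NA_real_, length(genes), nrow(params),
                 dimnames = list(genes, paste(params$type, params$gene,
                                              sep = ":")))
  for (p in seq_len(nrow(params))) {
    perturbed <- function(mult) {
      s2 <- sys
      if (params$type[p] == "kp")
        s2@kp[params$gene[p]] <- s2@kp[params$gene[p]] * mult
      else
        s2@kd[params$gene[p]] <- s2@kd[params$gene[p]] * mult
      s2 <- syncRates(s2)
      tryCatch(odeTwin(s2, init = base), error = function(e) NULL)
    }
    up <- perturbed(1 + h)
    dn <- perturbed(1 - h)
    if (is.null(up) || is.null(dn)) next
    sens[, p] <- (up - dn) / (2 * h * pmax(base, 1e-12))
  }
  out <- data.frame(parameter = colnames(sens), gene = params$gene,
                    type = params$type,
                    mean_abs_sensitivity = colMeans(abs(sens)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_abs_sensitivity), ]
  rownames(out) <- NULL
  attr(out, "matrix") <- sens
  out
}
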