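#' Fit a four-parameter logistic dose-response curve
#'
#' Bounded least-squares fit of
#' \code{y = L + (U - L) / (1 + (EC50 / x)^s)} to percentage-inhibition
#' responses at positive doses (nM). Bounds absorb screening noise beyond
#' [0, 100]: L in [-20, 50], U in [0, 150], slope in (0, 10], EC50 within
#' a decade of the assayed dose range. If the fit does not converge (or
#' the responses are constant), the curve falls back to monotone
#' interpolation of the raw responses with a warning.
#'
#' @param doses positive dose vector (nM), >= 4 distinct values for a
#'   proper fit.
#' @param responses percent inhibition at \code{doses}.
#' @return object of class \code{CurveFit4PL}: parameters \code{L},
#'   \code{U}, \code{slope}, \code{ec50}, \code{residual} (sum of squared
#'   residuals), \code{fallback} flag and the data.
#' @export
fit4PL <- function(doses, responses) {
  stopifnot(length(doses) == length(responses), all(doses > 0))
  out <- list(L = NA_real_, U = NA_real_, slope = NA_real_, ec50 = NA_real_,
              residual = NA_real_, fallback = FALSE,
              doses = doses, responses = responses)
  class(out) <- "CurveFit4PL"
  if (length(unique(doses)) < 4 || diff(range(responses)) < 1e-8) {
    warning("degenerate dose-response data; using monotone interpolation")
    out$fallback <- TRUE
    return(out)
  }
  lo <- c(L = -20, U = 0, slope = 1e-6, ec50 = min(doses) / 10)
  hi <- c(L = 50, U = 150, slope = 10, ec50 = max(doses) * 10)
  mid <- min(responses) + diff(range(responses)) / 2
  ec0 <- tryCatch(exp(stats::approx(responses, log(doses), xout = mid,
                                    ties = mean)$y),
                  error = function(e) NA_real_)
  if (!is.finite(ec0)) ec0 <- exp(mean(log(range(doses))))
  start <- c(L = max(lo["L"], min(responses)),
             U = min(hi["U"], max(responses)),
             slope = 1, ec0)
  start <- pmin(pmax(start, lo + 1e-9), hi - 1e-9)
  names(start) <- names(lo)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      responses ~ L + (U - L) / (1 + (ec50 / doses)^slope),
      start = as.list(start), lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("4PL fit did not converge; using monotone interpolation")
    out$fallback <- TRUE
    return(out)
  }
  cf <- stats::coef(fit)
  out$L <- unname(cf["L"]); out$U <- unname(cf["U"])
  out$slope <- unname(cf["slope"]); out$ec50 <- unname(cf["ec50"])
  out$residual <- sum(stats::residuals(fit)^2)
  out
}

#' Evaluate a fitted 4PL curve (or its interpolation fallback)
#'
#' @param fit a \code{CurveFit4PL} from \code{\link{fit4PL}}.
#' @param x doses (nM) at which to evaluate.
#' @return predicted percent inhibition.
#' @export
predict4PL <- function(fit, x) {
  if (fit$fallback) {
    ord <- order(fit$doses)
    return(stats::approx(fit$doses[ord], fit$responses[ord], xout = x,
                         rule = 2, ties = mean)$y)
  }
  fit$L + (fit$U - fit$L) / (1 + (fit$ec50 / x)^fit$slope)
}

#' @export
print.CurveFit4PL <- function(x, ...) {
  if (x$fallback) {
    cat("CurveFit4PL (interpolation fallback,", length(x$doses), "doses)\n")
  } else {
    cat(sprintf("CurveFit4PL: L=%.3g U=%.3g slope=%.3g EC50=%.4g nM (SSR %.3g)\n",
                x$L, x$U, x$slope, x$ec50, x$residual))
  }
  invisible(x)
}

#' Bliss excess-volume synergy score of a dose-response matrix
#'
#' Averages, over the grid of nonzero dose combinations, the difference
#' between the observed combination inhibition and the Bliss independence
#' expectation computed from the single-agent margins. Inhibition enters
#' as fractions (percent / 100); the default expectation is probabilistic
#' independence \code{f1 + f2 - f1*f2}, with the plain product
#' \code{f1*f2} available via \code{literalProduct = TRUE}. The score is
#' returned on the percentage-point scale.
#'
#' @param m a \code{\link{DoseResponseMatrix-class}} whose first row and
#'   column are the single-agent margins.
#' @param useFittedMargins smooth the margins through
#'   \code{\link{fit4PL}} before scoring (default), or use the raw
#'   margins.
#' @param literalProduct use the plain product expectation instead of
#'   Bliss independence.
#' @return list of class \code{SynergyScore}: \code{drug1}, \code{drug2},
#'   \code{method = "bliss"}, \code{score} (percentage points), \code{n}
#'   (nonzero grid cells).
#' @export
blissScore <- function(m, useFittedMargins = TRUE, literalProduct = FALSE) {
  stopifnot(is(m, "DoseResponseMatrix"))
  inh <- m@inhibition
  if (m@conc1[1] != 0 || m@conc2[1] != 0)
    stop("dose matrix must include the zero dose of each drug")
  n1 <- length(m@conc1) - 1
  n2 <- length(m@conc2) - 1
  if (n1 < 1 || n2 < 1) stop("need at least one nonzero dose per drug")
  marg1 <- inh[-1, 1]
  marg2 <- inh[1, -1]
  if (anyNA(marg1) || anyNA(marg2)) stop("missing single-agent margin")
  if (useFittedMargins && n1 >= 4 && n2 >= 4) {
    f1 <- fit4PL(m@conc1[-1], marg1)
    f2 <- fit4PL(m@conc2[-1], marg2)
    marg1 <- predict4PL(f1, m@conc1[-1])
    marg2 <- predict4PL(f2, m@conc2[-1])
  }
  fc <- inh[-1, -1, drop = FALSE] / 100
  f1 <- marg1 / 100
  f2 <- marg2 / 100
  expect <- if (literalProduct) outer(f1, f2) else
    outer(f1, f2, function(a, b) a + b - a * b)
  score <- mean(fc - expect) * 100
  structure(list(drug1 = m@drug1, drug2 = m@drug2, method = "bliss",
                 score = score, n = n1 * n2), class = "SynergyScore")
}

#' Highest-single-agent (HSA) synergy score
#'
#' \code{S = y_combination - max(y1, y2)}: the gain of the combination
#' over the better single treatment, in percentage-inhibition points.
#' Vectorized over replicates.
#'
#' @param yComb combination percent inhibition.
#' @param y1,y2 single-agent percent inhibition.
#' @return numeric HSA score(s).
#' @export
hsaScore <- function(yComb, y1, y2) yComb - pmax(y1, y2)

#' Multiplicative siRNA double-knockdown synergy score
#'
#' For each cross-drug target pair, the excess of the observed double
#' knockdown inhibition over the multiplicative expectation of the two
#' single knockdowns (all as fractions in [0, 1]); the pair scores are
#' averaged and reported on the percentage scale.
#'
#' @param yPair double-knockdown inhibition fractions, one per target
#'   pair.
#' @param y1,y2 matching single-knockdown fractions.
#' @return mean synergy score x 100 (percentage points).
#' @export
sirnaPairSynergy <- function(yPair, y1, y2) {
  stopifnot(length(yPair) == length(y1), length(y1) == length(y2))
  if (length(yPair) == 0) stop("empty target-pair set")
  mean(yPair - y1 * y2) * 100
}

#' Percent gene expression from qPCR cross-points
#'
#' Housekeeping-corrected knockdown efficiency:
#' \code{100 * 0.5^(Cp1 - Cp2) / 0.5^(Cp3 - Cp4)}, where Cp1/Cp2 are the
#' target-gene cross-points after/before knockdown and Cp3/Cp4 those of
#' the housekeeping gene.
#'
#' @param cp1,cp2,cp3,cp4 qPCR cross-point cycle numbers.
#' @return percent remaining expression.
#' @export
qpcrPercentExpression <- function(cp1, cp2, cp3, cp4) {
  stopifnot(all(is.finite(c(cp1, cp2, cp3, cp4))))
  100 * 0.5^(cp1 - cp2) / 0.5^(cp3 - cp4)
}

#' Viability and cytotoxicity from CellTiter-Glo / CellTox Green readouts
#'
#' Viability is the day-5 to day-1 CellTiter-Glo ratio; cytotoxicity is
#' the day-5 CellTox Green death readout divided by that viability. When
#' positive/negative control viabilities are supplied, percent inhibition
#' is derived by normalizing between them.
#'
#' @param ctgDay1,ctgDay5 CellTiter-Glo luminescence at day 1 and day 5
#'   (> 0 at day 1).
#' @param ctxDay5 CellTox Green readout at day 5.
#' @param negCtrl,posCtrl optional control viabilities (negative = full
#'   growth, positive = full kill).
#' @return list with \code{viability}, \code{cytotoxicity} and, when
#'   controls are given, \code{percent_inhibition}.
#' @export
crisprViabilityCytotoxicity <- function(ctgDay1, ctgDay5, ctxDay5,
                                        negCtrl = NULL, posCtrl = NULL) {
  if (any(ctgDay1 <= 0)) stop("day-1 CellTiter-Glo readout must be positive")
  viability <- ctgDay5 / ctgDay1
  cytotoxicity <- ctxDay5 / viability
  out <- list(viability = viability, cytotoxicity = cytotoxicity)
  if (!is.null(negCtrl) && !is.null(posCtrl))
    out$percent_inhibition <- 100 * (negCtrl - viability) / (negCtrl - posCtrl)
  out
}

#' @export
print.SynergyScore <- function(x, ...) {
  cat(sprintf("SynergyScore [%s] %s + %s: %.3f (n = %d)\n",
              x$method, x$drug1, x$drug2, x$score, x$n))
  invisible(x)
}

#' Score a batch of dose-response matrices
#'
#' Computes the Bliss score of every matrix (replicates scored separately
#' and also averaged per pair) plus the HSA score at the maximal assayed
#' doses.
#'
#' @param matrices list of \code{\link{DoseResponseMatrix-class}} objects.
#' @param ... passed to \code{\link{blissScore}}.
#' @return data.frame: drug1, drug2, replicate, bliss, hsa_at_max_dose,
#'   plus a \code{"pairMeans"} attribute with per-pair averaged Bliss.
#' @export
scoreDoseMatrices <- function(matrices, ...) {
  rows <- lapply(seq_along(matrices), function(i) {
    m <- matrices[[i]]
    b <- blissScore(m, ...)
    inh <- m@inhibition
    hsa <- hsaScore(inh[nrow(inh), ncol(inh)],
                    inh[nrow(inh), 1], inh[1, ncol(inh)])
    data.frame(drug1 = m@drug1, drug2 = m@drug2, replicate = i,
               bliss = b$score, hsa_at_max_dose = hsa,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  means <- stats::aggregate(bliss ~ drug1 + drug2, out, mean)
  pairkey <- paste(out$drug1, out$drug2, sep = "\r")
  out$replicate <- stats::ave(seq_len(nrow(out)), pairkey, FUN = seq_along)
  attr(out, "pairMeans") <- means
  out
}
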