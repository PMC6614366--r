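# Independent brute-force evaluator of the min-max averaging predictor.
# Works on explicit character sets with literal loops over all pairwise
# set relations -- deliberately naive, shares no code with the package's
# incidence-matrix implementation. Boundary conventions: no strict-subset
# training profile -> y_min = 0; no strict-superset -> y_max = 1.
bruteForceTimma <- function(d, profiles, y) {
  isEq <- vapply(profiles, function(p) setequal(p, d), logical(1))
  if (any(isEq)) return(mean(y[isEq]))
  isSub <- vapply(profiles, function(p) all(p %in% d) && !setequal(p, d),
                  logical(1))
  isSup <- vapply(profiles, function(p) all(d %in% p) && !setequal(p, d),
                  logical(1))
  if (!any(isSub)) {
    ymin <- 0
  } else {
    subI <- which(isSub)
    h <- subI[which.max(y[subI])]
    vals <- y[h]
    for (j in seq_along(profiles)) {
      if (j == h || !isSub[j]) next
      if (all(profiles[[h]] %in% profiles[[j]]) &&
          !setequal(profiles[[j]], profiles[[h]]) && y[j] < y[h])
        vals <- c(vals, y[j])
    }
    ymin <- mean(vals)
  }
  if (!any(isSup)) {
    ymax <- 1
  } else {
    supI <- which(isSup)
    l <- supI[which.min(y[supI])]
    vals <- y[l]
    for (j in seq_along(profiles)) {
      if (j == l || !isSup[j]) next
      if (all(profiles[[j]] %in% profiles[[l]]) &&
          !setequal(profiles[[j]], profiles[[l]]) && y[j] > y[l])
        vals <- c(vals, y[j])
    }
    ymax <- mean(vals)
  }
  (ymin + ymax) / 2
}

# Random small predictor instance (profiles may be empty to stress the
# boundary conventions).
randomTimmaInstance <- function(maxDrugs = 6, maxKinases = 5) {
  nk <- sample(2:maxKinases, 1)
  nd <- sample(2:maxDrugs, 1)
  uni <- paste0("t", seq_len(nk))
  profiles <- lapply(seq_len(nd), function(i) sample(uni, sample(0:nk, 1)))
  names(profiles) <- paste0("d", seq_len(nd))
  list(universe = uni, profiles = profiles, y = stats::runif(nd),
       d = sample(uni, sample(0:nk, 1)))
}

# Exact 4PL curve evaluations used to build fixtures.
logistic4 <- function(p, x) p[1] + (p[2] - p[1]) / (1 + (p[4] / x)^p[3])
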