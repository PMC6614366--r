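#' Binarize drug-target profiles from a Kd matrix
#'
#' A kinase is a positive target of a drug when its Kd is within
#' \code{fold} times the drug's minimal Kd across all kinases
#' (\code{Kd <= fold * min Kd}, drug-specific threshold). Missing Kd never
#' yields a target. The default 50-fold rule gives the permissive profiles
#' used for model fitting; see \code{\link{potentTargets}} for the
#' stricter deconvolution rule.
#'
#' @param kd a \code{\link{KdMatrix-class}}.
#' @param fold fold-threshold over the per-drug minimal Kd; >= 1.
#' @return named list mapping each drug to its character target set.
#' @export
binarizeTargets <- function(kd, fold = 50) {
  stopifnot(is(kd, "KdMatrix"), fold >= 1)
  m <- kdValues(kd)
  out <- lapply(seq_len(nrow(m)), function(i) {
    row <- m[i, ]
    if (!any(is.finite(row))) stop("drug without any finite Kd: ", rownames(m)[i])
    colnames(m)[which(row <= fold * min(row, na.rm = TRUE))]
  })
  stats::setNames(out, rownames(m))
}

#' Normalize raw drug sensitivity scores to [0, 1]
#'
#' Min-max normalization of non-negative DSS values so that the least
#' sensitive drug maps to 0 and the most sensitive to 1; order-preserving.
#'
#' @param dss named non-negative numeric vector of raw DSS values.
#' @return named numeric vector in [0, 1].
#' @export
normalizeDss <- function(dss) {
  stopifnot(is.numeric(dss), all(dss >= 0))
  rng <- range(dss)
  if (diff(rng) == 0) stop("degenerate screen: all DSS values equal")
  (dss - rng[1]) / diff(rng)
}

# Set profiles (list of character vectors) -> logical incidence matrix.
profilesToMatrix <- function(profiles, universe = NULL) {
  if (is.null(universe)) universe <- sort(unique(unlist(profiles)))
  m <- matrix(FALSE, length(profiles), length(universe),
              dimnames = list(names(profiles), universe))
  for (i in seq_along(profiles)) m[i, match(profiles[[i]], universe)] <- TRUE
  m
}

# Min-max averaging predictor on logical encodings.
# d: logical vector over the kinase universe; P: logical N x K training
# profiles; y: training sensitivities in [0, 1]. Boundary pseudo-drugs:
# the empty set acts as a subset anchor with y = 0, the full universe as a
# superset anchor with y = 1, so y_min/y_max are always defined.
timmaPredictCore <- function(d, P, y) {
  if (nrow(P) == 0) return(0.5)
  dm <- matrix(d, nrow(P), length(d), byrow = TRUE)
  equal <- rowSums(xor(P, dm)) == 0L
  if (any(equal)) return(mean(y[equal]))
  isSub <- rowSums(P & !dm) == 0L           # d_i subset of d (strict: !equal)
  isSup <- rowSums(dm & !P) == 0L           # d subset of d_i
  # y_min from the maximal-sensitivity strict-subset drug h
  if (!any(isSub)) {
    ymin <- 0
  } else {
    subIdx <- which(isSub)
    h <- subIdx[which.max(y[subIdx])]
    hm <- matrix(P[h, ], nrow(P), length(d), byrow = TRUE)
    supOfH <- rowSums(hm & !P) == 0L & rowSums(xor(P, hm)) > 0L
    j <- which(isSub & supOfH & y < y[h])
    j <- setdiff(j, h)
    ymin <- mean(c(y[h], y[j]))
  }
  # y_max from the minimal-sensitivity strict-superset drug l
  if (!any(isSup)) {
    ymax <- 1
  } else {
    supIdx <- which(isSup)
    l <- supIdx[which.min(y[supIdx])]
    lm <- matrix(P[l, ], nrow(P), length(d), byrow = TRUE)
    subOfL <- rowSums(P & !lm) == 0L & rowSums(xor(P, lm)) > 0L
    j <- which(isSup & subOfL & y > y[l])
    j <- setdiff(j, l)
    ymax <- mean(c(y[l], y[j]))
  }
  (ymin + ymax) / 2
}

#' Predict multi-target inhibition sensitivity by min-max averaging
#'
#' Set-theoretic sensitivity predictor: if the query target set equals a
#' training profile, the prediction is the mean sensitivity of the
#' matching drugs; otherwise it is the midpoint of a minimization average
#' over strict-subset profiles (anchored at the most sensitive subset
#' drug) and a maximization average over strict-superset profiles
#' (anchored at the least sensitive superset drug). The empty set (y = 0)
#' and the full kinase universe (y = 1) act as boundary pseudo-drugs so
#' the prediction is always defined.
#'
#' @param targets character target set (or logical vector over
#'   \code{universe}).
#' @param profiles named list of training target sets, or a logical
#'   drugs x kinases matrix.
#' @param y training sensitivities in [0, 1], aligned with
#'   \code{profiles}.
#' @param universe kinase universe; defaults to the union of profiles and
#'   query.
#' @return predicted sensitivity in [0, 1].
#' @export
predictSensitivity <- function(targets, profiles, y, universe = NULL) {
  if (is.list(profiles)) {
    if (is.null(universe))
      universe <- sort(unique(c(unlist(profiles), as.character(targets))))
    P <- profilesToMatrix(profiles, universe)
  } else {
    P <- profiles
    universe <- colnames(P)
  }
  stopifnot(length(y) == nrow(P), all(y >= 0 & y <= 1))
  d <- if (is.logical(targets)) targets else universe %in% targets
  timmaPredictCore(d, P, y)
}

# Mean leave-one-out absolute error of the predictor with profiles
# projected onto the candidate target set S (column index vector).
timmaLooError <- function(P, y, S) {
  Ps <- P[, S, drop = FALSE]
  n <- nrow(P)
  errs <- vapply(seq_len(n), function(i) {
    abs(y[i] - timmaPredictCore(Ps[i, ], Ps[-i, , drop = FALSE], y[-i]))
  }, numeric(1))
  mean(errs)
}

#' Select the essential target set of a drug screen
#'
#' Greedy forward-floating subset search over the kinase universe,
#' minimizing the mean leave-one-out absolute error of
#' \code{\link{predictSensitivity}} on the training screen: at each step
#' the kinase whose addition most reduces the error is added (ties broken
#' lexicographically by symbol), then removals that strictly improve the
#' error are applied. The search stops when no addition improves the
#' error or \code{maxSize} is reached, and is fully deterministic.
#'
#' @param profiles named list of binarized target sets (from
#'   \code{\link{binarizeTargets}}) or a logical drugs x kinases matrix.
#' @param y named normalized sensitivities in [0, 1] (one per drug).
#' @param maxSize maximum size of the selected set (default 20).
#' @param minImprove minimum leave-one-out error reduction an addition
#'   (or removal) must achieve to be accepted (default 0.01 on the
#'   normalized sensitivity scale); guards the search against chasing
#'   noise-level improvements.
#' @param universe kinase universe to search over.
#' @param seed recorded for provenance; the search itself is
#'   deterministic.
#' @return a \code{\link{TimmaModel-class}}.
#' @export
selectEssentialTargets <- function(profiles, y, maxSize = 20,
                                   minImprove = 0.01, universe = NULL,
                                   seed = NULL) {
  if (is.list(profiles)) {
    if (is.null(universe)) universe <- sort(unique(unlist(profiles)))
    P <- profilesToMatrix(profiles, universe)
  } else {
    P <- profiles
    universe <- colnames(P)
  }
  if (maxSize < 1) stop("maxSize must be >= 1")
  if (nrow(P) < 3) stop("need at least 3 drugs")
  maxSize <- min(maxSize, ncol(P))
  y <- y[rownames(P)]
  stopifnot(!anyNA(y))
  kinOrder <- order(colnames(P))        # lexicographic candidate order
  S <- integer(0)
  curErr <- Inf
  repeat {
    cand <- setdiff(kinOrder, S)
    if (length(cand) == 0 || length(S) >= maxSize) break
    addErr <- vapply(cand, function(k) timmaLooError(P, y, c(S, k)), numeric(1))
    best <- which.min(addErr)           # first min = lexicographic tie-break
    if (addErr[best] < curErr - minImprove || length(S) == 0) {
      S <- c(S, cand[best])
      curErr <- addErr[best]
    } else break
    # floating removal: drop any earlier pick whose removal improves LOO
    repeat {
      if (length(S) <= 2) break
      removable <- S[-length(S)]
      remErr <- vapply(removable, function(k) timmaLooError(P, y, setdiff(S, k)),
                       numeric(1))
      bst <- which.min(remErr)
      if (remErr[bst] < curErr - minImprove) {
        S <- setdiff(S, removable[bst])
        curErr <- remErr[bst]
      } else break
    }
  }
  if (length(S) == 0) stop("no target improves the leave-one-out error")
  targets <- colnames(P)[S]
  methods::new("TimmaModel", targets = targets, profiles = P,
               projected = P[, S, drop = FALSE], y = y,
               looError = curErr, fold = NA_real_)
}

#' Fit a TIMMA model from a Kd matrix and raw sensitivity scores
#'
#' Convenience wrapper: binarize targets at \code{fold}, min-max normalize
#' DSS, then run \code{\link{selectEssentialTargets}}.
#'
#' @inheritParams binarizeTargets
#' @inheritParams selectEssentialTargets
#' @param dss named raw DSS vector.
#' @return a \code{\link{TimmaModel-class}}.
#' @export
fitTimmaModel <- function(kd, dss, fold = 50, maxSize = 20,
                          minImprove = 0.01, seed = NULL) {
  prof <- binarizeTargets(kd, fold)
  y <- normalizeDss(dss[names(prof)])
  model <- selectEssentialTargets(prof, y, maxSize = maxSize,
                                  minImprove = minImprove,
                                  universe = kinaseNames(kd), seed = seed)
  model@fold <- fold
  model
}

#' Predict the sensitivity and synergy of a drug combination
#'
#' The combination's target profile is the union of the two drugs'
#' selected-target profiles; its sensitivity is predicted with the min-max
#' averaging rule against the training profiles projected onto the
#' essential set. The default predicted synergy score is HSA-style on
#' predictions, \code{y_d - max(yhat1, yhat2)}; the raw predicted
#' sensitivity \code{y_d} is always reported alongside.
#'
#' @param model a fitted \code{\link{TimmaModel-class}}.
#' @param drug1,drug2 training drug identifiers.
#' @param score \code{"hsa"} (default) or \code{"raw"}: which quantity to
#'   place in the \code{synergy} column.
#' @return one-row data.frame: drug1, drug2, y_combination, yhat1, yhat2,
#'   synergy, score_type.
#' @export
predictCombination <- function(model, drug1, drug2, score = c("hsa", "raw")) {
  score <- match.arg(score)
  Ps <- model@projected
  for (d in c(drug1, drug2))
    if (!d %in% rownames(Ps)) stop("unknown drug: ", d)
  y <- model@y
  d1 <- Ps[drug1, ]
  d2 <- Ps[drug2, ]
  dc <- d1 | d2
  yd <- timmaPredictCore(dc, Ps, y)
  y1 <- timmaPredictCore(d1, Ps, y)
  y2 <- timmaPredictCore(d2, Ps, y)
  syn <- if (score == "hsa") yd - max(y1, y2) else yd
  data.frame(drug1 = drug1, drug2 = drug2, y_combination = yd,
             yhat1 = y1, yhat2 = y2, synergy = syn, score_type = score,
             stringsAsFactors = FALSE)
}

#' Predict all pairwise drug combinations of a fitted model
#'
#' @inheritParams predictCombination
#' @param pairs optional 2-column matrix/data.frame of drug pairs;
#'   defaults to all unordered training pairs.
#' @return data.frame of \code{\link{predictCombination}} rows.
#' @export
predictAllCombinations <- function(model, pairs = NULL, score = c("hsa", "raw")) {
  score <- match.arg(score)
  drugs <- rownames(model@projected)
  if (is.null(pairs)) {
    idx <- utils::combn(drugs, 2)
    pairs <- data.frame(drug1 = idx[1, ], drug2 = idx[2, ],
                        stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i)
    predictCombination(model, pairs[i, 1], pairs[i, 2], score = score)))
}

#' Build the drug-target combination network of a fitted model
#'
#' Selected kinases whose drug-binding patterns across the training drugs
#' are identical are indistinguishable by the data and merged into one
#' node; each node is annotated with the drugs that hit it. Two nodes are
#' adjacent when at least one drug hits both, so redundant (parallel)
#' sensitivity routes appear as alternative paths and combination
#' effectiveness can be read from cut structure.
#'
#' @param model a fitted \code{\link{TimmaModel-class}}.
#' @return a \code{\link{CombinationNetwork-class}}.
#' @export
buildCombinationNetwork <- function(model) {
  Ps <- model@projected
  if (ncol(Ps) == 0) stop("model has an empty selected target set")
  pat <- apply(Ps, 2, paste, collapse = "")
  groups <- split(colnames(Ps), pat)
  nodes <- lapply(groups, function(kin) {
    hit <- rownames(Ps)[Ps[, kin[1]]]
    list(kinases = sort(kin), drugs = hit)
  })
  names(nodes) <- vapply(nodes, function(nd)
    paste(nd$kinases, collapse = "|"), character(1))
  nodes <- nodes[order(names(nodes))]
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = names(nodes))
  if (length(nodes) > 1) {
    cmb <- utils::combn(length(nodes), 2)
    keep <- vapply(seq_len(ncol(cmb)), function(i) {
      length(intersect(nodes[[cmb[1, i]]]$drugs,
                       nodes[[cmb[2, i]]]$drugs)) > 0
    }, logical(1))
    if (any(keep))
      g <- igraph::add_edges(g, as.vector(cmb[, keep, drop = FALSE]))
  }
  methods::new("CombinationNetwork", nodes = nodes, graph = g)
}

#' Infer combination effectiveness from network breakdown
#'
#' Removes every node hit by either drug and counts the weakly-connected
#' components among the remaining nodes. The combination is predicted
#' effective when the removal breaks the network into more components
#' than the intact network has, or empties it entirely.
#'
#' @param net a \code{\link{CombinationNetwork-class}}.
#' @param drug1,drug2 drug identifiers annotated in the network.
#' @return list with \code{components_before}, \code{components_after},
#'   \code{removed_nodes} and \code{predicted_effective}.
#' @export
networkCutInference <- function(net, drug1, drug2) {
  hit <- vapply(net@nodes, function(nd)
    any(c(drug1, drug2) %in% nd$drugs), logical(1))
  before <- igraph::count_components(net@graph)
  keep <- names(net@nodes)[!hit]
  if (length(keep) == 0) {
    after <- 0L
    effective <- TRUE
  } else {
    sub <- igraph::induced_subgraph(net@graph, keep)
    after <- igraph::count_components(sub)
    effective <- after > before
  }
  list(components_before = before, components_after = after,
       removed_nodes = sum(hit), predicted_effective = effective)
}
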