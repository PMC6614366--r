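#' @import methods
NULL

#' Drug-kinase binding affinity matrix
#'
#' Container for a drugs x kinases matrix of dissociation constants (Kd, nM)
#' as produced by kinome-wide binding assays such as KINOMEscan. A missing
#' (\code{NA}) cell means the kinase was not bound at the assayed
#' concentration range (or not assayed); such cells never become targets
#' during binarization.
#'
#' @slot kd numeric matrix, drugs in rows, kinases in columns, dimnames
#'   required; all non-missing entries strictly positive (nM).
#' @export
setClass("KdMatrix", representation(kd = "matrix"))

setValidity("KdMatrix", function(object) {
  kd <- object@kd
  msg <- character()
  if (is.null(rownames(kd)) || is.null(colnames(kd)))
    msg <- c(msg, "kd matrix must carry drug rownames and kinase colnames")
  else {
    if (anyDuplicated(rownames(kd))) msg <- c(msg, "duplicate drug identifiers")
    if (anyDuplicated(colnames(kd))) msg <- c(msg, "duplicate kinase identifiers")
  }
  if (!is.numeric(kd)) msg <- c(msg, "kd values must be numeric")
  if (any(kd <= 0, na.rm = TRUE)) msg <- c(msg, "non-positive Kd")
  if (nrow(kd) > 0 && any(rowSums(is.finite(kd)) == 0))
    msg <- c(msg, "every drug needs at least one finite Kd")
  if (length(msg)) msg else TRUE
})

#' Dose-response inhibition matrix for a drug pair
#'
#' An n x m grid of percentage-inhibition readouts over the dose
#' combinations of two drugs, including the zero dose of each drug, so the
#' first row/column hold the single-agent margins and cell (1,1) is the
#' untreated control. Values outside [0, 100] are retained (assay noise).
#'
#' @slot drug1,drug2 single drug identifiers (rows = drug1 doses).
#' @slot conc1,conc2 strictly increasing dose vectors in nM, starting at 0.
#' @slot inhibition numeric matrix, \code{length(conc1)} x
#'   \code{length(conc2)}, percent inhibition.
#' @export
setClass("DoseResponseMatrix",
  representation(drug1 = "character", drug2 = "character",
                 conc1 = "numeric", conc2 = "numeric",
                 inhibition = "matrix"))

setValidity("DoseResponseMatrix", function(object) {
  msg <- character()
  for (nm in c("conc1", "conc2")) {
    cc <- slot(object, nm)
    if (length(cc) < 2) msg <- c(msg, paste(nm, "needs at least 2 doses"))
    if (any(diff(cc) <= 0)) msg <- c(msg, paste(nm, "must be strictly increasing"))
    if (cc[1] < 0) msg <- c(msg, paste(nm, "doses must be non-negative"))
  }
  if (!identical(dim(object@inhibition),
                 c(length(object@conc1), length(object@conc2))))
    msg <- c(msg, "inhibition grid dimensions must match dose vectors")
  if (length(msg)) msg else TRUE
})

#' Signed directed signaling network
#'
#' Literature-curated (OmniPath-style) signed edges between gene symbols.
#'
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{sign} (\code{"activation"} or \code{"inhibition"}); no duplicate
#'   triples.
#' @export
setClass("SignedNetwork", representation(edges = "data.frame"))

setValidity("SignedNetwork", function(object) {
  ed <- object@edges
  msg <- character()
  if (!all(c("source", "target", "sign") %in% names(ed)))
    return("edges needs columns source, target, sign")
  if (!all(ed$sign %in% c("activation", "inhibition")))
    msg <- c(msg, "sign must be 'activation' or 'inhibition'")
  if (any(!nzchar(ed$source)) || any(!nzchar(ed$target)))
    msg <- c(msg, "gene symbols must be non-empty")
  if (anyDuplicated(ed[c("source", "target", "sign")]))
    msg <- c(msg, "duplicate (source, target, sign) triples")
  if (length(msg)) msg else TRUE
})

#' Fitted TIMMA network pharmacology model
#'
#' Result of the essential-target subset search: the selected kinase set S,
#' the training drugs' binarized target profiles (full and projected onto
#' S), their normalized sensitivities, and the leave-one-out error of the
#' min-max averaging predictor on the training screen.
#'
#' @slot targets selected essential kinases S (ordered as selected).
#' @slot profiles logical drugs x kinases matrix over the full universe.
#' @slot projected logical drugs x |S| matrix (profiles restricted to S).
#' @slot y named numeric vector of normalized sensitivities in [0, 1].
#' @slot looError mean leave-one-out absolute prediction error in [0, 1].
#' @slot fold Kd fold-threshold used for binarization.
#' @export
setClass("TimmaModel",
  representation(targets = "character", profiles = "matrix",
                 projected = "matrix", y = "numeric",
                 looError = "numeric", fold = "numeric"))

setValidity("TimmaModel", function(object) {
  msg <- character()
  if (length(object@targets) < 1) msg <- c(msg, "selected target set is empty")
  if (!all(object@targets %in% colnames(object@profiles)))
    msg <- c(msg, "selected targets must lie in the kinase universe")
  if (length(object@looError) != 1 ||
      object@looError < 0 || object@looError > 1)
    msg <- c(msg, "looError must be a single value in [0, 1]")
  if (any(object@y < 0 | object@y > 1))
    msg <- c(msg, "sensitivities must lie in [0, 1]")
  if (!identical(rownames(object@projected), rownames(object@profiles)))
    msg <- c(msg, "projected profiles must cover the training drugs")
  if (length(msg)) msg else TRUE
})

#' Drug-target combination network
#'
#' Partition of the selected targets into nodes of kinases with identical
#' drug-binding patterns, annotated with the drugs hitting each node, plus
#' an adjacency graph (nodes sharing a drug are connected) used for
#' cut-based effectiveness inference.
#'
#' @slot nodes list; each element a list with \code{kinases} (character)
#'   and \code{drugs} (character hitting the node).
#' @slot graph igraph object over the node labels.
#' @export
setClass("CombinationNetwork",
  representation(nodes = "list", graph = "ANY"))

#' Stochastic reaction system compiled from a signed network
#'
#' Mass-action reaction set for Gillespie simulation and its ODE twin.
#' Each activation edge A -> B becomes a conversion reaction with
#' propensity kp(B)*X_A (or a catalytic A -> A + B variant), each
#' inhibition edge B -| C a bimolecular annihilation with propensity
#' kd(C)*X_B*X_C, and each gene a first-order self-degradation kd(A)*X_A.
#' Genes without activating inputs may receive a constant production
#' source. An optional growth module adds the pGrowth species whose birth
#' propensity is pGrowth*(ln2/t_div)*f(TP53), gating cell division.
#'
#' @slot species species names (genes, plus "pGrowth" when growth is on).
#' @slot stoich integer stoichiometry matrix, reactions x species.
#' @slot type integer propensity type per reaction: 0 constant, 1 linear,
#'   2 bilinear, 3 growth.
#' @slot k rate constant per reaction (per hour units).
#' @slot a,b species indices entering the propensity (NA if unused).
#' @slot kref which named parameter each rate derives from ("kp:GENE",
#'   "kd:GENE" or "growth"), so calibration can rescale consistently.
#' @slot kp,kd named per-gene production and degradation constants (/h).
#' @slot growth list of growth parameters: \code{tdiv} (h), \code{Q}
#'   (molecules), \code{beta}, \code{pGrowth0}, \code{theta},
#'   \code{tp53} (species name gating growth, or NA).
#' @export
setClass("ReactionSystem",
  representation(species = "character", stoich = "matrix",
                 type = "integer", k = "numeric",
                 a = "integer", b = "integer", kref = "character",
                 kp = "numeric", kd = "numeric", growth = "list"))

setValidity("ReactionSystem", function(object) {
  msg <- character()
  nr <- nrow(object@stoich)
  if (ncol(object@stoich) != length(object@species))
    msg <- c(msg, "stoichiometry columns must match species")
  for (nm in c("type", "k", "a", "b", "kref"))
    if (length(slot(object, nm)) != nr)
      msg <- c(msg, paste(nm, "length must match reaction count"))
  if (any(object@k < 0)) msg <- c(msg, "rate constants must be non-negative")
  if (any(object@kp <= 0) || any(object@kd <= 0))
    msg <- c(msg, "kp and kd must be positive")
  genes <- setdiff(object@species, "pGrowth")
  ndeg <- vapply(genes, function(g) {
    i <- match(g, object@species)
    sum(object@type == 1L & object@a == i & object@stoich[, i] == -1L &
        rowSums(object@stoich != 0L) == 1L)
  }, integer(1))
  if (any(ndeg != 1L))
    msg <- c(msg, "every gene needs exactly one self-degradation reaction")
  if (length(msg)) msg else TRUE
})
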