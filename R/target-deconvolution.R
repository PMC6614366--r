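#' Potent targets of a drug under the strict 10-fold Kd rule
#'
#' A kinase counts as a potent target when its Kd is strictly lower than
#' \code{fold} times the drug's minimal Kd across all kinases
#' (\code{Kd < fold * min Kd}). Note the boundary differs deliberately
#' from \code{\link{binarizeTargets}}, whose permissive 50-fold rule is
#' inclusive ("50-fold or less").
#'
#' @param kd a \code{\link{KdMatrix-class}}.
#' @param drug drug identifier.
#' @param fold fold-threshold (default 10).
#' @return character vector of kinase symbols.
#' @export
potentTargets <- function(kd, drug, fold = 10) {
  m <- kdValues(kd)
  if (!drug %in% rownames(m)) stop("unknown drug: ", drug)
  row <- m[drug, ]
  colnames(m)[which(row < fold * min(row, na.rm = TRUE))]
}

#' Filter a target set to expressed genes
#'
#' Removes non-expressed targets: genes whose log2 expression is below
#' \code{minLog2} (strictly) are dropped; genes absent from the
#' expression table are treated as non-expressed and dropped with a
#' warning.
#'
#' @param targets character vector of gene symbols.
#' @param expr expression data.frame from
#'   \code{\link{readExpressionTable}} (columns gene, log2_expression).
#' @param minLog2 retention threshold (kept iff log2 expression >=
#'   \code{minLog2}; default 6).
#' @return filtered character vector.
#' @export
expressionFilter <- function(targets, expr, minLog2 = 6) {
  if (length(targets) == 0) return(character(0))
  lev <- expr$log2_expression[match(targets, expr$gene)]
  missing <- is.na(lev)
  if (any(missing))
    warning(sum(missing), " target(s) absent from the expression table, ",
            "treated as non-expressed: ",
            paste(targets[missing], collapse = ", "))
  targets[!missing & lev >= minLog2]
}

# Unordered, deduplicated cross pairs of two target sets, self-pairs
# excluded; returned as a sorted two-column character matrix.
crossPairs <- function(t1, t2) {
  if (length(t1) == 0 || length(t2) == 0)
    return(matrix(character(0), 0, 2))
  g <- expand.grid(a = t1, b = t2, stringsAsFactors = FALSE)
  g <- g[g$a != g$b, , drop = FALSE]
  if (nrow(g) == 0) return(matrix(character(0), 0, 2))
  m <- t(apply(as.matrix(g), 1, sort))
  m <- m[!duplicated(paste(m[, 1], m[, 2], sep = "\r")), , drop = FALSE]
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Catalog the candidate target pairs behind two drug combinations
#'
#' For each combination, potent targets of both drugs are derived with
#' the strict 10-fold Kd rule and filtered to expressed genes; the
#' combination's candidate pairs are all unordered cross pairs between
#' the two drugs' surviving target sets (self-pairs excluded). Pairs are
#' then classified: G1 = unique to combination A, G2 = shared, G3 =
#' unique to combination B.
#'
#' @param comboA,comboB length-2 character vectors of drug identifiers.
#' @param kd a \code{\link{KdMatrix-class}}.
#' @param expr expression table (see \code{\link{expressionFilter}}).
#' @param fold Kd fold-threshold (default 10, strict).
#' @param minLog2 expression threshold (default 6).
#' @return data.frame with columns gene1, gene2, group
#'   (\code{"G1"}/\code{"G2"}/\code{"G3"}); attribute \code{"genes"}
#'   holds the filtered gene universe.
#' @export
pairCatalog <- function(comboA, comboB, kd, expr, fold = 10, minLog2 = 6) {
  stopifnot(length(comboA) == 2, length(comboB) == 2)
  filtered <- function(drug) {
    t <- expressionFilter(potentTargets(kd, drug, fold), expr, minLog2)
    if (length(t) == 0)
      stop("no surviving targets for drug: ", drug)
    t
  }
  pairsOf <- function(combo)
    crossPairs(filtered(combo[1]), filtered(combo[2]))
  pa <- pairsOf(comboA)
  pb <- pairsOf(comboB)
  keyA <- paste(pa[, 1], pa[, 2], sep = "\r")
  keyB <- paste(pb[, 1], pb[, 2], sep = "\r")
  shared <- intersect(keyA, keyB)
  mk <- function(m, keys, keep, grp) {
    sel <- keys %in% keep
    if (!any(sel)) return(NULL)
    data.frame(gene1 = m[sel, 1], gene2 = m[sel, 2], group = grp,
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(pa, keyA, setdiff(keyA, keyB), "G1"),
               mk(pa, keyA, shared, "G2"),
               mk(pb, keyB, setdiff(keyB, keyA), "G3"))
  rownames(out) <- NULL
  attr(out, "genes") <- sort(unique(c(out$gene1, out$gene2)))
  out
}
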