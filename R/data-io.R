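# Decimal text that survives a parse round trip bit-exactly.
fullPrec <- function(x) sprintf("%.17g", x)

#' Read a drug-kinase Kd matrix from CSV
#'
#' Supports the two shapes published drug-target tables ship in: a wide
#' drugs x kinases grid (first column = drug identifiers, remaining columns
#' one per kinase) and a long, tidy table with columns
#' \code{drug, kinase, kd}. Blank or unparseable Kd cells become missing
#' ("not bound at the assayed range"); the number of coerced cells is
#' reported as a warning.
#'
#' @param path CSV file path.
#' @param dialect \code{"wide"} or \code{"long"}.
#' @return a \code{\link{KdMatrix-class}} object.
#' @export
readKdMatrix <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) stop("empty or malformed Kd table: ", path)
  if (dialect == "wide") {
    drugs <- as.character(raw[[1]])
    if (anyDuplicated(drugs)) stop("duplicate drug labels in ", path)
    if (anyDuplicated(names(raw)[-1])) stop("duplicate kinase labels in ", path)
    vals <- as.matrix(raw[, -1, drop = FALSE])
    kd <- matrix(suppressWarnings(as.numeric(vals)), nrow = nrow(vals),
                 dimnames = list(drugs, colnames(vals)))
    nbad <- sum(!is.na(vals) & nzchar(trimws(vals)) & is.na(kd))
    if (nbad > 0) warning(nbad, " unparseable Kd cells treated as missing")
  } else {
    need <- c("drug", "kinase", "kd")
    names(raw) <- tolower(names(raw))
    if (!all(need %in% names(raw)))
      stop("long dialect needs columns drug, kinase, kd")
    if (anyDuplicated(raw[c("drug", "kinase")]))
      stop("duplicate (drug, kinase) rows in ", path)
    vals <- raw$kd
    num <- suppressWarnings(as.numeric(vals))
    nbad <- sum(!is.na(vals) & nzchar(trimws(as.character(vals))) & is.na(num))
    if (nbad > 0) warning(nbad, " unparseable Kd cells treated as missing")
    drugs <- unique(as.character(raw$drug))
    kin <- unique(as.character(raw$kinase))
    kd <- matrix(NA_real_, length(drugs), length(kin),
                 dimnames = list(drugs, kin))
    kd[cbind(match(raw$drug, drugs), match(raw$kinase, kin))] <- num
  }
  if (any(kd <= 0, na.rm = TRUE)) stop("non-positive Kd in ", path)
  methods::new("KdMatrix", kd = kd)
}

#' Construct a KdMatrix from a numeric matrix
#'
#' @param kd numeric matrix with drug rownames and kinase colnames; NA =
#'   not bound / not assayed.
#' @return a \code{\link{KdMatrix-class}}.
#' @export
KdMatrix <- function(kd) methods::new("KdMatrix", kd = kd)

#' Read an n x m dose-response percentage-inhibition matrix
#'
#' Expects a CSV whose first column holds drug-1 doses (nM) and whose
#' header row holds drug-2 doses, both starting at 0 and strictly
#' increasing; cell (0, 0) is the untreated control. Inhibition values
#' outside [0, 100] are retained as assay noise.
#'
#' @param path CSV file path.
#' @param drug1,drug2 optional drug labels (defaults taken from the file's
#'   corner header as \code{"drug1/drug2"} when present).
#' @return a \code{\link{DoseResponseMatrix-class}}.
#' @export
readDoseMatrix <- function(path, drug1 = NULL, drug2 = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) < 2 || ncol(raw) < 3) stop("dose matrix too small: ", path)
  corner <- names(raw)[1]
  if (is.null(drug1) || is.null(drug2)) {
    parts <- strsplit(corner, "/", fixed = TRUE)[[1]]
    if (length(parts) == 2) {
      if (is.null(drug1)) drug1 <- parts[1]
      if (is.null(drug2)) drug2 <- parts[2]
    } else {
      if (is.null(drug1)) drug1 <- "drug1"
      if (is.null(drug2)) drug2 <- "drug2"
    }
  }
  conc1 <- suppressWarnings(as.numeric(raw[[1]]))
  conc2 <- suppressWarnings(as.numeric(names(raw)[-1]))
  if (anyNA(conc1) || anyNA(conc2))
    stop("non-numeric concentration header in ", path)
  if (any(diff(conc1) <= 0) || any(diff(conc2) <= 0))
    stop("non-monotone concentration header in ", path)
  inh <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(inh) <- "double"
  dimnames(inh) <- list(format(conc1, trim = TRUE), format(conc2, trim = TRUE))
  methods::new("DoseResponseMatrix", drug1 = drug1, drug2 = drug2,
               conc1 = conc1, conc2 = conc2, inhibition = inh)
}

#' Construct a DoseResponseMatrix in code
#'
#' @param drug1,drug2 drug labels.
#' @param conc1,conc2 dose vectors (nM) including 0, strictly increasing.
#' @param inhibition percent-inhibition grid, rows = conc1, cols = conc2.
#' @export
DoseResponseMatrix <- function(drug1, drug2, conc1, conc2, inhibition) {
  dimnames(inhibition) <- list(format(conc1, trim = TRUE),
                               format(conc2, trim = TRUE))
  methods::new("DoseResponseMatrix", drug1 = drug1, drug2 = drug2,
               conc1 = conc1, conc2 = conc2, inhibition = inhibition)
}

#' Read a signed signaling network from SIF-style text
#'
#' Three tab- (or whitespace-) separated columns: source, sign, target,
#' with sign \code{+} (activation) or \code{-} (inhibition).
#'
#' @param path SIF file path.
#' @return a \code{\link{SignedNetwork-class}}.
#' @export
readSignedNetwork <- function(path) {
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("source", "sign", "target"))
  bad <- !raw$sign %in% c("+", "-")
  if (any(bad)) stop("unknown sign token(s): ",
                     paste(unique(raw$sign[bad]), collapse = ", "))
  SignedNetwork(data.frame(
    source = raw$source, target = raw$target,
    sign = ifelse(raw$sign == "+", "activation", "inhibition"),
    stringsAsFactors = FALSE))
}

#' Construct a SignedNetwork from an edge table
#'
#' @param edges data.frame with columns source, target, sign
#'   ("activation"/"inhibition").
#' @export
SignedNetwork <- function(edges) {
  rownames(edges) <- NULL
  methods::new("SignedNetwork", edges = edges)
}

#' Read a gene expression table
#'
#' CSV with columns \code{gene}, \code{log2_expression} and optionally
#' \code{rpkm}; returns a data.frame keyed by gene symbol (opaque,
#' case-sensitive).
#'
#' @param path CSV file path.
#' @export
readExpressionTable <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  if (!all(c("gene", "log2_expression") %in% names(raw)))
    stop("expression table needs columns gene, log2_expression")
  if (anyDuplicated(raw$gene)) stop("duplicate gene symbols in ", path)
  if ("rpkm" %in% names(raw) && any(raw$rpkm < 0, na.rm = TRUE))
    stop("negative RPKM in ", path)
  raw
}

#' Read single-drug sensitivity scores (DSS)
#'
#' CSV with columns \code{drug} and \code{dss}; raw scores are
#' non-negative area-under-curve-like summaries of single-agent
#' dose-response.
#'
#' @param path CSV file path.
#' @return named numeric vector of raw DSS values.
#' @export
readSensitivityScores <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  if (!all(c("drug", "dss") %in% names(raw)))
    stop("sensitivity table needs columns drug, dss")
  if (anyDuplicated(raw$drug)) stop("duplicate drug labels in ", path)
  if (any(raw$dss < 0)) stop("negative DSS in ", path)
  stats::setNames(raw$dss, raw$drug)
}

#' Write a pipeline product to disk
#'
#' Round-trippable serialization for the pipeline's typed products:
#' \code{KdMatrix} -> wide CSV, \code{DoseResponseMatrix} -> CSV grid,
#' \code{SignedNetwork} -> SIF, \code{TimmaModel} -> JSON, synergy-score
#' data.frames -> CSV. \code{read(write(x))} reproduces \code{x}.
#'
#' @param obj the object to serialize.
#' @param path destination file path.
#' @return \code{path}, invisibly.
#' @export
setGeneric("writeResults", function(obj, path) standardGeneric("writeResults"))

#' @rdname writeResults
setMethod("writeResults", "KdMatrix", function(obj, path) {
  kd <- obj@kd
  chr <- matrix(fullPrec(kd), nrow(kd), dimnames = dimnames(kd))
  chr[is.na(kd)] <- ""
  df <- data.frame(drug = rownames(kd), chr, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
})

#' @rdname writeResults
setMethod("writeResults", "DoseResponseMatrix", function(obj, path) {
  chr <- matrix(fullPrec(obj@inhibition), nrow(obj@inhibition))
  df <- data.frame(c1 = fullPrec(obj@conc1), chr, check.names = FALSE)
  names(df) <- c(paste0(obj@drug1, "/", obj@drug2), fullPrec(obj@conc2))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
})

#' @rdname writeResults
setMethod("writeResults", "SignedNetwork", function(obj, path) {
  ed <- obj@edges
  utils::write.table(
    data.frame(ed$source, ifelse(ed$sign == "activation", "+", "-"), ed$target),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
})

#' @rdname writeResults
setMethod("writeResults", "TimmaModel", function(obj, path) {
  payload <- list(
    targets = obj@targets,
    drugs = rownames(obj@profiles),
    kinases = colnames(obj@profiles),
    profiles = apply(obj@profiles, 1, function(r) colnames(obj@profiles)[r],
                     simplify = FALSE),
    y = as.list(obj@y),
    loo_error = obj@looError,
    fold = obj@fold)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
})

#' @rdname writeResults
setMethod("writeResults", "data.frame", function(obj, path) {
  utils::write.csv(obj, path, row.names = FALSE)
  invisible(path)
})

#' Read back a TIMMA model written by \code{writeResults}
#'
#' @param path JSON file path.
#' @return a \code{\link{TimmaModel-class}}.
#' @export
readTimmaModel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  prof <- matrix(FALSE, length(p$drugs), length(p$kinases),
                 dimnames = list(p$drugs, p$kinases))
  for (d in p$drugs) prof[d, unlist(p$profiles[[d]])] <- TRUE
  y <- unlist(p$y)
  methods::new("TimmaModel", targets = p$targets, profiles = prof,
               projected = prof[, p$targets, drop = FALSE],
               y = y[p$drugs], looError = p$loo_error, fold = p$fold)
}
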