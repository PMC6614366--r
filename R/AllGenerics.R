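#' @rdname KdMatrix-class
#' @param object,x a \code{KdMatrix}, \code{TimmaModel} or
#'   \code{ReactionSystem}.
#' @export
setGeneric("drugNames", function(x) standardGeneric("drugNames"))

#' @rdname KdMatrix-class
#' @export
setGeneric("kinaseNames", function(x) standardGeneric("kinaseNames"))

#' @rdname KdMatrix-class
#' @export
setGeneric("kdValues", function(x) standardGeneric("kdValues"))

#' @rdname TimmaModel-class
#' @export
setGeneric("selectedTargets", function(x) standardGeneric("selectedTargets"))

#' @rdname TimmaModel-class
#' @export
setGeneric("looError", function(x) standardGeneric("looError"))

#' @rdname TimmaModel-class
#' @export
setGeneric("trainingSensitivities",
           function(x) standardGeneric("trainingSensitivities"))

#' @rdname SignedNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname ReactionSystem-class
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname ReactionSystem-class
#' @export
setGeneric("reactionCount", function(x) standardGeneric("reactionCount"))

#' @rdname ReactionSystem-class
#' @export
setGeneric("productionRates", function(x) standardGeneric("productionRates"))

#' @rdname ReactionSystem-class
#' @export
setGeneric("degradationRates", function(x) standardGeneric("degradationRates"))

setMethod("drugNames", "KdMatrix", function(x) rownames(x@kd))
setMethod("kinaseNames", "KdMatrix", function(x) colnames(x@kd))
setMethod("kdValues", "KdMatrix", function(x) x@kd)
setMethod("drugNames", "TimmaModel", function(x) rownames(x@profiles))
setMethod("kinaseNames", "TimmaModel", function(x) colnames(x@profiles))
setMethod("selectedTargets", "TimmaModel", function(x) x@targets)
setMethod("looError", "TimmaModel", function(x) x@looError)
setMethod("trainingSensitivities", "TimmaModel", function(x) x@y)
setMethod("networkEdges", "SignedNetwork", function(x) x@edges)
setMethod("speciesNames", "ReactionSystem", function(x) x@species)
setMethod("reactionCount", "ReactionSystem", function(x) nrow(x@stoich))
setMethod("productionRates", "ReactionSystem", function(x) x@kp)
setMethod("degradationRates", "ReactionSystem", function(x) x@kd)

setMethod("show", "KdMatrix", function(object) {
  kd <- object@kd
  cat("KdMatrix:", nrow(kd), "drugs x", ncol(kd), "kinases;",
      sum(is.finite(kd)), "measured Kd values\n")
  cat("  Kd range (nM):",
      format(suppressWarnings(min(kd, na.rm = TRUE))), "-",
      format(suppressWarnings(max(kd, na.rm = TRUE))), "\n")
})

setMethod("show", "DoseResponseMatrix", function(object) {
  cat("DoseResponseMatrix:", object@drug1, "x", object@drug2, "\n")
  cat("  grid:", length(object@conc1), "x", length(object@conc2),
      "doses incl. 0;  inhibition range:",
      format(round(min(object@inhibition), 1)), "-",
      format(round(max(object@inhibition), 1)), "%\n")
})

setMethod("show", "SignedNetwork", function(object) {
  ed <- object@edges
  cat("SignedNetwork:", nrow(ed), "edges (",
      sum(ed$sign == "activation"), "activation /",
      sum(ed$sign == "inhibition"), "inhibition ) over",
      length(unique(c(ed$source, ed$target))), "genes\n")
})

setMethod("show", "TimmaModel", function(object) {
  cat("TimmaModel:", length(object@targets), "selected targets from",
      ncol(object@profiles), "kinases;", nrow(object@profiles),
      "training drugs\n")
  cat("  targets:", paste(object@targets, collapse = ", "), "\n")
  cat("  leave-one-out error:", format(round(object@looError, 4)), "\n")
})

setMethod("show", "CombinationNetwork", function(object) {
  cat("CombinationNetwork:", length(object@nodes), "target-group nodes\n")
  for (nm in names(object@nodes)) {
    nd <- object@nodes[[nm]]
    cat("  ", nm, ": {", paste(nd$kinases, collapse = ","), "} hit by ",
        length(nd$drugs), " drugs\n", sep = "")
  }
})

setMethod("show", "ReactionSystem", function(object) {
  cat("ReactionSystem:", length(object@species), "species,",
      nrow(object@stoich), "reactions\n")
  if (!is.na(object@growth$tp53))
    cat("  growth module on; TP53 gate =", object@growth$tp53,
        " t_div =", object@growth$tdiv, "h\n")
})
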