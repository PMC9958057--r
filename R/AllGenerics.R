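#' Labeling kind of a partition
#'
#' @param x an \code{EdgePartition} or \code{SymbolicEdgePartition}.
#' @return \code{"degree"} or \code{"reduced_reverse"}.
#' @export
setGeneric("labelingKind", function(x) standardGeneric("labelingKind"))

#' @rdname labelingKind
#' @export
setMethod("labelingKind", "EdgePartition", function(x) x@labeling)

#' @rdname labelingKind
#' @export
setMethod("labelingKind", "SymbolicEdgePartition", function(x) x@labeling)

#' Edge classes of a partition
#'
#' @param x an \code{EdgePartition} or \code{SymbolicEdgePartition}.
#' @return a data.frame copy of the classes table: columns \code{a}, \code{b},
#'   and \code{count} (numeric partition) or \code{slope}, \code{intercept}
#'   (symbolic partition).
#' @export
setGeneric("partitionClasses", function(x) standardGeneric("partitionClasses"))

#' @rdname partitionClasses
#' @export
setMethod("partitionClasses", "EdgePartition", function(x) {
  cl <- x@classes
  rownames(cl) <- NULL
  cl
})

#' @rdname partitionClasses
#' @export
setMethod("partitionClasses", "SymbolicEdgePartition", function(x) {
  cl <- x@classes
  rownames(cl) <- NULL
  cl
})

#' Coefficients of a linear form
#'
#' @param x a \code{LinearForm}.
#' @return a numeric scalar.
#' @export
setGeneric("formSlope", function(x) standardGeneric("formSlope"))

#' @rdname formSlope
#' @export
setMethod("formSlope", "LinearForm", function(x) x@slope)

#' @rdname formSlope
#' @export
setGeneric("formIntercept", function(x) standardGeneric("formIntercept"))

#' @rdname formSlope
#' @export
setMethod("formIntercept", "LinearForm", function(x) x@intercept)

#' Name of an index specification
#'
#' @param x an \code{IndexSpec}.
#' @return character scalar.
#' @export
setGeneric("indexName", function(x) standardGeneric("indexName"))

#' @rdname indexName
#' @export
setMethod("indexName", "IndexSpec", function(x) x@name)

#' Edge-weight function of an index specification
#'
#' @param x an \code{IndexSpec}.
#' @return the symmetric weight function w(a, b).
#' @export
setGeneric("weightFunction", function(x) standardGeneric("weightFunction"))

#' @rdname weightFunction
#' @export
setMethod("weightFunction", "IndexSpec", function(x) x@weight)

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph: %d vertices, %d edges, max degree %s\n",
              vertexCount(object), edgeCount(object),
              if (vertexCount(object) > 0) maxDegree(object) else "NA"))
})

setMethod("show", "EdgePartition", function(object) {
  cat(sprintf("EdgePartition (%s labeling), %d classes, %d edges\n",
              object@labeling, nrow(object@classes),
              sum(object@classes$count)))
  if (nrow(object@classes) > 0) {
    cl <- object@classes
    cat(paste0("  (", cl$a, ",", cl$b, "): ", cl$count, collapse = "\n"),
        "\n")
  }
})

.formatLinear <- function(slope, intercept) {
  s <- format(slope)
  if (intercept == 0) return(paste0(s, "n"))
  sprintf("%sn %s %s", s, if (intercept < 0) "-" else "+",
          format(abs(intercept)))
}

setMethod("show", "LinearForm", function(object) {
  cat("LinearForm:", .formatLinear(object@slope, object@intercept), "\n")
})

setMethod("show", "SymbolicEdgePartition", function(object) {
  cat(sprintf("SymbolicEdgePartition (%s labeling), %d classes\n",
              object@labeling, nrow(object@classes)))
  cl <- object@classes
  if (nrow(cl) > 0) {
    cat(paste0("  (", cl$a, ",", cl$b, "): ",
               mapply(.formatLinear, cl$slope, cl$intercept),
               collapse = "\n"), "\n")
    tot <- totalEdgeForm(object)
    cat("  total:", .formatLinear(tot@slope, tot@intercept), "edges\n")
  }
})

setMethod("show", "IndexSpec", function(object) {
  cat(sprintf("IndexSpec %s (%s labeling, %s family)%s\n",
              object@name, object@labeling, object@family,
              if (is.na(object@alpha)) ""
              else sprintf(", alpha = %g", object@alpha)))
})

setMethod("show", "QsprFit", function(object) {
  co <- object@coefficients
  terms <- sprintf("%.6g(TI)", co[["a1"]])
  if (object@degree == 2L)
    terms <- paste0(sprintf("%.6g(TI)^2 + ", co[["a2"]]), terms)
  cat(sprintf("QsprFit degree %d%s%s\n  P = %s %+.6g\n",
              object@degree,
              if (nzchar(object@property))
                paste0(": ", object@property) else "",
              if (nzchar(object@index))
                paste0(" ~ ", object@index) else "",
              terms, co[["gamma"]]))
  d <- object@diagnostics
  if (!is.null(d$r.squared))
    cat(sprintf(
      "  R2 %.4f | chi2 %.4f | avg residual %.4f%% | RMSE %.4f (n) / %.4f (n-p)\n",
      d$r.squared, d$chi.square, d$avg.residual.pct, d$rmse.n, d$rmse.np))
})
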