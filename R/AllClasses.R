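#' @import methods
NULL

LABELING_KINDS <- c("degree", "reduced_reverse")

#' Molecular graph of a hydrogen-suppressed chemical structure
#'
#' An undirected simple graph whose vertices are heavy atoms and whose edges
#' are covalent bonds. The class wraps an \pkg{igraph} object; use
#' \code{\link{buildGraph}} or \code{\link{readEdgeList}} to construct one,
#' and the accessors \code{\link{vertexNames}}, \code{\link{edgeMatrix}},
#' \code{\link{degreeMap}} etc. rather than touching the slot.
#'
#' @slot graph an undirected, simple, vertex-named \code{igraph} graph.
#' @seealso \code{\link{buildGraph}}, \code{\link{edgePartition}},
#'   \code{\link{indexValue}}
#' @export
setClass("MolecularGraph", slots = c(graph = "ANY"))

setValidity("MolecularGraph", function(object) {
  g <- object@graph
  if (!igraph::is_igraph(g))
    return("slot 'graph' must be an igraph object")
  if (igraph::is_directed(g))
    return("graph must be undirected")
  if (any(igraph::which_loop(g)))
    return("graph must not contain self-loops")
  if (any(igraph::which_multiple(g)))
    return("graph must not contain parallel edges")
  if (is.null(igraph::V(g)$name))
    return("graph vertices must be named")
  TRUE
})

#' Edge partition of a molecular graph
#'
#' Counts of edges grouped by the unordered pair of endpoint labels, where
#' labels are either plain vertex degrees or reduced reverse degrees
#' (see \code{\link{reducedReverseDegrees}}). Label pairs are canonicalized
#' with the larger label first. Every degree-based topological index is a
#' linear functional of this partition.
#'
#' @slot labeling either \code{"degree"} or \code{"reduced_reverse"}.
#' @slot classes data.frame with integer columns \code{a}, \code{b}
#'   (\code{a >= b}) and non-negative integer \code{count}.
#' @seealso \code{\link{edgePartition}}, \code{\link{indexFromPartition}}
#' @export
setClass("EdgePartition",
         slots = c(labeling = "character", classes = "data.frame"))

setValidity("EdgePartition", function(object) {
  if (!(object@labeling %in% LABELING_KINDS))
    return(sprintf("labeling must be one of %s",
                   paste(sQuote(LABELING_KINDS), collapse = ", ")))
  cl <- object@classes
  if (!all(c("a", "b", "count") %in% names(cl)))
    return("classes must have columns 'a', 'b', 'count'")
  if (nrow(cl) > 0) {
    if (any(cl$a < 1 | cl$b < 1)) return("labels must be positive integers")
    if (any(cl$a < cl$b)) return("label pairs must be canonical (a >= b)")
    if (any(cl$count < 0)) return("class counts must be non-negative")
  }
  TRUE
})

#' Linear polynomial a*n + b in the repeat count n
#'
#' The value of any edge-sum topological index on a graph family whose
#' edge-class counts grow linearly in the number of repeat units n is itself
#' linear in n; this class holds the two coefficients.
#'
#' @slot slope coefficient of n.
#' @slot intercept constant term.
#' @seealso \code{\link{closedForm}}, \code{\link{evaluateForm}}
#' @export
setClass("LinearForm", slots = c(slope = "numeric", intercept = "numeric"))

setValidity("LinearForm", function(object) {
  if (length(object@slope) != 1L || length(object@intercept) != 1L)
    return("slope and intercept must be scalars")
  if (!is.finite(object@slope) || !is.finite(object@intercept))
    return("slope and intercept must be finite")
  TRUE
})

#' Symbolic edge partition of a repeat-unit graph family
#'
#' Like \code{\linkS4class{EdgePartition}} but each class count is a linear
#' form slope*n + intercept in the repeat count n. The packaged partition of
#' the hyaluronic-acid--paclitaxel conjugate family is the canonical example
#' (\code{\link{hapPartition}}).
#'
#' @slot labeling either \code{"degree"} or \code{"reduced_reverse"}.
#' @slot classes data.frame with columns \code{a}, \code{b} (canonical,
#'   \code{a >= b}), \code{slope}, \code{intercept}; each class count must
#'   evaluate to a non-negative integer for all integers n >= 1.
#' @seealso \code{\link{closedForm}}, \code{\link{instantiatePartition}},
#'   \code{\link{impliedVertexForm}}
#' @export
setClass("SymbolicEdgePartition",
         slots = c(labeling = "character", classes = "data.frame"))

setValidity("SymbolicEdgePartition", function(object) {
  if (!(object@labeling %in% LABELING_KINDS))
    return(sprintf("labeling must be one of %s",
                   paste(sQuote(LABELING_KINDS), collapse = ", ")))
  cl <- object@classes
  if (!all(c("a", "b", "slope", "intercept") %in% names(cl)))
    return("classes must have columns 'a', 'b', 'slope', 'intercept'")
  if (nrow(cl) > 0) {
    if (any(cl$a < 1 | cl$b < 1)) return("labels must be positive integers")
    if (any(cl$a < cl$b)) return("label pairs must be canonical (a >= b)")
    # counts must be non-negative integers for all n >= 1; linearity makes
    # n = 1 plus a non-negative slope sufficient
    if (any(cl$slope != round(cl$slope)) ||
        any(cl$intercept != round(cl$intercept)))
      return("class count coefficients must be integers")
    if (any(cl$slope < 0))
      return("class count slopes must be non-negative")
    if (any(cl$slope + cl$intercept < 0))
      return("class counts must be non-negative at n = 1")
  }
  TRUE
})

#' Specification of a degree-based topological index
#'
#' A named, symmetric edge-weight rule w(a, b) over endpoint labels, together
#' with the labeling kind the rule applies to (plain degrees for the classical
#' indices, reduced reverse degrees for the RR family) and, for Randic-type
#' indices, the exponent alpha.
#'
#' @slot name identifier, e.g. \code{"RRM1"}, \code{"ABC"}, \code{"RRR_-1"}.
#' @slot labeling either \code{"degree"} or \code{"reduced_reverse"}.
#' @slot weight vectorized symmetric function of two positive labels.
#' @slot alpha Randic exponent, \code{NA} for non-Randic indices.
#' @slot family literature family the formula comes from (documentation only).
#' @seealso \code{\link{indexCatalog}}, \code{\link{getIndexSpec}},
#'   \code{\link{randicSpec}}
#' @export
setClass("IndexSpec",
         slots = c(name = "character", labeling = "character",
                   weight = "function", alpha = "numeric",
                   family = "character"))

setValidity("IndexSpec", function(object) {
  if (!(object@labeling %in% LABELING_KINDS))
    return(sprintf("labeling must be one of %s",
                   paste(sQuote(LABELING_KINDS), collapse = ", ")))
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a non-empty string")
  w <- object@weight
  probe <- expand.grid(a = 1:6, b = 1:6)
  vals <- w(probe$a, probe$b)
  if (!all(is.finite(vals)))
    return("weight must be finite for all positive integer label pairs")
  if (max(abs(vals - w(probe$b, probe$a))) > 1e-12)
    return("weight must be symmetric: w(a,b) == w(b,a)")
  TRUE
})

#' Fitted curvilinear QSPR model
#'
#' A degree-1 or degree-2 polynomial regression of a physico-chemical
#' property on a topological index, with the diagnostics used in the
#' benzenoid study: R-squared, chi-square goodness of fit, average absolute
#' residual percentage, and RMSE under both denominator conventions.
#' Constructed by \code{\link{fitPolynomial}} (ordinary least squares) or
#' \code{\link{polynomialModel}} (explicit, e.g. printed, coefficients).
#'
#' @slot degree 1L or 2L.
#' @slot coefficients named numeric vector \code{gamma} (constant),
#'   \code{a1} (linear), and for degree 2 \code{a2} (quadratic).
#' @slot property name of the modelled property ("" if unspecified).
#' @slot index name of the predictor index ("" if unspecified).
#' @slot fit the underlying \code{lm} object, or \code{NULL} for models
#'   built from explicit coefficients.
#' @slot diagnostics list with elements \code{r.squared}, \code{chi.square},
#'   \code{avg.residual.pct}, \code{rmse.n}, \code{rmse.np} (empty for
#'   explicit-coefficient models until diagnostics are computed on data).
#' @export
setClass("QsprFit",
         slots = c(degree = "integer", coefficients = "numeric",
                   property = "character", index = "character",
                   fit = "ANY", diagnostics = "list"))

setValidity("QsprFit", function(object) {
  if (!(object@degree %in% c(1L, 2L))) return("degree must be 1 or 2")
  need <- if (object@degree == 1L) c("gamma", "a1") else c("gamma", "a1", "a2")
  if (!all(need %in% names(object@coefficients)))
    return(sprintf("coefficients must be named %s",
                   paste(sQuote(need), collapse = ", ")))
  d <- object@diagnostics
  if (!is.null(d$r.squared) && is.finite(d$r.squared) &&
      (d$r.squared < -1e-12 || d$r.squared > 1 + 1e-12))
    return("r.squared must lie in [0, 1]")
  TRUE
})
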