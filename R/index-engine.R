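# Edge-weight rules. All are vectorized, symmetric functions of two positive
# integer endpoint labels. The ABC-type weight is 0 (not an error) at the
# degenerate pair (1,1), where the numerator a + b - 2 vanishes.

.W <- list(
  sum      = function(a, b) a + b,
  prod     = function(a, b) a * b,
  sum2     = function(a, b) (a + b)^2,
  prod2    = function(a, b) (a * b)^2,
  forgotten = function(a, b) a^2 + b^2,
  abc      = function(a, b) sqrt((a + b - 2) / (a * b)),
  ga       = function(a, b) 2 * sqrt(a * b) / (a + b),
  harmonic = function(a, b) 2 / (a + b),
  go1      = function(a, b) (a + b) + a * b,
  go2      = function(a, b) (a + b) * a * b,
  hgo1     = function(a, b) ((a + b) + a * b)^2,
  hgo2     = function(a, b) ((a + b) * a * b)^2
)

.newSpec <- function(name, labeling, weight, family, alpha = NA_real_) {
  methods::new("IndexSpec", name = name, labeling = labeling,
               weight = weight, alpha = alpha, family = family)
}

#' Randic-type index specification
#'
#' The Randic-type index with exponent alpha sums (label(u) * label(v))^alpha
#' over all edges. With reduced-reverse labeling and alpha = 1 it coincides
#' with the second reduced-reverse Zagreb index.
#'
#' @param alpha real exponent; the study uses 1, -1, 1/2 and -1/2.
#' @param labeling \code{"reduced_reverse"} (default) or \code{"degree"}.
#' @return an \code{\linkS4class{IndexSpec}}.
#' @export
randicSpec <- function(alpha, labeling = c("reduced_reverse", "degree")) {
  labeling <- match.arg(labeling)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  force(alpha)
  prefix <- if (labeling == "reduced_reverse") "RRR" else "R"
  .newSpec(sprintf("%s_%g", prefix, alpha), labeling,
           function(a, b) (a * b)^alpha, "Randic", alpha = alpha)
}

#' Catalog of the 26 topological index specifications
#'
#' Returns the ten reduced-reverse-degree indices of the study (first and
#' second Zagreb, first and second hyper-Zagreb, forgotten, atom-bond
#' connectivity, geometric-arithmetic, and Randic-type with exponents -1,
#' 1/2 and -1/2) together with the sixteen classical degree-based comparison
#' indices (Zagreb M1/M2, hyper-Zagreb HM1/HM2, forgotten F, ABC, Randic R
#' and its exponent variants, geometric-arithmetic GA, harmonic H, Gourava
#' GO1/GO2 and hyper-Gourava HGO1/HGO2). The reduced-reverse Randic index
#' with exponent 1 is identical to RRM2 and is therefore not duplicated in
#' the catalog; it is available through \code{\link{randicSpec}}.
#'
#' @return a named list of 26 \code{\linkS4class{IndexSpec}} objects.
#' @export
indexCatalog <- function() {
  rr <- "reduced_reverse"; dg <- "degree"
  specs <- list(
    .newSpec("RRM1",  rr, .W$sum,       "Zagreb"),
    .newSpec("RRM2",  rr, .W$prod,      "Zagreb"),
    .newSpec("RRHM1", rr, .W$sum2,      "hyper-Zagreb"),
    .newSpec("RRHM2", rr, .W$prod2,     "hyper-Zagreb"),
    .newSpec("RRF",   rr, .W$forgotten, "forgotten"),
    .newSpec("RRABC", rr, .W$abc,       "ABC"),
    .newSpec("RRGA",  rr, .W$ga,        "geometric-arithmetic"),
    randicSpec(-1,   rr),
    randicSpec(0.5,  rr),
    randicSpec(-0.5, rr),
    .newSpec("M1",   dg, .W$sum,       "Zagreb"),
    .newSpec("M2",   dg, .W$prod,      "Zagreb"),
    .newSpec("HM1",  dg, .W$sum2,      "hyper-Zagreb"),
    .newSpec("HM2",  dg, .W$prod2,     "hyper-Zagreb"),
    .newSpec("F",    dg, .W$forgotten, "forgotten"),
    .newSpec("ABC",  dg, .W$abc,       "ABC"),
    .newSpec("R",    dg, function(a, b) (a * b)^-0.5, "Randic",
             alpha = -0.5),
    .newSpec("GA",   dg, .W$ga,        "geometric-arithmetic"),
    .newSpec("H",    dg, .W$harmonic,  "harmonic"),
    randicSpec(-1,   dg),
    randicSpec(0.5,  dg),
    randicSpec(-0.5, dg),
    .newSpec("GO1",  dg, .W$go1,  "Gourava"),
    .newSpec("GO2",  dg, .W$go2,  "Gourava"),
    .newSpec("HGO1", dg, .W$hgo1, "hyper-Gourava"),
    .newSpec("HGO2", dg, .W$hgo2, "hyper-Gourava")
  )
  names(specs) <- vapply(specs, indexName, character(1))
  specs
}

#' Look up an index specification by name
#'
#' Names are case-insensitive. The bare Randic names \code{"RRR"} and
#' \code{"R"} accept an explicit exponent through \code{alpha}; for the
#' catalog variants the exponent is part of the name (e.g. \code{"RRR_-1"}).
#'
#' @param name index identifier.
#' @param alpha optional Randic exponent (only for names \code{"R"} /
#'   \code{"RRR"}).
#' @return an \code{\linkS4class{IndexSpec}}.
#' @export
getIndexSpec <- function(name, alpha = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.null(alpha)) {
    up <- toupper(name)
    if (up == "RRR") return(randicSpec(alpha, "reduced_reverse"))
    if (up == "R")   return(randicSpec(alpha, "degree"))
    stop(sprintf("'alpha' is only meaningful for Randic-type names, not %s",
                 sQuote(name)))
  }
  cat <- indexCatalog()
  hit <- match(toupper(name), toupper(names(cat)))
  if (is.na(hit))
    stop(sprintf("unknown index %s; available: %s", sQuote(name),
                 paste(names(cat), collapse = ", ")))
  cat[[hit]]
}

#' Topological index of a molecular graph by direct edge summation
#'
#' Sums the spec's weight function over all edges, applied to the endpoint
#' labels under the spec's labeling kind (vertex degrees, or reduced reverse
#' degrees computed with the maximum degree of this graph).
#'
#' @param g a non-empty \code{MolecularGraph}.
#' @param spec an \code{\linkS4class{IndexSpec}} (see
#'   \code{\link{indexCatalog}}), or an index name passed to
#'   \code{\link{getIndexSpec}}.
#' @return numeric scalar; 0 for a graph with no edges. A graph containing an
#'   isolated vertex triggers a warning (such vertices contribute nothing).
#' @examples
#' hexagon <- buildGraph(cbind(1:6, c(2:6, 1)))
#' indexValue(hexagon, "RRM1")                     # 24
#' indexValue(hexagon, getIndexSpec("RRR", -1))    # 1.5
#' @export
indexValue <- function(g, spec) {
  stopifnot(methods::is(g, "MolecularGraph"))
  if (is.character(spec)) spec <- getIndexSpec(spec)
  stopifnot(methods::is(spec, "IndexSpec"))
  if (vertexCount(g) == 0L) stop("graph has no vertices")
  d <- degreeMap(g)
  if (any(d == 0L))
    warning("graph contains isolated vertices; they contribute nothing to the index")
  if (edgeCount(g) == 0L) return(0)
  labels <- switch(spec@labeling,
                   degree = d,
                   reduced_reverse = max(d) - d + 2L)
  em <- edgeMatrix(g)
  sum(spec@weight(labels[em[, 1L]], labels[em[, 2L]]))
}

#' Topological index from a numeric edge partition
#'
#' Evaluates sum over classes of count * w(a, b). Equals
#' \code{\link{indexValue}} on any graph having this partition.
#'
#' @param p an \code{\linkS4class{EdgePartition}} whose labeling kind matches
#'   the spec's.
#' @param spec an \code{\linkS4class{IndexSpec}} or index name.
#' @return numeric scalar.
#' @export
indexFromPartition <- function(p, spec) {
  stopifnot(methods::is(p, "EdgePartition"))
  if (is.character(spec)) spec <- getIndexSpec(spec)
  stopifnot(methods::is(spec, "IndexSpec"))
  if (p@labeling != spec@labeling)
    stop(sprintf("partition labeling (%s) does not match index labeling (%s)",
                 p@labeling, spec@labeling))
  cl <- p@classes
  if (nrow(cl) == 0L) return(0)
  sum(cl$count * spec@weight(cl$a, cl$b))
}

#' Closed-form index polynomial from a symbolic edge partition
#'
#' For a graph family whose edge-class counts are linear forms in the repeat
#' count n, every edge-sum index is itself linear in n. The closed form is
#' obtained by weighting the class-count slopes and intercepts separately:
#' for every integer n >= 1, evaluating the result equals
#' \code{\link{indexFromPartition}} on the partition instantiated at n.
#' Coefficients are accumulated in double precision.
#'
#' @param sp a \code{\linkS4class{SymbolicEdgePartition}} whose labeling kind
#'   matches the spec's.
#' @param spec an \code{\linkS4class{IndexSpec}} or index name.
#' @return a \code{\linkS4class{LinearForm}}.
#' @examples
#' closedForm(hapPartition(), "RRM1")  # 664n + 4
#' @export
closedForm <- function(sp, spec) {
  stopifnot(methods::is(sp, "SymbolicEdgePartition"))
  if (is.character(spec)) spec <- getIndexSpec(spec)
  stopifnot(methods::is(spec, "IndexSpec"))
  if (sp@labeling != spec@labeling)
    stop(sprintf("partition labeling (%s) does not match index labeling (%s)",
                 sp@labeling, spec@labeling))
  cl <- sp@classes
  w <- spec@weight(cl$a, cl$b)
  methods::new("LinearForm",
               slope = sum(cl$slope * w),
               intercept = sum(cl$intercept * w))
}

#' Evaluate a linear form at a repeat count
#'
#' @param f a \code{\linkS4class{LinearForm}}.
#' @param n positive integer repeat count.
#' @return slope * n + intercept.
#' @export
evaluateForm <- function(f, n) {
  stopifnot(methods::is(f, "LinearForm"))
  if (!is.numeric(n) || any(n < 1) || any(n != round(n)))
    stop("n must be a positive integer (n >= 1)")
  f@slope * n + f@intercept
}

#' All 26 catalog indices of a graph
#'
#' @param g a non-empty \code{MolecularGraph}.
#' @return data.frame with columns \code{index}, \code{labeling},
#'   \code{value}.
#' @export
allIndices <- function(g) {
  cat <- indexCatalog()
  data.frame(
    index = names(cat),
    labeling = vapply(cat, function(s) s@labeling, character(1)),
    value = vapply(cat, function(s) indexValue(g, s), numeric(1)),
    row.names = NULL)
}
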