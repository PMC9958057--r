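#' Build a molecular graph from an edge list
#'
#' Vertices are the union of the endpoint identifiers; duplicate pairs (in
#' either order) collapse to a single undirected edge. Identifiers are opaque
#' and coerced to character. The convention throughout the package is
#' hydrogen-suppressed: vertices are heavy atoms only.
#'
#' @param edgePairs a two-column matrix or data.frame, or a list of length-2
#'   vectors, one edge per row/element.
#' @param vertices optional character vector of additional vertex identifiers
#'   (e.g. isolated vertices); endpoints are always included.
#' @return a \code{\linkS4class{MolecularGraph}}.
#' @examples
#' g <- buildGraph(rbind(c(1, 2), c(2, 3)))
#' vertexCount(g)  # 3
#' edgeCount(g)    # 2
#' @export
buildGraph <- function(edgePairs, vertices = NULL) {
  em <- .asEdgeMatrix(edgePairs)
  loops <- em[, 1L] == em[, 2L]
  if (any(loops))
    stop(sprintf("self-loop pair not allowed: (%s, %s)",
                 em[which(loops)[1L], 1L], em[which(loops)[1L], 2L]))
  # canonicalize each pair, drop duplicates
  a <- pmin(em[, 1L], em[, 2L])
  b <- pmax(em[, 1L], em[, 2L])
  keep <- !duplicated(paste(a, b, sep = "\r"))
  verts <- unique(c(a, b, as.character(vertices)))
  if (length(verts) == 0L)
    stop("graph must have at least one vertex")
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(verts), name = verts)
  if (any(keep))
    g <- igraph::add_edges(g, t(cbind(a, b)[keep, , drop = FALSE]))
  methods::new("MolecularGraph", graph = g)
}

.asEdgeMatrix <- function(edgePairs) {
  if (is.list(edgePairs) && !is.data.frame(edgePairs)) {
    if (length(edgePairs) == 0L)
      return(matrix(character(0), ncol = 2L))
    if (any(lengths(edgePairs) != 2L))
      stop("each edge pair must have exactly two identifiers")
    edgePairs <- do.call(rbind, lapply(edgePairs, as.character))
  }
  edgePairs <- as.matrix(edgePairs)
  if (ncol(edgePairs) != 2L)
    stop("edge pairs must have exactly two identifiers per edge")
  storage.mode(edgePairs) <- "character"
  edgePairs
}

#' Number of vertices of a molecular graph
#' @param g a \code{MolecularGraph}.
#' @return integer.
#' @export
vertexCount <- function(g) {
  stopifnot(methods::is(g, "MolecularGraph"))
  igraph::vcount(g@graph)
}

#' Number of edges of a molecular graph
#' @param g a \code{MolecularGraph}.
#' @return integer.
#' @export
edgeCount <- function(g) {
  stopifnot(methods::is(g, "MolecularGraph"))
  igraph::ecount(g@graph)
}

#' Vertex identifiers of a molecular graph
#' @param g a \code{MolecularGraph}.
#' @return character vector.
#' @export
vertexNames <- function(g) {
  stopifnot(methods::is(g, "MolecularGraph"))
  igraph::V(g@graph)$name
}

#' Edge matrix of a molecular graph
#' @param g a \code{MolecularGraph}.
#' @return two-column character matrix, one edge per row.
#' @export
edgeMatrix <- function(g) {
  stopifnot(methods::is(g, "MolecularGraph"))
  igraph::as_edgelist(g@graph, names = TRUE)
}

#' Vertex degrees
#'
#' The degree of a vertex is the number of edges incident on it; the values
#' sum to twice the edge count (handshake lemma).
#'
#' @param g a non-empty \code{MolecularGraph}.
#' @return named integer vector, one entry per vertex.
#' @export
degreeMap <- function(g) {
  stopifnot(methods::is(g, "MolecularGraph"))
  if (vertexCount(g) == 0L) stop("graph has no vertices")
  igraph::degree(g@graph)
}

#' Maximum vertex degree
#'
#' @param g a non-empty \code{MolecularGraph}.
#' @return Delta(G), a positive integer.
#' @export
maxDegree <- function(g) {
  if (methods::is(g, "MolecularGraph") && vertexCount(g) == 0L)
    stop("maximum degree is undefined for an empty graph")
  max(degreeMap(g))
}

#' Reduced reverse vertex degrees
#'
#' The reduced reverse degree of a vertex v is
#' \deqn{RR(v) = \Delta(G) - d(v) + 2,}
#' where \eqn{\Delta(G)} is the maximum degree of the graph and d(v) the
#' degree of v. The minimum attainable value is 2, attained exactly by the
#' vertices of maximum degree. \eqn{\Delta(G)} is always computed on the
#' graph that is passed in, never on a larger chemical family.
#'
#' @param g a non-empty \code{MolecularGraph}.
#' @return named integer vector of labels, all >= 2.
#' @export
reducedReverseDegrees <- function(g) {
  d <- degreeMap(g)
  maxDegree(g) - d + 2L
}

#' Edge partition by endpoint labels
#'
#' Groups the edges of a graph by the unordered pair of endpoint labels,
#' under either plain-degree or reduced-reverse-degree labeling. Class counts
#' always sum to the edge count, and the partition is invariant under vertex
#' relabeling.
#'
#' @param g a non-empty \code{MolecularGraph}.
#' @param labeling \code{"degree"} or \code{"reduced_reverse"}.
#' @return an \code{\linkS4class{EdgePartition}}.
#' @examples
#' hexagon <- buildGraph(cbind(1:6, c(2:6, 1)))
#' edgePartition(hexagon, "reduced_reverse")  # single class (2,2): 6
#' @export
edgePartition <- function(g, labeling = c("degree", "reduced_reverse")) {
  stopifnot(methods::is(g, "MolecularGraph"))
  labeling <- match.arg(labeling)
  labels <- switch(labeling,
                   degree = degreeMap(g),
                   reduced_reverse = reducedReverseDegrees(g))
  em <- edgeMatrix(g)
  la <- labels[em[, 1L]]
  lb <- labels[em[, 2L]]
  a <- pmax(la, lb)
  b <- pmin(la, lb)
  if (length(a) == 0L) {
    classes <- data.frame(a = integer(0), b = integer(0), count = integer(0))
  } else {
    agg <- stats::aggregate(list(count = rep(1L, length(a))),
                            by = list(a = a, b = b), FUN = sum)
    classes <- agg[order(-agg$a, -agg$b), , drop = FALSE]
    rownames(classes) <- NULL
  }
  methods::new("EdgePartition", labeling = labeling, classes = classes)
}

#' Construct an edge partition from explicit classes
#'
#' @param labeling \code{"degree"} or \code{"reduced_reverse"}.
#' @param a,b positive integer endpoint labels (canonicalized internally).
#' @param count non-negative integer edge counts per class.
#' @return an \code{\linkS4class{EdgePartition}}.
#' @export
newEdgePartition <- function(labeling, a, b, count) {
  hi <- pmax(a, b); lo <- pmin(a, b)
  classes <- data.frame(a = as.integer(hi), b = as.integer(lo),
                        count = as.numeric(count))
  classes <- classes[order(-classes$a, -classes$b), , drop = FALSE]
  rownames(classes) <- NULL
  methods::new("EdgePartition", labeling = labeling, classes = classes)
}

#' Construct a symbolic edge partition from explicit classes
#'
#' @param labeling \code{"degree"} or \code{"reduced_reverse"}.
#' @param a,b positive integer endpoint labels (canonicalized internally).
#' @param slope,intercept integer coefficients of each class count, a
#'   linear form slope*n + intercept in the repeat count n.
#' @return a \code{\linkS4class{SymbolicEdgePartition}}.
#' @export
newSymbolicPartition <- function(labeling, a, b, slope, intercept) {
  hi <- pmax(a, b); lo <- pmin(a, b)
  classes <- data.frame(a = as.integer(hi), b = as.integer(lo),
                        slope = as.numeric(slope),
                        intercept = as.numeric(intercept))
  classes <- classes[order(-classes$a, -classes$b), , drop = FALSE]
  rownames(classes) <- NULL
  methods::new("SymbolicEdgePartition", labeling = labeling, classes = classes)
}

#' Total number of edges of a partition
#' @param p an \code{EdgePartition}.
#' @return numeric scalar, the sum of class counts.
#' @export
totalEdgeCount <- function(p) {
  stopifnot(methods::is(p, "EdgePartition"))
  sum(p@classes$count)
}

#' Total edge count of a symbolic partition, as a linear form
#' @param sp a \code{SymbolicEdgePartition}.
#' @return a \code{\linkS4class{LinearForm}} in the repeat count n.
#' @export
totalEdgeForm <- function(sp) {
  stopifnot(methods::is(sp, "SymbolicEdgePartition"))
  methods::new("LinearForm", slope = sum(sp@classes$slope),
               intercept = sum(sp@classes$intercept))
}

#' Instantiate a symbolic partition at a concrete repeat count
#'
#' @param sp a \code{SymbolicEdgePartition}.
#' @param n integer repeat count, n >= 1.
#' @return the \code{\linkS4class{EdgePartition}} whose counts are the class
#'   forms evaluated at n.
#' @export
instantiatePartition <- function(sp, n) {
  stopifnot(methods::is(sp, "SymbolicEdgePartition"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("n must be a single integer >= 1")
  cl <- sp@classes
  newEdgePartition(sp@labeling, cl$a, cl$b, cl$slope * n + cl$intercept)
}
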