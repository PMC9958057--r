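# Benzenoid systems are built on a flat-top hexagonal lattice in axial
# coordinates (q, r). Scaling corner positions by (2, 2/sqrt(3)) makes every
# corner an integer lattice point, so shared corners of adjacent hexagons
# unify exactly, with no floating-point merging rule.

.HEX_NEIGHBOURS <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                         c(1, -1), c(-1, 1))

.hexCorners <- function(q, r) {
  cx <- 3L * q
  cy <- 2L * r + q
  dx <- c(2L, 1L, -1L, -2L, -1L, 1L)
  dy <- c(0L, 1L, 1L, 0L, -1L, -1L)
  cbind(x = cx + dx, y = cy + dy)
}

#' Benzenoid (fused-hexagon) molecular graph
#'
#' Builds the hydrogen-suppressed skeleton of a benzenoid system from a set
#' of hexagon cells in axial lattice coordinates. Each cell contributes its
#' six boundary vertices and edges; corners and edges shared between adjacent
#' cells are merged. All vertex degrees are 2 or 3. For h cells fused in a
#' catafused (tree-like) arrangement the graph has 4h + 2 vertices and
#' 5h + 1 edges.
#'
#' @param cells two-column integer matrix (or list of length-2 vectors) of
#'   axial coordinates (q, r), one hexagon per row. The cell set must be
#'   edge-connected.
#' @return a \code{\linkS4class{MolecularGraph}}.
#' @examples
#' benzene <- hexagonalSystem(rbind(c(0, 0)))
#' naphthalene <- hexagonalSystem(rbind(c(0, 0), c(1, 0)))
#' edgeCount(naphthalene)  # 11
#' @export
hexagonalSystem <- function(cells) {
  if (is.list(cells) && !is.data.frame(cells))
    cells <- do.call(rbind, cells)
  cells <- as.matrix(cells)
  if (ncol(cells) != 2L || nrow(cells) == 0L)
    stop("cells must be a non-empty two-column matrix of axial coordinates")
  storage.mode(cells) <- "integer"
  cells <- unique(cells)
  if (!.hexConnected(cells))
    stop("hexagon cell set must be edge-connected")
  edges <- NULL
  for (i in seq_len(nrow(cells))) {
    co <- .hexCorners(cells[i, 1L], cells[i, 2L])
    ids <- paste(co[, 1L], co[, 2L], sep = ":")
    edges <- rbind(edges, cbind(ids, ids[c(2:6, 1L)]))
  }
  buildGraph(edges)
}

.hexConnected <- function(cells) {
  n <- nrow(cells)
  if (n == 1L) return(TRUE)
  key <- paste(cells[, 1L], cells[, 2L])
  seen <- logical(n)
  seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (i in frontier) {
      nb <- sweep(.HEX_NEIGHBOURS, 2L, cells[i, ], `+`)
      hits <- match(paste(nb[, 1L], nb[, 2L]), key)
      hits <- hits[!is.na(hits)]
      hits <- hits[!seen[hits]]
      seen[hits] <- TRUE
      nxt <- c(nxt, hits)
    }
    frontier <- nxt
  }
  all(seen)
}

#' Symbolic edge partition of the hyaluronic-acid--paclitaxel conjugate
#'
#' The reduced-reverse-degree edge partition of the (HAP)_n conjugate
#' polymer, n >= 1: nine label classes whose counts are linear in the number
#' of repeat units n. Loaded from the packaged fixture; the total edge count
#' is 96n.
#'
#' @return a \code{\linkS4class{SymbolicEdgePartition}}.
#' @export
hapPartition <- function() loadFixture("hap_partition")

#' Published closed-form HAP index polynomials
#'
#' The closed forms as printed in the source tables, for comparison with
#' \code{\link{closedForm}} on the packaged partition. Two of the printed
#' forms (RRGA and the Randic type with exponent -1/2) do not agree with
#' direct summation over the partition; see
#' \code{\link{hapClosedFormReport}}.
#'
#' @return data.frame with columns \code{index}, \code{slope},
#'   \code{intercept}.
#' @export
hapPrintedForms <- function() loadFixture("hap_printed_forms")

#' Computed versus published HAP closed forms
#'
#' Recomputes every reduced-reverse closed form from the packaged partition
#' by direct weighted summation and tabulates it against the published
#' coefficients. Agreement holds to printed precision for eight of the ten
#' indices; the RRGA and Randic(-1/2) rows disagree and are reported, not
#' reconciled.
#'
#' @return data.frame with computed and printed slope/intercept columns and
#'   an \code{agrees} flag (slopes within 5e-4 relative, i.e. agreement at
#'   the precision the coefficients were printed with).
#' @export
hapClosedFormReport <- function() {
  sp <- hapPartition()
  printed <- hapPrintedForms()
  computed <- lapply(printed$index, function(nm) closedForm(sp, nm))
  out <- data.frame(
    index = printed$index,
    computed.slope = vapply(computed, formSlope, numeric(1)),
    computed.intercept = vapply(computed, formIntercept, numeric(1)),
    printed.slope = printed$slope,
    printed.intercept = printed$intercept)
  out$agrees <- abs(out$computed.slope - out$printed.slope) <=
    5e-4 * pmax(1, abs(out$printed.slope))
  out
}

#' Vertex count implied by an edge partition
#'
#' For a graph without isolated vertices, summing 1/d(u) + 1/d(v) over all
#' edges counts every vertex exactly once. Mapping a reduced-reverse label a
#' back to a degree via d = delta + 2 - a therefore recovers the vertex
#' count of the family from its symbolic partition, as a linear form in n.
#'
#' @param sp a \code{\linkS4class{SymbolicEdgePartition}} with
#'   reduced-reverse labeling.
#' @param delta the maximum degree of the underlying graphs; every label a
#'   must satisfy 2 <= a <= delta + 1 so that the implied degree is >= 1.
#' @return a \code{\linkS4class{LinearForm}} (vertices as a function of n).
#' @examples
#' impliedVertexForm(hapPartition(), delta = 4)  # slope 87
#' @export
impliedVertexForm <- function(sp, delta) {
  stopifnot(methods::is(sp, "SymbolicEdgePartition"))
  w <- .reciprocalDegreeWeights(sp@classes, delta)
  methods::new("LinearForm",
               slope = sum(sp@classes$slope * w),
               intercept = sum(sp@classes$intercept * w))
}

#' @rdname impliedVertexForm
#' @param p a numeric \code{\linkS4class{EdgePartition}} with reduced-reverse
#'   labeling (for \code{impliedVertexCount}).
#' @export
impliedVertexCount <- function(p, delta) {
  stopifnot(methods::is(p, "EdgePartition"))
  w <- .reciprocalDegreeWeights(p@classes, delta)
  sum(p@classes$count * w)
}

.reciprocalDegreeWeights <- function(classes, delta) {
  stopifnot(is.numeric(delta), length(delta) == 1L, delta >= 1)
  labels <- c(classes$a, classes$b)
  if (any(labels < 2 | labels > delta + 1))
    stop(sprintf(
      "labels must lie in [2, %d] for maximum degree %d (implied degree >= 1)",
      as.integer(delta) + 1L, as.integer(delta)))
  da <- delta + 2 - classes$a
  db <- delta + 2 - classes$b
  1 / da + 1 / db
}

#' Random connected molecular graph
#'
#' Generates a connected simple graph with all vertex degrees bounded by
#' \code{maxDeg}: a random recursive tree under the degree cap, plus up to
#' \code{nVertices} random extra edges where capacity allows. Deterministic
#' for a fixed seed (the caller's RNG state is left untouched).
#'
#' @param nVertices number of vertices, >= 2.
#' @param maxDeg degree cap, >= 1 (>= 2 whenever nVertices > 2).
#' @param seed integer seed.
#' @return a \code{\linkS4class{MolecularGraph}}.
#' @export
randomMolecularGraph <- function(nVertices, maxDeg, seed) {
  stopifnot(nVertices >= 2, maxDeg >= 1)
  if (nVertices > 2 && maxDeg < 2)
    stop("a connected graph on more than 2 vertices needs maxDeg >= 2")
  .withSeed(seed, {
    deg <- integer(nVertices)
    edges <- matrix(integer(0), ncol = 2L)
    for (v in 2:nVertices) {
      candidates <- which(deg[seq_len(v - 1L)] < maxDeg)
      u <- if (length(candidates) == 1L) candidates else sample(candidates, 1L)
      edges <- rbind(edges, c(u, v))
      deg[u] <- deg[u] + 1L
      deg[v] <- deg[v] + 1L
    }
    seenKey <- paste(edges[, 1L], edges[, 2L])
    for (i in seq_len(nVertices)) {
      uv <- sort(sample.int(nVertices, 2L))
      key <- paste(uv[1L], uv[2L])
      if (!(key %in% seenKey) && deg[uv[1L]] < maxDeg && deg[uv[2L]] < maxDeg) {
        edges <- rbind(edges, uv)
        deg[uv] <- deg[uv] + 1L
        seenKey <- c(seenKey, key)
      }
    }
    buildGraph(matrix(paste0("v", edges), ncol = 2L))
  })
}

# Evaluate expr under a fixed seed without disturbing the session RNG.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
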