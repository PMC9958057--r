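#' Read a molecular graph from an edge-list file
#'
#' One edge per line, two whitespace- or tab-separated vertex identifiers;
#' everything after \code{#} is a comment; blank lines are ignored.
#'
#' @param path file path.
#' @return a \code{\linkS4class{MolecularGraph}}.
#' @export
readEdgeList <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop(sprintf("no edges in %s", path))
  toks <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad) > 0L)
    stop(sprintf("line %d does not have exactly two identifiers", bad[1L]))
  buildGraph(do.call(rbind, toks))
}

#' Write an edge partition to JSON or CSV
#'
#' JSON schema: \code{{"labeling": ..., "classes": [{"a":5,"b":4,"count":2},
#' ...]}}; symbolic partitions use \code{"slope"}/\code{"intercept"} instead
#' of \code{"count"}. CSV carries the same columns plus a \code{labeling}
#' column.
#'
#' @param p an \code{EdgePartition} or \code{SymbolicEdgePartition}.
#' @param path output file path.
#' @param format \code{"json"} or \code{"csv"}; defaults from the file
#'   extension.
#' @return \code{path}, invisibly.
#' @export
writePartition <- function(p, path, format = NULL) {
  stopifnot(methods::is(p, "EdgePartition") ||
            methods::is(p, "SymbolicEdgePartition"))
  if (is.null(format))
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  format <- match.arg(format, c("json", "csv"))
  cl <- partitionClasses(p)
  if (format == "json") {
    jsonlite::write_json(list(labeling = labelingKind(p), classes = cl),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(cbind(labeling = labelingKind(p), cl), path,
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read an edge partition from JSON or CSV
#'
#' Symbolic and numeric partitions are distinguished by their fields
#' (\code{slope}/\code{intercept} versus \code{count}).
#'
#' @param path file written by \code{\link{writePartition}} (or following
#'   its schema).
#' @return an \code{EdgePartition} or \code{SymbolicEdgePartition}.
#' @export
readPartition <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
    labeling <- unique(df$labeling)
    if (length(labeling) != 1L)
      stop("CSV partition must have a single labeling value")
    cl <- df[setdiff(names(df), "labeling")]
  } else {
    obj <- jsonlite::fromJSON(path)
    labeling <- obj$labeling
    cl <- as.data.frame(obj$classes)
  }
  if (all(c("slope", "intercept") %in% names(cl)))
    newSymbolicPartition(labeling, cl$a, cl$b, cl$slope, cl$intercept)
  else if ("count" %in% names(cl))
    newEdgePartition(labeling, cl$a, cl$b, cl$count)
  else stop("partition file has neither 'count' nor 'slope'/'intercept' fields")
}

#' Read a hexagonal system from JSON
#'
#' Schema: \code{{"cells": [[0,0],[1,0], ...]}} with axial (q, r) hexagon
#' coordinates.
#'
#' @param path JSON file path.
#' @return a \code{\linkS4class{MolecularGraph}} built by
#'   \code{\link{hexagonalSystem}}.
#' @export
readHexSystem <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  obj <- jsonlite::fromJSON(path)
  if (is.null(obj$cells)) stop("hex system JSON must have a 'cells' field")
  hexagonalSystem(obj$cells)
}
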