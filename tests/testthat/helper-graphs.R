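# Small named structures used across the test files.

makeCycle <- function(n) buildGraph(cbind(seq_len(n), c(seq_len(n)[-1], 1L)))

makePath <- function(n) buildGraph(cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L))

hexChain <- function(h) hexagonalSystem(cbind(seq_len(h) - 1L, 0L))

# seeded bank of random test graphs with varied size and degree cap
randomGraphBank <- function(nGraphs, baseSeed = 20260923) {
  lapply(seq_len(nGraphs), function(i) {
    randomMolecularGraph(nVertices = 8L + (i %% 30L),
                         maxDeg = 2L + (i %% 4L),
                         seed = baseSeed + i)
  })
}

# apply a deterministic vertex-name bijection
relabelGraph <- function(g, seed = 1L) {
  nm <- vertexNames(g)
  perm <- withr_seed_sample(nm, seed)
  map <- stats::setNames(paste0("w", seq_along(nm)), perm)
  em <- edgeMatrix(g)
  buildGraph(cbind(map[em[, 1L]], map[em[, 2L]]))
}

withr_seed_sample <- function(x, seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(x)
}
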