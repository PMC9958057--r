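test_that("catalog holds the 26 documented specs with correct weights", {
  cat <- indexCatalog()
  expect_length(cat, 26L)
  expect_equal(sum(vapply(cat, function(s) s@labeling, "") ==
                     "reduced_reverse"), 10L)
  expect_equal(sum(vapply(cat, function(s) s@labeling, "") == "degree"), 16L)

  expect_equal(weightFunction(getIndexSpec("RRM1"))(2, 2), 4)
  expect_equal(weightFunction(getIndexSpec("RRABC"))(5, 3), sqrt(6 / 15))
  expect_equal(weightFunction(getIndexSpec("RRR", alpha = -1))(2, 2), 0.25)
  expect_equal(weightFunction(getIndexSpec("GO1"))(2, 3), 11)
  expect_equal(weightFunction(getIndexSpec("HGO2"))(2, 2), 256)
  expect_equal(weightFunction(getIndexSpec("H"))(2, 2), 0.5)
  # lookups are case-insensitive; unknown names list the alternatives
  expect_equal(indexName(getIndexSpec("rrga")), "RRGA")
  expect_error(getIndexSpec("XYZ"), "RRM1")
})

test_that("direct edge summation matches the worked examples", {
  hexagon <- makeCycle(6)
  expect_equal(indexValue(hexagon, getIndexSpec("RRR", alpha = -1)), 1.5)
  expect_equal(indexValue(hexagon, "RRM1"), 24)
  # naphthalene under the classical Randic(-1): 6/4 + 4/6 + 1/9
  expect_equal(indexValue(hexChain(2), "R_-1"), 6 / 4 + 4 / 6 + 1 / 9)
  # no edges -> 0, with a warning about the isolated vertices
  iso <- buildGraph(rbind(c("a", "b")), vertices = "c")
  expect_warning(v <- indexValue(iso, "M1"), "isolated")
  expect_equal(v, 2)  # single edge with both endpoint degrees 1
})

test_that("partition summation agrees with examples and rejects mismatches", {
  p <- newEdgePartition("reduced_reverse", 2, 2, 6)
  expect_equal(indexFromPartition(p, "RRM1"), 24)
  expect_equal(totalEdgeCount(instantiatePartition(hapPartition(), 1)), 96)
  pq <- newEdgePartition("reduced_reverse", 3, 2, 2)
  expect_equal(indexFromPartition(pq, "RRGA"), 2 * (2 * sqrt(6) / 5))
  expect_error(indexFromPartition(p, "M1"), "labeling")
})

test_that("closed forms weight slopes and intercepts separately", {
  f <- closedForm(hapPartition(), "RRM1")
  expect_equal(formSlope(f), 664)
  expect_equal(formIntercept(f), 4)
  f <- closedForm(hapPartition(), "RRF")
  expect_equal(formSlope(f), 2418)
  expect_equal(formIntercept(f), 30)
  sp <- newSymbolicPartition("reduced_reverse", 2, 2, 1, 0)
  f <- closedForm(sp, "RRM2")
  expect_equal(formSlope(f), 4)
  expect_equal(formIntercept(f), 0)
  expect_error(closedForm(hapPartition(), "M1"), "labeling")
})

test_that("linear forms evaluate as slope*n + intercept for n >= 1", {
  f <- new("LinearForm", slope = 664, intercept = 4)
  expect_equal(evaluateForm(f, 1), 668)
  expect_equal(evaluateForm(new("LinearForm", slope = 0, intercept = 0), 7), 0)
  expect_equal(evaluateForm(new("LinearForm", slope = 8.8986,
                                intercept = -0.0819), 2), 17.7153)
  expect_error(evaluateForm(f, 0), "positive integer")
})

test_that("direct sums equal partition sums for every catalog spec", {
  cat <- indexCatalog()
  for (g in randomGraphBank(50)) {
    pDeg <- edgePartition(g, "degree")
    pRR <- edgePartition(g, "reduced_reverse")
    for (spec in cat) {
      p <- if (spec@labeling == "degree") pDeg else pRR
      expect_equal(indexValue(g, spec), indexFromPartition(p, spec),
                   tolerance = 1e-9)
    }
  }
})

test_that("closed forms agree with instantiated partitions for n = 1..5", {
  sp <- hapPartition()
  for (spec in indexCatalog()) {
    if (spec@labeling != "reduced_reverse") next
    f <- closedForm(sp, spec)
    for (n in 1:5)
      expect_equal(evaluateForm(f, n),
                   indexFromPartition(instantiatePartition(sp, n), spec),
                   tolerance = 1e-9)
  }
})

test_that("Randic exponent 1 coincides with the second Zagreb weight", {
  rrr1 <- randicSpec(1, "reduced_reverse")
  for (g in randomGraphBank(10))
    expect_equal(indexValue(g, rrr1), indexValue(g, "RRM2"))
})

test_that("geometric-arithmetic sums are bounded by the edge count", {
  for (g in randomGraphBank(10)) {
    for (nm in c("RRGA", "GA"))
      expect_lte(indexValue(g, nm), edgeCount(g) + 1e-12)
  }
  # equality iff every edge joins equally labelled endpoints
  expect_equal(indexValue(makeCycle(6), "RRGA"), 6)
  expect_lt(indexValue(makePath(3), "RRGA"), 2)
})

test_that("index values are invariant under vertex relabeling", {
  g <- randomMolecularGraph(25, 3, seed = 11)
  h <- relabelGraph(g, seed = 2)
  for (nm in c("RRM1", "RRABC", "GA", "HGO2", "R_-0.5"))
    expect_equal(indexValue(h, nm), indexValue(g, nm), tolerance = 1e-12)
})
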