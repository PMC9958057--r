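test_that("buildGraph constructs simple graphs and collapses duplicates", {
  g <- buildGraph(rbind(c(1, 2), c(2, 3)))
  expect_equal(vertexCount(g), 3L)
  expect_equal(edgeCount(g), 2L)

  hexagon <- makeCycle(6)
  expect_equal(vertexCount(hexagon), 6L)
  expect_equal(edgeCount(hexagon), 6L)
  expect_true(all(degreeMap(hexagon) == 2L))

  dup <- buildGraph(rbind(c(1, 2), c(2, 1)))
  expect_equal(vertexCount(dup), 2L)
  expect_equal(edgeCount(dup), 1L)
})

test_that("buildGraph rejects self-loops naming the offending pair", {
  expect_error(buildGraph(rbind(c(1, 2), c(3, 3))), "\\(3, 3\\)")
})

test_that("degree map matches incidence counts and the handshake lemma", {
  expect_equal(unname(degreeMap(makePath(3))), c(1L, 2L, 1L))
  naph <- hexChain(2)
  d <- degreeMap(naph)
  expect_equal(sum(d == 2L), 8L)
  expect_equal(sum(d == 3L), 2L)
  for (g in randomGraphBank(10))
    expect_equal(sum(degreeMap(g)), 2L * edgeCount(g))
})

test_that("maximum degree is the max over the degree map", {
  expect_equal(maxDegree(makeCycle(6)), 2L)
  expect_equal(maxDegree(hexChain(2)), 3L)
  star <- buildGraph(cbind("c", paste0("leaf", 1:4)))
  expect_equal(maxDegree(star), 4L)
})

test_that("reduced reverse degrees are Delta - d + 2 with minimum 2", {
  expect_true(all(reducedReverseDegrees(makeCycle(6)) == 2L))
  # path on 3 vertices: Delta = 2, leaves labelled 3, centre labelled 2
  rr <- reducedReverseDegrees(makePath(3))
  expect_equal(sort(unname(rr)), c(2L, 3L, 3L))
  # a degree-1 vertex in a Delta = 4 graph gets label 5
  star <- buildGraph(cbind("c", paste0("leaf", 1:4)))
  expect_equal(unname(reducedReverseDegrees(star)[["leaf1"]]), 5L)
  for (g in randomGraphBank(10)) {
    rr <- reducedReverseDegrees(g)
    expect_true(all(rr >= 2L))
    expect_equal(unname(rr == 2L), unname(degreeMap(g) == maxDegree(g)))
  }
})

test_that("edge partitions cover all edges in canonical classes", {
  p <- edgePartition(makeCycle(6), "reduced_reverse")
  expect_equal(partitionClasses(p),
               data.frame(a = 2L, b = 2L, count = 6L))

  p3 <- edgePartition(makePath(3), "reduced_reverse")
  expect_equal(partitionClasses(p3),
               data.frame(a = 3L, b = 2L, count = 2L))

  pd <- edgePartition(hexChain(2), "degree")
  expect_equal(partitionClasses(pd),
               data.frame(a = c(3L, 3L, 2L), b = c(3L, 2L, 2L),
                          count = c(1L, 4L, 6L)))

  for (g in randomGraphBank(10)) {
    for (kind in c("degree", "reduced_reverse"))
      expect_equal(totalEdgeCount(edgePartition(g, kind)), edgeCount(g))
  }
  expect_error(edgePartition(makeCycle(6), "bogus"))
})

test_that("edge partitions are invariant under vertex relabeling", {
  for (g in randomGraphBank(5)) {
    h <- relabelGraph(g)
    for (kind in c("degree", "reduced_reverse"))
      expect_equal(partitionClasses(edgePartition(h, kind)),
                   partitionClasses(edgePartition(g, kind)))
  }
})

test_that("edge-list reader handles comments and blank lines", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# benzene ring", "1 2", "", "2\t3", "3 4 # bond",
               "4 5", "5 6", "6 1"), f)
  g <- readEdgeList(f)
  expect_equal(edgeCount(g), 6L)
  expect_true(all(degreeMap(g) == 2L))
  expect_error(readEdgeList(file.path(tempdir(), "missing.txt")),
               "not found")
})

test_that("partitions round-trip through JSON and CSV", {
  p <- edgePartition(hexChain(3), "reduced_reverse")
  for (ext in c(".json", ".csv")) {
    f <- withr::local_tempfile(fileext = ext)
    writePartition(p, f)
    q <- readPartition(f)
    expect_equal(labelingKind(q), labelingKind(p))
    expect_equal(partitionClasses(q), partitionClasses(p))
  }
  sp <- hapPartition()
  f <- withr::local_tempfile(fileext = ".json")
  writePartition(sp, f)
  expect_equal(partitionClasses(readPartition(f)), partitionClasses(sp))
})
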