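test_that("exact polynomial data are recovered exactly", {
  x <- 1:10
  fit <- fitPolynomial(x, 2 * x + 1, degree = 1)
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 1e-10)
  expect_equal(diagnostics(fit)$r.squared, 1, tolerance = 1e-12)

  fitq <- fitPolynomial(x, 3 * x^2 - x + 0.5, degree = 2)
  expect_equal(unname(coef(fitq)), c(0.5, -1, 3), tolerance = 1e-9)
  expect_error(fitPolynomial(rep(2, 10), 1:10, 1), "rank deficient")
  expect_error(fitPolynomial(1:3, 1:3, 2), "at least")
})

test_that("near-noiseless data recover generating coefficients to 1e-6", {
  set.seed(42)
  x <- runif(40, 1, 6)
  eps <- rnorm(40, sd = 1e-9)
  fit <- fitPolynomial(x, 4.2 * x - 7.5 + eps, degree = 1)
  expect_equal(unname(coef(fit)), c(-7.5, 4.2), tolerance = 1e-6)
  fitq <- fitPolynomial(x, -1.1 * x^2 + 0.3 * x + 2 + eps, degree = 2)
  expect_equal(unname(coef(fitq)), c(2, 0.3, -1.1), tolerance = 1e-6)
})

test_that("OLS residuals on the training data sum to zero", {
  for (degree in 1:2) {
    props <- loadFixture("benzenoid_properties")
    ti <- loadFixture("benzenoid_ti")[["RRR_-1"]]
    fit <- fitPolynomial(ti, props$BP, degree)
    expect_equal(sum(props$BP - predict(fit, ti)), 0, tolerance = 1e-8)
  }
})

test_that("explicit-coefficient models evaluate the printed equations", {
  lin <- polynomialModel(gamma = -75.26, a1 = 129)
  expect_equal(predict(lin, 1.5), 118.24)
  quad <- polynomialModel(gamma = -192.6, a1 = 202.4, a2 = -10.47)
  expect_equal(predict(quad, 1.5), 87.4425)
  expect_equal(predict(polynomialModel(0, 0), 3.7), 0)
})

test_that("chi-square statistic is the residual form with positive observed", {
  expect_equal(chiSquareGof(c(4), c(2)), 1)
  expect_equal(chiSquareGof(c(3, 7), c(3, 7)), 0)
  expect_error(chiSquareGof(c(1, 0), c(1, 1)), "positive")
  o <- c(10, 20, 30); p <- c(12, 18, 33)
  perm <- c(3, 1, 2)
  expect_equal(chiSquareGof(o[perm], p[perm]), chiSquareGof(o, p))
  expect_equal(chisqCritical(25, 0.05), 37.652, tolerance = 1e-4)
  expect_true(gofAccept(20))
  expect_false(gofAccept(40))
})

test_that("average residual percent is the mean absolute relative error", {
  expect_equal(avgResidualPercent(c(100), c(90)), 10)
  expect_equal(avgResidualPercent(c(5, 8), c(5, 8)), 0)
  expect_error(avgResidualPercent(c(1, 0), c(1, 1)), "nonzero")
  o <- c(10, 20, 30); p <- c(12, 18, 33)
  perm <- c(2, 3, 1)
  expect_equal(avgResidualPercent(o[perm], p[perm]), avgResidualPercent(o, p))
})

test_that("both RMSE denominator conventions are available", {
  expect_equal(rmse(c(1, 2), c(1, 2), "n"), 0)
  expect_equal(rmse(c(3, 4), c(0, 0), "n"), sqrt(12.5))
  expect_equal(rmse(c(3, 4), c(0, 0), "n-p", p = 1), 5)
  expect_error(rmse(c(3, 4), c(0, 0), "n-p", p = 2), "positive")
})

test_that("quadratic R-squared dominates linear on every packaged property", {
  props <- loadFixture("benzenoid_properties")
  ti <- loadFixture("benzenoid_ti")[["RRR_-1"]]
  for (prop in setdiff(names(props), "SNo")) {
    r1 <- diagnostics(fitPolynomial(ti, props[[prop]], 1))$r.squared
    r2 <- diagnostics(fitPolynomial(ti, props[[prop]], 2))$r.squared
    expect_gte(r2, r1 - 1e-12)
  }
})

test_that("model selection screens on R-squared and flags failures", {
  set.seed(7)
  x <- runif(26, 1, 5)
  strong <- data.frame(good = x)
  y <- data.frame(P = 3 * x + rnorm(26, sd = 0.1))
  sel <- selectBestModels(y, strong, degree = 1)
  expect_equal(sel$summary$index, "good")
  expect_gte(sel$summary$r.squared, 0.8)

  weak <- data.frame(bad = rnorm(26))
  sel2 <- selectBestModels(y, weak, degree = 1)
  expect_true(is.na(sel2$summary$index))
  expect_match(sel2$summary$flag, "none above threshold")

  both <- data.frame(noisy = x + rnorm(26, sd = 0.4), clean = x)
  sel3 <- selectBestModels(y, both, degree = 1)
  expect_equal(sel3$summary$index, "clean")

  flat <- data.frame(P = rep(5, 26))
  sel4 <- selectBestModels(flat, strong, degree = 1)
  expect_match(sel4$summary$flag, "degenerate")
})

test_that("comparison reports give one row per property", {
  props <- loadFixture("benzenoid_properties")
  props <- props[setdiff(names(props), "SNo")]
  ti <- loadFixture("benzenoid_ti")[["RRR_-1"]]
  rr <- data.frame(`RRR_-1` = ti, check.names = FALSE)
  set.seed(3)
  classical <- data.frame(M1 = ti^2 + rnorm(26, sd = 2),
                          ABC = sqrt(ti) + rnorm(26, sd = 0.05))
  rep <- comparisonReport(props, rr, classical)
  expect_equal(nrow(rep), ncol(props))
  expect_equal(rep$property, names(props))
  bp <- rep[rep$property == "BP", ]
  expect_equal(bp$rr.linear.index, "RRR_-1")
  expect_gte(bp$rr.quadratic.r.squared, bp$rr.linear.r.squared - 1e-12)
})
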