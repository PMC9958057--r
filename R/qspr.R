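#' Fit a curvilinear QSPR model by ordinary least squares
#'
#' Fits P = a1*TI + gamma (degree 1) or P = a2*TI^2 + a1*TI + gamma
#' (degree 2) by OLS and populates the diagnostics of the benzenoid study
#' from the unrounded fit: R-squared, the residual-based chi-square
#' statistic (\code{\link{chiSquareGof}}), the mean absolute residual
#' percentage, and RMSE under both the n and n - p denominator conventions.
#'
#' @param x numeric vector of index values (not all identical).
#' @param y numeric vector of property values, same length, length >=
#'   degree + 2.
#' @param degree 1 or 2.
#' @param property,index optional names carried into the result.
#' @return a \code{\linkS4class{QsprFit}}.
#' @examples
#' fit <- fitPolynomial(1:10, 2 * (1:10) + 1, degree = 1)
#' coef(fit)  # gamma 1, a1 2
#' @export
fitPolynomial <- function(x, y, degree = 1, property = "", index = "") {
  stopifnot(is.numeric(x), is.numeric(y))
  degree <- as.integer(degree)
  if (!(degree %in% c(1L, 2L))) stop("degree must be 1 or 2")
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < degree + 2L)
    stop(sprintf("need at least %d observations for degree %d",
                 degree + 2L, degree))
  if (stats::sd(x) == 0)
    stop("design is rank deficient: all x values are identical")
  fit <- if (degree == 1L) stats::lm(y ~ x)
         else stats::lm(y ~ x + I(x^2))
  co <- unname(stats::coef(fit))
  coefs <- if (degree == 1L) c(gamma = co[1L], a1 = co[2L])
           else c(gamma = co[1L], a1 = co[2L], a2 = co[3L])
  pred <- unname(stats::fitted(fit))
  methods::new("QsprFit", degree = degree, coefficients = coefs,
               property = property, index = index, fit = fit,
               diagnostics = .qsprDiagnostics(y, pred, degree,
                                              summary(fit)$r.squared))
}

.qsprDiagnostics <- function(observed, predicted, degree, r.squared) {
  p <- degree + 1L
  list(
    r.squared = r.squared,
    chi.square = if (all(observed > 0))
      chiSquareGof(observed, predicted) else NA_real_,
    avg.residual.pct = if (all(observed != 0))
      avgResidualPercent(observed, predicted) else NA_real_,
    rmse.n = rmse(observed, predicted, "n"),
    rmse.np = rmse(observed, predicted, "n-p", p = p))
}

#' QSPR model from explicit (e.g. published) coefficients
#'
#' Builds a \code{\linkS4class{QsprFit}} from given polynomial coefficients,
#' without fitting. Used to evaluate published, rounded model equations
#' against observed data.
#'
#' @param gamma constant term.
#' @param a1 linear coefficient.
#' @param a2 quadratic coefficient; supply to get a degree-2 model.
#' @param property,index optional names carried into the result.
#' @return a \code{\linkS4class{QsprFit}} with empty diagnostics.
#' @export
polynomialModel <- function(gamma, a1, a2 = NULL, property = "", index = "") {
  degree <- if (is.null(a2) || (length(a2) == 1L && a2 == 0)) 1L else 2L
  coefs <- if (degree == 1L) c(gamma = gamma, a1 = a1)
           else c(gamma = gamma, a1 = a1, a2 = a2)
  methods::new("QsprFit", degree = degree, coefficients = coefs,
               property = property, index = index, fit = NULL,
               diagnostics = list())
}

#' @describeIn fitPolynomial evaluate a fitted or explicit model at new
#'   index values.
#' @param object a \code{QsprFit}.
#' @param newdata numeric vector of index values.
#' @param ... unused.
#' @export
setMethod("predict", "QsprFit", function(object, newdata, ...) {
  co <- object@coefficients
  out <- co[["gamma"]] + co[["a1"]] * newdata
  if (object@degree == 2L) out <- out + co[["a2"]] * newdata^2
  unname(out)
})

#' @describeIn fitPolynomial model coefficients, named \code{gamma},
#'   \code{a1} (and \code{a2}).
#' @export
setMethod("coef", "QsprFit", function(object, ...) object@coefficients)

#' Diagnostics of a QSPR model
#'
#' @param object a \code{QsprFit}.
#' @return named list: \code{r.squared}, \code{chi.square},
#'   \code{avg.residual.pct}, \code{rmse.n}, \code{rmse.np}. Empty for
#'   explicit-coefficient models (compute them against data with
#'   \code{\link{modelDiagnostics}}).
#' @export
diagnostics <- function(object) {
  stopifnot(methods::is(object, "QsprFit"))
  object@diagnostics
}

#' Compute diagnostics of a model against observed data
#'
#' Evaluates the model at \code{x} and returns the study's diagnostics for
#' the resulting predictions. R-squared is reported as the squared Pearson
#' correlation between observed and predicted values (identical to the OLS
#' coefficient of determination when the model was fitted to these data).
#'
#' @param object a \code{QsprFit}.
#' @param x numeric vector of index values.
#' @param y numeric vector of observed property values.
#' @return named list as in \code{\link{diagnostics}}.
#' @export
modelDiagnostics <- function(object, x, y) {
  stopifnot(methods::is(object, "QsprFit"), length(x) == length(y))
  pred <- predict(object, x)
  .qsprDiagnostics(y, pred, object@degree, stats::cor(y, pred)^2)
}

#' Residual-based chi-square goodness-of-fit statistic
#'
#' The statistic used in the benzenoid study: sum over molecules of
#' (observed - predicted)^2 / observed. This is a residual statistic on
#' continuous measurements, not a counts-based Pearson test; the study
#' compares it against the tabulated critical value 37.652 (25 degrees of
#' freedom, 5 percent level), available as \code{\link{chisqCritical}}.
#'
#' @param observed positive numeric vector.
#' @param predicted numeric vector of equal length.
#' @return the statistic (non-negative scalar).
#' @export
chiSquareGof <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (any(observed <= 0))
    stop("all observed values must be positive")
  sum((observed - predicted)^2 / observed)
}

#' Critical value for the chi-square goodness-of-fit comparison
#'
#' @param df degrees of freedom; the study uses the number of molecules
#'   minus one (25).
#' @param level significance level.
#' @return upper critical value; 37.65 at the defaults.
#' @export
chisqCritical <- function(df = 25, level = 0.05) {
  stats::qchisq(1 - level, df)
}

#' Accept or reject a model by the chi-square criterion
#'
#' @param statistic value returned by \code{\link{chiSquareGof}}.
#' @param critical critical value (defaults to the study's packaged
#'   constant, 37.652).
#' @return \code{TRUE} if the model is accepted (statistic below the
#'   critical value).
#' @export
gofAccept <- function(statistic, critical = loadFixture("chi2_critical")) {
  statistic < critical
}

#' Mean absolute residual percentage
#'
#' Mean over records of 100 * |observed - predicted| / observed.
#'
#' @param observed numeric vector with no zero entries.
#' @param predicted numeric vector of equal length.
#' @return non-negative scalar.
#' @export
avgResidualPercent <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (any(observed == 0))
    stop("observed values must be nonzero")
  mean(100 * abs(observed - predicted) / observed)
}

#' Root mean square error
#'
#' Both denominator conventions are exposed because published tables do not
#' always state which was used: \code{"n"} divides the residual sum of
#' squares by the number of records, \code{"n-p"} by the residual degrees of
#' freedom.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param denominator \code{"n"} or \code{"n-p"}.
#' @param p number of model coefficients (including the constant); required
#'   for \code{"n-p"}.
#' @return non-negative scalar.
#' @export
rmse <- function(observed, predicted, denominator = c("n", "n-p"), p = 2L) {
  stopifnot(length(observed) == length(predicted))
  denominator <- match.arg(denominator)
  den <- if (denominator == "n") length(observed) else length(observed) - p
  if (den <= 0) stop("denominator must be positive")
  sqrt(sum((observed - predicted)^2) / den)
}

#' Best index per property under the R-squared screen
#'
#' Fits every supplied index column against every property at the given
#' polynomial degree, discards fits with R-squared below the screening
#' threshold (0.8, the IAMC recommendation adopted by the study), and keeps
#' the maximum-R-squared survivor. Exact ties are broken by fewer model
#' coefficients, then lexicographically by index name. Properties with no
#' survivor are flagged, not dropped.
#'
#' @param properties data.frame of property columns (numeric), one row per
#'   molecule.
#' @param indexValues data.frame or named list of index-value vectors
#'   aligned with \code{properties}.
#' @param degree 1 or 2.
#' @param threshold R-squared screening threshold.
#' @return list with \code{summary} (data.frame: property, index, degree,
#'   r.squared, flag) and \code{models} (named list of \code{QsprFit},
#'   keyed \code{"property~index"}).
#' @export
selectBestModels <- function(properties, indexValues, degree = 1,
                             threshold = 0.8) {
  properties <- as.data.frame(properties)
  indexValues <- as.data.frame(indexValues, optional = TRUE,
                               check.names = FALSE)
  stopifnot(nrow(properties) == nrow(indexValues))
  rows <- list(); models <- list()
  for (prop in names(properties)) {
    y <- properties[[prop]]
    if (stats::sd(y) == 0) {
      rows[[prop]] <- data.frame(property = prop, index = NA_character_,
                                 degree = degree, r.squared = NA_real_,
                                 flag = "degenerate response")
      next
    }
    fits <- list(); r2 <- numeric(0)
    for (idx in names(indexValues)) {
      f <- fitPolynomial(indexValues[[idx]], y, degree,
                         property = prop, index = idx)
      fits[[idx]] <- f
      r2[idx] <- diagnostics(f)$r.squared
    }
    if (!any(is.finite(r2))) {
      rows[[prop]] <- data.frame(property = prop, index = NA_character_,
                                 degree = degree, r.squared = NA_real_,
                                 flag = "degenerate response")
      next
    }
    ok <- names(r2)[is.finite(r2) & r2 >= threshold]
    if (length(ok) == 0L) {
      rows[[prop]] <- data.frame(property = prop, index = NA_character_,
                                 degree = degree,
                                 r.squared = max(r2, na.rm = TRUE),
                                 flag = "none above threshold")
      next
    }
    best <- ok[order(-r2[ok], ok)][1L]
    rows[[prop]] <- data.frame(property = prop, index = best,
                               degree = degree, r.squared = r2[[best]],
                               flag = "")
    models[[paste0(prop, "~", best)]] <- fits[[best]]
  }
  list(summary = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       models = models)
}

#' Reduced-reverse versus classical index comparison report
#'
#' For each property, reports the best classical degree-based index (linear
#' fit) and the best reduced-reverse index for both the linear and the
#' quadratic model, with their R-squared values: the shape of the study's
#' comparison table.
#'
#' @param properties data.frame of property columns, one row per molecule.
#' @param rrValues reduced-reverse index value columns (data.frame or named
#'   list), aligned with \code{properties}.
#' @param classicalValues classical index value columns, aligned likewise.
#' @param threshold R-squared screening threshold passed through to
#'   \code{\link{selectBestModels}}.
#' @return data.frame with one row per property.
#' @export
comparisonReport <- function(properties, rrValues, classicalValues,
                             threshold = 0.8) {
  cls <- selectBestModels(properties, classicalValues, 1, threshold)$summary
  rr1 <- selectBestModels(properties, rrValues, 1, threshold)$summary
  rr2 <- selectBestModels(properties, rrValues, 2, threshold)$summary
  data.frame(
    property = cls$property,
    classical.index = cls$index,
    classical.r.squared = cls$r.squared,
    rr.linear.index = rr1$index,
    rr.linear.r.squared = rr1$r.squared,
    rr.quadratic.index = rr2$index,
    rr.quadratic.r.squared = rr2$r.squared,
    flag = ifelse(nzchar(cls$flag) | nzchar(rr1$flag) | nzchar(rr2$flag),
                  trimws(paste(cls$flag, rr1$flag, rr2$flag)), ""))
}
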