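# Packaged in-study data. Loaders parse from inst/extdata on every call, so
# callers always receive fresh (defensive) copies.

.fixturePath <- function(file) {
  p <- system.file("extdata", file, package = "rrtopo")
  if (!nzchar(p)) stop(sprintf("packaged fixture file missing: %s", file))
  p
}

.FIXTURES <- list(
  benzenoid_properties = function() {
    df <- utils::read.csv(.fixturePath("benzenoid_properties.csv"),
                          check.names = FALSE)
    stopifnot(nrow(df) == 26L, !anyNA(df), all(df$EM < df$MW),
              all(df$HAC == round(df$HAC) & df$HAC > 0))
    df
  },
  benzenoid_ti = function() {
    df <- utils::read.csv(.fixturePath("benzenoid_ti.csv"),
                          check.names = FALSE)
    stopifnot(nrow(df) == 26L, !anyNA(df))
    df
  },
  model_coefficients = function() {
    df <- utils::read.csv(.fixturePath("model_coefficients.csv"),
                          check.names = FALSE)
    stopifnot(nrow(df) == 24L, !anyNA(df))
    df
  },
  hap_partition = function()
    readPartition(.fixturePath("hap_partition.json")),
  hap_printed_forms = function()
    utils::read.csv(.fixturePath("hap_printed_forms.csv"),
                    check.names = FALSE),
  chi2_critical = function() 37.652
)

#' Names of the packaged fixtures
#' @return character vector of identifiers accepted by
#'   \code{\link{loadFixture}}.
#' @export
fixtureNames <- function() names(.FIXTURES)

#' Load a packaged fixture
#'
#' The bundle holds the in-study data: the 26-molecule benzenoid property
#' table (\code{"benzenoid_properties"}; columns BP, CT, CP, CV, GE, LogP,
#' MR, HL, PI, MW, EM, HAC), the published reduced-reverse Randic(-1) index
#' column for those molecules (\code{"benzenoid_ti"}), the published linear
#' and quadratic model coefficients (\code{"model_coefficients"}), the
#' symbolic edge partition of the HAP conjugate family
#' (\code{"hap_partition"}), the published HAP closed forms
#' (\code{"hap_printed_forms"}), and the chi-square critical constant
#' (\code{"chi2_critical"}, 37.652 at 25 d.o.f. and the 5 percent level).
#' Loaders validate on read and return fresh copies.
#'
#' @param name fixture identifier, see \code{\link{fixtureNames}}.
#' @return the parsed fixture (data.frame, partition object, or scalar).
#' @examples
#' props <- loadFixture("benzenoid_properties")
#' props$BP[1]  # 80.1
#' @export
loadFixture <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(name %in% names(.FIXTURES)))
    stop(sprintf("unknown fixture %s; available: %s", sQuote(name),
                 paste(names(.FIXTURES), collapse = ", ")))
  .FIXTURES[[name]]()
}

#' Published model coefficients as QsprFit objects
#'
#' @param degree 1 (linear) or 2 (quadratic).
#' @param property optional property name filter.
#' @return named list of \code{\linkS4class{QsprFit}} objects built from the
#'   published coefficients, keyed by property.
#' @export
printedModels <- function(degree = 1, property = NULL) {
  co <- loadFixture("model_coefficients")
  co <- co[co$degree == degree, , drop = FALSE]
  if (!is.null(property)) co <- co[co$property %in% property, , drop = FALSE]
  out <- lapply(seq_len(nrow(co)), function(i)
    polynomialModel(gamma = co$gamma[i], a1 = co$a1[i],
                    a2 = if (degree == 2) co$a2[i] else NULL,
                    property = co$property[i], index = co$index[i]))
  names(out) <- co$property
  out
}
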