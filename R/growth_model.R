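#' Growth-model coefficient set
#'
#' Bundles the six regression coefficients of the seminal-root growth model:
#' a logistic time course
#' \deqn{SRL(DAS) = K / (1 + C e^{-r\,DAS})}
#' whose upper asymptote \eqn{K} (the "full length" of the seminal root, mm)
#' is a unimodal Hoerl-type function of the PEG 6000 mass concentration
#' \deqn{K(PEG) = a\,(PEG + d)^{b}\, e^{-c (PEG + d)}.}
#'
#' The logistic shape coefficient `C` is taken positive with a `+` sign in
#' the denominator, the canonical convention under which the curve rises
#' from low values towards the asymptote `K`; see the methods vignette for
#' the sign-convention discussion.
#'
#' @param C dimensionless logistic shape coefficient, > 0.
#' @param r logistic growth rate, per day, > 0.
#' @param a Hoerl scale coefficient, mm %^-b, > 0.
#' @param b dimensionless Hoerl power, > 0.
#' @param c Hoerl decay rate, per % PEG, > 0.
#' @param d PEG concentration offset, %, >= 0.
#' @return An object of class `growth_params`: a named numeric vector with
#'   elements `C`, `r`, `a`, `b`, `c`, `d`.
#' @seealso [reference_params()] for the published coefficient set used as
#'   the package default, [full_length_K()], [predict_srl()].
#' @examples
#' p <- growth_params(C = 2.402, r = 0.235, a = 5.64, b = 4, c = 0.677, d = 0)
#' optimal_peg(p)
#' @export
growth_params <- function(C, r, a, b, c, d = 0) {
  p <- c(C = as.numeric(C), r = as.numeric(r), a = as.numeric(a),
         b = as.numeric(b), c = as.numeric(c), d = as.numeric(d))
  validate_growth_params(p)
  structure(p, class = "growth_params")
}

validate_growth_params <- function(p) {
  if (length(p) != 6L || !all(c("C", "r", "a", "b", "c", "d") %in% names(p)))
    stop("growth_params requires the six coefficients C, r, a, b, c, d",
         call. = FALSE)
  if (any(!is.finite(p)))
    stop("growth_params coefficients must be finite", call. = FALSE)
  bad <- character(0)
  if (p[["C"]] <= 0) bad <- c(bad, "C > 0")
  if (p[["r"]] <= 0) bad <- c(bad, "r > 0")
  if (p[["a"]] <= 0) bad <- c(bad, "a > 0")
  if (p[["b"]] <= 0) bad <- c(bad, "b > 0")
  if (p[["c"]] <= 0) bad <- c(bad, "c > 0")
  if (p[["d"]] < 0)  bad <- c(bad, "d >= 0")
  if (length(bad))
    stop("invalid growth_params: require ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(p)
}

#' @export
print.growth_params <- function(x, digits = 4, ...) {
  cat("Seminal-root growth model coefficients:\n")
  print(signif(unclass(x), digits))
  if (x[["b"]] / x[["c"]] > x[["d"]]) {
    cat(sprintf("Optimum: K = %.0f mm at %.1f%% PEG\n",
                max_full_length(x), optimal_peg(x)))
  }
  invisible(x)
}

#' Published reference coefficients
#'
#' The coefficient set estimated from a glasshouse experiment on rice cv.
#' Nipponbare grown hydroponically in PEG 6000 solutions at consecutive
#' concentrations (1% steps, 0--25%), with seminal root length measured
#' daily from images between 7 and 20 days after seeding. Shipped as the
#' package's reference parameterization: it is the default for the
#' synthetic-data generator and the worked examples.
#'
#' Under these coefficients the full seminal root length K peaks at 126 mm
#' at 5.9% PEG.
#'
#' @return A [growth_params()] object with C = 2.402, r = 0.235, a = 5.64,
#'   b = 4.00, c = 0.677, d = 0.
#' @export
reference_params <- function() {
  growth_params(C = 2.402, r = 0.235, a = 5.64, b = 4.00, c = 0.677, d = 0)
}

#' Logistic seminal-root time course
#'
#' Evaluates the logistic growth curve
#' \eqn{SRL = K / (1 + C e^{-r\,DAS})} for given asymptote `K`.
#'
#' @param das days after seeding; non-negative, real-valued, vectorised.
#' @param K upper asymptote (full seminal root length), mm, >= 0. Recycled
#'   against `das`.
#' @param params a [growth_params()] object (only `C` and `r` are used).
#' @return SRL in mm, in `[0, K)`; strictly increasing in `das` and tending
#'   to `K` as `das` grows.
#' @export
logistic_srl <- function(das, K, params) {
  validate_growth_params(params)
  if (any(das < 0)) stop("das must be >= 0", call. = FALSE)
  if (any(K < 0)) stop("K must be >= 0", call. = FALSE)
  K / (1 + params[["C"]] * exp(-params[["r"]] * das))
}

#' Full seminal root length as a function of PEG concentration
#'
#' Evaluates the Hoerl-type dose-response
#' \eqn{K(PEG) = a (PEG + d)^b e^{-c(PEG + d)}}, the asymptote of the
#' logistic time course. The curve rises from zero, peaks at
#' \eqn{PEG = b/c - d} and decays towards zero: mild osmotic stress
#' promotes seminal-root elongation while strong stress suppresses it.
#'
#' @param peg PEG 6000 mass concentration, %; vectorised, requires
#'   `peg + d >= 0`.
#' @inheritParams logistic_srl
#' @return K in mm (>= 0).
#' @export
full_length_K <- function(peg, params) {
  validate_growth_params(params)
  x <- peg + params[["d"]]
  if (any(x < 0)) stop("peg + d must be >= 0", call. = FALSE)
  params[["a"]] * x^params[["b"]] * exp(-params[["c"]] * x)
}

#' Predicted seminal root length
#'
#' Composition of the dose-response asymptote and the logistic time course:
#' `logistic_srl(das, full_length_K(peg, params), params)`.
#'
#' @inheritParams full_length_K
#' @inheritParams logistic_srl
#' @return SRL in mm. `peg` and `das` are recycled against each other.
#' @export
predict_srl <- function(peg, das, params) {
  logistic_srl(das, full_length_K(peg, params), params)
}

#' Analytic derivative of the full length with respect to PEG
#'
#' The exact derivative of [full_length_K()]:
#' \deqn{dK/dPEG = a\, e^{-c(PEG+d)} (PEG+d)^{b-1} \{b - c (PEG+d)\}.}
#' It vanishes at the interior optimum \eqn{PEG = b/c - d}, is positive on
#' the rising limb and negative beyond the peak.
#'
#' @inheritParams full_length_K
#' @return dK/dPEG in mm per % PEG.
#' @export
dK_dPEG <- function(peg, params) {
  validate_growth_params(params)
  x <- peg + params[["d"]]
  if (any(x <= 0) && params[["b"]] < 1)
    stop("dK/dPEG undefined at peg + d <= 0 when b < 1", call. = FALSE)
  if (any(x < 0)) stop("peg + d must be >= 0", call. = FALSE)
  a <- params[["a"]]; b <- params[["b"]]; cc <- params[["c"]]
  a * exp(-cc * x) * x^(b - 1) * (b - cc * x)
}

#' PEG concentration maximizing the full seminal root length
#'
#' Closed form `b/c - d`, the unique interior maximizer of
#' [full_length_K()]. Requires `b/c > d` so that the optimum lies at a
#' nonnegative concentration.
#'
#' @inheritParams full_length_K
#' @return Optimal PEG concentration, %.
#' @export
optimal_peg <- function(params) {
  validate_growth_params(params)
  opt <- params[["b"]] / params[["c"]] - params[["d"]]
  if (opt <= 0)
    stop("no interior maximum at nonnegative PEG: b/c <= d", call. = FALSE)
  opt
}

#' Maximum full seminal root length
#'
#' [full_length_K()] evaluated at [optimal_peg()].
#'
#' @inheritParams full_length_K
#' @return K at the optimum, mm.
#' @export
max_full_length <- function(params) {
  full_length_K(optimal_peg(params), params)
}

# Anchor table for the % PEG -> osmotic pressure lookup. The first row pins
# pure water at zero; the remaining rows are the printed equivalences for
# this PEG 6000 / temperature regime. Above the last anchor the final
# segment's slope is extended.
.osmotic_anchors <- data.frame(
  peg = c(0, 3, 5.9, 11),
  mpa = c(0, 0.01, 0.04, 0.15)
)

#' Osmotic-pressure equivalent of a PEG 6000 concentration
#'
#' A documentation utility, not a physical model: monotone piecewise-linear
#' interpolation through anchor equivalences (3% -> 0.01 MPa,
#' 5.9% -> 0.04 MPa, 11% -> 0.15 MPa) reported for this experimental
#' regime, pinned at 0% -> 0 MPa and extended linearly above 11%. The
#' underlying concentration-to-water-potential conversion depends on
#' temperature and on the mass-concentration basis and is not reproduced
#' here.
#'
#' @param peg PEG 6000 concentration, %; must lie in `[0, 25]`. Vectorised.
#' @return Osmotic pressure equivalent, MPa (nonnegative, monotone
#'   nondecreasing in `peg`).
#' @export
osmotic_equivalent <- function(peg) {
  if (any(peg < 0 | peg > 25))
    stop("peg must lie in [0, 25]", call. = FALSE)
  anc <- .osmotic_anchors
  slope_hi <- diff(utils::tail(anc$mpa, 2)) / diff(utils::tail(anc$peg, 2))
  ifelse(peg > max(anc$peg),
         max(anc$mpa) + slope_hi * (peg - max(anc$peg)),
         stats::approx(anc$peg, anc$mpa, xout = pmin(peg, max(anc$peg)),
                       method = "linear", rule = 2)$y)
}

#' Serialize growth-model coefficients to JSON
#'
#' @param params a [growth_params()] object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`): a flat
#'   object with keys `C`, `r`, `a`, `b`, `c`, `d`.
#' @export
params_to_json <- function(params, path = NULL) {
  validate_growth_params(params)
  js <- jsonlite::toJSON(as.list(unclass(params)), auto_unbox = TRUE,
                         digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' Deserialize growth-model coefficients from JSON
#'
#' @param x a JSON string or a path to a JSON file holding a flat object
#'   with keys `C`, `r`, `a`, `b`, `c`, `d`.
#' @return A [growth_params()] object.
#' @export
params_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  need <- c("C", "r", "a", "b", "c", "d")
  if (!all(need %in% names(obj)))
    stop("JSON must contain keys C, r, a, b, c, d", call. = FALSE)
  growth_params(C = obj$C, r = obj$r, a = obj$a, b = obj$b, c = obj$c,
                d = obj$d)
}
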