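# Joint nonlinear least squares for the six-coefficient growth model.
#
# The objective is sum over rows of (srl - predict_srl(peg, das, theta))^2.
# The scale coefficient a enters the prediction linearly, so it is profiled
# out analytically at every objective evaluation: for fixed (C, r, b, c, d)
# the prediction is a * g(peg, das) and the optimal a is
# sum(y g) / sum(g^2), clipped to its bounds. This leaves a 4- (d fixed)
# or 5-dimensional problem optimized on the log scale, which removes the
# severe a/b/c scale coupling of the raw parameterization.

.fit_bounds <- list(C = c(1e-6, 100), r = c(1e-6, 5), a = c(1e-12, 1e6),
                    b = c(1e-6, 20), c = c(1e-6, 10), d = c(0, 10))

# basis g such that prediction = a * g; theta named (C, r, b, c, d)
.fit_basis <- function(theta, peg, das) {
  x <- peg + theta[["d"]]
  x^theta[["b"]] * exp(-theta[["c"]] * x) /
    (1 + theta[["C"]] * exp(-theta[["r"]] * das))
}

.profile_a <- function(g, y) {
  denom <- sum(g * g)
  if (!is.finite(denom) || denom <= 0) return(.fit_bounds$a[1])
  min(max(sum(y * g) / denom, .fit_bounds$a[1]), .fit_bounds$a[2])
}

.fit_sse <- function(theta, peg, das, y) {
  g <- .fit_basis(theta, peg, das)
  if (any(!is.finite(g))) return(.Machine$double.xmax)
  a <- .profile_a(g, y)
  sse <- sum((y - a * g)^2)
  if (!is.finite(sse)) .Machine$double.xmax else sse
}

# pack/unpack: log scale for C, r, b, c; raw scale for d (boundary at 0)
.fit_pack <- function(theta, fix_d) {
  v <- log(theta[c("C", "r", "b", "c")])
  if (!fix_d) v <- c(v, d = theta[["d"]])
  v
}

.fit_unpack <- function(v, fix_d, d0 = 0) {
  theta <- c(exp(v[1:4]), if (fix_d) d0 else max(v[[5]], 0))
  names(theta) <- c("C", "r", "b", "c", "d")
  theta
}

#' Fit the growth model to an observation table
#'
#' Jointly estimates the coefficients (C, r, a, b, c and optionally d) of
#' the logistic-with-Hoerl-asymptote growth model by unweighted nonlinear
#' least squares over all rows of a long-format observation table. The
#' scale coefficient `a` is profiled out analytically; the remaining
#' coefficients are optimized (L-BFGS-B on the log scale, Nelder-Mead
#' polish) from a multi-start scheme: the default start
#' (C, r, a, b, c, d) = (2, 0.2, 1, 2, 0.5, 0) plus seeded multiplicative
#' log-normal perturbations. The best start by final SSE wins, ties broken
#' by start index.
#'
#' Identifiability requires at least 2 distinct observation days (to
#' separate C and r) and at least 4 distinct PEG levels (to pin the
#' dose-response shape).
#'
#' @param table a long-format observation table with columns `peg`, `das`,
#'   `replicate`, `srl`, `source` (see [generate_observations()]).
#' @param fix_d if `TRUE` (default) the concentration offset d is fixed at
#'   0, the boundary value reported for the reference experiment;
#'   otherwise d is estimated on `[0, 10]`.
#' @param n_starts number of multi-start initial points (>= 1).
#' @param seed integer seed for the start perturbations.
#' @return An object of class `fit_result`: a list with elements `params`
#'   ([growth_params()]), `sse` (mm^2), `r_squared`, `rmse` (mm), `n_obs`,
#'   `converged`, `n_starts`, `start_sses` (initial objective value of
#'   each start) and `seed`.
#' @examples
#' tab <- generate_observations(experiment_design(), reference_params(),
#'                              noise_model(additive_sd = 0, seed = 1))
#' fit <- fit_growth_model(tab, seed = 1)
#' fit$params
#' @export
fit_growth_model <- function(table, fix_d = TRUE, n_starts = 10, seed = 1L) {
  validate_observation_table(table)
  if (length(unique(table$das)) < 2L)
    stop("identifiability: need >= 2 distinct DAS values", call. = FALSE)
  if (length(unique(table$peg)) < 4L)
    stop("identifiability: need >= 4 distinct PEG levels", call. = FALSE)
  if (n_starts < 1L) stop("n_starts must be >= 1", call. = FALSE)
  peg <- table$peg; das <- table$das; y <- table$srl

  base <- c(C = 2, r = 0.2, b = 2, c = 0.5, d = 0)
  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      if (i == 1L) return(base)
      s <- base
      s[c("C", "r", "b", "c")] <- s[c("C", "r", "b", "c")] *
        stats::rlnorm(4, 0, 0.5)
      if (!fix_d) s[["d"]] <- stats::runif(1, 0, 2)
      s
    })
  })

  lower <- log(c(.fit_bounds$C[1], .fit_bounds$r[1],
                 .fit_bounds$b[1], .fit_bounds$c[1]))
  upper <- log(c(.fit_bounds$C[2], .fit_bounds$r[2],
                 .fit_bounds$b[2], .fit_bounds$c[2]))
  if (!fix_d) {
    lower <- c(lower, .fit_bounds$d[1])
    upper <- c(upper, .fit_bounds$d[2])
  }

  obj <- function(v) .fit_sse(.fit_unpack(v, fix_d), peg, das, y)

  run_start <- function(s) {
    v0 <- .fit_pack(s, fix_d)
    sse0 <- obj(v0)
    fit <- tryCatch(
      stats::optim(v0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 2000, factr = 1e3)),
      error = function(e) list(par = v0, value = sse0, convergence = 52L))
    # Nelder-Mead polish then a second bounded pass; iterate until the
    # relative SSE improvement stalls (< 1e-10) or the eval budget is hit.
    best <- fit
    for (k in 1:6) {
      prev <- best$value
      nm <- stats::optim(best$par, function(v)
        obj(pmin(pmax(v, lower), upper)),
        method = "Nelder-Mead",
        control = list(maxit = 2000, reltol = 1e-14))
      nm$par <- pmin(pmax(nm$par, lower), upper)
      lb <- tryCatch(
        stats::optim(nm$par, obj, method = "L-BFGS-B", lower = lower,
                     upper = upper,
                     control = list(maxit = 2000, factr = 1e3)),
        error = function(e) nm)
      best <- if (lb$value <= nm$value) lb else nm
      if (prev - best$value < 1e-10 * max(prev, .Machine$double.eps)) break
    }
    list(par = best$par, sse = best$value, sse0 = sse0,
         converged = k < 6 || isTRUE(best$convergence == 0))
  }

  runs <- lapply(starts, run_start)
  sses <- vapply(runs, `[[`, numeric(1), "sse")
  best_i <- which.min(sses)  # ties: first index
  best <- runs[[best_i]]
  theta <- .fit_unpack(best$par, fix_d)
  g <- .fit_basis(theta, peg, das)
  a_hat <- .profile_a(g, y)
  params <- growth_params(C = theta[["C"]], r = theta[["r"]], a = a_hat,
                          b = theta[["b"]], c = theta[["c"]],
                          d = theta[["d"]])
  gof <- goodness_of_fit(table, params)
  structure(list(params = params,
                 sse = best$sse,
                 r_squared = gof[["r_squared"]],
                 rmse = gof[["rmse"]],
                 n_obs = nrow(table),
                 converged = isTRUE(best$converged),
                 n_starts = as.integer(n_starts),
                 start_sses = vapply(runs, `[[`, numeric(1), "sse0"),
                 seed = as.integer(seed)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Growth-model fit: n = %d, SSE = %.4g mm^2, R^2 = %.3f, RMSE = %.2f mm\n",
              x$n_obs, x$sse, x$r_squared, x$rmse))
  print(x$params)
  if (!x$converged) cat("warning: optimizer did not report convergence\n")
  invisible(x)
}

#' Goodness of fit of a coefficient set on an observation table
#'
#' Pooled coefficient of determination and root mean square error of the
#' model predictions over all rows: `r_squared = 1 - SSE/SST` with SST
#' taken about the grand mean of the observed SRL values, and
#' `rmse = sqrt(SSE / n)`.
#'
#' @inheritParams fit_growth_model
#' @param params a [growth_params()] object.
#' @return Named numeric vector `c(r_squared = , rmse = )`.
#' @export
goodness_of_fit <- function(table, params) {
  validate_observation_table(table)
  pred <- predict_srl(table$peg, table$das, params)
  sse <- sum((table$srl - pred)^2)
  sst <- sum((table$srl - mean(table$srl))^2)
  if (sst == 0)
    stop("SST is zero: observations are constant", call. = FALSE)
  c(r_squared = 1 - sse / sst, rmse = sqrt(sse / nrow(table)))
}

#' Compare the modelled full length K with harvest measurements
#'
#' Root mean square error between `full_length_K(peg, params)` and the
#' directly measured SRL of a single-day harvest table (typically the
#' 30-DAS ruler measurement), across all rows.
#'
#' @param harvest an observation table whose rows share one `das` value.
#' @param params a [growth_params()] object.
#' @return RMSE in mm.
#' @export
compare_K_to_harvest <- function(harvest, params) {
  validate_observation_table(harvest)
  if (length(unique(harvest$das)) != 1L)
    stop("harvest table must contain a single DAS value", call. = FALSE)
  k <- full_length_K(harvest$peg, params)
  sqrt(mean((harvest$srl - k)^2))
}

#' Serialize a fit result to JSON
#'
#' @param fit a `fit_result` from [fit_growth_model()].
#' @param path optional file path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`) with the
#'   coefficients and the fields `sse`, `r_squared`, `rmse`, `n_obs`,
#'   `converged`, `seed`, `n_starts`.
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  obj <- list(coefficients = as.list(unclass(fit$params)),
              sse = fit$sse, r_squared = fit$r_squared, rmse = fit$rmse,
              n_obs = fit$n_obs, converged = fit$converged,
              seed = fit$seed, n_starts = fit$n_starts)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}
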