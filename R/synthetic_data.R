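#' Consecutive-concentration experiment design
#'
#' Describes the sampling scheme of a consecutive-PEG root-growth
#' experiment: which PEG levels are prepared, which failed and are
#' excluded from analysis, the daily observation window, the number of
#' replicate bottles, and the day of the destructive ruler harvest.
#'
#' The defaults emulate the design of the reference study: 26 levels
#' (0--25% in 1% steps) of which 0% and 6% failed, 3 replicate bottles per
#' level, daily image observation from 7 to 20 days after seeding (DAS),
#' and a ruler harvest at 30 DAS. With these defaults the observation
#' table has 24 x 14 x 3 = 1008 rows.
#'
#' @param peg_levels numeric vector of prepared PEG concentrations (%).
#' @param excluded_levels levels dropped from the analysis (failed
#'   treatments); must be a subset of `peg_levels`.
#' @param das_range inclusive integer span of daily observations,
#'   `c(first, last)`.
#' @param replications number of replicate bottles per level, >= 1.
#' @param harvest_das day of the destructive ruler measurement.
#' @param one_photo_per_treatment_day if `TRUE`, only a single (seeded)
#'   replicate is retained per treatment-day, emulating selection of one
#'   usable photo per treatment per day (336 rows under the defaults).
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(peg_levels = 0:25,
                              excluded_levels = c(0, 6),
                              das_range = c(7, 20),
                              replications = 3,
                              harvest_das = 30,
                              one_photo_per_treatment_day = FALSE) {
  if (!all(excluded_levels %in% peg_levels))
    stop("excluded_levels must be a subset of peg_levels", call. = FALSE)
  if (any(peg_levels < 0 | peg_levels > 100))
    stop("peg_levels must lie in [0, 100]", call. = FALSE)
  if (replications < 1) stop("replications must be >= 1", call. = FALSE)
  if (length(das_range) != 2L || das_range[2] < das_range[1])
    stop("das_range must be c(first, last) with last >= first",
         call. = FALSE)
  included <- sort(setdiff(peg_levels, excluded_levels))
  if (length(included) == 0L)
    stop("design excludes every PEG level", call. = FALSE)
  structure(list(peg_levels = sort(unique(peg_levels)),
                 excluded_levels = sort(unique(excluded_levels)),
                 das_range = as.integer(das_range),
                 replications = as.integer(replications),
                 harvest_das = as.numeric(harvest_das),
                 one_photo_per_treatment_day =
                   isTRUE(one_photo_per_treatment_day)),
            class = "experiment_design")
}

included_levels <- function(design) {
  sort(setdiff(design$peg_levels, design$excluded_levels))
}

#' @export
print.experiment_design <- function(x, ...) {
  inc <- included_levels(x)
  cat("Consecutive-PEG experiment design\n")
  cat(sprintf("  PEG levels: %d prepared, %d analysed (excluded: %s)\n",
              length(x$peg_levels), length(inc),
              paste(x$excluded_levels, collapse = ", ")))
  cat(sprintf("  DAS %d-%d daily, %d replicate bottle(s), harvest at %g DAS\n",
              x$das_range[1], x$das_range[2], x$replications, x$harvest_das))
  n_das <- x$das_range[2] - x$das_range[1] + 1L
  n <- length(inc) * n_das *
    if (x$one_photo_per_treatment_day) 1L else x$replications
  cat(sprintf("  Observation rows: %d\n", n))
  invisible(x)
}

#' Measurement-noise model for synthetic observations
#'
#' Additive Gaussian noise with an optional proportional component: an
#' observation of a true length `mu` is drawn as
#' `mu + N(0, additive_sd + proportional_cv * mu)` and truncated at zero.
#' The defaults (5 mm additive, no proportional part) stand in for the
#' image-measurement scatter of daily root photographs; the study itself
#' publishes no error model.
#'
#' @param additive_sd additive standard deviation, mm, >= 0.
#' @param proportional_cv coefficient of variation of the proportional
#'   component, dimensionless, >= 0.
#' @param seed integer seed; the same seed always yields identical tables.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(additive_sd = 5, proportional_cv = 0, seed = 1L) {
  if (additive_sd < 0 || proportional_cv < 0)
    stop("noise magnitudes must be >= 0", call. = FALSE)
  structure(list(additive_sd = as.numeric(additive_sd),
                 proportional_cv = as.numeric(proportional_cv),
                 seed = as.integer(seed)),
            class = "noise_model")
}

# Run expr under a private RNG stream, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

new_observation_table <- function(peg, das, replicate, srl, source) {
  df <- data.frame(peg = as.numeric(peg), das = as.numeric(das),
                   replicate = as.integer(replicate),
                   srl = as.numeric(srl), source = as.character(source),
                   stringsAsFactors = FALSE)
  validate_observation_table(df)
  df
}

#' Validate a long-format observation table
#'
#' Checks the schema shared by all pipeline stages: exactly the columns
#' `peg`, `das`, `replicate`, `srl`, `source`; nonnegative lengths; and a
#' unique key `(peg, das, replicate, source)`.
#'
#' @param table a data frame.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_observation_table <- function(table) {
  need <- c("peg", "das", "replicate", "srl", "source")
  if (!is.data.frame(table))
    stop("observation table must be a data frame", call. = FALSE)
  if (!setequal(names(table), need))
    stop("observation table must have exactly the columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(table) == 0L)
    stop("observation table is empty", call. = FALSE)
  if (any(!is.finite(table$srl)) || any(table$srl < 0))
    stop("srl must be finite and >= 0", call. = FALSE)
  if (!all(table$source %in% c("image", "ruler")))
    stop("source must be 'image' or 'ruler'", call. = FALSE)
  key <- paste(table$peg, table$das, table$replicate, table$source)
  if (anyDuplicated(key))
    stop("duplicate (peg, das, replicate, source) keys", call. = FALSE)
  invisible(table)
}

simulate_rows <- function(peg, das, replicate, params, noise, source) {
  mu <- predict_srl(peg, das, params)
  sd <- noise$additive_sd + noise$proportional_cv * mu
  srl <- pmax(0, mu + stats::rnorm(length(mu), 0, sd))
  new_observation_table(peg, das, replicate, srl, source)
}

#' Generate a synthetic daily observation table
#'
#' Simulates the image-based daily SRL record of a consecutive-PEG
#' experiment: one row per included PEG level, observation day and
#' replicate, with `srl` drawn from the growth model plus measurement
#' noise (truncated at zero). Generation is seeded from `noise$seed` and
#' fully reproducible.
#'
#' @param design an [experiment_design()].
#' @param params a [growth_params()] coefficient set.
#' @param noise a [noise_model()].
#' @return A long-format data frame with columns `peg`, `das`,
#'   `replicate`, `srl`, `source` (`"image"`).
#' @examples
#' tab <- generate_observations(experiment_design(), reference_params(),
#'                              noise_model(seed = 42))
#' nrow(tab)  # 1008
#' @export
generate_observations <- function(design, params, noise) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(noise, "noise_model"))
  validate_growth_params(params)
  grid <- expand.grid(replicate = seq_len(design$replications),
                      das = seq(design$das_range[1], design$das_range[2]),
                      peg = included_levels(design))
  grid <- grid[order(grid$peg, grid$das, grid$replicate), ]
  with_seed(noise$seed, {
    if (design$one_photo_per_treatment_day) {
      keep <- unlist(lapply(
        split(seq_len(nrow(grid)), list(grid$peg, grid$das), drop = TRUE),
        function(idx) idx[sample.int(length(idx), 1L)]))
      grid <- grid[sort(keep), ]
    }
    simulate_rows(grid$peg, grid$das, grid$replicate, params, noise, "image")
  })
}

#' Generate a synthetic harvest (ruler) table
#'
#' Simulates the destructive end-of-experiment measurement: one row per
#' included PEG level and replicate at `design$harvest_das`, with
#' `source = "ruler"`. Under the default design this yields 24 x 3 = 72
#' rows. The harvest seed is offset from the observation seed so the two
#' tables use independent noise streams.
#'
#' @inheritParams generate_observations
#' @return A long-format data frame as in [generate_observations()].
#' @export
generate_harvest <- function(design, params, noise) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(noise, "noise_model"))
  validate_growth_params(params)
  grid <- expand.grid(replicate = seq_len(design$replications),
                      peg = included_levels(design))
  grid <- grid[order(grid$peg, grid$replicate), ]
  with_seed(noise$seed + 1000000L, {
    simulate_rows(grid$peg, design$harvest_das, grid$replicate, params,
                  noise, "ruler")
  })
}

#' Read and write observation tables as CSV
#'
#' Lossless long-format CSV round trip with header
#' `peg,das,replicate,srl,source`, dot decimal separator and no row names.
#' Both directions validate the schema (see
#' [validate_observation_table()]).
#'
#' @param table an observation table.
#' @param path file path.
#' @return `write_table` returns `path` invisibly; `read_table` returns
#'   the validated data frame.
#' @export
write_table <- function(table, path) {
  validate_observation_table(table)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_observation_table(df)
  new_observation_table(df$peg, df$das, df$replicate, df$srl, df$source)
}
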