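#' Specify a synthetic county-exposure study
#'
#' Defines the ground truth for a simulated county-level exposure table:
#' the number of counties, a block-correlation structure among standardized
#' exposure variables, planted standardized effects on the outcome, and the
#' outcome noise level. Exposures are jointly Gaussian; real county exposures
#' are mixed-scale, but every variable is z-scored before modelling, so
#' Gaussianity is the minimal structure the downstream models assume.
#'
#' @param n_counties Number of counties (rows) to simulate.
#' @param variable_blocks A list of blocks, each a list or named vector with
#'   elements `size` (number of variables) and `rho` (common within-block
#'   correlation). Variables in different blocks are independent.
#' @param planted_effects Named numeric vector of standardized coefficients;
#'   names must match generated variable names (`B<block>V<index>`).
#' @param noise_sd Standard deviation of the additive Gaussian outcome noise.
#' @param seed Integer master seed; each generator draws from its own
#'   deterministic sub-stream.
#'
#' @return An object of class `synthetic_spec`.
#' @examples
#' spec <- synthetic_spec(
#'   n_counties = 62,
#'   variable_blocks = list(list(size = 4, rho = 0.7), list(size = 16, rho = 0)),
#'   planted_effects = c(B1V1 = 0.5, B2V1 = 0.5),
#'   noise_sd = 1, seed = 1
#' )
#' X <- generate_exposures(spec)
#' @export
synthetic_spec <- function(n_counties = 62,
                           variable_blocks = list(list(size = 20, rho = 0)),
                           planted_effects = c(),
                           noise_sd = 1,
                           seed = 1) {
  assert_scalar_number(n_counties, "n_counties", min = 1)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  assert_scalar_number(seed, "seed")
  if (!is.list(variable_blocks) || length(variable_blocks) == 0) {
    abort("`variable_blocks` must be a non-empty list of blocks.")
  }
  blocks <- purrr::imap(variable_blocks, function(b, i) {
    b <- as.list(b)
    size <- as.integer(b$size)
    rho <- as.numeric(b$rho)
    if (is.na(size) || size < 1) abort(sprintf("block %d: `size` must be >= 1", i))
    if (is.na(rho) || rho < -1 || rho > 1) {
      abort(sprintf("block %d: `rho` must be in [-1, 1]", i))
    }
    # An equicorrelation matrix of dimension m is PSD iff rho >= -1/(m-1).
    if (size > 1 && rho < -1 / (size - 1)) {
      abort(sprintf(
        "block %d: correlation %.3f with %d variables is not positive semi-definite (needs rho >= %.3f)",
        i, rho, size, -1 / (size - 1)
      ))
    }
    list(size = size, rho = rho)
  })
  var_names <- unlist(purrr::imap(blocks, function(b, i) {
    sprintf("B%dV%d", i, seq_len(b$size))
  }))
  effects <- planted_effects
  if (length(effects) > 0) {
    unknown <- setdiff(names(effects), var_names)
    if (length(unknown) > 0) {
      abort(sprintf(
        "planted effect(s) not among generated variables: %s",
        paste(unknown, collapse = ", ")
      ))
    }
  }
  structure(
    list(
      n_counties = as.integer(n_counties), blocks = blocks,
      variables = var_names, planted_effects = effects,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %d counties, %d variables in %d block(s), %d planted effect(s), noise_sd = %g, seed = %d\n",
    x$n_counties, length(x$variables), length(x$blocks),
    length(x$planted_effects), x$noise_sd, x$seed
  ))
  invisible(x)
}

#' Generate a county-by-exposure table
#'
#' Draws standardized exposure variables from a jointly Gaussian model whose
#' correlation matrix is block-diagonal with the within-block correlations
#' given in the spec. Deterministic for a fixed spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with a `county` id column and one column per variable.
#' @export
generate_exposures <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_counties
  cols <- with_substream(spec$seed, "exposures", {
    purrr::imap(spec$blocks, function(b, i) {
      z <- matrix(rnorm(n * b$size), nrow = n)
      if (b$size > 1 && b$rho != 0) {
        R <- matrix(b$rho, b$size, b$size)
        diag(R) <- 1
        z <- z %*% chol(R)
      }
      colnames(z) <- sprintf("B%dV%d", i, seq_len(b$size))
      z
    })
  })
  out <- tibble::as_tibble(do.call(cbind, cols))
  dplyr::bind_cols(tibble::tibble(county = sprintf("C%03d", seq_len(n))), out)
}

#' Generate a linear outcome with planted standardized effects
#'
#' Adds an outcome column `y = sum(beta_i * x_i) + e`, `e ~ N(0, noise_sd^2)`,
#' to an exposure table. The realized population R-squared,
#' `Var(Xb) / (Var(Xb) + noise_sd^2)` with `Var(Xb)` the sample variance of
#' the linear predictor on this design, is attached as attribute
#' `population_r2`.
#'
#' @param data Exposure tibble (e.g. from [generate_exposures()]).
#' @param effects Named numeric vector of standardized coefficients; names
#'   must be columns of `data`.
#' @param noise_sd Noise standard deviation.
#' @param seed Master seed (sub-stream `"outcome"`); `NULL` uses the current
#'   RNG state.
#' @param outcome Name of the outcome column to create.
#' @return `data` with the outcome column appended; attributes
#'   `population_r2` and `linear_predictor_var`.
#' @export
generate_outcome <- function(data, effects, noise_sd, seed = NULL,
                             outcome = "y") {
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  effects <- effects[names(effects) != ""]
  unknown <- setdiff(names(effects), names(data))
  if (length(unknown) > 0) {
    abort(sprintf(
      "unknown effect name(s): %s", paste(unknown, collapse = ", ")
    ))
  }
  n <- nrow(data)
  lp <- rep(0, n)
  for (v in names(effects)) lp <- lp + effects[[v]] * data[[v]]
  eps <- with_substream(seed, "outcome", rnorm(n, 0, noise_sd))
  out <- data
  out[[outcome]] <- lp + eps
  v_lp <- if (n > 1) var(lp) else 0
  attr(out, "linear_predictor_var") <- v_lp
  attr(out, "population_r2") <-
    if (v_lp + noise_sd^2 > 0) v_lp / (v_lp + noise_sd^2) else 0
  out
}

#' Noise level for a target population R-squared
#'
#' Solves `R2 = Var(Xb) / (Var(Xb) + sd^2)` for `sd` on a given design, so
#' outcomes can be calibrated to a target explained-variance fraction.
#'
#' @inheritParams generate_outcome
#' @param r2 Target population R-squared in (0, 1).
#' @return The noise standard deviation.
#' @export
noise_sd_for_r2 <- function(data, effects, r2) {
  if (!is.numeric(r2) || r2 <= 0 || r2 >= 1) abort("`r2` must be in (0, 1).")
  lp <- rep(0, nrow(data))
  for (v in names(effects)) lp <- lp + effects[[v]] * data[[v]]
  sqrt(var(lp) * (1 - r2) / r2)
}

#' Generate Poisson case counts for one county stratum
#'
#' Simulates age-band case counts with mean `rate * population / 100000`,
#' the fixture used to exercise direct age standardization.
#'
#' @param true_rates Nonnegative per-age-band incidence rates per 100,000.
#' @param populations Positive per-age-band person-years, aligned with
#'   `true_rates`.
#' @param seed Master seed (sub-stream `"counts"`); `NULL` uses current RNG.
#' @param age_bands Optional band labels; defaults to names of `true_rates`
#'   or `band1..bandK`.
#' @return Tibble with columns `age_band`, `cases`, `population`.
#' @export
generate_counts <- function(true_rates, populations, seed = NULL,
                            age_bands = NULL) {
  if (length(true_rates) != length(populations)) {
    abort("`true_rates` and `populations` must be aligned (same length).")
  }
  if (any(true_rates < 0) || any(populations < 0)) {
    abort("`true_rates` and `populations` must be nonnegative.")
  }
  bands <- age_bands %||% names(true_rates) %||%
    sprintf("band%d", seq_along(true_rates))
  mu <- true_rates * populations / 1e5
  cases <- with_substream(seed, "counts", rpois(length(mu), mu))
  tibble::tibble(
    age_band = bands,
    cases = as.integer(cases),
    population = as.numeric(populations)
  )
}

#' Specify a piecewise log-linear incidence trend
#'
#' Ground truth for an annual age-standardized rate series whose log is
#' piecewise linear in calendar year with slope `log(1 + APC/100)` in each
#' segment, continuous at the break years (the segmented-regression
#' convention for joinpoint models).
#'
#' @param start_year,end_year First and last calendar years (inclusive).
#' @param baseline_rate Rate per 100,000 at `start_year`.
#' @param segment_apcs 1-3 annual-percent-change values (percent), one per
#'   segment.
#' @param break_years 0-2 interior break years, strictly increasing.
#' @param noise_sd_log SD of Gaussian noise added on the log-rate scale.
#' @param seed Integer master seed.
#' @return An object of class `trend_spec`.
#' @export
trend_spec <- function(start_year = 2000, end_year = 2018,
                       baseline_rate = 50, segment_apcs = 0,
                       break_years = integer(), noise_sd_log = 0,
                       seed = 1) {
  assert_scalar_number(baseline_rate, "baseline_rate", min = 1e-12)
  assert_scalar_number(noise_sd_log, "noise_sd_log", min = 0)
  if (end_year <= start_year) abort("`end_year` must exceed `start_year`.")
  if (length(segment_apcs) != length(break_years) + 1) {
    abort("need exactly one APC per segment: length(segment_apcs) must equal length(break_years) + 1.")
  }
  if (length(segment_apcs) < 1 || length(segment_apcs) > 3) {
    abort("between 1 and 3 segments (0-2 break years) are supported.")
  }
  if (any(segment_apcs <= -100)) {
    abort("APC values must exceed -100% (rates stay positive).")
  }
  if (length(break_years) > 0) {
    if (is.unsorted(break_years, strictly = TRUE)) {
      abort("`break_years` must be strictly increasing.")
    }
    if (min(break_years) <= start_year || max(break_years) >= end_year) {
      abort("`break_years` must lie strictly inside (start_year, end_year).")
    }
  }
  structure(
    list(
      start_year = as.integer(start_year), end_year = as.integer(end_year),
      baseline_rate = baseline_rate, segment_apcs = as.numeric(segment_apcs),
      break_years = as.numeric(break_years), noise_sd_log = noise_sd_log,
      seed = as.integer(seed)
    ),
    class = "trend_spec"
  )
}

#' Generate an annual incidence-rate series from a trend spec
#'
#' @param spec A [trend_spec()].
#' @return Tibble with columns `year` and `rate` (per 100,000).
#' @export
generate_trend_series <- function(spec) {
  stopifnot(inherits(spec, "trend_spec"))
  years <- spec$start_year:spec$end_year
  slopes <- log(1 + spec$segment_apcs / 100)
  # per-year slope: slope of the segment the year-interval [t, t+1) falls in
  seg_of <- findInterval(years[-length(years)], spec$break_years) + 1
  log_rate <- log(spec$baseline_rate) + c(0, cumsum(slopes[seg_of]))
  noise <- with_substream(
    spec$seed, "trend",
    rnorm(length(years), 0, spec$noise_sd_log)
  )
  tibble::tibble(year = years, rate = exp(log_rate + noise))
}

#' Materialize a miniature synthetic study on disk
#'
#' Writes the CSV files the pipeline reads (exposures, stratum counts,
#' standard-population weights, annual trend series) plus a JSON sidecar
#' recording the ground truth, so an end-to-end run can be checked against
#' known parameters.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [synthetic_spec()] for the exposure table and outcome.
#' @param trend A [trend_spec()] for the annual series.
#' @param cancer,age_group,sex Labels for the single simulated stratum.
#' @return Invisibly, a named list of the file paths written.
#' @export
write_fixtures <- function(dir, spec = synthetic_spec(), trend = trend_spec(),
                           cancer = "synthetic", age_group = "25-49",
                           sex = "all") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- generate_exposures(spec)
  Xy <- generate_outcome(X, spec$planted_effects, spec$noise_sd,
    seed = spec$seed
  )
  exposures_path <- file.path(dir, "exposures.csv")
  readr::write_csv(Xy, exposures_path)

  std <- us_standard_population()
  bands <- std$age_band[6:10]
  weights <- std$weight[6:10]
  counts <- purrr::map_dfr(seq_len(spec$n_counties), function(i) {
    cc <- generate_counts(
      true_rates = rep(40, length(bands)),
      populations = rep(5e4, length(bands)),
      seed = spec$seed + i, age_bands = bands
    )
    dplyr::mutate(cc,
      county = sprintf("C%03d", i), cancer = cancer,
      age_group = age_group, sex = sex, .before = 1
    )
  })
  counts_path <- file.path(dir, "counts.csv")
  readr::write_csv(counts, counts_path)
  std_path <- file.path(dir, "std_population.csv")
  readr::write_csv(std[6:10, ], std_path)

  series <- dplyr::mutate(generate_trend_series(trend),
    cancer = cancer, sex = sex
  )
  series_path <- file.path(dir, "trend.csv")
  readr::write_csv(series, series_path)

  truth <- list(
    planted_effects = as.list(spec$planted_effects),
    noise_sd = spec$noise_sd,
    population_r2 = attr(Xy, "population_r2"),
    trend = list(
      segment_apcs = trend$segment_apcs,
      break_years = trend$break_years
    ),
    stratum_true_rate = 40,
    seed = spec$seed
  )
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)

  invisible(list(
    exposures = exposures_path, counts = counts_path,
    std_population = std_path, trend = series_path, truth = truth_path
  ))
}
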