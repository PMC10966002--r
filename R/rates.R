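#' The 2000 U.S. standard population (5-year age bands)
#'
#' Standard-million weights used for direct age standardization, shipped as
#' configuration (a plain CSV under `inst/extdata`) so an alternative
#' standard can be swapped in. Weights are renormalized over whichever bands
#' are present in the data, so partial age ranges (e.g. 25-49) are handled.
#'
#' @return Tibble with columns `age_band` and `weight` (weights sum to 1).
#' @export
us_standard_population <- function() {
  path <- system.file("extdata", "us_std_2000.csv", package = "ecoincidence")
  std <- readr::read_csv(path, show_col_types = FALSE)
  std$weight <- std$std_pop / sum(std$std_pop)
  std[, c("age_band", "weight")]
}

#' Directly age-standardized incidence rate
#'
#' Computes the direct age-standardized rate per 100,000:
#' `100000 * sum_a w_a * cases_a / pop_a`, with the standard-population
#' weights `w` renormalized over the age bands present in `counts`. The
#' result is therefore invariant to any uniform rescaling of the weights.
#'
#' @param counts Data frame with columns `age_band`, `cases`, `population`
#'   for one county stratum.
#' @param std Data frame with columns `age_band`, `weight`
#'   (default [us_standard_population()]).
#' @return The standardized rate per 100,000 (scalar).
#' @examples
#' counts <- tibble::tibble(
#'   age_band = c("a", "b"), cases = c(10, 30), population = c(1e5, 1e5)
#' )
#' std <- tibble::tibble(age_band = c("a", "b"), weight = c(0.5, 0.5))
#' direct_standardized_rate(counts, std) # 20
#' @export
direct_standardized_rate <- function(counts, std = us_standard_population()) {
  assert_columns(counts, c("age_band", "cases", "population"), "`counts`")
  assert_columns(std, c("age_band", "weight"), "`std`")
  extra <- setdiff(counts$age_band, std$age_band)
  if (length(extra) > 0) {
    abort(sprintf(
      "age band(s) not in the standard population: %s",
      paste(extra, collapse = ", ")
    ))
  }
  if (anyDuplicated(counts$age_band)) {
    abort("duplicate age bands in `counts`.")
  }
  bad <- counts$age_band[counts$population <= 0]
  if (length(bad) > 0) {
    abort(sprintf(
      "zero or negative population in age band(s): %s",
      paste(bad, collapse = ", ")
    ))
  }
  if (any(counts$cases < 0)) abort("negative case counts.")
  w <- std$weight[match(counts$age_band, std$age_band)]
  w <- w / sum(w)
  1e5 * sum(w * counts$cases / counts$population)
}

#' Age-standardize rates for every county stratum in a counts table
#'
#' Applies [direct_standardized_rate()] within each
#' (county, cancer, age_group, sex) group and records cumulative case
#' counts, producing the rate table the screening stage consumes.
#'
#' @param counts Data frame with columns `county`, `cancer`, `age_group`,
#'   `sex`, `age_band`, `cases`, `population`.
#' @param std Standard-population data frame (`age_band`, `weight`).
#' @return Tibble with one row per county stratum: the grouping columns,
#'   `rate` (per 100,000) and `cum_cases`.
#' @export
age_standardize <- function(counts, std = us_standard_population()) {
  assert_columns(
    counts,
    c("county", "cancer", "age_group", "sex", "age_band", "cases", "population"),
    "`counts`"
  )
  counts |>
    dplyr::group_by(.data$county, .data$cancer, .data$age_group, .data$sex) |>
    dplyr::group_modify(function(d, key) {
      tibble::tibble(
        rate = direct_standardized_rate(d, std),
        cum_cases = sum(d$cases)
      )
    }) |>
    dplyr::ungroup()
}

#' Stratum inclusion filter
#'
#' A (cancer, age_group, sex) stratum is analyzed only if the number of
#' counties reporting strictly more than `min_cases` cumulative cases
#' strictly exceeds `min_fraction` of the total county count. Both
#' inequalities are strict, reproducing the worked threshold of 38 counties
#' out of 62 at the 60% fraction.
#'
#' @param rates Rate table with columns `cancer`, `age_group`, `sex`,
#'   `county`, `cum_cases` (e.g. from [age_standardize()]).
#' @param n_counties_total Total number of counties in the study region.
#' @param min_fraction Fraction of counties that must qualify (default 0.6).
#' @param min_cases Cumulative case count a county must strictly exceed
#'   (default 5).
#' @return Tibble with one row per stratum: `cancer`, `age_group`, `sex`,
#'   `n_qualifying`, `retained`; attribute `min_required` gives the smallest
#'   qualifying-county count that passes.
#' @examples
#' inclusion_threshold(62) # 38
#' @export
inclusion_filter <- function(rates, n_counties_total,
                             min_fraction = 0.6, min_cases = 5) {
  assert_columns(
    rates, c("cancer", "age_group", "sex", "county", "cum_cases"), "`rates`"
  )
  out <- rates |>
    dplyr::group_by(.data$cancer, .data$age_group, .data$sex) |>
    dplyr::summarise(
      n_qualifying = sum(.data$cum_cases > min_cases),
      .groups = "drop"
    ) |>
    dplyr::mutate(retained = .data$n_qualifying > min_fraction * n_counties_total)
  attr(out, "min_required") <-
    inclusion_threshold(n_counties_total, min_fraction)
  out
}

#' Smallest qualifying-county count that passes the inclusion filter
#'
#' The smallest integer strictly greater than `min_fraction * n_total`.
#'
#' @param n_total Total number of counties.
#' @param min_fraction Required fraction (default 0.6).
#' @return Integer threshold.
#' @export
inclusion_threshold <- function(n_total, min_fraction = 0.6) {
  as.integer(floor(min_fraction * n_total + 1e-9) + 1L)
}

#' Percent difference between two rates
#'
#' `100 * (rate_a - rate_ref) / rate_ref`, e.g. a state rate relative to the
#' national rate.
#'
#' @param rate_a Rate to compare.
#' @param rate_ref Positive reference rate.
#' @return Percent difference.
#' @export
percent_difference <- function(rate_a, rate_ref) {
  if (any(rate_ref <= 0)) abort("`rate_ref` must be > 0.")
  100 * (rate_a - rate_ref) / rate_ref
}
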