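# Stage 1 of the association analysis: z-scoring, per-factor bivariable and
# covariate-adjusted linear models, and the p < 0.1 pooling rule.

#' Z-score columns of a data frame
#'
#' Scales each selected column to mean 0 and standard deviation 1 (sample
#' SD, n-1 denominator), so regression coefficients on the scaled data are
#' standardized coefficients comparable across variables. The centers and
#' scales used are recorded in the `standardization` attribute.
#'
#' @param data A data frame.
#' @param cols Character vector of columns to scale; default: all numeric
#'   columns.
#' @return `data` with the selected columns scaled; attribute
#'   `standardization` is a tibble of (variable, center, scale).
#' @examples
#' standardize_columns(tibble::tibble(x = c(1, 2, 3)))$x # -1 0 1
#' @export
standardize_columns <- function(data, cols = NULL) {
  cols <- cols %||% names(data)[purrr::map_lgl(data, is.numeric)]
  assert_columns(data, cols)
  params <- purrr::map_dfr(cols, function(v) {
    x <- data[[v]]
    s <- sd(x, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      abort(sprintf("column `%s` is constant and cannot be standardized.", v))
    }
    tibble::tibble(variable = v, center = mean(x, na.rm = TRUE), scale = s)
  })
  out <- data
  for (i in seq_len(nrow(params))) {
    v <- params$variable[i]
    out[[v]] <- (data[[v]] - params$center[i]) / params$scale[i]
  }
  attr(out, "standardization") <- params
  out
}

# One-row broom-style summary of one coefficient of an lm fit.
coef_row <- function(fit, term, conf_level = 0.95) {
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm)) {
    abort(sprintf("term `%s` dropped from the fit (rank deficiency).", term))
  }
  est <- sm[term, "Estimate"]
  se <- sm[term, "Std. Error"]
  df <- fit$df.residual
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  p <- sm[term, "Pr(>|t|)"]
  # orthogonal-by-construction fixtures: a zero slope with exact zero
  # t-statistic has p = 1
  if (is.nan(p)) p <- degenerate_p(est)
  tibble::tibble(
    term = term, estimate = est, conf.low = est - tcrit * se,
    conf.high = est + tcrit * se, p.value = p,
    n = length(fit$residuals)
  )
}

#' Bivariable linear association
#'
#' OLS of the outcome on a single exposure with intercept. On z-scored data
#' the slope equals the sample Pearson correlation.
#'
#' @param data Data frame of complete standardized observations.
#' @param outcome,x Column names of outcome and exposure.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `term`, `estimate`, `conf.low`, `conf.high`,
#'   `p.value`, `n`.
#' @export
fit_bivariable <- function(data, outcome, x, conf_level = 0.95) {
  assert_columns(data, c(outcome, x))
  d <- data[complete.cases(data[, c(outcome, x)]), c(outcome, x)]
  if (nrow(d) < 3) abort("need at least 3 complete observations.")
  dd <- stats::setNames(d, c(".y", ".x"))
  fit <- lm(.y ~ .x, data = dd)
  coef_row(fit, ".x", conf_level) |>
    dplyr::mutate(term = x)
}

#' Covariate-adjusted linear association
#'
#' OLS of the outcome on one exposure plus a set of adjustment covariates;
#' reports the exposure's partial coefficient. With an empty adjustment set
#' this reduces exactly to [fit_bivariable()].
#'
#' @inheritParams fit_bivariable
#' @param adjust Character vector of adjustment covariate names (may be
#'   empty); must not contain `x`.
#' @return One-row tibble as in [fit_bivariable()].
#' @export
fit_adjusted <- function(data, outcome, x, adjust = character(),
                         conf_level = 0.95) {
  if (x %in% adjust) {
    abort(sprintf("exposure `%s` also appears in the adjustment set.", x))
  }
  if (length(adjust) == 0) return(fit_bivariable(data, outcome, x, conf_level))
  vars <- c(outcome, x, adjust)
  assert_columns(data, vars)
  d <- data[complete.cases(data[, vars]), vars]
  if (nrow(d) < length(vars) + 1) abort("too few complete observations.")
  safe <- c(".y", ".x", sprintf(".a%d", seq_along(adjust)))
  dd <- stats::setNames(d, safe)
  fit <- lm(.y ~ ., data = dd)
  if (fit$rank < length(vars)) {
    dropped <- safe[-1][is.na(coef(fit)[-1])]
    orig <- c(x, adjust)[match(dropped, safe[-1])]
    abort(sprintf(
      "rank-deficient design; collinear column(s): %s",
      paste(orig, collapse = ", ")
    ))
  }
  coef_row(fit, ".x", conf_level) |>
    dplyr::mutate(term = x)
}

#' Race-collinearity exception for the adjustment set
#'
#' The percent-white covariate is dropped from a factor's adjustment set
#' when it is highly correlated with that factor (|Pearson r| strictly
#' greater than `threshold`), since including both would make the adjusted
#' model unstable.
#'
#' @param data Data frame containing both columns.
#' @param x Exposure column name.
#' @param race Race covariate column name.
#' @param adjust Adjustment set the race variable belongs to.
#' @param threshold Correlation threshold (default 0.6, strict `>`).
#' @return List with `adjust` (possibly without `race`), `dropped`
#'   (logical) and `r` (the correlation).
#' @export
race_collinearity_rule <- function(data, x, race, adjust, threshold = 0.6) {
  assert_columns(data, c(x, race))
  r <- cor(data[[x]], data[[race]], use = "pairwise.complete.obs")
  dropped <- !is.na(r) && abs(r) > threshold && race %in% adjust
  list(
    adjust = if (dropped) setdiff(adjust, race) else adjust,
    dropped = dropped, r = r
  )
}

#' Screen individual risk factors
#'
#' Stage 1 of the two-stage association analysis. For each exposure, two
#' linear models are fitted on z-scored data: a bivariable model of the
#' outcome on the exposure alone, and a model adjusted for the race &
#' socio-economic covariates (with the race covariate dropped for factors
#' highly correlated with it; see [race_collinearity_rule()]). A factor is
#' pooled for the multivariable stage when either model gives a two-sided
#' p-value below `p_threshold`. Per-factor complete cases are used
#' (listwise deletion); factors whose fits fail are logged and excluded,
#' not fatal.
#'
#' @param data Data frame of standardized county observations.
#' @param outcome Outcome column name.
#' @param exposures Character vector of candidate exposure columns.
#' @param adjust Adjustment covariate names (default empty).
#' @param race_var Name of the race covariate within `adjust`
#'   (`NULL` = no race exception).
#' @param p_threshold Pooling threshold on the smaller of the two p-values
#'   (default 0.1; 0.2 / 0.3 for sensitivity analyses).
#' @param race_r_threshold Correlation threshold for the race exception
#'   (default 0.6).
#' @return Tibble with one row per screened factor: `variable`,
#'   `est_unadj`, `p_unadj`, `est_adj`, `p_adj`, `race_dropped`, `pooled`,
#'   `n_unadj`, `n_adj`. Attributes: `pooled` (character vector of pooled
#'   variables) and `log` (per-factor error messages, if any).
#' @export
screen <- function(data, outcome, exposures, adjust = character(),
                   race_var = NULL, p_threshold = 0.1,
                   race_r_threshold = 0.6) {
  assert_columns(data, c(outcome, intersect(adjust, names(data))))
  log <- character()
  rows <- purrr::map(exposures, function(v) {
    tryCatch(
      {
        rule <- if (!is.null(race_var) && race_var %in% adjust) {
          race_collinearity_rule(data, v, race_var, adjust, race_r_threshold)
        } else {
          list(adjust = adjust, dropped = FALSE, r = NA_real_)
        }
        unadj <- fit_bivariable(data, outcome, v)
        adj <- fit_adjusted(data, outcome, v, rule$adjust)
        tibble::tibble(
          variable = v,
          est_unadj = unadj$estimate, p_unadj = unadj$p.value,
          est_adj = adj$estimate, p_adj = adj$p.value,
          race_dropped = rule$dropped,
          pooled = min(unadj$p.value, adj$p.value) < p_threshold,
          n_unadj = unadj$n, n_adj = adj$n
        )
      },
      error = function(e) {
        log[[length(log) + 1]] <<- sprintf("%s: %s", v, conditionMessage(e))
        NULL
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "pooled") <- if (nrow(out)) out$variable[out$pooled] else character()
  attr(out, "log") <- log
  out
}

#' Plot screening results
#'
#' Unadjusted and adjusted standardized estimates per factor, with pooled
#' factors highlighted.
#'
#' @param records Screening tibble from [screen()].
#' @return A ggplot object.
#' @export
plot_screening <- function(records) {
  d <- records |>
    tidyr::pivot_longer(
      c("est_unadj", "est_adj"),
      names_to = "model", values_to = "estimate"
    ) |>
    dplyr::mutate(model = dplyr::recode(.data$model,
      est_unadj = "bivariable", est_adj = "adjusted"
    ))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$estimate, y = stats::reorder(.data$variable, .data$estimate),
    colour = .data$model, shape = .data$pooled
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "Standardized estimate", y = NULL,
      colour = "Model", shape = "Pooled"
    )
}
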