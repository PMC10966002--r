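# Segmented log-linear trend analysis: continuous piecewise-linear fits of
# log rate on calendar year (hinge basis), APC per segment, AAPC overall.

validate_series <- function(data, year = "year", rate = "rate") {
  assert_columns(data, c(year, rate), "series")
  yrs <- data[[year]]
  rts <- data[[rate]]
  if (is.unsorted(yrs, strictly = TRUE)) {
    abort("years must be strictly increasing.")
  }
  if (any(rts <= 0)) {
    abort(sprintf(
      "nonpositive rate(s) at year(s): %s (log-linear model requires rates > 0)",
      paste(yrs[rts <= 0], collapse = ", ")
    ))
  }
  list(year = as.numeric(yrs), log_rate = log(rts))
}

# zero-residual fits get the documented degenerate p: 0 for a nonzero
# slope, 1 for a zero slope; CIs collapse to the point estimate.
degenerate_p <- function(slope, tol = 1e-10) {
  ifelse(abs(slope) > tol, 0, 1)
}

#' Fit a segmented log-linear trend with fixed joinpoints
#'
#' Least-squares fit of `log(rate)` on year as a continuous piecewise-linear
#' function with hinge terms at the supplied break years. Each segment's
#' slope `b` yields an annual percent change `APC = 100 * (exp(b) - 1)` with
#' a t-based 95% confidence interval and two-sided p-value from the fit's
#' covariance.
#'
#' @param data Data frame with year and rate columns.
#' @param breaks Numeric vector of 0 or more interior break years.
#' @param year,rate Column names (defaults `"year"`, `"rate"`).
#' @param min_seg_obs Minimum observations per segment, endpoints included
#'   (default 3).
#' @param conf_level Confidence level for APC intervals (default 0.95).
#' @return An object of class `joinpoint_fit`; see [tidy.joinpoint_fit()]
#'   and [glance.joinpoint_fit()].
#' @examples
#' series <- generate_trend_series(trend_spec(segment_apcs = 5))
#' fit <- fit_joinpoint(series)
#' tidy(fit)
#' @export
fit_joinpoint <- function(data, breaks = numeric(), year = "year",
                          rate = "rate", min_seg_obs = 3,
                          conf_level = 0.95) {
  s <- validate_series(data, year, rate)
  x <- s$year
  y <- s$log_rate
  n <- length(x)
  breaks <- sort(as.numeric(breaks))
  if (length(breaks) > 0 &&
    (min(breaks) <= min(x) || max(breaks) >= max(x))) {
    abort("break years must lie strictly inside the observed year range.")
  }
  bounds <- c(min(x), breaks, max(x))
  n_seg <- length(breaks) + 1
  for (i in seq_len(n_seg)) {
    n_obs <- sum(x >= bounds[i] & x <= bounds[i + 1])
    if (n_obs < min_seg_obs) {
      abort(sprintf(
        "segment %d (%s-%s) has %d observation(s); at least %d required",
        i, format(bounds[i]), format(bounds[i + 1]), n_obs, min_seg_obs
      ))
    }
  }
  X <- cbind(1, x - min(x))
  for (tau in breaks) X <- cbind(X, pmax(x - tau, 0))
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  rss <- sum(fit$residuals^2)
  p_par <- ncol(X)
  df_resid <- n - p_par
  scale_tol <- 1e-10 * max(1, sum(y^2))
  degenerate <- rss < scale_tol

  # slope of segment i = coef2 + sum of hinge coefficients up to i
  L <- matrix(0, n_seg, p_par)
  for (i in seq_len(n_seg)) L[i, 2:(1 + i)] <- 1
  slopes <- drop(L %*% coefs)

  if (degenerate || df_resid <= 0) {
    slope_cov <- matrix(0, n_seg, n_seg)
    se <- rep(0, n_seg)
    pvals <- degenerate_p(slopes)
    tcrit <- 0
  } else {
    sigma2 <- rss / df_resid
    XtX_inv <- chol2inv(chol(crossprod(X)))
    slope_cov <- sigma2 * (L %*% XtX_inv %*% t(L))
    se <- sqrt(pmax(diag(slope_cov), 0))
    pvals <- 2 * pt(-abs(slopes / se), df_resid)
    tcrit <- qt(1 - (1 - conf_level) / 2, df_resid)
  }

  segments <- tibble::tibble(
    segment = seq_len(n_seg),
    start = bounds[-length(bounds)],
    end = bounds[-1],
    slope = slopes,
    se = se,
    apc = 100 * (exp(slopes) - 1),
    conf.low = 100 * (exp(slopes - tcrit * se) - 1),
    conf.high = 100 * (exp(slopes + tcrit * se) - 1),
    p.value = pvals
  )

  structure(
    list(
      year = x, log_rate = y, breaks = breaks, coefficients = coefs,
      segments = segments, slope_cov = slope_cov, n = n, rss = rss,
      df_resid = df_resid, degenerate = degenerate,
      conf_level = conf_level,
      bic = joinpoint_bic(rss, n, length(breaks)),
      fitted_log = drop(X %*% coefs), trace = NULL
    ),
    class = "joinpoint_fit"
  )
}

# BIC for a segmented fit with k joinpoints: 2(k+1) parameters (each
# joinpoint contributes a location and a slope change). RSS floored so a
# perfect fit yields a finite value.
joinpoint_bic <- function(rss, n, k) {
  n * log(max(rss, 1e-12) / n) + 2 * (k + 1) * log(n)
}

#' @export
print.joinpoint_fit <- function(x, ...) {
  cat(sprintf(
    "<joinpoint_fit> %d years, %d joinpoint(s)%s, RSS = %.4g, BIC = %.2f\n",
    x$n, length(x$breaks),
    if (length(x$breaks)) paste0(" at ", paste(x$breaks, collapse = ", ")) else "",
    x$rss, x$bic
  ))
  print(x$segments)
  invisible(x)
}

#' @describeIn fit_joinpoint Per-segment APC estimates as a tibble.
#' @param x A `joinpoint_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.joinpoint_fit <- function(x, ...) x$segments

#' @describeIn fit_joinpoint One-row fit summary (n, joinpoints, RSS, BIC,
#'   AAPC over the full span).
#' @exportS3Method generics::glance
glance.joinpoint_fit <- function(x, ...) {
  a <- aapc(x)
  tibble::tibble(
    n = x$n, n_joinpoints = length(x$breaks), rss = x$rss, bic = x$bic,
    aapc = a$aapc, aapc.conf.low = a$conf.low, aapc.conf.high = a$conf.high,
    aapc.p.value = a$p.value
  )
}

# All admissible placements of k interior breaks at observed years.
admissible_placements <- function(x, k, min_seg_obs) {
  n <- length(x)
  if (k == 0) {
    return(if (n >= min_seg_obs) list(numeric()) else list())
  }
  interior <- x[-c(1, n)]
  if (length(interior) < k) return(list())
  cand <- combn(interior, k, simplify = FALSE)
  keep <- purrr::map_lgl(cand, function(br) {
    bounds <- c(x[1], br, x[n])
    all(purrr::map_int(
      seq_len(k + 1),
      function(i) sum(x >= bounds[i] & x <= bounds[i + 1])
    ) >= min_seg_obs)
  })
  cand[keep]
}

# Lean inner path for the grid/permutation search: hinge-basis RSS via
# lm.fit only, no fit objects.
hinge_design <- function(x, breaks) {
  X <- cbind(1, x - min(x))
  for (tau in breaks) X <- cbind(X, pmax(x - tau, 0))
  X
}

best_placement <- function(x, yl, k, min_seg_obs,
                           placements = admissible_placements(x, k, min_seg_obs)) {
  if (length(placements) == 0) return(NULL)
  rsss <- vapply(placements, function(br) {
    sum(stats::lm.fit(hinge_design(x, br), yl)$residuals^2)
  }, numeric(1))
  i <- which.min(rsss)
  list(breaks = placements[[i]], rss = rsss[i])
}

#' Search for the number and placement of joinpoints
#'
#' Grid search over all admissible break placements at observed years for
#' each candidate number of joinpoints; within each size the placement with
#' the smallest residual sum of squares wins. Across sizes, either a
#' sequential permutation test (the convention of the NCI joinpoint tool;
#' default) or BIC picks the final model.
#'
#' The permutation test compares k against k+1 joinpoints: residuals of the
#' best k-joinpoint fit are permuted and added back to its fitted values,
#' both model sizes are refit on each permuted series, and the observed RSS
#' ratio is ranked among the permuted ones. The search advances while the
#' permutation p-value is below `alpha`.
#'
#' @inheritParams fit_joinpoint
#' @param max_joinpoints Maximum joinpoints considered (default 2).
#' @param selection `"permutation"` (default) or `"bic"`.
#' @param n_perm Number of permutations per sequential test (default 499).
#' @param seed Seed for the permutation draws (`NULL` = current RNG state).
#' @param alpha Level of each sequential permutation test (default 0.05).
#' @return The selected `joinpoint_fit`, with a `trace` tibble recording
#'   the per-size best RSS and the selection path.
#' @export
search_joinpoints <- function(data, max_joinpoints = 2, min_seg_obs = 3,
                              selection = c("permutation", "bic"),
                              n_perm = 499, seed = NULL, alpha = 0.05,
                              year = "year", rate = "rate") {
  selection <- match.arg(selection)
  s <- validate_series(data, year, rate)
  n <- length(s$year)
  if (n < 2) abort("series too short: at least 2 years required.")

  if (n < min_seg_obs) {
    fit <- fit_joinpoint(data, numeric(), year, rate, min_seg_obs = 2)
    fit$trace <- tibble::tibble(
      k = 0L, rss = fit$rss, bic = fit$bic, note = "series shorter than min_seg_obs; fell back to 0 joinpoints"
    )
    warn("series shorter than `min_seg_obs`; returning the 0-joinpoint fit.")
    return(fit)
  }

  x <- s$year
  yl <- s$log_rate
  placements_by_k <- purrr::map(
    0:max_joinpoints,
    function(k) admissible_placements(x, k, min_seg_obs)
  )
  best <- purrr::map(0:max_joinpoints, function(k) {
    best_placement(x, yl, k, min_seg_obs, placements_by_k[[k + 1]])
  })
  avail <- !purrr::map_lgl(best, is.null)
  trace <- tibble::tibble(
    k = 0:max_joinpoints,
    available = avail,
    rss = purrr::map_dbl(best, function(f) if (is.null(f)) NA_real_ else f$rss),
    breaks = purrr::map_chr(best, function(f) {
      if (is.null(f)) NA_character_ else paste(f$breaks, collapse = ",")
    }),
    p_perm = NA_real_,
    note = NA_character_
  )
  trace$bic <- purrr::map2_dbl(trace$rss, trace$k, function(r, k) {
    if (is.na(r)) NA_real_ else joinpoint_bic(r, n, k)
  })

  if (selection == "bic") {
    chosen <- which.min(trace$bic)
  } else {
    scale_tol <- 1e-10 * max(1, sum(yl^2))
    chosen <- 1L
    for (k in seq_len(max_joinpoints)) {
      if (!avail[k + 1]) break
      f0 <- best[[chosen]]
      if (f0$rss < scale_tol) {
        trace$note[k + 1] <- "null fit already exact; stopped"
        break
      }
      f1 <- best[[k + 1]]
      stat_obs <- f0$rss / max(f1$rss, 1e-300)
      fitted0 <- stats::lm.fit(hinge_design(x, f0$breaks), yl)$fitted.values
      resid0 <- yl - fitted0
      stat_perm <- with_substream(seed, paste0("joinpoint_perm_", k), {
        purrr::map_dbl(seq_len(n_perm), function(b) {
          y_star <- fitted0 + sample(resid0)
          r0 <- best_placement(
            x, y_star, chosen - 1L, min_seg_obs, placements_by_k[[chosen]]
          )$rss
          r1 <- best_placement(
            x, y_star, k, min_seg_obs, placements_by_k[[k + 1]]
          )$rss
          r0 / max(r1, 1e-300)
        })
      })
      p_perm <- (1 + sum(stat_perm >= stat_obs)) / (n_perm + 1)
      trace$p_perm[k + 1] <- p_perm
      if (p_perm < alpha) chosen <- k + 1L else break
    }
  }

  fit <- fit_joinpoint(data, best[[chosen]]$breaks, year, rate, min_seg_obs)
  fit$trace <- trace[, c(
    "k", "available", "rss", "bic", "breaks", "p_perm", "note"
  )]
  fit
}

#' Average annual percent change over a year range
#'
#' The AAPC is the segment-length-weighted geometric average of the APCs:
#' `100 * (exp(sum(w_i * b_i) / sum(w_i)) - 1)` with `w_i` the number of
#' years of segment `i` inside `range`. Its confidence interval comes from
#' the delta method on the weighted slope, using the fit covariance; with
#' zero joinpoints the AAPC equals the single APC with an identical
#' interval.
#'
#' @param fit A `joinpoint_fit`.
#' @param range Length-2 numeric year interval (default: full fitted span).
#' @return One-row tibble: `aapc`, `conf.low`, `conf.high`, `p.value`.
#' @export
aapc <- function(fit, range = NULL) {
  stopifnot(inherits(fit, "joinpoint_fit"))
  span <- c(min(fit$year), max(fit$year))
  range <- range %||% span
  if (length(range) != 2 || range[1] >= range[2]) {
    abort("`range` must be an increasing year interval of length 2.")
  }
  lo <- pmax(fit$segments$start, range[1])
  hi <- pmin(fit$segments$end, range[2])
  w <- pmax(hi - lo, 0)
  if (sum(w) <= 0) abort("`range` does not overlap the fitted span.")
  a <- w / sum(w)
  wb <- sum(a * fit$segments$slope)
  v <- drop(t(a) %*% fit$slope_cov %*% a)
  se <- sqrt(max(v, 0))
  if (fit$degenerate || se == 0) {
    p <- degenerate_p(wb)
    lo_b <- hi_b <- wb
  } else {
    tcrit <- qt(1 - (1 - fit$conf_level) / 2, fit$df_resid)
    p <- 2 * pt(-abs(wb / se), fit$df_resid)
    lo_b <- wb - tcrit * se
    hi_b <- wb + tcrit * se
  }
  tibble::tibble(
    aapc = 100 * (exp(wb) - 1),
    conf.low = 100 * (exp(lo_b) - 1),
    conf.high = 100 * (exp(hi_b) - 1),
    p.value = p
  )
}

#' Classify a fitted trend as increasing, decreasing or stable
#'
#' Increasing if the AAPC is positive with p < `alpha`, decreasing if
#' negative with p < `alpha`, otherwise stable.
#'
#' @param fit A `joinpoint_fit`.
#' @param alpha Significance level (default 0.05).
#' @return One of `"increasing"`, `"decreasing"`, `"stable"`.
#' @export
classify_trend <- function(fit, alpha = 0.05) {
  a <- aapc(fit)
  if (a$p.value < alpha && a$aapc > 0) "increasing"
  else if (a$p.value < alpha && a$aapc < 0) "decreasing"
  else "stable"
}

#' Plot a segmented trend fit
#'
#' Observed annual rates (points, log-scaled axis) with the fitted
#' piecewise log-linear trend and joinpoints marked.
#'
#' @param object A `joinpoint_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.joinpoint_fit <- function(object, ...) {
  d <- tibble::tibble(
    year = object$year,
    rate = exp(object$log_rate),
    fitted = exp(object$fitted_log)
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$rate)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "Year", y = "Age-standardized rate per 100,000 (log scale)",
      title = sprintf("%d joinpoint(s)", length(object$breaks))
    )
  if (length(object$breaks) > 0) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$breaks, linetype = "dashed", colour = "grey50"
    )
  }
  p
}
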