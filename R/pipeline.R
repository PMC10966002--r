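# End-to-end orchestration: fixtures -> rates -> inclusion -> screening ->
# selection (+ trends), with validation, a sensitivity sweep and a
# reproducible run manifest.

#' Assemble and validate a pipeline configuration
#'
#' @param exposures Path to the exposures CSV (`county` + one column per
#'   variable; may contain a precomputed outcome column).
#' @param counts Path to the stratum counts CSV (`county`, `cancer`,
#'   `age_group`, `sex`, `age_band`, `cases`, `population`); optional when
#'   `rates` is given.
#' @param rates Path to a precomputed rate table CSV (`county`, `cancer`,
#'   `age_group`, `sex`, `rate`, `cum_cases`); optional when `counts` is
#'   given.
#' @param std_population Path to a standard-population CSV (`age_band`,
#'   `weight` or `std_pop`); `NULL` uses [us_standard_population()].
#' @param trend Optional path to an annual series CSV (`year`, `rate`,
#'   `cancer`, `sex`).
#' @param out_dir Output directory for report files.
#' @param outcome Outcome column in the exposures table (used when
#'   present; otherwise the standardized rate of each stratum is the
#'   outcome).
#' @param adjust Forced adjustment covariate names.
#' @param race_var Race covariate name within `adjust`.
#' @param spatial Spatial candidate columns appended to every pooled set
#'   (default `c("LAT", "LAT2")`, used when present).
#' @param screen_p Screening p-value threshold (0.1 main; 0.2/0.3
#'   sensitivity).
#' @param conflict_r Conflict-graph threshold (0.6 main; 0.5 sensitivity).
#' @param adj_r2_min Adjusted R-squared floor (default 0.3).
#' @param delta_bic BIC comparability window (default 2).
#' @param min_cases,min_fraction Inclusion-filter parameters (defaults 5
#'   and 0.6).
#' @param max_joinpoints Maximum joinpoints for trend analysis (default 2).
#' @param joinpoint_selection `"permutation"` or `"bic"`.
#' @param race_as_candidate Sensitivity flag: select the race covariate by
#'   BIC instead of forcing it.
#' @param seed Master seed for every random sub-stream.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(exposures, counts = NULL, rates = NULL,
                            std_population = NULL, trend = NULL,
                            out_dir = "ecoincidence_out", outcome = "y",
                            adjust = c("POV", "INS", "RACE"),
                            race_var = "RACE", spatial = c("LAT", "LAT2"),
                            screen_p = 0.1, conflict_r = 0.6,
                            adj_r2_min = 0.3, delta_bic = 2.0,
                            min_cases = 5, min_fraction = 0.6,
                            max_joinpoints = 2,
                            joinpoint_selection = c("permutation", "bic"),
                            race_as_candidate = FALSE, seed = 1) {
  if (!screen_p %in% c(0.1, 0.2, 0.3)) {
    abort("`screen_p` must be one of 0.1, 0.2, 0.3.")
  }
  if (!conflict_r %in% c(0.5, 0.6)) {
    abort("`conflict_r` must be 0.5 or 0.6.")
  }
  if (is.null(counts) && is.null(rates)) {
    abort("one of `counts` or `rates` must be supplied.")
  }
  structure(
    list(
      exposures = exposures, counts = counts, rates = rates,
      std_population = std_population, trend = trend, out_dir = out_dir,
      outcome = outcome, adjust = adjust, race_var = race_var,
      spatial = spatial, screen_p = screen_p, conflict_r = conflict_r,
      adj_r2_min = adj_r2_min, delta_bic = delta_bic,
      min_cases = min_cases, min_fraction = min_fraction,
      max_joinpoints = max_joinpoints,
      joinpoint_selection = match.arg(joinpoint_selection),
      race_as_candidate = isTRUE(race_as_candidate),
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

read_std <- function(path) {
  if (is.null(path)) return(us_standard_population())
  std <- readr::read_csv(path, show_col_types = FALSE)
  if (!"weight" %in% names(std) && "std_pop" %in% names(std)) {
    std$weight <- std$std_pop / sum(std$std_pop)
  }
  assert_columns(std, c("age_band", "weight"), basename(path))
  std
}

#' Validate pipeline input files
#'
#' Checks file readability, required columns, county-key consistency
#' across files, duplicate rows and value ranges. Never mutates inputs.
#'
#' @param config A [pipeline_config()].
#' @return Tibble of findings: `level` (`"error"`/`"warning"`), `file`,
#'   `message`. Zero rows means a clean bundle.
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  findings <- list()
  note <- function(level, file, message) {
    findings[[length(findings) + 1]] <<-
      tibble::tibble(level = level, file = file, message = message)
  }
  read_or_note <- function(path, label) {
    if (is.null(path)) return(NULL)
    if (!file.exists(path)) {
      note("error", label, "file does not exist")
      return(NULL)
    }
    tryCatch(
      readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
      error = function(e) {
        note("error", label, paste("unreadable:", conditionMessage(e)))
        NULL
      }
    )
  }

  exp_df <- read_or_note(config$exposures, "exposures")
  if (!is.null(exp_df)) {
    if (nrow(exp_df) == 0) note("error", "exposures", "file has no rows")
    if (!"county" %in% names(exp_df)) {
      note("error", "exposures", "missing column: county")
    } else if (anyDuplicated(exp_df$county)) {
      note("error", "exposures", "duplicate county ids")
    }
  }

  counts_df <- read_or_note(config$counts, "counts")
  if (!is.null(counts_df)) {
    needed <- c("county", "cancer", "age_group", "sex", "age_band", "cases", "population")
    miss <- setdiff(needed, names(counts_df))
    if (length(miss) > 0) {
      note("error", "counts", paste("missing column(s):", paste(miss, collapse = ", ")))
    } else {
      if (any(counts_df$population < 0)) {
        note("error", "counts", "negative population value(s)")
      }
      if (any(counts_df$cases < 0)) {
        note("error", "counts", "negative case count(s)")
      }
      if (!is.null(exp_df) && "county" %in% names(exp_df)) {
        only_exp <- setdiff(exp_df$county, counts_df$county)
        if (length(only_exp) > 0) {
          note("warning", "counts", sprintf(
            "county id(s) in exposures but not in counts: %s",
            paste(utils::head(only_exp, 5), collapse = ", ")
          ))
        }
      }
    }
  }

  trend_df <- read_or_note(config$trend, "trend")
  if (!is.null(trend_df)) {
    miss <- setdiff(c("year", "rate"), names(trend_df))
    if (length(miss) > 0) {
      note("error", "trend", paste("missing column(s):", paste(miss, collapse = ", ")))
    } else if (any(trend_df$rate <= 0)) {
      note("error", "trend", "nonpositive rate value(s)")
    }
  }

  if (length(findings) == 0) {
    tibble::tibble(level = character(), file = character(), message = character())
  } else {
    dplyr::bind_rows(findings)
  }
}

# screening + selection for one outcome vector on one exposure frame
analyze_stratum <- function(frame, outcome, config) {
  exposure_vars <- setdiff(
    names(frame)[purrr::map_lgl(frame, is.numeric)],
    c(outcome, config$adjust, config$spatial)
  )
  frame_std <- standardize_columns(frame)
  records <- screen(
    frame_std, outcome, exposure_vars,
    adjust = intersect(config$adjust, names(frame_std)),
    race_var = config$race_var, p_threshold = config$screen_p
  )
  pooled <- attr(records, "pooled")
  candidates <- c(pooled, intersect(config$spatial, names(frame_std)))
  roles <- race_candidate_mode(
    candidates, intersect(config$adjust, names(frame_std)),
    race_var = config$race_var, as_candidate = config$race_as_candidate
  )
  selection <- if (length(roles$candidates) > 0) {
    select_models(
      frame_std, outcome, roles$candidates, roles$forced,
      r_threshold = config$conflict_r, adj_r2_min = config$adj_r2_min,
      delta_bic = config$delta_bic
    )
  } else {
    NULL
  }
  list(screening = records, selection = selection)
}

#' Run the full study pipeline
#'
#' Reads the configured input files, age-standardizes rates (when counts
#' are supplied), applies the stratum inclusion filter, and for every
#' retained stratum runs screening and multivariable selection; an annual
#' series, if supplied, gets the joinpoint trend analysis. Writes TSV/CSV
#' reports and a JSON run manifest to `config$out_dir`. A rerun with the
#' same inputs and seed is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  diags <- validate_inputs(config)
  if (any(diags$level == "error")) {
    abort(paste(
      "input validation failed:",
      paste(sprintf("[%s] %s", diags$file[diags$level == "error"],
        diags$message[diags$level == "error"]
      ), collapse = "; ")
    ))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ecoincidence")),
    seed = config$seed,
    config = config[c(
      "screen_p", "conflict_r", "adj_r2_min", "delta_bic", "min_cases",
      "min_fraction", "max_joinpoints", "joinpoint_selection",
      "race_as_candidate", "outcome"
    )],
    stages = list()
  )

  exposures <- readr::read_csv(config$exposures, show_col_types = FALSE)

  if (!is.null(config$counts)) {
    counts <- readr::read_csv(config$counts, show_col_types = FALSE)
    std <- read_std(config$std_population)
    rates <- age_standardize(counts, std)
    readr::write_csv(rates, out("rates.csv"))
  } else {
    rates <- readr::read_csv(config$rates, show_col_types = FALSE)
  }
  n_total <- dplyr::n_distinct(rates$county)
  incl <- inclusion_filter(rates, n_total,
    min_fraction = config$min_fraction, min_cases = config$min_cases
  )
  readr::write_tsv(incl, out("inclusion.tsv"))
  manifest$stages$rates <- list(
    n_counties = n_total, n_strata = nrow(incl),
    n_retained = sum(incl$retained),
    min_required_counties = attr(incl, "min_required")
  )

  retained <- incl[incl$retained, ]
  stratum_results <- list()
  for (i in seq_len(nrow(retained))) {
    key <- retained[i, ]
    tag <- sprintf("%s_%s_%s", key$cancer, key$age_group, key$sex)
    tag <- gsub("[^A-Za-z0-9_.-]", "_", tag)
    sub_rates <- dplyr::semi_join(
      rates, key[, c("cancer", "age_group", "sex")],
      by = c("cancer", "age_group", "sex")
    )
    if (config$outcome %in% names(exposures)) {
      frame <- exposures
      outcome_col <- config$outcome
    } else {
      frame <- dplyr::inner_join(
        exposures, sub_rates[, c("county", "rate")],
        by = "county"
      )
      outcome_col <- "rate"
    }
    res <- analyze_stratum(frame, outcome_col, config)
    readr::write_tsv(res$screening, out(sprintf("screening_%s.tsv", tag)))
    if (!is.null(res$selection)) {
      combos <- res$selection$combinations |>
        dplyr::mutate(members = purrr::map_chr(.data$members, subset_id))
      readr::write_tsv(combos, out(sprintf("combinations_%s.tsv", tag)))
      readr::write_tsv(
        res$selection$models, out(sprintf("models_%s.tsv", tag))
      )
      readr::write_tsv(
        tidy(res$selection), out(sprintf("ranking_%s.tsv", tag))
      )
      if (!res$selection$empty) {
        readr::write_tsv(
          tidy(res$selection$best), out(sprintf("coefficients_%s.tsv", tag))
        )
      }
    }
    stratum_results[[tag]] <- list(
      n_screened = nrow(res$screening),
      n_pooled = sum(res$screening$pooled),
      empty = is.null(res$selection) || res$selection$empty,
      best_subset = if (!is.null(res$selection) && !res$selection$empty) {
        glance(res$selection)$best_subset
      } else {
        NA_character_
      }
    )
  }
  manifest$stages$strata <- stratum_results

  if (!is.null(config$trend)) {
    series <- readr::read_csv(config$trend, show_col_types = FALSE)
    fit <- search_joinpoints(series,
      max_joinpoints = config$max_joinpoints,
      selection = config$joinpoint_selection, seed = config$seed
    )
    a <- aapc(fit)
    seg <- tidy(fit)
    readr::write_tsv(seg, out("trend_segments.tsv"))
    readr::write_tsv(
      dplyr::mutate(a, classification = classify_trend(fit)),
      out("trend_aapc.tsv")
    )
    manifest$stages$trend <- list(
      n_joinpoints = length(fit$breaks), breaks = fit$breaks,
      aapc = a$aapc, classification = classify_trend(fit)
    )
  }

  jsonlite::write_json(
    manifest, out("manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}

#' Sensitivity sweep over screening and conflict thresholds
#'
#' Re-runs screening and selection for one analysis frame over the grid of
#' screening p thresholds and conflict correlation thresholds, mirroring
#' the study's sensitivity analyses, and returns a comparison table.
#'
#' @param data Analysis frame (counties by variables, outcome included).
#' @param outcome Outcome column name.
#' @param exposures Candidate exposure columns.
#' @param adjust Forced adjustment covariates.
#' @param race_var Race covariate name.
#' @param spatial Spatial candidate columns (used when present).
#' @param p_grid Screening thresholds (default `c(0.1, 0.2, 0.3)`).
#' @param r_grid Conflict thresholds (default `c(0.6, 0.5)`).
#' @param adj_r2_min,delta_bic Passed to [pool_and_prune()].
#' @return Tibble with one row per grid cell: thresholds, pooled count,
#'   whether a model cleared the floor, the best subset and its BIC and
#'   adjusted R-squared.
#' @export
run_sweep <- function(data, outcome, exposures,
                      adjust = character(), race_var = "RACE",
                      spatial = c("LAT", "LAT2"),
                      p_grid = c(0.1, 0.2, 0.3), r_grid = c(0.6, 0.5),
                      adj_r2_min = 0.3, delta_bic = 2.0) {
  frame_std <- standardize_columns(data)
  grid <- tidyr::expand_grid(screen_p = p_grid, conflict_r = r_grid)
  purrr::pmap_dfr(grid, function(screen_p, conflict_r) {
    records <- screen(frame_std, outcome, exposures,
      adjust = intersect(adjust, names(frame_std)),
      race_var = race_var, p_threshold = screen_p
    )
    pooled <- attr(records, "pooled")
    candidates <- c(pooled, intersect(spatial, names(frame_std)))
    if (length(candidates) == 0) {
      return(tibble::tibble(
        screen_p = screen_p, conflict_r = conflict_r,
        n_pooled = 0L, empty = TRUE,
        best_subset = NA_character_, best_bic = NA_real_,
        best_adj_r2 = NA_real_
      ))
    }
    sel <- select_models(frame_std, outcome, candidates,
      intersect(adjust, names(frame_std)),
      r_threshold = conflict_r, adj_r2_min = adj_r2_min,
      delta_bic = delta_bic
    )
    g <- glance(sel)
    tibble::tibble(
      screen_p = screen_p, conflict_r = conflict_r,
      n_pooled = length(pooled), empty = g$empty,
      best_subset = g$best_subset, best_bic = g$best_bic,
      best_adj_r2 = g$best_adj_r2
    )
  })
}
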