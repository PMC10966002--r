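# Stage 2: conflict-graph decorrelation, exhaustive best-subset search by
# BIC with forced adjustment covariates, pooling, adjusted-R2 filtering,
# nested-model pruning and final ranking.

#' Build the correlation conflict graph
#'
#' Nodes are the candidate variables; an edge joins every pair whose
#' pairwise-complete Pearson correlation exceeds `r_threshold` in absolute
#' value (strict `>`). Variables joined by an edge are never allowed in the
#' same model combination.
#'
#' @param data Data frame of county observations.
#' @param candidates Character vector of candidate variable names
#'   (at least 2).
#' @param r_threshold Conflict threshold (default 0.6; 0.5 for sensitivity
#'   analyses).
#' @return Object of class `conflict_graph`: list with `nodes`, `edges`
#'   (tibble `a`, `b`, `r`), `adjacency` (logical matrix) and `threshold`.
#' @export
build_conflict_graph <- function(data, candidates, r_threshold = 0.6) {
  if (length(candidates) < 2) abort("need at least 2 candidate variables.")
  assert_columns(data, candidates)
  for (v in candidates) {
    x <- data[[v]]
    if (sd(x, na.rm = TRUE) %in% c(0, NA)) {
      abort(sprintf("candidate `%s` is constant.", v))
    }
  }
  R <- cor(as.data.frame(data[, candidates]), use = "pairwise.complete.obs")
  adj <- abs(R) > r_threshold
  diag(adj) <- FALSE
  idx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  edges <- tibble::tibble(
    a = candidates[idx[, 1]], b = candidates[idx[, 2]],
    r = R[idx]
  )
  structure(
    list(
      nodes = candidates, edges = edges, adjacency = adj,
      threshold = r_threshold
    ),
    class = "conflict_graph"
  )
}

#' @export
print.conflict_graph <- function(x, ...) {
  cat(sprintf(
    "<conflict_graph> %d nodes, %d edge(s) at |r| > %g\n",
    length(x$nodes), nrow(x$edges), x$threshold
  ))
  invisible(x)
}

#' Enumerate all maximal compatible combinations
#'
#' A compatible combination is an independent set of the conflict graph: a
#' set of variables containing no conflicting pair. Only maximal
#' independent sets are returned (each exactly once, in a deterministic
#' order); this is lossless for the downstream search because every
#' independent set is a subset of some maximal one, and the best-subset
#' step already examines every subset of each combination.
#'
#' @param graph A [build_conflict_graph()] result.
#' @param max_nodes Guard on node count (default 40); beyond it the
#'   enumeration may explode and a stricter correlation threshold is
#'   advised.
#' @return Tibble with columns `id`, `members` (list column of character
#'   vectors), `size`, `maximal` (all `TRUE`).
#' @export
enumerate_combinations <- function(graph, max_nodes = 40) {
  stopifnot(inherits(graph, "conflict_graph"))
  p <- length(graph$nodes)
  if (p > max_nodes) {
    abort(sprintf(
      "%d candidate nodes exceed the enumeration ceiling (%d); consider a stricter correlation threshold.",
      p, max_nodes
    ))
  }
  g <- igraph::graph_from_adjacency_matrix(
    graph$adjacency,
    mode = "undirected"
  )
  igraph::V(g)$name <- graph$nodes
  # maximal independent sets of g = maximal cliques of the complement
  sets <- igraph::max_cliques(igraph::complementer(g))
  members <- purrr::map(sets, function(s) sort(igraph::V(g)$name[s]))
  members <- members[order(purrr::map_chr(members, subset_id))]
  tibble::tibble(
    id = seq_along(members),
    members = members,
    size = lengths(members),
    maximal = TRUE
  )
}

#' Bayesian information criterion from a Gaussian residual sum of squares
#'
#' `BIC = n * log(RSS / n) + k * log(n)`, the Gaussian profile
#' log-likelihood form with constant terms dropped (constants cancel when
#' comparing models fit to the same data). `k` counts every estimated
#' coefficient including the intercept and forced covariates. RSS is
#' floored at `1e-12` so a perfect fit yields a finite value.
#'
#' @param rss Residual sum of squares.
#' @param n Number of observations (`n > k`).
#' @param k Number of estimated coefficients.
#' @return BIC (scalar).
#' @export
bic_gaussian <- function(rss, n, k) {
  if (n <= k) abort("`n` must exceed `k`.")
  n * log(max(rss, 1e-12) / n) + k * log(n)
}

#' Adjusted R-squared from sums of squares
#'
#' `1 - (RSS / (n - k)) / (TSS / (n - 1))`.
#'
#' @inheritParams bic_gaussian
#' @param tss Total sum of squares (`> 0`).
#' @return Adjusted R-squared (scalar).
#' @export
adjusted_r2 <- function(rss, tss, n, k) {
  if (n <= k) abort("`n` must exceed `k`.")
  if (tss <= 0) abort("`tss` must be > 0.")
  1 - (rss / (n - k)) / (tss / (n - 1))
}

# Apply weak-hierarchy constraints: each name in `names(hierarchy)` may be
# selected only together with its parent hierarchy[[name]].
respects_hierarchy <- function(members, hierarchy) {
  if (length(hierarchy) == 0) return(TRUE)
  for (child in names(hierarchy)) {
    if (child %in% members && !(hierarchy[[child]] %in% members)) return(FALSE)
  }
  TRUE
}

#' Exhaustive best-subset search within one combination
#'
#' Fits every subset of the combination's variables (the empty subset
#' included) together with the forced adjustment covariates, and returns
#' the model minimizing BIC. A weak hierarchy can be imposed (by default a
#' squared-latitude term is admitted only alongside latitude). Subsets with
#' rank-deficient designs are skipped and logged.
#'
#' @param data Data frame of (standardized) county observations.
#' @param outcome Outcome column name.
#' @param combination Character vector of candidate variables (a compatible
#'   combination); at most 25 (2^p exhaustive guard).
#' @param forced Character vector of covariates included in every model
#'   (disjoint from `combination`).
#' @param max_size Optional cap on selected-subset size.
#' @param hierarchy Named character vector: each name may enter only with
#'   its value present (default `c(LAT2 = "LAT")`, applied only when those
#'   columns exist).
#' @return Object of class `fitted_model`: list with `subset`, `forced`,
#'   `coefficients` (tibble with 95% CIs and p-values), `n`, `k`, `rss`,
#'   `tss`, `bic`, `adj_r2`, `skipped` (log of skipped subsets).
#' @export
best_subset <- function(data, outcome, combination, forced = character(),
                        max_size = NULL, hierarchy = c(LAT2 = "LAT")) {
  if (length(intersect(combination, forced)) > 0) {
    abort("`combination` and `forced` must be disjoint.")
  }
  if (length(combination) > 25) {
    abort(sprintf(
      "combination of %d variables exceeds the exhaustive-search guard (25).",
      length(combination)
    ))
  }
  vars <- c(outcome, forced, combination)
  assert_columns(data, vars)
  d <- data[complete.cases(data[, vars]), vars]
  n <- nrow(d)
  hierarchy <- hierarchy[names(hierarchy) %in% combination &
    hierarchy %in% combination]

  y <- d[[outcome]]
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) abort("outcome has no variance on the complete cases.")
  Xall <- cbind(`(Intercept)` = rep(1, n), as.matrix(d[, c(forced, combination), drop = FALSE]))
  G <- crossprod(Xall)
  gy <- crossprod(Xall, y)
  yty <- sum(y^2)
  base_idx <- seq_len(1 + length(forced))
  p <- length(combination)

  subsets <- purrr::map(0:p, function(m) {
    if (!is.null(max_size) && m > max_size) return(NULL)
    if (m == 0) return(list(integer()))
    combn(seq_len(p), m, simplify = FALSE)
  })
  subsets <- purrr::flatten(purrr::compact(subsets))

  best <- NULL
  skipped <- character()
  for (s in subsets) {
    members <- combination[s]
    if (!respects_hierarchy(members, hierarchy)) next
    idx <- c(base_idx, 1 + length(forced) + s)
    k <- length(idx)
    if (n <= k) next
    Gs <- G[idx, idx, drop = FALSE]
    ok <- TRUE
    ch <- tryCatch(chol(Gs), error = function(e) {
      ok <<- FALSE
      NULL
    })
    if (!ok) {
      skipped <- c(skipped, subset_id(members))
      next
    }
    beta <- backsolve(ch, forwardsolve(t(ch), gy[idx]))
    rss <- max(yty - sum(beta * gy[idx]), 0)
    bic <- bic_gaussian(rss, n, k)
    cand <- list(members = members, idx = idx, k = k, rss = rss, bic = bic)
    if (is.null(best) || bic < best$bic - 1e-12 ||
      (abs(bic - best$bic) <= 1e-12 && better_tiebreak(members, best$members))) {
      best <- cand
    }
  }
  if (is.null(best)) abort("no estimable subset (all designs rank-deficient).")

  refit <- fit_standardized_model(d, outcome, best$members, forced)
  structure(
    list(
      subset = best$members, forced = forced,
      coefficients = refit$coefficients,
      n = n, k = best$k, rss = best$rss, tss = tss, bic = best$bic,
      adj_r2 = adjusted_r2(best$rss, tss, n, best$k),
      skipped = skipped
    ),
    class = "fitted_model"
  )
}

# BIC tie-break: fewer variables, then lexicographically smaller id.
better_tiebreak <- function(members, incumbent) {
  if (length(members) != length(incumbent)) {
    return(length(members) < length(incumbent))
  }
  subset_id(members) < subset_id(incumbent)
}

# lm refit of one selected model, for coefficient inference.
fit_standardized_model <- function(d, outcome, subset, forced,
                                   conf_level = 0.95) {
  rhs <- c(forced, subset)
  if (length(rhs) == 0) {
    dd <- stats::setNames(d[, outcome, drop = FALSE], ".y")
    fit <- lm(.y ~ 1, data = dd)
    coefs <- tibble::tibble(
      term = character(), estimate = numeric(), conf.low = numeric(),
      conf.high = numeric(), p.value = numeric()
    )
    return(list(fit = fit, coefficients = coefs))
  }
  safe <- sprintf(".v%d", seq_along(rhs))
  dd <- stats::setNames(d[, c(outcome, rhs)], c(".y", safe))
  fit <- lm(.y ~ ., data = dd)
  sm <- summary(fit)$coefficients
  df <- fit$df.residual
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  rows <- match(safe, rownames(sm))
  coefs <- tibble::tibble(
    term = rhs,
    estimate = sm[rows, "Estimate"],
    conf.low = sm[rows, "Estimate"] - tcrit * sm[rows, "Std. Error"],
    conf.high = sm[rows, "Estimate"] + tcrit * sm[rows, "Std. Error"],
    p.value = sm[rows, "Pr(>|t|)"],
    forced = rhs %in% forced
  )
  list(fit = fit, coefficients = coefs)
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf(
    "<fitted_model> subset {%s} + %d forced, n = %d, BIC = %.2f, adj R2 = %.3f\n",
    subset_id(x$subset), length(x$forced), x$n, x$bic, x$adj_r2
  ))
  invisible(x)
}

#' @describeIn best_subset Coefficients of the selected model as a tibble.
#' @param x A `fitted_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.fitted_model <- function(x, ...) x$coefficients

#' @describeIn best_subset One-row model summary.
#' @exportS3Method generics::glance
glance.fitted_model <- function(x, ...) {
  tibble::tibble(
    subset = subset_id(x$subset), n_selected = length(x$subset),
    n_forced = length(x$forced), n = x$n, k = x$k,
    rss = x$rss, bic = x$bic, adj_r2 = x$adj_r2
  )
}

#' Pool, filter, prune and rank candidate models
#'
#' Combines the per-combination best models into a final ranking:
#' (1) models with adjusted R-squared below `adj_r2_min` are dropped;
#' (2) duplicate selected subsets are collapsed; (3) nested models (one
#' selected subset a strict subset of another) are grouped by connected
#' components of the nesting relation and only the lowest-BIC member of
#' each group is retained; (4) survivors are ranked by BIC ascending (ties:
#' fewer variables, then lexicographic); (5) survivors within `delta_bic`
#' of the best are flagged comparable (strict `<`).
#'
#' @param models List of `fitted_model` objects fitted on the same outcome,
#'   sample and forced set (so BICs are comparable).
#' @param adj_r2_min Adjusted R-squared floor (default 0.3).
#' @param delta_bic Comparability window on BIC differences (default 2).
#' @return Object of class `selection_result`: list with `models` (audit
#'   tibble over the full pool), `ranking` (survivors), `best` (the winning
#'   `fitted_model`, or `NULL`), `empty` (flag: no model clears the
#'   adjusted R-squared floor), `adj_r2_min`, `delta_bic`.
#' @export
pool_and_prune <- function(models, adj_r2_min = 0.3, delta_bic = 2.0) {
  stopifnot(length(models) > 0, all(purrr::map_lgl(models, inherits, "fitted_model")))
  pool <- purrr::map_dfr(seq_along(models), function(i) {
    m <- models[[i]]
    tibble::tibble(
      model = i, subset = subset_id(m$subset),
      size = length(m$subset), bic = m$bic, adj_r2 = m$adj_r2
    )
  })
  pool$survived_filter <- pool$adj_r2 >= adj_r2_min

  kept <- pool[pool$survived_filter, ]
  if (nrow(kept) == 0) {
    return(structure(
      list(
        models = pool, ranking = kept, best = NULL, empty = TRUE,
        adj_r2_min = adj_r2_min, delta_bic = delta_bic
      ),
      class = "selection_result"
    ))
  }

  # deduplicate identical subsets (keep first; identical subsets on the
  # same data have identical BIC)
  kept <- kept[!duplicated(kept$subset), ]

  # nesting relation: A ~ B iff strict subset either way; groups are
  # connected components
  sets <- purrr::map(kept$model, function(i) models[[i]]$subset)
  m <- nrow(kept)
  nest_adj <- matrix(FALSE, m, m)
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        nested <- (all(sets[[i]] %in% sets[[j]]) ||
          all(sets[[j]] %in% sets[[i]]))
        nest_adj[i, j] <- nest_adj[j, i] <- nested
      }
    }
  }
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(nest_adj, mode = "undirected")
  )$membership
  kept$nested_group <- comp
  kept <- kept |>
    dplyr::group_by(.data$nested_group) |>
    dplyr::arrange(.data$bic, .data$size, .data$subset, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()

  kept <- kept |> dplyr::arrange(.data$bic, .data$size, .data$subset)
  kept$rank <- seq_len(nrow(kept))
  kept$comparable <- (kept$bic - kept$bic[1]) < delta_bic

  structure(
    list(
      models = pool, ranking = kept, best = models[[kept$model[1]]],
      empty = FALSE, adj_r2_min = adj_r2_min, delta_bic = delta_bic
    ),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  if (x$empty) {
    cat(sprintf(
      "<selection_result> no model reaches adjusted R2 >= %g (pool of %d)\n",
      x$adj_r2_min, nrow(x$models)
    ))
  } else {
    cat(sprintf(
      "<selection_result> %d ranked model(s), best subset {%s} (BIC %.2f, adj R2 %.3f)\n",
      nrow(x$ranking), x$ranking$subset[1], x$ranking$bic[1],
      x$ranking$adj_r2[1]
    ))
  }
  invisible(x)
}

#' @describeIn pool_and_prune Ranked surviving models as a tibble.
#' @param x A `selection_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.selection_result <- function(x, ...) x$ranking

#' @describeIn pool_and_prune One-row summary of the selection.
#' @exportS3Method generics::glance
glance.selection_result <- function(x, ...) {
  tibble::tibble(
    n_pooled = nrow(x$models),
    n_survived = sum(x$models$survived_filter),
    n_ranked = nrow(x$ranking),
    n_comparable = if (x$empty) 0L else sum(x$ranking$comparable),
    empty = x$empty,
    best_subset = if (x$empty) NA_character_ else x$ranking$subset[1],
    best_bic = if (x$empty) NA_real_ else x$ranking$bic[1],
    best_adj_r2 = if (x$empty) NA_real_ else x$ranking$adj_r2[1]
  )
}

#' Plot a selection result
#'
#' Coefficients (with 95% intervals) of the best model, selected and forced
#' covariates distinguished.
#'
#' @param object A `selection_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.selection_result <- function(object, ...) {
  if (object$empty) {
    return(
      ggplot2::ggplot() +
        ggplot2::annotate("text", x = 0, y = 0, label = "no model passes the adjusted R2 floor") +
        ggplot2::theme_void()
    )
  }
  d <- tidy(object$best)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$estimate, y = stats::reorder(.data$term, .data$estimate),
    colour = .data$forced
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "Standardized coefficient (95% CI)", y = NULL,
      colour = "Forced"
    )
}

#' Move the race covariate between forced and candidate roles
#'
#' In the main analysis the race covariate is forced into every model; in a
#' sensitivity mode it instead joins the candidate pool and is selected by
#' BIC like any other variable (entering the conflict graph, so it never
#' co-occurs with variables it conflicts with).
#'
#' @param candidates Character vector of candidate variables.
#' @param forced Character vector of forced covariates.
#' @param race_var Name of the race covariate (default `"RACE"`).
#' @param as_candidate If `TRUE`, move `race_var` from `forced` to
#'   `candidates` (default `FALSE`: keep forced).
#' @return List with updated `candidates` and `forced`.
#' @export
race_candidate_mode <- function(candidates, forced, race_var = "RACE",
                                as_candidate = FALSE) {
  if (as_candidate && race_var %in% forced) {
    forced <- setdiff(forced, race_var)
    candidates <- union(candidates, race_var)
  }
  list(candidates = candidates, forced = forced)
}

#' Run the full multivariable selection stage
#'
#' Builds the conflict graph over the candidates, enumerates all maximal
#' compatible combinations, runs the exhaustive best-subset search (BIC,
#' forced covariates always included) within each combination, then pools,
#' filters, prunes and ranks the resulting models.
#'
#' @inheritParams best_subset
#' @param candidates Character vector of candidate variables (e.g. the
#'   pooled set from [screen()] plus spatial terms).
#' @param r_threshold Conflict-graph correlation threshold (default 0.6).
#' @param adj_r2_min Adjusted R-squared floor (default 0.3).
#' @param delta_bic BIC comparability window (default 2).
#' @param max_nodes Enumeration guard passed to [enumerate_combinations()].
#' @return A `selection_result` with the extra elements `graph`,
#'   `combinations` and `fits` (the per-combination best models).
#' @export
select_models <- function(data, outcome, candidates, forced = character(),
                          r_threshold = 0.6, adj_r2_min = 0.3,
                          delta_bic = 2.0, max_size = NULL,
                          hierarchy = c(LAT2 = "LAT"), max_nodes = 40) {
  if (length(candidates) == 0) {
    abort("no candidate variables to select from.")
  }
  if (length(candidates) == 1) {
    combos <- tibble::tibble(
      id = 1L, members = list(candidates), size = 1L, maximal = TRUE
    )
    graph <- NULL
  } else {
    graph <- build_conflict_graph(data, candidates, r_threshold)
    combos <- enumerate_combinations(graph, max_nodes = max_nodes)
  }
  fits <- purrr::map(combos$members, function(members) {
    best_subset(data, outcome, members, forced,
      max_size = max_size, hierarchy = hierarchy
    )
  })
  result <- pool_and_prune(fits, adj_r2_min = adj_r2_min, delta_bic = delta_bic)
  result$graph <- graph
  result$combinations <- combos
  result$fits <- fits
  result
}
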