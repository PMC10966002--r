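# Independent reference implementations (oracles) used to cross-check the
# package's optimized code paths, plus small fixture builders. The oracles
# deliberately use different machinery (stats::lm, exhaustive subset
# enumeration, straightforward loops) from the implementation they check.

# Exhaustive best-subset reference: lm fit per subset, BIC with the same
# parameter count convention, same tie-break (fewer variables, then
# lexicographic id).
oracle_best_subset <- function(data, outcome, combination,
                               forced = character(),
                               hierarchy = c(LAT2 = "LAT")) {
  vars <- c(outcome, forced, combination)
  d <- data[stats::complete.cases(data[, vars]), vars]
  n <- nrow(d)
  hierarchy <- hierarchy[names(hierarchy) %in% combination &
    hierarchy %in% combination]
  p <- length(combination)
  best <- NULL
  for (code in 0:(2^p - 1)) {
    members <- combination[bitwAnd(code, 2^(seq_len(p) - 1)) > 0]
    ok <- TRUE
    for (child in names(hierarchy)) {
      if (child %in% members && !(hierarchy[[child]] %in% members)) ok <- FALSE
    }
    if (!ok) next
    rhs <- c(forced, members)
    fit <- if (length(rhs) == 0) {
      stats::lm(d[[outcome]] ~ 1)
    } else {
      stats::lm(d[[outcome]] ~ ., data = as.data.frame(d[, rhs, drop = FALSE]))
    }
    k <- length(stats::coef(fit))
    if (n <= k || anyNA(stats::coef(fit))) next
    rss <- sum(stats::residuals(fit)^2)
    bic <- n * log(max(rss, 1e-12) / n) + k * log(n)
    cand <- list(members = sort(members), bic = bic, rss = rss, k = k)
    if (is.null(best)) {
      best <- cand
    } else if (bic < best$bic - 1e-12) {
      best <- cand
    } else if (abs(bic - best$bic) <= 1e-12) {
      tie <- length(members) < length(best$members) ||
        (length(members) == length(best$members) &&
          paste(sort(members), collapse = "+") <
            paste(best$members, collapse = "+"))
      if (tie) best <- cand
    }
  }
  best
}

# Brute-force maximal independent sets of an adjacency matrix (p <= 12):
# enumerate every subset, keep the independent ones, then keep those not
# strictly contained in another independent set.
oracle_maximal_independent_sets <- function(adj) {
  p <- nrow(adj)
  nodes <- if (is.null(rownames(adj))) as.character(seq_len(p)) else rownames(adj)
  indep <- list()
  for (code in 0:(2^p - 1)) {
    members <- which(bitwAnd(code, 2^(seq_len(p) - 1)) > 0)
    if (length(members) < 2 || !any(adj[members, members])) {
      indep[[length(indep) + 1]] <- members
    }
  }
  maximal <- Filter(function(s) {
    !any(vapply(indep, function(t) length(t) > length(s) && all(s %in% t),
      logical(1)
    ))
  }, indep)
  ids <- vapply(
    maximal,
    function(s) paste(sort(nodes[s]), collapse = "+"), character(1)
  )
  sort(ids[ids != ""])
}

# Straightforward reference for pooling/filtering/pruning/ranking.
oracle_pool_and_prune <- function(models, adj_r2_min = 0.3, delta_bic = 2) {
  info <- lapply(models, function(m) {
    list(
      subset = sort(m$subset),
      id = if (length(m$subset)) paste(sort(m$subset), collapse = "+") else "(none)",
      bic = m$bic, adj_r2 = m$adj_r2
    )
  })
  info <- Filter(function(m) m$adj_r2 >= adj_r2_min, info)
  if (length(info) == 0) return(list(empty = TRUE, ranking = character()))
  info <- info[!duplicated(vapply(info, `[[`, character(1), "id"))]
  m <- length(info)
  # union-find over the nesting relation
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (m > 1) {
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        a <- info[[i]]$subset
        b <- info[[j]]$subset
        if (all(a %in% b) || all(b %in% a)) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  groups <- vapply(seq_len(m), find, integer(1))
  kept <- lapply(unique(groups), function(g) {
    cand <- info[groups == g]
    ord <- order(
      vapply(cand, `[[`, numeric(1), "bic"),
      vapply(cand, function(x) length(x$subset), integer(1)),
      vapply(cand, `[[`, character(1), "id")
    )
    cand[[ord[1]]]
  })
  ord <- order(
    vapply(kept, `[[`, numeric(1), "bic"),
    vapply(kept, function(x) length(x$subset), integer(1)),
    vapply(kept, `[[`, character(1), "id")
  )
  kept <- kept[ord]
  bics <- vapply(kept, `[[`, numeric(1), "bic")
  list(
    empty = FALSE,
    ranking = vapply(kept, `[[`, character(1), "id"),
    bic = bics,
    comparable = (bics - bics[1]) < delta_bic
  )
}

# Brute-force joinpoint search by BIC: enumerate every admissible break
# placement at observed years for each size, fit with stats::lm on the
# hinge basis, pick min RSS per size, then min BIC across sizes.
oracle_joinpoint_search <- function(series, max_joinpoints = 2,
                                    min_seg_obs = 3) {
  x <- series$year
  yl <- log(series$rate)
  n <- length(x)
  hinge_fit <- function(breaks) {
    X <- cbind(x - min(x))
    for (tau in breaks) X <- cbind(X, pmax(x - tau, 0))
    fit <- stats::lm(yl ~ X)
    sum(stats::residuals(fit)^2)
  }
  best <- NULL
  for (k in 0:max_joinpoints) {
    placements <- if (k == 0) {
      list(numeric())
    } else {
      interior <- x[-c(1, n)]
      if (length(interior) < k) next
      cand <- utils::combn(interior, k, simplify = FALSE)
      Filter(function(br) {
        bounds <- c(x[1], br, x[n])
        all(vapply(
          seq_len(k + 1),
          function(i) sum(x >= bounds[i] & x <= bounds[i + 1]),
          integer(1)
        ) >= min_seg_obs)
      }, cand)
    }
    if (length(placements) == 0) next
    rsss <- vapply(placements, hinge_fit, numeric(1))
    i <- which.min(rsss)
    bic <- n * log(max(rsss[i], 1e-12) / n) + 2 * (k + 1) * log(n)
    if (is.null(best) || bic < best$bic) {
      best <- list(k = k, breaks = placements[[i]], rss = rsss[i], bic = bic)
    }
  }
  best
}

# A fitted_model stand-in for unit tests of pool_and_prune (only the
# fields that function reads).
fake_model <- function(subset, bic, adj_r2) {
  structure(
    list(subset = subset, forced = character(), bic = bic, adj_r2 = adj_r2),
    class = "fitted_model"
  )
}

# Standardized analysis frame with planted effects among noise candidates.
make_planted_frame <- function(seed, n = 62, n_candidates = 20,
                               betas = c(0.5, 0.5), target_r2 = 0.5) {
  spec <- synthetic_spec(
    n_counties = n,
    variable_blocks = list(list(size = n_candidates, rho = 0)),
    planted_effects = stats::setNames(
      betas, sprintf("B1V%d", seq_along(betas))
    ),
    noise_sd = 1, seed = seed
  )
  X <- generate_exposures(spec)
  noise_sd <- if (length(betas) > 0 && target_r2 > 0) {
    noise_sd_for_r2(X, spec$planted_effects, target_r2)
  } else {
    1
  }
  Xy <- generate_outcome(X, spec$planted_effects, noise_sd, seed = seed)
  standardize_columns(Xy)
}

# Two exactly orthonormal (sample) vectors, for constructing pairs with an
# exact sample correlation.
orthonormal_pair <- function(n, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(cbind(stats::rnorm(n), stats::rnorm(n))))
  a <- scale(q[, 1])[, 1]
  b <- stats::residuals(stats::lm(q[, 2] ~ a))
  b <- scale(b)[, 1]
  list(a = a, b = b)
}
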