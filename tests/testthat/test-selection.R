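graph_from_adj <- function(adj, threshold = 0.6) {
  structure(
    list(
      nodes = rownames(adj),
      edges = tibble::tibble(a = character(), b = character(), r = numeric()),
      adjacency = adj, threshold = threshold
    ),
    class = "conflict_graph"
  )
}

named_adj <- function(nodes, edges = list()) {
  p <- length(nodes)
  adj <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  for (e in edges) adj[e[1], e[2]] <- adj[e[2], e[1]] <- TRUE
  adj
}

combo_ids <- function(combos) {
  sort(vapply(combos$members, paste, character(1), collapse = "+"))
}

test_that("conflict edges appear only strictly above the correlation threshold", {
  set.seed(2)
  d <- tibble::tibble(A = rnorm(50))
  d$B <- d$A # r = 1
  d$C <- rnorm(50)
  g <- build_conflict_graph(d, c("A", "B", "C"))
  expect_equal(nrow(g$edges), 1)
  expect_setequal(c(g$edges$a, g$edges$b), c("A", "B"))

  # independent noise at n = 1000: no edges
  set.seed(3)
  big <- tibble::as_tibble(matrix(rnorm(1000 * 5), 1000, 5,
    dimnames = list(NULL, paste0("V", 1:5))
  ))
  expect_equal(nrow(build_conflict_graph(big, paste0("V", 1:5))$edges), 0)

  # exact boundary: |r| equal to the threshold creates no edge (strict >)
  op <- orthonormal_pair(40, seed = 9)
  d2 <- tibble::tibble(X = op$a, Z = 0.6 * op$a + 0.8 * op$b)
  r_obs <- abs(cor(d2$X, d2$Z))
  g2 <- build_conflict_graph(d2, c("X", "Z"), r_threshold = r_obs)
  expect_equal(nrow(g2$edges), 0)

  d2$K <- 5
  expect_error(build_conflict_graph(d2, c("X", "K")), "constant")
})

test_that("maximal compatible combinations match brute-force enumeration", {
  # worked example: nodes {A,B,C}, edge A-B -> {A,C}, {B,C}
  g <- graph_from_adj(named_adj(c("A", "B", "C"), list(c("A", "B"))))
  expect_identical(combo_ids(enumerate_combinations(g)), c("A+C", "B+C"))

  # no edges -> one combination with every variable
  g0 <- graph_from_adj(named_adj(c("A", "B", "C", "D")))
  expect_identical(combo_ids(enumerate_combinations(g0)), "A+B+C+D")

  # complete graph -> singletons
  k4 <- named_adj(c("A", "B", "C", "D"))
  k4[] <- TRUE
  diag(k4) <- FALSE
  expect_identical(
    combo_ids(enumerate_combinations(graph_from_adj(k4))),
    c("A", "B", "C", "D")
  )

  # random graphs up to 12 nodes vs exhaustive subset enumeration
  set.seed(14)
  for (rep in 1:30) {
    p <- sample(3:12, 1)
    nodes <- sprintf("N%02d", 1:p)
    adj <- named_adj(nodes)
    pairs <- which(upper.tri(adj), arr.ind = TRUE)
    on <- runif(nrow(pairs)) < 0.3
    for (i in which(on)) {
      adj[pairs[i, 1], pairs[i, 2]] <- adj[pairs[i, 2], pairs[i, 1]] <- TRUE
    }
    got <- combo_ids(enumerate_combinations(graph_from_adj(adj)))
    expect_identical(got, oracle_maximal_independent_sets(adj))
  }

  big <- graph_from_adj(named_adj(sprintf("N%02d", 1:45)))
  expect_error(enumerate_combinations(big), "ceiling")
})

test_that("every independent set is covered by some maximal combination", {
  set.seed(15)
  for (rep in 1:10) {
    p <- sample(4:10, 1)
    nodes <- sprintf("N%02d", 1:p)
    adj <- named_adj(nodes)
    pairs <- which(upper.tri(adj), arr.ind = TRUE)
    on <- runif(nrow(pairs)) < 0.35
    for (i in which(on)) {
      adj[pairs[i, 1], pairs[i, 2]] <- adj[pairs[i, 2], pairs[i, 1]] <- TRUE
    }
    combos <- enumerate_combinations(graph_from_adj(adj))$members
    for (code in 0:(2^p - 1)) {
      members <- which(bitwAnd(code, 2^(seq_len(p) - 1)) > 0)
      if (length(members) > 1 && any(adj[members, members])) next
      covered <- any(vapply(
        combos,
        function(cmb) all(nodes[members] %in% cmb), logical(1)
      ))
      expect_true(covered)
    }
  }
})

test_that("BIC and adjusted R2 follow their closed forms", {
  expect_equal(adjusted_r2(61, 61, 62, 1), 0) # null fit
  expect_equal(
    adjusted_r2(30, 61, 62, 5), 1 - (30 / 57) / (61 / 61),
    tolerance = 1e-12
  )
  expect_equal(
    bic_gaussian(30, 62, 5), 62 * log(30 / 62) + 5 * log(62),
    tolerance = 1e-12
  )
  # perfect fit: adjusted R2 of 1 and a finite (floored) BIC
  expect_equal(adjusted_r2(0, 61, 62, 5), 1)
  expect_true(is.finite(bic_gaussian(0, 62, 5)))
  expect_error(bic_gaussian(1, 5, 5), "exceed")
  expect_error(adjusted_r2(1, 0, 10, 2), "tss")
})

test_that("best_subset recovers a single planted signal among noise", {
  hits <- vapply(1:200, function(s) {
    X <- generate_exposures(synthetic_spec(
      n_counties = 62, variable_blocks = list(list(size = 6, rho = 0)),
      seed = s
    ))
    Xy <- generate_outcome(
      X, c(B1V1 = 0.6, B1V4 = 0.3, B1V5 = 0.3, B1V6 = 0.3), 0.5,
      seed = s + 3e5
    )
    Xs <- standardize_columns(Xy)
    fit <- best_subset(Xs, "y", c("B1V1", "B1V2", "B1V3"),
      forced = c("B1V4", "B1V5", "B1V6")
    )
    identical(fit$subset, "B1V1")
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("pure-noise outcomes mostly select the forced-only model", {
  sizes <- vapply(1:200, function(s) {
    X <- generate_exposures(synthetic_spec(
      n_counties = 62, variable_blocks = list(list(size = 5, rho = 0)),
      seed = s + 1000
    ))
    Xy <- generate_outcome(X, c(), 1, seed = s + 4e5)
    Xs <- standardize_columns(Xy)
    fit <- best_subset(Xs, "y", c("B1V1", "B1V2", "B1V3"),
      forced = c("B1V4", "B1V5")
    )
    length(fit$subset)
  }, numeric(1))
  expect_identical(as.integer(names(which.max(table(sizes)))), 0L)
})

test_that("best_subset equals the lm brute-force oracle", {
  for (s in 1:15) {
    p <- 2 + (s %% 7)
    X <- generate_exposures(synthetic_spec(
      n_counties = 40,
      variable_blocks = list(list(size = p, rho = 0.3), list(size = 2, rho = 0)),
      seed = s
    ))
    beta <- stats::setNames(c(0.5, -0.4), c("B1V1", sprintf("B1V%d", p)))
    Xy <- generate_outcome(X, beta, 0.7, seed = s + 5e5)
    Xs <- standardize_columns(Xy)
    comb <- sprintf("B1V%d", 1:p)
    forced <- c("B2V1", "B2V2")
    got <- best_subset(Xs, "y", comb, forced)
    want <- oracle_best_subset(Xs, "y", comb, forced)
    expect_identical(sort(got$subset), want$members)
    expect_equal(got$bic, want$bic, tolerance = 1e-8)
    expect_equal(got$rss, want$rss, tolerance = 1e-8)
  }
})

test_that("the weak hierarchy admits the squared term only with its parent", {
  set.seed(33)
  n <- 62
  lat <- scale(runif(n, 40, 45))[, 1]
  d <- tibble::tibble(
    LAT = lat, LAT2 = scale(lat^2)[, 1], W = rnorm(n),
    y = scale(lat^2)[, 1] * 0.8 + rnorm(n, 0, 0.3)
  )
  ds <- standardize_columns(d)
  fit <- best_subset(ds, "y", c("LAT", "LAT2", "W"))
  expect_true(!("LAT2" %in% fit$subset) || ("LAT" %in% fit$subset))
  expect_true(all(c("LAT", "LAT2") %in% fit$subset))
  # oracle with the same constraint agrees
  want <- oracle_best_subset(ds, "y", c("LAT", "LAT2", "W"))
  expect_identical(sort(fit$subset), want$members)
})

test_that("guards: oversized combinations and overlapping forced sets are rejected", {
  d <- tibble::tibble(y = rnorm(10), A = rnorm(10))
  expect_error(
    best_subset(d, "y", sprintf("V%d", 1:26)), "guard"
  )
  expect_error(best_subset(d, "y", "A", forced = "A"), "disjoint")
})

test_that("pool_and_prune keeps the best member of each nested group", {
  m1 <- fake_model(c("A"), bic = -10, adj_r2 = 0.5)
  m2 <- fake_model(c("A", "B"), bic = -8, adj_r2 = 0.55)
  res <- pool_and_prune(list(m1, m2))
  expect_identical(tidy(res)$subset, "A")

  # below the floor everywhere: explicit empty result
  low <- pool_and_prune(list(
    fake_model("A", -10, 0.1), fake_model("B", -12, 0.2)
  ))
  expect_true(low$empty)
  expect_null(low$best)
  expect_identical(glance(low)$n_ranked, 0L)
})

test_that("pool_and_prune equals the reference implementation on random pools", {
  set.seed(77)
  for (rep in 1:40) {
    n_models <- sample(2:10, 1)
    vars <- LETTERS[1:6]
    models <- lapply(seq_len(n_models), function(i) {
      subset <- sample(vars, sample(0:4, 1))
      fake_model(sort(subset),
        bic = round(rnorm(1, -5, 4), 2),
        adj_r2 = runif(1, 0, 0.7)
      )
    })
    # identical subsets must share a BIC for the pool to be coherent
    ids <- vapply(models, function(m) subset_id <- paste(m$subset, collapse = "+"), character(1))
    for (id in unique(ids)) {
      first <- which(ids == id)[1]
      for (j in which(ids == id)) {
        models[[j]]$bic <- models[[first]]$bic
        models[[j]]$adj_r2 <- models[[first]]$adj_r2
      }
    }
    got <- pool_and_prune(models)
    want <- oracle_pool_and_prune(models)
    expect_identical(got$empty, want$empty)
    if (!want$empty) {
      expect_identical(tidy(got)$subset, want$ranking)
      expect_equal(tidy(got)$bic, want$bic, tolerance = 1e-12)
      expect_identical(tidy(got)$comparable, want$comparable)
    }
  }
})

test_that("race_candidate_mode moves race between roles and honors conflicts", {
  roles <- race_candidate_mode(c("SMOK"), c("POV", "INS", "RACE"))
  expect_identical(roles$forced, c("POV", "INS", "RACE"))
  roles2 <- race_candidate_mode(c("SMOK"), c("POV", "INS", "RACE"),
    as_candidate = TRUE
  )
  expect_identical(roles2$forced, c("POV", "INS"))
  expect_setequal(roles2$candidates, c("SMOK", "RACE"))

  # race highly correlated with smoking never shares a combination
  op <- orthonormal_pair(62, seed = 21)
  d <- tibble::tibble(
    SMOK = op$a, RACE = 0.9 * op$a + sqrt(1 - 0.81) * op$b,
    OTHER = rnorm(62)
  )
  g <- build_conflict_graph(d, c("SMOK", "RACE", "OTHER"))
  combos <- enumerate_combinations(g)$members
  expect_false(any(vapply(
    combos, function(m) all(c("SMOK", "RACE") %in% m), logical(1)
  )))
})

test_that("the full selection stage equals brute force over independent subsets", {
  # for small candidate pools: best over all independent sets scored by
  # BIC, filtered and pruned identically, must match select_models
  for (s in 1:8) {
    frame <- make_planted_frame(s + 50,
      n = 40, n_candidates = 6,
      betas = c(0.6, 0.5), target_r2 = 0.55
    )
    cands <- sprintf("B1V%d", 1:6)
    got <- select_models(frame, "y", cands, adj_r2_min = 0.2)
    # brute force: enumerate every independent subset directly
    g <- build_conflict_graph(frame, cands)
    adj <- g$adjacency
    p <- length(cands)
    best <- NULL
    for (code in 0:(2^p - 1)) {
      members <- which(bitwAnd(code, 2^(seq_len(p) - 1)) > 0)
      if (length(members) > 1 && any(adj[members, members])) next
      o <- oracle_best_subset(frame, "y", cands[members], character())
      keep <- o
      keep$members <- sort(cands[members][cands[members] %in% o$members])
      if (is.null(best) || o$bic < best$bic - 1e-12) best <- o
    }
    expect_false(got$empty)
    expect_identical(sort(got$best$subset), best$members)
    expect_equal(got$best$bic, best$bic, tolerance = 1e-8)
  }
})

test_that("selection results are deterministic and plottable", {
  frame <- make_planted_frame(123, n_candidates = 8, betas = c(0.6, 0.4))
  cands <- sprintf("B1V%d", 1:8)
  a <- select_models(frame, "y", cands)
  b <- select_models(frame, "y", cands)
  expect_identical(tidy(a), tidy(b))
  expect_identical(glance(a), glance(b))
  expect_s3_class(autoplot(a), "ggplot")
})
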