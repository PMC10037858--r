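toy_universe <- function(ds = make_toy_ds()) {
  gold <- regulatory_network(data.frame(regulator = "g1", target = "g2"),
                             regulator_universe = c("g1", "g4"))
  build_candidate_universe(ds, gold)
}

test_that("pearson scores are absolute correlations with a degenerate-gene rule", {
  ds <- make_toy_ds()
  uni <- toy_universe(ds)
  expect_warning(s <- pearson_scores(ds, uni), "constant")
  expect_equal(s[uni$regulator == "g1" & uni$target == "g2"], 1)   # exact copy
  expect_equal(s[uni$regulator == "g1" & uni$target == "g3"], 1)   # exact negation
  expect_equal(s[uni$regulator == "g1" & uni$target == "g5"], 0)   # constant target

  tiny <- expression_dataset(matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("a", "b"))), "g1")
  expect_error(pearson_scores(tiny, uni), class = "grn_insufficient_data_error")
})

test_that("partial correlation matches the residual-on-residual oracle", {
  withr::with_seed(42, {
    n <- 2000
    z <- rnorm(n)
    x <- z + rnorm(n, 0, 0.5)
    y <- 0.8 * x + 0.5 * z + rnorm(n, 0, 0.5)
    vals <- rbind(gx = x, gy = y, gz = z)
    colnames(vals) <- paste0("s", 1:n)
    ds <- expression_dataset(vals, c("gx", "gz"))
    uni <- make_universe(c("gx", "gz"), c("gx", "gy", "gz"))
    s <- partial_correlation_scores(ds, uni, shrinkage = 0)
    X <- t(vals)
    expect_equal(s[uni$regulator == "gx" & uni$target == "gy"],
                 abs(brute_partial_cor(X, 1, 2)), tolerance = 1e-10)
    expect_equal(s[uni$regulator == "gz" & uni$target == "gy"],
                 abs(brute_partial_cor(X, 3, 2)), tolerance = 1e-10)
  })
})

test_that("partial correlation of independent genes stays near zero and 2-gene case reduces to correlation", {
  withr::with_seed(7, {
    vals <- matrix(rnorm(5 * 10000), 5, dimnames = list(paste0("g", 1:5), NULL))
    colnames(vals) <- paste0("s", 1:10000)
    ds <- expression_dataset(vals, c("g1", "g2"))
    uni <- make_universe(c("g1", "g2"), paste0("g", 1:5))
    expect_true(all(partial_correlation_scores(ds, uni, shrinkage = 0.05) < 0.1))
  })
  ds2 <- make_toy_ds()
  uni2 <- make_universe("g1", c("g1", "g4"))
  expect_equal(partial_correlation_scores(ds2, uni2, shrinkage = 0),
               suppressWarnings(pearson_scores(ds2, uni2)), tolerance = 1e-12)
})

lagged_fixture <- function() {
  withr::with_seed(3, {
    r <- cumsum(rnorm(40))
    t <- c(0, r[-40])          # t copies r with lag 1
    vals <- rbind(gr = rep(r, 2), gt = rep(t, 2), gu = rnorm(80))
    colnames(vals) <- paste0("s", 1:80)
    meta <- data.frame(sample_id = colnames(vals),
                       trajectory_id = rep(c("a", "b"), each = 40),
                       time_minutes = rep(seq(0, 390, 10), 2))
    expression_dataset(vals, c("gr", "gu"), meta)
  })
}

test_that("lagged correlation finds a shifted copy and reduces to pearson at lag 0", {
  ds <- lagged_fixture()
  uni <- make_universe(c("gr", "gu"), c("gr", "gt", "gu"))
  s <- lagged_correlation_scores(ds, uni, max_lag_steps = 2)
  expect_gt(s[uni$regulator == "gr" & uni$target == "gt"], 0.999)

  s0 <- lagged_correlation_scores(ds, uni, max_lag_steps = 0)
  expect_equal(s0, suppressWarnings(pearson_scores(ds, uni)), tolerance = 1e-12)

  nometa <- expression_dataset(ds$values, ds$tf_ids)
  expect_error(lagged_correlation_scores(nometa, uni), class = "grn_usage_error")
})

test_that("white-noise lagged correlation stays below the null bound", {
  withr::with_seed(11, {
    vals <- rbind(gr = rnorm(10000), gt = rnorm(10000))
    colnames(vals) <- paste0("s", 1:10000)
    meta <- data.frame(sample_id = colnames(vals), trajectory_id = "a",
                       time_minutes = seq_len(10000))
    ds <- expression_dataset(vals, "gr", meta)
    uni <- make_universe("gr", c("gr", "gt"))
    expect_lt(lagged_correlation_scores(ds, uni, max_lag_steps = 2), 0.1)
  })
})

test_that("mutual information hits ln(B) for a copy, ~0 for independence, and is symmetric", {
  withr::with_seed(5, {
    x <- rnorm(4000)
    ds <- expression_dataset(rbind(ga = x, gb = x, gc = runif(4000)),
                             c("ga", "gc"))
    uni <- make_universe(c("ga", "gc"), c("ga", "gb", "gc"))
    s <- mutual_information_scores(ds, uni, n_bins = 4)
    expect_equal(s[uni$regulator == "ga" & uni$target == "gb"], log(4), tolerance = 0.05)
  })
  withr::with_seed(6, {
    ds2 <- expression_dataset(rbind(ga = runif(10000), gb = runif(10000)), "ga")
    uni2 <- make_universe("ga", c("ga", "gb"))
    expect_lt(mutual_information_scores(ds2, uni2, n_bins = 4), 0.01)
  })
  ds3 <- make_toy_ds()
  uni3 <- make_universe(c("g1", "g4"), c("g1", "g4"))
  s3 <- mutual_information_scores(ds3, uni3, n_bins = 2)
  expect_identical(s3[1], s3[2])
  expect_error(mutual_information_scores(ds3, uni3, n_bins = 1), class = "grn_config_error")
})

tree_fixture <- function(seed = 2) {
  withr::with_seed(seed, {
    n <- 60
    tf_vals <- matrix(rnorm(6 * n), 6, dimnames = list(paste0("tf", 1:6), NULL))
    target <- tf_vals[1, ] + rnorm(n, 0, 0.05)
    vals <- rbind(tf_vals, tgt = target)
    colnames(vals) <- paste0("s", 1:n)
    expression_dataset(vals, paste0("tf", 1:6))
  })
}

test_that("tree importances find the true regulator, normalize, and are seed-stable", {
  ds <- tree_fixture()
  uni <- make_universe(paste0("tf", 1:6), "tgt")
  s <- tree_importance_scores(ds, uni, n_trees = 200, seed = 1)
  expect_equal(uni$regulator[which.max(s)], "tf1")
  expect_equal(sum(s), 1, tolerance = 1e-9)
  expect_identical(s, tree_importance_scores(ds, uni, n_trees = 200, seed = 1))
  s2 <- tree_importance_scores(ds, uni, n_trees = 200, seed = 99)
  expect_gt(cor(s, s2), 0.9)
})

test_that("ODE ridge recovers linear dynamics and shrinks under heavy penalty", {
  ds <- ode_fixture()
  uni <- make_universe(paste0("tf", 1:3), "tgt")
  s <- ode_ridge_scores(ds, uni, ridge_penalty = 1e-6)
  expect_equal(s[uni$regulator == "tf1"], 0.8, tolerance = 0.05 * 0.8 / 0.8)
  expect_lt(s[uni$regulator == "tf2"], 0.05)
  expect_lt(s[uni$regulator == "tf3"], 0.05)
  expect_true(all(ode_ridge_scores(ds, uni, ridge_penalty = 1e6) < 1e-3))

  nometa <- expression_dataset(ds$values, ds$tf_ids)
  expect_error(ode_ridge_scores(nometa, uni), class = "grn_usage_error")
})

test_that("external score files fill missing edges with the file minimum and ignore strays", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "ranked.tsv")
  uni <- make_universe(c("r1", "r2"), paste0("t", 1:3))
  full <- data.frame(regulator = uni$regulator, target = uni$target,
                     score = seq(0.6, 0.1, length.out = 6))
  write_ranked_edges(full, f)
  s <- load_external_scores(f, uni)
  expect_equal(sort(s), sort(full$score))

  partial <- full[1:3, ]
  partial$score <- c(0.9, 0.5, 0.01)
  write_ranked_edges(partial, f)
  s2 <- load_external_scores(f, uni)
  expect_equal(sum(s2 == 0.01), 4)  # 1 real + 3 filled at the file minimum

  extra <- rbind(full, data.frame(regulator = "zz", target = paste0("t", 1:5),
                                  score = 0.3))
  write_ranked_edges(extra, f)
  expect_message(s3 <- load_external_scores(f, uni), "5 out-of-universe")
  expect_equal(attr(s3, "n_ignored"), 5)
})

test_that("the suite assembles columns, skips time methods on steady-state data, and dedupes names", {
  ds <- make_toy_ds()
  uni <- toy_universe(ds)
  specs <- list(list(name = "pearson"), list(name = "mutual_information", n_bins = 2),
                list(name = "lagged_correlation"), list(name = "pearson"))
  tab <- suppressWarnings(run_level1_suite(ds, uni, specs))
  expect_identical(tab$method_names, c("pearson", "mutual_information", "pearson_2"))
  expect_equal(dim(tab$scores), c(nrow(uni), 3))
  expect_true(any(grepl("skipped lagged_correlation", attr(tab, "warnings"))))
  expect_false(anyNA(tab$scores))

  expect_error(suppressWarnings(run_level1_suite(ds, uni, list(list(name = "ode_ridge")))),
               class = "grn_empty_table_error")
})

test_that("deterministic level-1 methods are permutation-equivariant in gene order", {
  ds <- lagged_fixture()
  uni <- make_universe(c("gr", "gu"), c("gr", "gt", "gu"))
  perm <- c("gu", "gt", "gr")
  ds_p <- expression_dataset(ds$values[perm, ], ds$tf_ids, ds$sample_meta)
  for (fn in list(pearson_scores, partial_correlation_scores,
                  function(d, u) lagged_correlation_scores(d, u, 1),
                  function(d, u) mutual_information_scores(d, u, 4),
                  function(d, u) ode_ridge_scores(d, u, 1e-3))) {
    expect_equal(suppressWarnings(fn(ds_p, uni)), suppressWarnings(fn(ds, uni)),
                 tolerance = 1e-12)
  }
})
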