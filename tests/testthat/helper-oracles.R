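# Independent oracles and fixture builders shared across the suite.

# Brute-force AUPRC: enumerate every distinct score as a threshold, compute
# the (recall, precision) point at each, and integrate precision over recall
# steps. Independent of the package's average-precision implementation.
brute_auprc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  prev_recall <- 0
  ap <- 0
  for (th in thr) {
    sel <- scores >= th
    tp <- sum(labels[sel] == 1)
    precision <- tp / sum(sel)
    recall <- tp / P
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Partial correlation of variables i and j given the rest, by the
# residual-on-residual definition (regress each on the remaining variables,
# correlate the residuals).
brute_partial_cor <- function(X, i, j) {
  others <- setdiff(seq_len(ncol(X)), c(i, j))
  if (length(others) == 0) return(cor(X[, i], X[, j]))
  ri <- resid(lm(X[, i] ~ X[, others]))
  rj <- resid(lm(X[, j] ~ X[, others]))
  cor(ri, rj)
}

# Small deterministic steady-state dataset: g1 is a TF, g2 copies it, g3 is
# its negation plus offset, g4 is unrelated, g5 constant.
make_toy_ds <- function() {
  x <- c(1, 3, 2, 5, 4, 6, 8, 7, 9, 10)
  vals <- rbind(g1 = x, g2 = x, g3 = 12 - x, g4 = c(2, 2, 9, 1, 7, 3, 8, 5, 6, 4),
                g5 = rep(5, 10))
  colnames(vals) <- paste0("s", 1:10)
  expression_dataset(vals, tf_ids = c("g1", "g4"))
}

make_universe <- function(regulators, targets, positive_keys = character()) {
  uni <- expand.grid(target = targets, regulator = regulators,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  uni <- uni[uni$regulator != uni$target, c("regulator", "target")]
  rownames(uni) <- NULL
  uni$label <- as.integer(paste(uni$regulator, uni$target) %in% positive_keys)
  structure(uni, class = c("candidate_universe", "data.frame"))
}

make_score_table <- function(universe, scores) {
  scores <- as.matrix(scores)
  structure(list(universe = universe, method_names = colnames(scores), scores = scores),
            class = "edge_score_table")
}

make_feature_table <- function(features, labels, regulators, side = "train") {
  features <- as.matrix(features)
  structure(list(edges = data.frame(regulator = regulators,
                                    target = paste0("t", seq_len(nrow(features)))),
                 features = features, labels = labels, side = side),
            class = "feature_table")
}

# Exact-Euler linear-dynamics fixture: the target integrates
# d(tgt)/dt = b_true * tf1 - decay * tgt, so an ODE regression with a tiny
# ridge penalty must recover b_true and assign ~0 to the other TFs.
ode_fixture <- function(b_true = 0.8, decay = 0.1, n_tfs = 3, n_steps = 30, dt = 1) {
  withr::with_seed(8, {
    tfs <- matrix(abs(rnorm(n_tfs * (n_steps + 1), 2, 1)), n_tfs)
    tgt <- numeric(n_steps + 1)
    tgt[1] <- 1
    for (i in seq_len(n_steps)) {
      tgt[i + 1] <- tgt[i] + dt * (b_true * tfs[1, i] - decay * tgt[i])
    }
    vals <- rbind(tfs, tgt)
    rownames(vals) <- c(paste0("tf", seq_len(n_tfs)), "tgt")
    colnames(vals) <- paste0("s", seq_len(n_steps + 1))
    meta <- data.frame(sample_id = colnames(vals), trajectory_id = "a",
                       time_minutes = seq(0, n_steps * dt, dt))
    expression_dataset(vals, paste0("tf", seq_len(n_tfs)), meta)
  })
}

# Complementary-oracle stacking fixture: two synthetic level-1 columns, each
# informative (label plus Gaussian noise) only on a disjoint half of the TFs
# and pure uniform noise on the other half. No single column ranks well
# everywhere; a level-2 model that learns to use both should.
complementary_fixture <- function(seed, n_tfs = 60, n_targets = 40,
                                  prevalence = 0.1, noise_sd = 0.3) {
  withr::with_seed(seed, {
    tfs <- sprintf("TF%02d", seq_len(n_tfs))
    targets <- sprintf("T%02d", seq_len(n_targets))
    uni <- make_universe(tfs, targets)
    uni$label <- rbinom(nrow(uni), 1, prevalence)
    half1 <- tfs[seq_len(n_tfs / 2)]
    in1 <- uni$regulator %in% half1
    colA <- ifelse(in1, uni$label + rnorm(nrow(uni), 0, noise_sd), runif(nrow(uni)))
    colB <- ifelse(!in1, uni$label + rnorm(nrow(uni), 0, noise_sd), runif(nrow(uni)))
    make_score_table(uni, cbind(oracle_a = colA, oracle_b = colB))
  })
}

# One full simulated-pipeline repetition: simulate a network + expression
# data, run all built-in level-1 methods, apply the default stacking
# protocol on one TF-disjoint split, and return the test-side AUPRC ratios.
run_pipeline_seed <- function(seed, n_genes = 50, n_tfs = 10, noise_sd = 0.05,
                              interval_minutes = 50) {
  cfg <- simulation_config(n_genes = n_genes, n_tfs = n_tfs, noise_sd = noise_sd,
                           interval_minutes = interval_minutes, seed = seed)
  net <- generate_network(cfg)
  ds <- simulate_expression(net, cfg)
  uni <- build_candidate_universe(ds, net)
  tab <- run_level1_suite(ds, uni)
  kf <- kurtosis_filter(tab)
  split <- tf_disjoint_split(net$regulator_universe, 2 / 3, seed)
  test_keep <- uni$regulator %in% split$test_tfs
  # redraw deterministically if the test side has no positive edge
  tries <- 0
  while ((sum(uni$label[test_keep]) == 0 ||
          length(unique(uni$label[!test_keep])) < 2) && tries < 20) {
    tries <- tries + 1
    split <- tf_disjoint_split(net$regulator_universe, 2 / 3, seed + 100000L * tries)
    test_keep <- uni$regulator %in% split$test_tfs
  }
  train <- assemble_features(tab, kf$retained, split, "train")
  test <- assemble_features(tab, kf$retained, split, "test")
  model <- fit_level2("naive_bayes", train)
  conf <- predict_level2(model, test)
  norm <- apply(tab$scores, 2, grnstack:::rank_normalize)
  labels <- uni$label[test_keep]
  l1 <- vapply(tab$method_names,
               function(m) auprc_ratio(norm[test_keep, m], labels), numeric(1))
  list(level1 = l1, ensemble = auprc_ratio(conf, labels))
}
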