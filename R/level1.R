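#' @name level1
#' @title Level-1 edge scoring methods
#'
#' @description
#' Each level-1 method assigns one confidence score (higher = more confident)
#' to every candidate regulator -> target edge. These are simplified
#' representatives of the three families commonly used for network
#' inference — correlation-based, information-theoretic, and model-based
#' (tree importances, ODE regression) — plus an adapter for externally
#' produced ranked-edge files.
NULL

uni_idx <- function(ds, universe) {
  list(reg = match(universe$regulator, ds$gene_ids),
       tgt = match(universe$target, ds$gene_ids))
}

check_samples <- function(ds, n_min, what) {
  if (ncol(ds$values) < n_min) {
    grn_abort(sprintf("%s needs >= %d samples, have %d", what, n_min, ncol(ds$values)),
              "grn_insufficient_data_error")
  }
}

abs_cor_matrix <- function(X, Y = NULL) {
  sdx <- apply(X, 1, sd)
  C <- suppressWarnings(if (is.null(Y)) cor(t(X)) else cor(t(X), t(Y)))
  n_const <- sum(sdx == 0)
  if (anyNA(C)) C[is.na(C)] <- 0
  list(C = abs(C), n_constant = n_const)
}

#' Absolute Pearson correlation scores
#'
#' `score(r -> t) = |cor(x_r, x_t)|` across all samples; constant genes get
#' score 0 with a warning.
#'
#' @param ds An [expression_dataset].
#' @param universe A candidate universe from [build_candidate_universe()].
#' @return Numeric score vector aligned with `universe` rows.
#' @export
pearson_scores <- function(ds, universe) {
  check_samples(ds, 3, "pearson_scores")
  ac <- abs_cor_matrix(ds$values)
  if (ac$n_constant > 0) warning(sprintf("%d constant gene(s) scored 0", ac$n_constant))
  ix <- uni_idx(ds, universe)
  unname(ac$C[cbind(ix$reg, ix$tgt)])
}

#' Shrunk partial correlation scores
#'
#' From the shrunk correlation matrix `R* = (1-s) R + s I` over the genes in
#' the candidate universe, computes the precision matrix `P = (R*)^-1` and
#' scores `|-P_rt / sqrt(P_rr P_tt)|` — the partial correlation of r and t
#' given all other genes.
#'
#' @inheritParams pearson_scores
#' @param shrinkage Diagonal shrinkage in `[0, 1]`; 0 can make the matrix
#'   singular for p >= n.
#' @export
partial_correlation_scores <- function(ds, universe, shrinkage = 0.1) {
  check_samples(ds, 3, "partial_correlation_scores")
  genes <- intersect(ds$gene_ids, unique(c(universe$regulator, universe$target)))
  X <- ds$values[genes, , drop = FALSE]
  R <- suppressWarnings(cor(t(X)))
  if (anyNA(R)) R[is.na(R)] <- 0
  diag(R) <- 1
  Rs <- (1 - shrinkage) * R + shrinkage * diag(nrow(R))
  P <- tryCatch(solve(Rs), error = function(e) {
    grn_abort("correlation matrix singular; increase shrinkage above 0", "grn_numerical_error")
  })
  d <- sqrt(diag(P))
  pc <- abs(-P / outer(d, d))
  ir <- match(universe$regulator, genes)
  it <- match(universe$target, genes)
  unname(pc[cbind(ir, it)])
}

#' Time-lagged correlation scores
#'
#' For each lag `l` in `0..max_lag_steps`, pairs regulator expression at
#' time index `i` with target expression at `i + l` within each trajectory
#' (never across trajectory boundaries), pools the pairs, and takes the
#' maximum absolute Pearson correlation over lags.
#'
#' @inheritParams pearson_scores
#' @param max_lag_steps Maximum lag in sampling steps.
#' @export
lagged_correlation_scores <- function(ds, universe, max_lag_steps = 2) {
  if (is.null(ds$sample_meta)) {
    grn_abort("no time metadata; use pearson_scores for steady-state data", "grn_usage_error")
  }
  traj <- ds$sample_meta$trajectory_id
  traj_idx <- split(seq_along(traj), traj)
  if (min(lengths(traj_idx)) <= max_lag_steps) {
    grn_abort("each trajectory must have more samples than max_lag_steps",
              "grn_insufficient_data_error")
  }
  ix <- uni_idx(ds, universe)
  best <- rep(0, nrow(universe))
  for (l in 0:max_lag_steps) {
    left <- unlist(lapply(traj_idx, function(s) s[seq_len(length(s) - l)]), use.names = FALSE)
    right <- unlist(lapply(traj_idx, function(s) s[seq_len(length(s) - l) + l]), use.names = FALSE)
    ac <- abs_cor_matrix(ds$values[, left, drop = FALSE], ds$values[, right, drop = FALSE])
    best <- pmax(best, ac$C[cbind(ix$reg, ix$tgt)])
  }
  unname(best)
}

equal_freq_bins <- function(x, n_bins) {
  ceiling(rank(x, ties.method = "first") * n_bins / length(x))
}

#' Pairwise mutual information scores
#'
#' Plug-in mutual information (natural log) of the joint histogram after
#' equal-frequency binning of each gene into `n_bins` bins. Symmetric: both
#' edge directions receive the same value.
#'
#' @inheritParams pearson_scores
#' @param n_bins Bins per axis (>= 2).
#' @export
mutual_information_scores <- function(ds, universe, n_bins = 4) {
  if (n_bins < 2) grn_abort("n_bins must be >= 2", "grn_config_error")
  check_samples(ds, n_bins, "mutual_information_scores")
  genes <- unique(c(universe$regulator, universe$target))
  B <- lapply(setNames(genes, genes), function(g) equal_freq_bins(ds$values[g, ], n_bins))
  n <- ncol(ds$values)
  key <- ifelse(universe$regulator < universe$target,
                edge_key(universe$regulator, universe$target),
                edge_key(universe$target, universe$regulator))
  pairs <- !duplicated(key)
  mi_of <- function(r, t) {
    joint <- tabulate((B[[r]] - 1L) * n_bins + B[[t]], nbins = n_bins^2) / n
    pr <- tapply(joint, rep(seq_len(n_bins), each = n_bins), sum)
    pt <- tapply(joint, rep(seq_len(n_bins), times = n_bins), sum)
    nz <- joint > 0
    sum(joint[nz] * log(joint[nz] / (pr[rep(seq_len(n_bins), each = n_bins)][nz] *
                                       pt[rep(seq_len(n_bins), times = n_bins)][nz])))
  }
  mi <- vapply(which(pairs), function(i) mi_of(universe$regulator[i], universe$target[i]),
               numeric(1))
  unname(mi[match(key, key[pairs])])
}

#' Tree-ensemble importance scores
#'
#' Per target gene, fits a random-forest regression of the target's
#' expression on all TF expression profiles (excluding the target itself)
#' and scores each regulator by its impurity importance, normalized per
#' target to sum to 1.
#'
#' @inheritParams pearson_scores
#' @param n_trees Trees per forest.
#' @param seed Seed making the column deterministic.
#' @export
tree_importance_scores <- function(ds, universe, n_trees = 100, seed = 1L) {
  check_samples(ds, 10, "tree_importance_scores")
  ix <- uni_idx(ds, universe)
  scores <- rep(NA_real_, nrow(universe))
  for (t in unique(universe$target)) {
    rows <- which(universe$target == t)
    tf_pred <- setdiff(unique(universe$regulator[rows]), t)
    tf_pred <- union(tf_pred, setdiff(intersect(ds$tf_ids, ds$gene_ids), t))
    if (length(tf_pred) == 0) grn_abort(sprintf("no TF predictors for target '%s'", t),
                                        "grn_consistency_error")
    X <- t(ds$values[tf_pred, , drop = FALSE])
    fit <- ranger::ranger(x = as.data.frame(X), y = ds$values[t, ],
                          num.trees = n_trees, importance = "impurity",
                          seed = seed, num.threads = 1)
    imp <- pmax(fit$variable.importance, 0)
    imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
    scores[rows] <- unname(imp[match(universe$regulator[rows], tf_pred)])
  }
  scores
}

#' ODE ridge-regression scores
#'
#' Models each target's expression dynamics as a linear ODE: the
#' finite-difference derivative of the target within each trajectory is
#' regressed (ridge, penalty on standardized predictors) on the TF
#' expression levels at the left endpoint plus the target's own level (the
#' decay term, which is not emitted as an edge). The score is the absolute
#' regression coefficient on the original scale.
#'
#' @inheritParams pearson_scores
#' @param ridge_penalty Nonnegative ridge penalty applied to the
#'   standardized predictors.
#' @export
ode_ridge_scores <- function(ds, universe, ridge_penalty = 0.01) {
  if (is.null(ds$sample_meta)) {
    grn_abort("ode_ridge_scores needs time metadata", "grn_usage_error")
  }
  traj_idx <- split(seq_len(ncol(ds$values)), ds$sample_meta$trajectory_id)
  traj_idx <- traj_idx[lengths(traj_idx) >= 2]
  if (length(traj_idx) == 0) {
    grn_abort("no trajectory with >= 2 time points", "grn_insufficient_data_error")
  }
  left <- unlist(lapply(traj_idx, function(s) s[-length(s)]), use.names = FALSE)
  right <- unlist(lapply(traj_idx, function(s) s[-1]), use.names = FALSE)
  dt <- ds$sample_meta$time_minutes[right] - ds$sample_meta$time_minutes[left]
  scores <- rep(NA_real_, nrow(universe))
  for (t in unique(universe$target)) {
    rows <- which(universe$target == t)
    regs <- setdiff(unique(universe$regulator[rows]), t)
    y <- (ds$values[t, right] - ds$values[t, left]) / dt
    X <- cbind(t(ds$values[regs, left, drop = FALSE]), .self. = ds$values[t, left])
    mu <- colMeans(X)
    sdv <- apply(X, 2, sd)
    ok <- sdv > 0
    beta <- rep(0, ncol(X))
    if (any(ok)) {
      Z <- scale(X[, ok, drop = FALSE], center = mu[ok], scale = sdv[ok])
      b <- solve(crossprod(Z) + ridge_penalty * diag(sum(ok)), crossprod(Z, y - mean(y)))
      beta[ok] <- b / sdv[ok]
    }
    names(beta) <- colnames(X)
    scores[rows] <- abs(beta)[match(universe$regulator[rows], colnames(X))]
    scores[rows][is.na(scores[rows])] <- 0  # self-edge slot never present
  }
  scores
}

#' Load externally produced scores onto the candidate universe
#'
#' Edges present in the ranked-edges file get their score; universe edges
#' absent from the file get the file's minimum score (fill policy); file
#' rows outside the universe are ignored, with the count recorded in the
#' `n_ignored` attribute.
#'
#' @inheritParams pearson_scores
#' @param path File in [write_ranked_edges()] format.
#' @export
load_external_scores <- function(path, universe) {
  df <- read_ranked_edges(path)
  hit <- match(edge_key(universe$regulator, universe$target),
               edge_key(df$regulator, df$target))
  scores <- df$score[hit]
  n_missing <- sum(is.na(hit))
  if (n_missing > 0) {
    if (nrow(df) == 0) grn_abort("external score file is empty", "grn_parse_error")
    scores[is.na(hit)] <- min(df$score)
  }
  n_ignored <- nrow(df) - sum(!is.na(hit))
  if (n_ignored > 0) {
    message(sprintf("load_external_scores: ignored %d out-of-universe row(s)", n_ignored))
  }
  attr(scores, "n_ignored") <- n_ignored
  scores
}

level1_registry <- function() {
  list(
    pearson = list(fn = pearson_scores, needs_time = FALSE),
    partial_correlation = list(fn = partial_correlation_scores, needs_time = FALSE),
    lagged_correlation = list(fn = lagged_correlation_scores, needs_time = TRUE),
    mutual_information = list(fn = mutual_information_scores, needs_time = FALSE),
    tree_importance = list(fn = tree_importance_scores, needs_time = FALSE),
    ode_ridge = list(fn = ode_ridge_scores, needs_time = TRUE)
  )
}

#' Default level-1 method suite
#'
#' One spec per built-in method with default parameters.
#' @export
default_level1_specs <- function() {
  lapply(names(level1_registry()), function(nm) list(name = nm))
}

#' Run a suite of level-1 methods into an edge-score table
#'
#' Executes each method spec (a list with a `name` naming a built-in method
#' plus its parameters, or a `name` + `file` pair pointing at an external
#' ranked-edges file) and assembles one score column per spec. Methods that
#' require time metadata are skipped with a warning when the dataset has
#' none; duplicate column names are suffixed `_2`, `_3`, ...
#'
#' @inheritParams pearson_scores
#' @param specs List of method specs; default [default_level1_specs()].
#' @return Object of class `edge_score_table`: list with `universe`,
#'   `method_names`, and the `scores` matrix (edges x methods). Degenerate
#'   all-tied columns are noted in the `warnings` attribute.
#' @export
run_level1_suite <- function(ds, universe, specs = default_level1_specs()) {
  reg <- level1_registry()
  cols <- list()
  notes <- character()
  for (sp in specs) {
    nm <- sp$name
    if (!is.null(sp$file)) {
      col <- load_external_scores(sp$file, universe)
      attributes(col) <- NULL
    } else {
      if (is.null(reg[[nm]])) grn_abort(sprintf("unknown level-1 method '%s'", nm),
                                        "grn_config_error")
      if (reg[[nm]]$needs_time && is.null(ds$sample_meta)) {
        warning(sprintf("skipping '%s': requires time metadata", nm))
        notes <- c(notes, sprintf("skipped %s (no time metadata)", nm))
        next
      }
      args <- c(list(ds = ds, universe = universe), sp[setdiff(names(sp), c("name", "file"))])
      col <- do.call(reg[[nm]]$fn, args)
    }
    while (nm %in% names(cols)) {
      i <- sum(grepl(paste0("^", sp$name, "(_[0-9]+)?$"), names(cols))) + 1L
      nm <- paste0(sp$name, "_", i)
    }
    cols[[nm]] <- col
  }
  if (length(cols) == 0) grn_abort("all level-1 methods were skipped; empty score table",
                                   "grn_empty_table_error")
  scores <- do.call(cbind, cols)
  for (j in seq_len(ncol(scores))) {
    if (length(unique(scores[, j])) < 2) {
      warning(sprintf("method '%s' ties all edges", colnames(scores)[j]))
      notes <- c(notes, sprintf("degenerate column %s (all ties)", colnames(scores)[j]))
    }
  }
  structure(list(universe = universe, method_names = colnames(scores), scores = scores),
            class = "edge_score_table", warnings = notes)
}
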