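#' @name level2
#' @title Level-2 ensemble models
#'
#' @description
#' The level-2 ensemble learns, from the gold-standard labels of the
#' training TFs, how to combine the level-1 confidence scores into a single
#' posterior for edge presence, and predicts edges of held-out TFs. Gaussian
#' Naive Bayes is the default: with only a handful of features and sparse
#' positive labels, its strong bias is an asset, and its Gaussian
#' class-conditional assumption is the reason for the positive-kurtosis
#' input filter upstream.
NULL

level2_kinds <- function() {
  c("voting", "logistic", "logistic_sgd", "naive_bayes", "svm", "knn",
    "random_forest", "adaboost", "gradient_boost")
}

check_both_classes <- function(labels) {
  if (length(unique(labels)) < 2) {
    grn_abort("training labels contain a single class; cannot fit a classifier",
              "grn_degenerate_training_error")
  }
}

# --- Gaussian Naive Bayes (hand-authored core model) -----------------------

fit_gnb <- function(X, y) {
  n <- nrow(X)
  classes <- c(0, 1)
  prior <- vapply(classes, function(k) mean(y == k), numeric(1))
  pop_var <- function(M) colMeans(M^2) - colMeans(M)^2
  floor_eps <- 1e-9 * max(pop_var(X), .Machine$double.eps)
  mu <- lapply(classes, function(k) colMeans(X[y == k, , drop = FALSE]))
  v <- lapply(classes, function(k) pmax(pop_var(X[y == k, , drop = FALSE]), floor_eps))
  list(prior = prior, mean = mu, var = v)
}

predict_gnb <- function(fit, X) {
  loglik <- vapply(1:2, function(k) {
    rowSums(dnorm(X, rep(fit$mean[[k]], each = nrow(X)),
                  rep(sqrt(fit$var[[k]]), each = nrow(X)), log = TRUE))
  }, numeric(nrow(X)))
  if (nrow(X) == 1) loglik <- matrix(loglik, nrow = 1)
  lp <- sweep(loglik, 2, log(fit$prior), "+")
  m <- pmax(lp[, 1], lp[, 2])
  exp(lp[, 2] - m) / (exp(lp[, 1] - m) + exp(lp[, 2] - m))
}

# --- logistic regression via SGD -------------------------------------------

fit_logistic_sgd <- function(X, y, learning_rate = 0.1, n_epochs = 25, seed = 1L) {
  w <- rep(0, ncol(X) + 1)
  Xi <- cbind(1, X)
  withr::with_seed(seed, {
    for (ep in seq_len(n_epochs)) {
      for (i in sample(nrow(Xi))) {
        p <- plogis(sum(w * Xi[i, ]))
        w <- w + learning_rate * (y[i] - p) * Xi[i, ]
      }
    }
  })
  w
}

# --- discrete AdaBoost over depth-1 rpart stumps ---------------------------

fit_adaboost <- function(X, y, n_rounds = 50) {
  df <- data.frame(y = factor(y, levels = c(0, 1)), X, check.names = FALSE)
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric()
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(y ~ ., data = df, weights = w,
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2, xval = 0))
    pred <- predict(fit, df, type = "class")
    miss <- pred != df$y
    err <- sum(w * miss) / sum(w)
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(miss, 1, -1))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  list(stumps = stumps, alphas = alphas)
}

predict_adaboost <- function(fit, X) {
  df <- as.data.frame(X)
  if (length(fit$stumps) == 0) return(rep(0.5, nrow(df)))
  F <- rep(0, nrow(df))
  for (m in seq_along(fit$stumps)) {
    h <- ifelse(predict(fit$stumps[[m]], df, type = "class") == "1", 1, -1)
    F <- F + fit$alphas[m] * h
  }
  plogis(2 * F)
}

#' Fit a level-2 ensemble model
#'
#' @param kind One of `"voting"` (no fitting; thresholded vote at predict
#'   time), `"logistic"`, `"logistic_sgd"`, `"naive_bayes"` (Gaussian class
#'   conditionals with a variance floor of `1e-9 *` the largest feature
#'   variance, class priors = empirical label frequencies), `"svm"`,
#'   `"knn"`, `"random_forest"`, `"adaboost"`, `"gradient_boost"`.
#' @param train A `feature_table` from [assemble_features()] with labels of
#'   both classes (except `voting`).
#' @param hyperparameters Named list; recognized entries per kind:
#'   `top_fraction` (voting, default 0.1), `learning_rate`/`n_epochs`
#'   (logistic_sgd), `cost`/`kernel` (svm), `k` (knn, default 5),
#'   `num_trees` (random_forest, default 200), `n_rounds` (adaboost /
#'   gradient_boost, default 50), `max_depth`/`eta` (gradient_boost),
#'   `seed` (any stochastic kind, default 1).
#' @param class_weight `"none"` (default; fit on the natural imbalanced
#'   labels) or `"balanced"` (inverse-prevalence case weights where the
#'   backend supports them).
#' @return Object of class `level2_model`.
#' @export
fit_level2 <- function(kind, train, hyperparameters = list(),
                       class_weight = c("none", "balanced")) {
  kind <- match.arg(kind, level2_kinds())
  class_weight <- match.arg(class_weight)
  stopifnot(inherits(train, "feature_table"))
  X <- train$features
  y <- train$labels
  hp <- hyperparameters
  seed <- if (!is.null(hp$seed)) hp$seed else 1L
  if (kind != "voting") check_both_classes(y)
  cw <- if (class_weight == "balanced") ifelse(y == 1, 0.5 / mean(y == 1), 0.5 / mean(y == 0))
        else rep(1, length(y))
  fit <- switch(kind,
    voting = list(top_fraction = if (!is.null(hp$top_fraction)) hp$top_fraction else 0.1),
    naive_bayes = fit_gnb(X, y),
    logistic = {
      df <- data.frame(y = y, X, check.names = FALSE)
      suppressWarnings(glm(y ~ ., data = df, family = binomial(), weights = cw))
    },
    logistic_sgd = fit_logistic_sgd(
      X, y,
      learning_rate = if (!is.null(hp$learning_rate)) hp$learning_rate else 0.1,
      n_epochs = if (!is.null(hp$n_epochs)) hp$n_epochs else 25, seed = seed),
    svm = withr::with_seed(seed, e1071::svm(
      x = X, y = factor(y, levels = c(0, 1)),
      kernel = if (!is.null(hp$kernel)) hp$kernel else "radial",
      cost = if (!is.null(hp$cost)) hp$cost else 1,
      class.weights = if (class_weight == "balanced")
        c("0" = 0.5 / mean(y == 0), "1" = 0.5 / mean(y == 1)) else NULL)),
    knn = {
      k <- if (!is.null(hp$k)) hp$k else 5L
      if (k > nrow(X)) grn_abort(sprintf("knn k=%d exceeds %d training rows", k, nrow(X)),
                                 "grn_config_error")
      list(X = X, y = y, k = k)
    },
    random_forest = ranger::ranger(
      x = as.data.frame(X), y = factor(y, levels = c(0, 1)), probability = TRUE,
      num.trees = if (!is.null(hp$num_trees)) hp$num_trees else 200,
      case.weights = cw, seed = seed, num.threads = 1),
    adaboost = fit_adaboost(X, y, n_rounds = if (!is.null(hp$n_rounds)) hp$n_rounds else 50),
    gradient_boost = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, weight = cw, nthread = 1)
      withr::with_seed(seed, xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = if (!is.null(hp$max_depth)) hp$max_depth else 3,
                      eta = if (!is.null(hp$eta)) hp$eta else 0.3,
                      nthread = 1),
        data = dtrain,
        nrounds = if (!is.null(hp$n_rounds)) hp$n_rounds else 50,
        verbose = 0))
    }
  )
  structure(list(kind = kind, fit = fit, retained_methods = colnames(X),
                 hyperparameters = hp),
            class = "level2_model")
}

#' @export
print.level2_model <- function(x, ...) {
  cat(sprintf("<level2_model> kind=%s, features: %s\n", x$kind,
              paste(x$retained_methods, collapse = ", ")))
  invisible(x)
}

#' Predict edge confidences with a fitted level-2 model
#'
#' Returns one confidence in `[0, 1]` per test edge: the class-1 posterior
#' for probabilistic kinds, the decision value mapped through a logistic
#' sigmoid for `svm`, or the fraction of retained methods ranking the edge
#' in their global top fraction for `voting`.
#'
#' @param model A `level2_model`.
#' @param test A `feature_table` with exactly the model's retained method
#'   columns, in order.
#' @return Numeric confidence vector aligned with `test` rows.
#' @export
predict_level2 <- function(model, test) {
  stopifnot(inherits(model, "level2_model"), inherits(test, "feature_table"))
  X <- test$features
  if (!identical(colnames(X), model$retained_methods)) {
    grn_abort(sprintf("feature columns do not match model (missing: %s; extra: %s)",
                      paste(setdiff(model$retained_methods, colnames(X)), collapse = ",") ,
                      paste(setdiff(colnames(X), model$retained_methods), collapse = ",")),
              "grn_contract_error")
  }
  p <- switch(model$kind,
    voting = rowMeans(X > 1 - model$fit$top_fraction),
    naive_bayes = predict_gnb(model$fit, X),
    logistic = {
      df <- as.data.frame(X)
      names(df) <- model$retained_methods
      unname(predict(model$fit, newdata = df, type = "response"))
    },
    logistic_sgd = unname(plogis(cbind(1, X) %*% model$fit)[, 1]),
    svm = {
      pr <- predict(model$fit, X, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      if (colnames(dv)[1] == "0/1") dv <- -dv  # orient so larger = class 1
      unname(plogis(dv[, 1]))
    },
    knn = {
      pred <- class::knn(model$fit$X, X, factor(model$fit$y, levels = c(0, 1)),
                         k = model$fit$k, prob = TRUE)
      pw <- attr(pred, "prob")
      ifelse(pred == "1", pw, 1 - pw)
    },
    random_forest = predict(model$fit, as.data.frame(X), num.threads = 1)$predictions[, "1"],
    adaboost = predict_adaboost(model$fit, X),
    gradient_boost = predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1))
  )
  p <- as.numeric(p)
  stopifnot(all(is.finite(p)))
  pmin(pmax(p, 0), 1)
}

#' Grid-search hyper-parameters with TF-disjoint cross-validation
#'
#' Exhaustive search over the grid; folds are TF-disjoint (fold assignment
#' by regulator), the selection metric is mean validation AUPRC, ties break
#' in grid order. Single-class folds are skipped; grid points infeasible on
#' the fold sizes (e.g. knn `k` larger than the training rows) are skipped
#' with a warning.
#'
#' @param kind Level-2 model kind.
#' @param tuning_table A `feature_table` with labels of both classes.
#' @param grid Named list of candidate values, e.g. `list(k = c(3, 5, 11))`;
#'   an empty grid returns an empty list (nothing to tune).
#' @param k_folds Number of folds.
#' @param seed Seed for the fold assignment.
#' @return Named list: the best hyper-parameter combination.
#' @export
tune_hyperparameters <- function(kind, tuning_table, grid, k_folds = 3, seed = 1L) {
  stopifnot(inherits(tuning_table, "feature_table"))
  if (length(grid) == 0) return(list())
  check_both_classes(tuning_table$labels)
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  regs <- unique(tuning_table$edges$regulator)
  fold_of_reg <- withr::with_seed(seed,
    setNames(rep(seq_len(k_folds), length.out = length(regs)), sample(regs)))
  fold <- fold_of_reg[tuning_table$edges$regulator]
  subset_ft <- function(keep) {
    structure(list(edges = tuning_table$edges[keep, , drop = FALSE],
                   features = tuning_table$features[keep, , drop = FALSE],
                   labels = tuning_table$labels[keep], side = tuning_table$side),
              class = "feature_table")
  }
  best <- NULL
  best_score <- -Inf
  any_valid <- FALSE
  for (i in seq_len(nrow(combos))) {
    hp <- as.list(combos[i, , drop = FALSE])
    scores <- c()
    for (f in seq_len(k_folds)) {
      tr <- subset_ft(fold != f)
      va <- subset_ft(fold == f)
      if (length(unique(tr$labels)) < 2 || length(unique(va$labels)) < 2) next
      fit <- tryCatch(fit_level2(kind, tr, hp), grn_config_error = function(e) {
        warning(sprintf("grid point %d infeasible: %s", i, conditionMessage(e)))
        NULL
      })
      if (is.null(fit)) break
      scores <- c(scores, auprc(predict_level2(fit, va), va$labels))
    }
    if (length(scores) == 0) next
    any_valid <- TRUE
    if (mean(scores) > best_score) {
      best_score <- mean(scores)
      best <- hp
    }
  }
  if (!any_valid) grn_abort("no grid point could be validated on any fold", "grn_tuning_error")
  best
}
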