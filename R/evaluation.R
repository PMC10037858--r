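#' Area under the precision-recall curve (average-precision form)
#'
#' Computes AUPRC as average precision: walking the edges in descending
#' score order, each positive contributes the precision at its threshold,
#' and the sum is divided by the number of positives. Tied scores form a
#' single threshold group whose end-of-group precision is assigned to every
#' positive in the group, so the value is invariant under strictly monotone
#' transforms of the scores and a constant predictor scores exactly the
#' positive prevalence.
#'
#' @param scores Numeric confidences, higher = more confident.
#' @param labels 0/1 edge-presence labels, same length.
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  if (length(scores) != length(labels)) grn_abort("scores/labels length mismatch", "grn_contract_error")
  if (anyNA(scores) || anyNA(labels)) grn_abort("NA in scores or labels", "grn_contract_error")
  P <- sum(labels == 1)
  if (P == 0) grn_abort("AUPRC undefined: no positive labels", "grn_undefined_metric_error")
  if (all(labels == 1)) {
    warning("no negative labels; AUPRC trivially 1")
    return(1)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  ends <- cumsum(rle(s)$lengths)            # last index of each tie group
  tp <- cumsum(l)[ends]
  prec <- tp / ends
  dtp <- diff(c(0L, tp))
  sum(dtp * prec) / P
}

#' AUPRC ratio versus a random predictor
#'
#' A random (or constant) predictor's expected AUPRC equals the positive
#' prevalence, so the ratio `auprc / prevalence` is ~1 for an uninformative
#' ranking and grows with enrichment of true edges at the top.
#'
#' @inheritParams auprc
#' @export
auprc_ratio <- function(scores, labels) {
  auprc(scores, labels) / (sum(labels == 1) / length(labels))
}

#' Non-parametric paired sign-flip resampling test
#'
#' One-sided test that paired values `a` exceed `b`: the statistic is the
#' mean paired difference, and its null distribution is generated by
#' randomly flipping the sign of each difference (exchangeability under the
#' null of no systematic direction). The Monte-Carlo p-value uses the +1
#' correction `(1 + #(resampled mean >= observed)) / (1 + n_resamples)`,
#' which makes the test conservative; `exhaustive = TRUE` enumerates all
#' `2^n` sign patterns instead (feasible for n <= ~20) and reports the
#' exact proportion.
#'
#' @param ratios_a,ratios_b Paired per-split values (aligned by split seed),
#'   length >= 5.
#' @param n_resamples Monte-Carlo resamples (ignored when `exhaustive`).
#' @param seed Seed for the resampling.
#' @param alternative `"greater"` (a > b, default) or `"two.sided"`.
#' @param exhaustive Enumerate all sign patterns exactly.
#' @return p-value.
#' @export
paired_resampling_pvalue <- function(ratios_a, ratios_b, n_resamples = 10000,
                                     seed = 1L, alternative = c("greater", "two.sided"),
                                     exhaustive = FALSE) {
  alternative <- match.arg(alternative)
  if (length(ratios_a) != length(ratios_b)) grn_abort("paired series length mismatch", "grn_pairing_error")
  n <- length(ratios_a)
  if (n < 5) grn_abort("need >= 5 paired values", "grn_pairing_error")
  d <- ratios_a - ratios_b
  obs <- mean(d)
  eps <- 1e-12 * max(1, abs(obs))
  stat <- function(m) if (alternative == "greater") m else abs(m)
  target <- stat(obs)
  if (exhaustive) {
    if (n > 25) grn_abort("exhaustive enumeration infeasible for n > 25", "grn_config_error")
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    means <- as.numeric(signs %*% d) / n
    return(mean(stat(means) >= target - eps))
  }
  flips <- withr::with_seed(seed,
    matrix(sample(c(-1, 1), n_resamples * n, replace = TRUE), n_resamples, n))
  means <- as.numeric(flips %*% d) / n
  (1 + sum(stat(means) >= target - eps)) / (1 + n_resamples)
}
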