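#' TF-disjoint train/test split
#'
#' Partitions the gold-standard regulator universe uniformly at random into
#' a training share and a testing share that share no transcription factors
#' (the 2:1 regulator split by default). `|train| = round(ratio * total)`,
#' clamped so both sides are non-empty.
#'
#' @param regulators Character vector of regulator ids (>= 2).
#' @param ratio Training share in (0, 1); default 2/3.
#' @param seed Integer seed; the partition is deterministic given the seed.
#' @return Object of class `split_spec` with `train_tfs`, `test_tfs`,
#'   `seed`, `ratio`.
#' @export
tf_disjoint_split <- function(regulators, ratio = 2 / 3, seed = 1L) {
  regulators <- unique(as.character(regulators))
  if (length(regulators) < 2) grn_abort("need >= 2 regulators to split", "grn_split_error")
  if (ratio <= 0 || ratio >= 1) grn_abort("ratio must be in (0, 1)", "grn_split_error")
  n <- length(regulators)
  n_train <- min(max(round(ratio * n), 1L), n - 1L)
  train <- withr::with_seed(seed, sample(regulators, n_train))
  structure(list(train_tfs = train, test_tfs = setdiff(regulators, train),
                 seed = as.integer(seed), ratio = ratio),
            class = "split_spec")
}

#' Positive-kurtosis input filter
#'
#' Computes the sample excess kurtosis `g2 = m4/m2^2 - 3` (population-moment
#' form; 0 for a Gaussian) of each method's full score column and retains
#' the methods with `g2 > 0`. The Gaussian Naive Bayes level-2 model assumes
#' Gaussian-like class-conditional score distributions; methods with
#' negative excess kurtosis (e.g. near-uniform outputs) violate that
#' assumption and are dropped. Zero-variance columns are dropped with a
#' warning (kurtosis undefined); if no method survives, all non-degenerate
#' methods are retained with a warning.
#'
#' @param table An `edge_score_table` from [run_level1_suite()].
#' @return List with `retained` (method names) and `kurtosis` (named vector
#'   of per-method excess kurtosis; `NA` for zero-variance columns).
#' @export
kurtosis_filter <- function(table) {
  stopifnot(inherits(table, "edge_score_table"))
  if (nrow(table$scores) < 4) grn_abort("need >= 4 edges for kurtosis", "grn_insufficient_data_error")
  g2 <- apply(table$scores, 2, excess_kurtosis)
  if (anyNA(g2)) {
    warning(sprintf("dropping zero-variance column(s): %s",
                    paste(names(g2)[is.na(g2)], collapse = ", ")))
  }
  retained <- names(g2)[!is.na(g2) & g2 > 0]
  if (length(retained) == 0) {
    warning("no method has positive excess kurtosis; retaining all non-degenerate methods")
    retained <- names(g2)[!is.na(g2)]
  }
  list(retained = retained, kurtosis = g2)
}

#' Assemble a normalized feature table for one split side
#'
#' Rank-normalizes each retained method's scores over the full candidate
#' universe (average ranks for ties, divided by the number of edges, so
#' values lie in (0, 1]), then restricts rows to candidate edges whose
#' regulator lies on the requested side of the split. Gold-standard labels
#' travel with the rows.
#'
#' @param table An `edge_score_table`.
#' @param retained Method names to keep (subset of `table$method_names`).
#' @param split A `split_spec` from [tf_disjoint_split()].
#' @param side `"train"` or `"test"`.
#' @return Object of class `feature_table`: list with `edges` (data.frame),
#'   `features` (matrix, rows = edges, columns = retained methods), `labels`
#'   (0/1 vector), `side`.
#' @export
assemble_features <- function(table, retained, split, side = c("train", "test")) {
  side <- match.arg(side)
  stopifnot(inherits(table, "edge_score_table"), inherits(split, "split_spec"))
  if (!all(retained %in% table$method_names)) {
    grn_abort("retained methods not all present in score table", "grn_config_error")
  }
  tf_set <- if (side == "train") split$train_tfs else split$test_tfs
  keep <- table$universe$regulator %in% tf_set
  if (!any(keep)) grn_abort(sprintf("no candidate edges on the %s side", side),
                            "grn_assembly_error")
  norm <- apply(table$scores[, retained, drop = FALSE], 2, rank_normalize)
  structure(
    list(edges = table$universe[keep, c("regulator", "target"), drop = FALSE],
         features = norm[keep, , drop = FALSE],
         labels = table$universe$label[keep],
         side = side),
    class = "feature_table"
  )
}

#' Average-rank community baseline
#'
#' Scores every candidate edge by the mean of its rank-normalized scores
#' across the retained methods — the classic "community" aggregation of
#' multiple inference methods. Higher = more confident; values in (0, 1].
#'
#' @inheritParams assemble_features
#' @return Numeric confidence vector aligned with `table$universe` rows.
#' @export
average_rank_baseline <- function(table, retained = table$method_names) {
  stopifnot(inherits(table, "edge_score_table"))
  if (length(retained) < 1) grn_abort("need >= 1 retained method", "grn_config_error")
  norm <- apply(table$scores[, retained, drop = FALSE], 2, rank_normalize)
  rowMeans(norm)
}
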