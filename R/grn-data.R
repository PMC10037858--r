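#' Construct an expression dataset
#'
#' Bundles a genes x samples expression matrix with the set of genes flagged
#' as transcription factors (TFs) and, optionally, per-sample time metadata
#' for time-series or pseudotime data.
#'
#' @param values Numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns.
#' @param tf_ids Character vector of regulator gene ids; must be a subset of
#'   the rownames of `values`.
#' @param sample_meta Optional data.frame with columns `sample_id`,
#'   `trajectory_id`, `time_minutes`, one row per column of `values`, in
#'   column order. Within a trajectory, times must be strictly increasing.
#'   `NULL` for steady-state data.
#' @return An object of class `expression_dataset` with elements `values`,
#'   `gene_ids`, `tf_ids`, `sample_meta`.
#' @export
expression_dataset <- function(values, tf_ids, sample_meta = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    grn_abort("expression matrix must have gene ids as rownames", "grn_format_error")
  }
  gene_ids <- rownames(values)
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    grn_abort(sprintf("duplicate gene id(s): %s", paste(head(dup, 5), collapse = ", ")),
              "grn_format_error")
  }
  if (!is.numeric(values)) {
    grn_abort("expression matrix contains non-numeric values", "grn_parse_error")
  }
  if (anyNA(values)) {
    grn_abort("expression matrix contains missing/non-numeric cells", "grn_parse_error")
  }
  tf_ids <- as.character(tf_ids)
  missing_tfs <- setdiff(tf_ids, gene_ids)
  if (length(missing_tfs) > 0) {
    grn_abort(sprintf("TF id(s) not present in expression matrix: %s",
                      paste(head(missing_tfs, 5), collapse = ", ")),
              "grn_consistency_error")
  }
  if (!is.null(sample_meta)) {
    sample_meta <- as.data.frame(sample_meta)
    required <- c("sample_id", "trajectory_id", "time_minutes")
    if (!all(required %in% names(sample_meta))) {
      grn_abort("sample_meta needs columns sample_id, trajectory_id, time_minutes",
                "grn_format_error")
    }
    if (nrow(sample_meta) != ncol(values)) {
      grn_abort("sample_meta must have one row per sample column", "grn_consistency_error")
    }
    for (tr in unique(sample_meta$trajectory_id)) {
      tms <- sample_meta$time_minutes[sample_meta$trajectory_id == tr]
      if (any(diff(tms) <= 0)) {
        grn_abort(sprintf("time_minutes not strictly increasing within trajectory '%s'", tr),
                  "grn_consistency_error")
      }
    }
  }
  structure(
    list(values = values, gene_ids = gene_ids, tf_ids = tf_ids,
         sample_meta = sample_meta),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d samples, %d TFs, %s\n",
              length(x$gene_ids), ncol(x$values), length(x$tf_ids),
              if (is.null(x$sample_meta)) "steady-state" else
                sprintf("%d trajectories", length(unique(x$sample_meta$trajectory_id)))))
  invisible(x)
}

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) return("\t")
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read an expression matrix, TF list and optional time metadata
#'
#' The matrix file is delimited text (tab first, then comma auto-detected)
#' with gene ids in the first column and a header row of sample ids. The TF
#' list file has one regulator id per line. The optional time metadata file
#' has columns `sample_id`, `trajectory_id`, `time_minutes`.
#'
#' @param path Expression matrix file.
#' @param tf_list_path TF list file.
#' @param time_meta_path Optional time metadata file.
#' @return An [expression_dataset].
#' @export
read_expression_matrix <- function(path, tf_list_path, time_meta_path = NULL) {
  if (!file.exists(path)) grn_abort(sprintf("expression file not found: %s", path), "grn_io_error")
  sep <- detect_delim(path)
  raw <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", quote = "", comment.char = "")
  if (ncol(raw) < 2) grn_abort("expression matrix needs gene id column plus >=1 sample", "grn_parse_error")
  gene_ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(storage_vals <- matrix(as.numeric(vals), nrow = nrow(vals),
                                          dimnames = list(gene_ids, colnames(vals))))
  if (anyNA(storage_vals)) {
    bad <- which(is.na(storage_vals), arr.ind = TRUE)[1, ]
    grn_abort(sprintf("non-numeric cell at gene '%s', sample '%s'",
                      gene_ids[bad[1]], colnames(vals)[bad[2]]), "grn_parse_error")
  }
  tfs <- readLines(tf_list_path)
  tfs <- trimws(tfs[nzchar(trimws(tfs))])
  meta <- NULL
  if (!is.null(time_meta_path)) {
    msep <- detect_delim(time_meta_path)
    meta <- read.table(time_meta_path, sep = msep, header = TRUE,
                       check.names = FALSE, quote = "", comment.char = "")
    idx <- match(colnames(storage_vals), meta$sample_id)
    if (anyNA(idx)) {
      grn_abort("time metadata missing entries for some samples", "grn_consistency_error")
    }
    meta <- meta[idx, c("sample_id", "trajectory_id", "time_minutes"), drop = FALSE]
    rownames(meta) <- NULL
  }
  expression_dataset(storage_vals, tfs, meta)
}

#' Write an expression dataset to delimited text
#'
#' @param ds An [expression_dataset].
#' @param path Output matrix file (tab-separated, gene ids in first column).
#' @param meta_path Optional output path for the sample metadata table.
#' @export
write_expression_matrix <- function(ds, path, meta_path = NULL) {
  df <- data.frame(gene_id = ds$gene_ids, ds$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path) && !is.null(ds$sample_meta)) {
    write.table(ds$sample_meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Construct a gold-standard regulatory network
#'
#' A directed edge set over (regulator, target) pairs with set semantics:
#' duplicates collapse, self-edges are rejected.
#'
#' @param edges data.frame with columns `regulator`, `target` (extra columns
#'   such as per-edge `sign`/`strength` annotations are kept).
#' @param regulator_universe Regulator ids the gold standard covers; defaults
#'   to the regulators appearing in `edges`.
#' @param on_self_edge `"error"` (default) or `"skip"` (drop with a warning).
#' @return An object of class `regulatory_network`.
#' @export
regulatory_network <- function(edges, regulator_universe = NULL,
                               on_self_edge = c("error", "skip")) {
  on_self_edge <- match.arg(on_self_edge)
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    edges$regulator <- as.character(edges$regulator)
    edges$target <- as.character(edges$target)
    self <- edges$regulator == edges$target
    if (any(self)) {
      if (on_self_edge == "error") {
        grn_abort(sprintf("self-edge not allowed: %s -> %s",
                          edges$regulator[which(self)[1]], edges$target[which(self)[1]]),
                  "grn_validation_error")
      }
      warning(sprintf("dropping %d self-edge(s)", sum(self)))
      edges <- edges[!self, , drop = FALSE]
    }
    edges <- edges[!duplicated(edge_key(edges$regulator, edges$target)), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(regulator = character(), target = character())
  }
  if (is.null(regulator_universe)) {
    regulator_universe <- unique(edges$regulator)
  } else {
    regulator_universe <- unique(as.character(regulator_universe))
    stray <- setdiff(edges$regulator, regulator_universe)
    if (length(stray) > 0) {
      grn_abort("edge regulator(s) outside regulator_universe", "grn_validation_error")
    }
  }
  structure(list(edges = edges, regulator_universe = regulator_universe),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("<regulatory_network> %d edges over %d regulators\n",
              nrow(x$edges), length(x$regulator_universe)))
  invisible(x)
}

#' Read a gold-standard edge list
#'
#' Each line is `regulator<TAB>target` (comma also accepted; an optional
#' third column is ignored). A BEELINE-style `Gene1 Gene2` header line is
#' skipped if present. Duplicate lines collapse to one edge.
#'
#' @inheritParams regulatory_network
#' @param path Edge list file.
#' @return A [regulatory_network].
#' @export
read_edge_list <- function(path, on_self_edge = c("error", "skip")) {
  if (!file.exists(path)) grn_abort(sprintf("edge list not found: %s", path), "grn_io_error")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(regulatory_network(data.frame(regulator = character(), target = character())))
  }
  sep <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  first <- tolower(trimws(parts[[1]][1:2]))
  if (identical(first, c("gene1", "gene2")) || identical(first, c("regulator", "target"))) {
    parts <- parts[-1]
  }
  if (length(parts) == 0) {
    return(regulatory_network(data.frame(regulator = character(), target = character())))
  }
  nf <- vapply(parts, length, integer(1))
  if (any(nf < 2)) {
    grn_abort(sprintf("edge list line %d has fewer than 2 columns", which(nf < 2)[1]),
              "grn_parse_error")
  }
  edges <- data.frame(regulator = trimws(vapply(parts, `[[`, character(1), 1)),
                      target = trimws(vapply(parts, `[[`, character(1), 2)))
  regulatory_network(edges, on_self_edge = match.arg(on_self_edge))
}

#' Write a ranked-edges file
#'
#' BEELINE-style tab-separated file with header `Gene1 Gene2 EdgeWeight`,
#' rows sorted by descending score with ties broken lexicographically by
#' (regulator, target).
#'
#' @param scored data.frame with columns `regulator`, `target`, `score`.
#' @param path Output file.
#' @export
write_ranked_edges <- function(scored, path) {
  scored <- as.data.frame(scored)
  if (anyNA(scored$score) || any(!is.finite(scored$score))) {
    grn_abort("ranked-edge scores must be finite (no NaN/NA/Inf)", "grn_validation_error")
  }
  ord <- order(-scored$score, scored$regulator, scored$target, method = "radix")
  out <- data.frame(Gene1 = scored$regulator[ord], Gene2 = scored$target[ord],
                    EdgeWeight = scored$score[ord])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ranked-edges file
#'
#' @param path File in [write_ranked_edges()] format.
#' @return data.frame with columns `regulator`, `target`, `score`, in file order.
#' @export
read_ranked_edges <- function(path) {
  if (!file.exists(path)) grn_abort(sprintf("ranked-edges file not found: %s", path), "grn_io_error")
  df <- tryCatch(
    read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
               quote = "", comment.char = "", colClasses = c("character", "character", "numeric")),
    error = function(e) grn_abort(sprintf("cannot parse ranked-edges file: %s", conditionMessage(e)),
                                  "grn_parse_error")
  )
  if (ncol(df) < 3) grn_abort("ranked-edges file needs 3 columns", "grn_parse_error")
  if (anyNA(df[[3]])) {
    grn_abort(sprintf("unparseable score at line %d", which(is.na(df[[3]]))[1] + 1L),
              "grn_parse_error")
  }
  data.frame(regulator = df[[1]], target = df[[2]], score = df[[3]])
}

#' Build the labeled candidate-edge universe
#'
#' Candidate edges are all (regulator, target) pairs with the regulator drawn
#' from the gold standard's regulator universe and targets from the dataset's
#' genes, excluding self-edges. Each edge is labeled 1 if present in the gold
#' standard, 0 otherwise (closed-world assumption).
#'
#' @param ds An [expression_dataset].
#' @param gold A [regulatory_network]; its regulators must all be flagged as
#'   TFs in `ds`.
#' @param include_tf_targets Should genes that are themselves TFs be eligible
#'   targets? Default `TRUE`.
#' @return Object of class `candidate_universe`: data.frame with columns
#'   `regulator`, `target`, `label`.
#' @export
build_candidate_universe <- function(ds, gold, include_tf_targets = TRUE) {
  regs <- gold$regulator_universe
  stray <- setdiff(regs, ds$tf_ids)
  if (length(stray) > 0) {
    grn_abort(sprintf("gold-standard regulator(s) not flagged as TFs in dataset: %s",
                      paste(head(stray, 5), collapse = ", ")), "grn_consistency_error")
  }
  regs <- regs[order(match(regs, ds$tf_ids))]
  targets <- ds$gene_ids
  if (!include_tf_targets) targets <- setdiff(targets, ds$tf_ids)
  uni <- expand.grid(target = targets, regulator = regs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  uni <- uni[uni$regulator != uni$target, c("regulator", "target")]
  rownames(uni) <- NULL
  uni$label <- as.integer(edge_key(uni$regulator, uni$target) %in%
                            edge_key(gold$edges$regulator, gold$edges$target))
  structure(uni, class = c("candidate_universe", "data.frame"))
}
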