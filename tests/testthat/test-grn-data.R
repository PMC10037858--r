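test_that("expression matrix round-trips through delimited text with TF and time metadata", {
  dir <- withr::local_tempdir()
  mat <- file.path(dir, "expr.tsv")
  writeLines(c("gene_id\ts1\ts2\ts3\ts4",
               "g1\t1\t2\t3\t4", "g2\t4\t3\t2\t1", "g3\t1\t1\t2\t2"), mat)
  tfs <- file.path(dir, "tfs.txt")
  writeLines("g1", tfs)
  meta <- file.path(dir, "meta.tsv")
  writeLines(c("sample_id\ttrajectory_id\ttime_minutes",
               "s1\tt1\t0", "s2\tt1\t10", "s3\tt1\t20", "s4\tt2\t0"), meta)

  ds <- read_expression_matrix(mat, tfs, meta)
  expect_length(ds$gene_ids, 3)
  expect_identical(ds$tf_ids, "g1")
  expect_equal(unname(ds$values["g2", ]), c(4, 3, 2, 1))
  expect_identical(ds$sample_meta$sample_id, c("s1", "s2", "s3", "s4"))

  # comma-delimited variant is auto-detected
  mat2 <- file.path(dir, "expr.csv")
  writeLines(c("gene_id,s1,s2,s3", "g1,1,2,3", "g2,3,2,1"), mat2)
  expect_length(read_expression_matrix(mat2, tfs)$gene_ids, 2)

  out <- file.path(dir, "roundtrip.tsv")
  write_expression_matrix(ds, out)
  expect_equal(read_expression_matrix(out, tfs)$values, ds$values)
})

test_that("expression reader rejects malformed input", {
  dir <- withr::local_tempdir()
  mat <- file.path(dir, "expr.tsv")
  tfs <- file.path(dir, "tfs.txt")
  writeLines(c("gene_id\ts1\ts2\ts3", "g1\t1\t2\t3", "g1\t4\t5\t6"), mat)
  writeLines("g1", tfs)
  expect_error(read_expression_matrix(mat, tfs), class = "grn_format_error")

  writeLines(c("gene_id\ts1\ts2\ts3", "g1\t1\t2\t3"), mat)
  writeLines("gX", tfs)
  expect_error(read_expression_matrix(mat, tfs), class = "grn_consistency_error")

  writeLines(c("gene_id\ts1\ts2\ts3", "g1\t1\toops\t3"), mat)
  writeLines("g1", tfs)
  expect_error(read_expression_matrix(mat, tfs), class = "grn_parse_error")
})

test_that("time metadata must be strictly increasing within a trajectory", {
  vals <- matrix(1:6, 2, dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  bad <- data.frame(sample_id = c("a", "b", "c"), trajectory_id = "t1",
                    time_minutes = c(0, 20, 20))
  expect_error(expression_dataset(vals, "g1", bad), class = "grn_consistency_error")
  good <- data.frame(sample_id = c("a", "b", "c"), trajectory_id = "t1",
                     time_minutes = c(0, 10, 20))
  expect_silent(expression_dataset(vals, "g1", good))
})

test_that("edge lists deduplicate, reject self-edges, and tolerate empty files", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "edges.tsv")
  writeLines(c("a\tb", "a\tc", "a\tb"), f)
  net <- read_edge_list(f)
  expect_equal(nrow(net$edges), 2)
  expect_identical(net$regulator_universe, "a")

  writeLines(c("a\ta"), f)
  expect_error(read_edge_list(f), class = "grn_validation_error")
  expect_warning(net2 <- read_edge_list(f, on_self_edge = "skip"), "self-edge")
  expect_equal(nrow(net2$edges), 0)

  writeLines(character(), f)
  empty <- read_edge_list(f)
  expect_equal(nrow(empty$edges), 0)
  expect_length(empty$regulator_universe, 0)

  writeLines("only_one_column", f)
  expect_error(read_edge_list(f), class = "grn_parse_error")
})

test_that("ranked-edge files sort by score with lexicographic tie-break and round-trip", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "ranked.tsv")
  scored <- data.frame(regulator = c("a", "a", "b", "a"),
                       target = c("b", "c", "x", "x"),
                       score = c(0.9, 0.1, 0.5, 0.5))
  write_ranked_edges(scored, f)
  back <- read_ranked_edges(f)
  expect_identical(readLines(f, n = 1), "Gene1\tGene2\tEdgeWeight")
  expect_identical(back$regulator, c("a", "a", "b", "a"))
  expect_identical(back$target, c("b", "x", "x", "c"))  # (a,x) before (b,x) at tied 0.5

  f2 <- file.path(dir, "ranked2.tsv")
  write_ranked_edges(back, f2)
  expect_identical(readLines(f), readLines(f2))

  scored$score[1] <- NaN
  expect_error(write_ranked_edges(scored, f), class = "grn_validation_error")
})

test_that("candidate universe has the closed-form size and gold-standard labels", {
  ds <- make_toy_ds()
  gold <- regulatory_network(data.frame(regulator = c("g1", "g1", "g4"),
                                        target = c("g2", "g3", "g5")))
  uni <- build_candidate_universe(ds, gold)
  # 2 regulators x 5 genes - 2 self-edges
  expect_equal(nrow(uni), 2 * 5 - 2)
  expect_equal(sum(uni$label), 3)
  expect_equal(uni$label[uni$regulator == "g1" & uni$target == "g2"], 1)
  expect_equal(uni$label[uni$regulator == "g1" & uni$target == "g4"], 0)

  # regulators disjoint from targets: no self-edges removed
  uni2 <- make_universe(c("r1", "r2"), paste0("t", 1:5))
  expect_equal(nrow(uni2), 10)

  # excluding TF targets shrinks the target set, not the regulator set
  uni3 <- build_candidate_universe(ds, gold, include_tf_targets = FALSE)
  expect_equal(nrow(uni3), 2 * 3)
  expect_equal(sum(uni3$label), 3)

  bad_gold <- regulatory_network(data.frame(regulator = "g2", target = "g3"))
  expect_error(build_candidate_universe(ds, bad_gold), class = "grn_consistency_error")
})

test_that("candidate universe size matches the closed form for random configurations", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n_genes <- sample(3:12, 1)
      genes <- paste0("g", seq_len(n_genes))
      tfs <- sample(genes, sample(seq_len(n_genes - 1), 1))
      edges <- expand.grid(regulator = tfs, target = genes, stringsAsFactors = FALSE)
      edges <- edges[edges$regulator != edges$target, ]
      gold_edges <- edges[sample(nrow(edges), min(3, nrow(edges))), ]
      ds <- expression_dataset(matrix(runif(n_genes * 4), n_genes,
                                      dimnames = list(genes, paste0("s", 1:4))), tfs)
      gold <- regulatory_network(gold_edges, regulator_universe = tfs)
      uni <- build_candidate_universe(ds, gold)
      expect_equal(nrow(uni), length(tfs) * n_genes - length(intersect(tfs, genes)))
      expect_equal(sum(uni$label), nrow(unique(gold_edges)))
    })
  }
})
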