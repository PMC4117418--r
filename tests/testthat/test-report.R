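fit_small <- local({
  sim <- simulate_cells(default_sim_spec(seed = 12))
  suppressMessages(gatetree(sim$table, components = 10, seed = 12))
})

test_that("strategy export/import round-trips routing exactly", {
  sim_new <- simulate_cells(default_sim_spec(seed = 99))
  path <- withr::local_tempfile(fileext = ".json")
  export_strategy(fit_small, path)
  back <- import_strategy(path)
  expect_identical(apply_tree(back$tree, sim_new$table),
                   apply_tree(fit_small$tree, sim_new$table))
  expect_identical(back$leaf_to_cluster, fit_small$populations)
  ## thresholds survive at full precision
  expect_identical(tree_signature(back$tree)$split,
                   tree_signature(fit_small$tree)$split)
  expect_true(nzchar(back$provenance$config_hash))
})

test_that("a single-leaf tree exports one population with no gates", {
  x <- matrix(rnorm(50), ncol = 1, dimnames = list(NULL, "m"))
  p <- purify(x, rep(1, 50), minbucket = 5)
  path <- withr::local_tempfile(fileext = ".json")
  export_strategy(p, path)
  doc <- jsonlite::read_json(path)
  expect_length(doc$populations, 1L)
  expect_length(doc$populations[[1]]$gates, 0L)
})

test_that("gate sequences mirror the root-to-leaf paths", {
  gates <- gate_sequences(fit_small$tree)
  leaves <- tree_leaves(fit_small$tree)
  expect_setequal(names(gates),
                  vapply(leaves, function(nd) as.character(nd$id),
                         character(1)))
  sig <- tree_signature(fit_small$tree)
  for (g in gates)
    if (nrow(g))
      expect_true(all(g$threshold %in% sig$split))
})

test_that("identical conditions give an all-zero induction matrix", {
  sim <- simulate_cells(default_sim_spec(seed = 13))
  ind <- signaling_induction(sim$table, sim$table, fit_small$tree,
                             signaling_markers = "M3")
  expect_true(all(ind == 0))
})

test_that("a shifted signalling marker is recovered in the right population", {
  sim <- simulate_cells(default_sim_spec(seed = 14))
  leaf <- apply_tree(fit_small$tree, sim$table)
  target <- leaf == names(fit_small$populations)[1]
  stim_vals <- unclass(sim$table)
  stim_vals[target, "M3"] <- stim_vals[target, "M3"] + 0.8
  stim <- expr_table(stim_vals, transformed = TRUE)
  ind <- signaling_induction(sim$table, stim, fit_small$tree, "M3")
  row <- match(paste0("leaf", names(fit_small$populations)[1]), rownames(ind))
  expect_equal(ind[row, "M3"], 0.8, tolerance = 1e-9)
  expect_equal(unname(ind[-row, "M3"]), rep(0, nrow(ind) - 1),
               tolerance = 1e-9)
  ## routing only uses surface markers: perturbing M3 moves no cell
  expect_identical(apply_tree(fit_small$tree, stim), leaf)
})

test_that("populations empty in one condition are NA, not zero", {
  sim <- simulate_cells(default_sim_spec(seed = 15))
  leaf <- apply_tree(fit_small$tree, sim$table)
  drop_leaf <- as.integer(names(fit_small$populations)[1])
  stim <- expr_table(unclass(sim$table)[leaf != drop_leaf, , drop = FALSE],
                     transformed = TRUE)
  ind <- signaling_induction(sim$table, stim, fit_small$tree, "M3")
  expect_true(is.na(ind[paste0("leaf", drop_leaf), "M3"]))
  expect_false(anyNA(ind[rownames(ind) != paste0("leaf", drop_leaf), ]))
})

test_that("fold-change mode reports differences of absolute means", {
  u <- expr_table(matrix(c(0, 0, -2, -2), 2, 2,
                         dimnames = list(NULL, c("m", "sig"))),
                  transformed = TRUE)
  tr <- grow_tree(matrix(c(0, 0), 2, 1, dimnames = list(NULL, "m")),
                  c(1, 1), minbucket = 1)
  s <- expr_table(matrix(c(0, 0, 1, 1), 2, 2,
                         dimnames = list(NULL, c("m", "sig"))),
                  transformed = TRUE)
  expect_equal(as.vector(signaling_induction(u, s, tr, "sig")), 3)
  expect_equal(as.vector(
    signaling_induction(u, s, tr, "sig", mode = "fold-change")), 1 - 2)
})

test_that("run_pipeline writes a reproducible run directory", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  spec <- default_sim_spec(seed = 21)
  suppressMessages(run_pipeline(spec = spec, out_dir = dir1, B = 3, seed = 21))
  suppressMessages(run_pipeline(spec = spec, out_dir = dir2, B = 3, seed = 21))
  for (f in c("strategy.json", "labels.tsv", "bootstrap.json", "report.json"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)),
                     info = f)
  report <- jsonlite::read_json(file.path(dir1, "report.json"))
  expect_gte(report$n_populations, report$n_clusters)
  expect_true(nzchar(report$config_hash))
  labels_df <- read.delim(file.path(dir1, "labels.tsv"))
  expect_equal(nrow(labels_df), 850L)
})

test_that("hclust and npem clusterings yield the same gating structure", {
  sim <- simulate_cells(default_sim_spec(seed = 22))
  f_np <- suppressMessages(gatetree(sim$table, clusterer = "npem",
                                    components = 10, seed = 22))
  f_hc <- gatetree(sim$table, clusterer = "hclust", components = 5,
                   seed = 22)
  expect_setequal(f_np$tree$markers_used, f_hc$tree$markers_used)
  expect_equal(length(f_np$populations), length(f_hc$populations))
  ## the two label sets agree up to renaming
  expect_gte(adjusted_rand(f_np$labels, f_hc$labels), 0.95)
})
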