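test_that("a constant marker gives statistic 0 and p-value 1", {
  out <- association_test(rep(3.2, 12), rep(1:3, 4))
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  expect_error(association_test(rnorm(5), rep(1, 5)), "one class")
})

test_that("permutation moments equal the exact enumeration moments", {
  set.seed(51)
  for (rep in 1:3) {
    n <- 6
    x <- rnorm(n)
    y <- sample(rep(1:2, 3))
    classes <- sort(unique(y))
    perms <- all_perms(n)
    Ts <- t(apply(perms, 1, function(p)
      vapply(classes, function(c) sum(x[p][y == c]), numeric(1))))
    mu_exact <- colMeans(Ts)
    Sigma_exact <- crossprod(sweep(Ts, 2, mu_exact)) / nrow(Ts)
    nj <- as.numeric(table(y))
    mu_formula <- mean(x) * nj
    Vg <- mean((x - mean(x))^2)
    Sigma_formula <- Vg * (n / (n - 1)) *
      (diag(nj, 2) - outer(nj, nj) / n)
    expect_equal(mu_formula, mu_exact, tolerance = 1e-10)
    expect_equal(Sigma_formula, Sigma_exact, tolerance = 1e-10)
  }
})

test_that("chi-squared ranking matches exact permutation enumeration (n <= 8)", {
  set.seed(52)
  for (rep in 1:3) {
    n <- 7
    y <- sample(c(rep(1, 4), rep(2, 3)))
    X <- cbind(a = rnorm(n), b = y + rnorm(n, sd = 0.4), c = rnorm(n, sd = 3))
    approx_p <- vapply(1:3, function(k)
      association_test(X[, k], y)$p_value, numeric(1))
    exact_p <- vapply(1:3, function(k)
      oracle_perm_pvalue(X[, k], y), numeric(1))
    expect_identical(order(approx_p), order(exact_p))
    ## implementation's statistic equals the independent ginv-based one
    for (k in 1:3)
      expect_equal(association_test(X[, k], y)$statistic,
                   oracle_assoc_stat(X[, k], y), tolerance = 1e-10)
  }
})

test_that("the marker carrying the class difference is selected", {
  set.seed(53)
  n <- 60
  y <- rep(1:2, each = n / 2)
  X <- cbind(M1 = rnorm(n), M2 = ifelse(y == 1, 0, 4) + rnorm(n),
             M3 = rnorm(n))
  sel <- select_split_variable(X, y)
  expect_false(sel$stop)
  expect_identical(sel$marker, "M2")
  ## shuffled labels: no marker associates (fixed seed, clearly null)
  sel_null <- select_split_variable(X[, c(1, 3)], sample(y))
  expect_true(sel_null$p_value > 0.05 || sel_null$stop)
})

test_that("marker 3 of the simulated design is never used for gating", {
  sim <- simulate_cells(default_sim_spec(seed = 3))
  fit <- suppressMessages(npem_fit(sim$table, m = 10, seed = 3))
  ref <- refine_labels(sim$table, fit$labels)
  tree <- grow_tree(sim$table, ref$labels)
  expect_false("M3" %in% tree$markers_used)
})

test_that("the best split matches the exhaustive-cut oracle", {
  x <- c(1, 2, 3, 10, 11)
  y <- c("A", "A", "A", "B", "B")
  out <- best_binary_split(x, y, minbucket = 1)
  ## the winning cut is after 3 (the perfect split); the reported split
  ## point is the centre of the empty interval (3, 10)
  expect_equal(out$profile$candidates[out$profile$argmax], 3)
  expect_equal(out$profile$candidates[out$profile$argmax],
               oracle_best_split(x, y)$split)
  expect_equal(out$split, 6.5)
  set.seed(54)
  for (rep in 1:5) {
    n <- sample(10:25, 1)
    xr <- round(rnorm(n), 1)
    yr <- sample(1:3, n, replace = TRUE)
    if (length(unique(yr)) < 2 || length(unique(xr)) < 2) next
    mine <- best_binary_split(xr, yr, minbucket = 2)
    ref <- oracle_best_split(xr, yr, minbucket = 2)
    expect_equal(mine$profile$candidates[mine$profile$argmax], ref$split)
    expect_equal(max(mine$profile$statistics), ref$score, tolerance = 1e-9)
    ## the reported split separates the same two groups as the raw cut
    expect_identical(xr <= mine$split, xr <= ref$split)
  }
})

test_that("separable labels outscore interleaved labels of equal size", {
  x <- 1:20
  sep <- rep(1:2, each = 10)
  inter <- rep(1:2, 10)
  s_sep <- max(best_binary_split(x, sep, minbucket = 2)$profile$statistics)
  s_int <- max(best_binary_split(x, inter, minbucket = 2)$profile$statistics)
  expect_gt(s_sep, s_int)
})

test_that("a bimodal marker's statistic profile peaks between the modes", {
  set.seed(55)
  x <- c(rnorm(50, 0, 0.5), rnorm(50, 6, 0.5))
  y <- rep(1:2, each = 50)
  out <- best_binary_split(x, y, minbucket = 5)
  ## the chosen cut is the largest lower-mode value: it separates the modes
  expect_equal(sum(x <= out$split), 50)
  expect_gt(out$split, 0)
  expect_lt(out$split, 4.5)
  ## exactly reproducible
  out2 <- best_binary_split(x, y, minbucket = 5)
  expect_identical(out$profile$candidates, out2$profile$candidates)
  expect_identical(out$profile$statistics, out2$profile$statistics)
  expect_error(best_binary_split(1:4, c(1, 1, 2, 2), minbucket = 3),
               "unsplittable")
})

test_that("tree growth handles pure, separable and degenerate inputs", {
  ## single cluster: single leaf of purity 1
  x1 <- matrix(rnorm(50), ncol = 1)
  t1 <- grow_tree(x1, rep(1, 50), minbucket = 5)
  expect_equal(t1$height, 0L)
  expect_equal(tree_leaves(t1)[[1]]$purity, 1)
  ## two separated 1-D clusters: height 1, two pure leaves
  x2 <- matrix(c(rnorm(40, 0), rnorm(40, 20)), ncol = 1)
  z2 <- rep(1:2, each = 40)
  t2 <- grow_tree(x2, z2, minbucket = 5)
  expect_equal(t2$height, 1L)
  leaves <- tree_leaves(t2)
  expect_equal(length(leaves), 2L)
  expect_equal(vapply(leaves, `[[`, numeric(1), "purity"), c(1, 1))
  ## leaves partition the training cells
  expect_equal(sum(vapply(leaves, `[[`, numeric(1), "n")), 80)
})

test_that("routing is self-consistent, boundary-inclusive and name-checked", {
  set.seed(56)
  x <- matrix(c(rnorm(40, 0), rnorm(40, 10)), ncol = 1,
              dimnames = list(NULL, "CD4"))
  z <- rep(1:2, each = 40)
  tree <- grow_tree(x, z, minbucket = 5)
  leaf_train <- apply_tree(tree, x)
  ## training partition reproduced exactly
  split_node <- Filter(function(nd) nd$kind == "internal", tree$nodes)[[1]]
  expect_true(all(leaf_train[x[, 1] <= split_node$split] ==
                    split_node$children[1]))
  ## a cell exactly at the split goes left
  at_cut <- matrix(split_node$split, 1, 1, dimnames = list(NULL, "CD4"))
  expect_equal(apply_tree(tree, at_cut), split_node$children[1])
  just_right <- at_cut + 1e-9
  expect_equal(apply_tree(tree, just_right), split_node$children[2])
  bad <- matrix(0, 1, 1, dimnames = list(NULL, "CD8"))
  expect_error(apply_tree(tree, bad), "CD4")
})

test_that("held-out cells are classified with <= 2% leaf-dominant error", {
  sim <- simulate_cells(default_sim_spec(seed = 11))
  fit <- suppressMessages(npem_fit(sim$table, m = 10, seed = 11))
  ref <- refine_labels(sim$table, fit$labels)
  set.seed(11)
  train <- sample(850, 425)
  test <- setdiff(1:850, train)
  xtr <- unclass(sim$table)[train, ]
  tree <- grow_tree(xtr, ref$labels[train])
  dom <- unlist(lapply(tree$nodes, function(nd)
    if (nd$kind == "leaf") nd$dominant else NA))
  pred <- dom[apply_tree(tree, unclass(sim$table)[test, ])]
  expect_lte(mean(pred != ref$labels[test]), 0.02)
})
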