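test_that("the bandwidth rule reproduces the pooled Silverman value", {
  tab <- expr_table(matrix(1:100, ncol = 1), markers = "m",
                    transformed = TRUE)
  h <- bandwidth_rule(tab)
  ## direct evaluation: sd(1:100) = 29.0115, IQR/1.34 = 36.94, 100^-0.2
  expect_equal(h, 0.9 * min(sd(1:100), IQR(1:100) / 1.34) * 100^(-0.2),
               tolerance = 1e-12)
  expect_equal(h, 10.394, tolerance = 1e-3)
})

test_that("the bandwidth is scale-equivariant and N^(-1/5)-dependent", {
  set.seed(7)
  x <- matrix(rnorm(60), 20, 3)
  h <- bandwidth_rule(x)
  expect_equal(bandwidth_rule(x * 3.7), 3.7 * h, tolerance = 1e-12)
  expect_equal(bandwidth_rule(rbind(x, x)), h * 2^(-1 / 5),
               tolerance = 1e-12)
  expect_error(bandwidth_rule(matrix(5, 10, 2)), "degenerate")
})

test_that("kmeans_init matches the exhaustive minimum-WSS 2-partition", {
  set.seed(1)
  x <- matrix(c(rnorm(4, 0, 0.2), rnorm(4, 10, 0.2)), ncol = 1)
  P <- kmeans_init(x, 2, seed = 1)
  z <- max.col(P)
  ## brute force: all 2^8 assignments, minimise within-cluster SS
  best <- NULL; best_wss <- Inf
  for (code in 0:(2^8 - 1)) {
    a <- as.integer(intToBits(code))[1:8]
    if (all(a == 0) || all(a == 1)) next
    wss <- sum((x[a == 0] - mean(x[a == 0]))^2) +
      sum((x[a == 1] - mean(x[a == 1]))^2)
    if (wss < best_wss) { best_wss <- wss; best <- a }
  }
  expect_equal(adjusted_rand(z, best), 1)
  expect_identical(P, kmeans_init(x, 2, seed = 1))   # deterministic
  expect_equal(kmeans_init(x, 1, seed = 1), matrix(1, 8, 1))
  expect_error(kmeans_init(x, 9, seed = 1), "components")
})

test_that("E-step, M-step and KDE-step match brute-force oracles to 1e-12", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:20, 1); r <- sample(1:3, 1); m <- sample(2:4, 1)
    x <- matrix(rnorm(n * r, sd = 2), n, r)
    w <- matrix(runif(n * m), n, m)
    w <- w / rowSums(w)
    lambda <- colMeans(w)
    h <- 0.6
    dens <- npem_kde_step(x, w, h)
    ## KDE-step vs oracle at arbitrary evaluation points
    for (j in seq_len(m)) for (k in seq_len(r)) {
      u <- c(-1.3, 0, 2.2)
      expect_equal(npem_density(dens, u, j, k),
                   vapply(u, oracle_kde, numeric(1), x[, k], w[, j],
                          lambda[j], h),
                   tolerance = 1e-12)
    }
    ## E-step vs oracle
    p <- npem_estep(x, lambda, dens)
    expect_equal(p, oracle_estep(x, lambda, x, w, h), tolerance = 1e-12)
    expect_equal(rowSums(p), rep(1, n), tolerance = 1e-9)
    ## M-step vs oracle
    expect_equal(npem_mstep(p), oracle_mstep(p), tolerance = 1e-12)
  }
})

test_that("E-step normalisation: equal densities give lambda, 3:1 ratio gives 0.923", {
  ## two one-point components in 1-D; evaluation at 0 sees density ratio
  ## dnorm(0) : dnorm(sqrt(2 log 3)) = 3 : 1
  train <- matrix(c(0, sqrt(2 * log(3))), 2, 1)
  w <- cbind(c(1, 0), c(0, 1))
  dens <- npem_kde_step(train, w, h = 1)
  p <- npem_estep(matrix(0, 1, 1), c(0.8, 0.2), dens)
  expect_equal(as.vector(p), c(0.24, 0.02) / 0.26, tolerance = 1e-12)
  p_sym <- npem_estep(matrix(0.5 * sqrt(2 * log(3)), 1, 1), c(0.5, 0.5), dens)
  expect_equal(as.vector(p_sym), c(0.5, 0.5), tolerance = 1e-12)
  ## component with (essentially) zero density at the cell is excluded
  far <- matrix(c(0, 50), 2, 1)
  dens_far <- npem_kde_step(far, w, h = 1)
  p_far <- npem_estep(matrix(0, 1, 1), c(0.5, 0.5), dens_far)
  expect_lt(p_far[1, 2], 1e-100)
})

test_that("single-point KDE is a normal density and uniform weights collapse", {
  dens <- npem_kde_step(matrix(1.7, 1, 1), matrix(1, 1, 1), h = 0.4)
  u <- seq(0, 3, by = 0.5)
  expect_equal(npem_density(dens, u, 1, 1), dnorm(u, 1.7, 0.4),
               tolerance = 1e-12)
  ## two cells at +-1, equal weights, h = 1: f(0) = phi(1)
  dens2 <- npem_kde_step(matrix(c(-1, 1), 2, 1), matrix(0.5, 2, 2), h = 1)
  expect_equal(npem_density(dens2, 0, 1, 1), dnorm(1), tolerance = 1e-12)
  ## uniform weights reduce to the ordinary unweighted KDE
  set.seed(3)
  xk <- rnorm(12)
  densu <- npem_kde_step(matrix(xk, ncol = 1), matrix(1 / 2, 12, 2), h = 0.5)
  plain <- vapply(u, function(ui) mean(dnorm((ui - xk) / 0.5)) / 0.5,
                  numeric(1))
  expect_equal(npem_density(densu, u, 1, 1), plain, tolerance = 1e-12)
})

test_that("component densities integrate to one", {
  set.seed(8)
  x <- matrix(rnorm(30), 15, 2)
  w <- matrix(runif(30), 15, 2); w <- w / rowSums(w)
  dens <- npem_kde_step(x, w, h = 0.7)
  grid <- seq(-8, 8, length.out = 2001)
  for (j in 1:2) for (k in 1:2) {
    f <- npem_density(dens, grid, j, k)
    expect_equal(sum(f) * diff(grid[1:2]), 1, tolerance = 1e-3)
  }
})

test_that("low-proportion components are dropped with a warning", {
  w <- cbind(rep(0.999, 10), rep(0.001, 10))
  expect_warning(dens <- npem_kde_step(matrix(rnorm(10)), w, h = 1),
                 "dropped")
  expect_equal(length(dens$lambda), 1L)
})

test_that("one E/M/KDE sweep is equivariant under permuting the cells", {
  set.seed(13)
  n <- 15
  x <- matrix(rnorm(n * 2), n, 2)
  w <- matrix(runif(n * 3), n, 3); w <- w / rowSums(w)
  perm <- sample(n)
  step <- function(x, w) {
    lambda <- npem_mstep(w)
    dens <- npem_kde_step(x, w, h = 0.5)
    npem_estep(x, lambda, dens)
  }
  p1 <- step(x, w)
  p2 <- step(x[perm, ], w[perm, ])
  expect_equal(p2, p1[perm, ], tolerance = 1e-12)
  expect_equal(npem_mstep(p2), npem_mstep(p1), tolerance = 1e-12)
})

test_that("npem_fit recovers two well-separated components exactly", {
  set.seed(31)
  x <- matrix(c(rnorm(100, 0, 1), rnorm(100, 10, 1)), ncol = 1)
  truth <- rep(1:2, each = 100)
  fit <- npem_fit(x, m = 2, seed = 31)
  expect_equal(adjusted_rand(fit$labels, truth), 1)
  expect_true(fit$converged)
  expect_equal(rowSums(fit$posteriors), rep(1, 200), tolerance = 1e-9)
  expect_equal(fit$lambda, colMeans(fit$posteriors), tolerance = 1e-12)
  ## bitwise determinism
  fit2 <- npem_fit(x, m = 2, seed = 31)
  expect_identical(fit$lambda, fit2$lambda)
  expect_identical(fit$posteriors, fit2$posteriors)
})

test_that("with m = 2 on one component the pooled density is the plain KDE", {
  set.seed(6)
  x <- matrix(rnorm(150), ncol = 1)
  fit <- suppressWarnings(suppressMessages(npem_fit(x, m = 2, seed = 6)))
  h <- fit$bandwidth
  grid <- seq(-4, 4, length.out = 401)
  pooled <- rowSums(vapply(seq_len(fit$m), function(j)
    fit$lambda[j] * npem_density(fit$density, grid, j, 1), numeric(401)))
  plain <- vapply(grid, function(u) mean(dnorm((u - x) / h)) / h, numeric(1))
  l1 <- sum(abs(pooled - plain)) * diff(grid[1:2])
  expect_lt(l1, 0.05)
})

test_that("hard labels reach ARI >= 0.99 at six within-sd separation", {
  aris <- vapply(1:20, function(s) {
    set.seed(s + 400)
    x <- matrix(c(rnorm(100, 0, 1), rnorm(100, 6, 1)), ncol = 1)
    fit <- suppressMessages(npem_fit(x, m = 2, seed = s))
    adjusted_rand(fit$labels, rep(1:2, each = 100))
  }, numeric(1))
  expect_gte(mean(aris), 0.99)
})

test_that("hierarchical clustering separates blobs under every linkage", {
  blobs <- two_blobs(n_per = 25, sep = 12, seed = 5)
  for (linkage in c("ward", "average", "complete")) {
    z <- hclust_labels(blobs$table, 2, linkage)
    expect_equal(adjusted_rand(z, blobs$labels), 1)
  }
  expect_equal(length(unique(hclust_labels(blobs$table, 50))), 50L)
  expect_error(hclust_labels(blobs$table, 51), "clusters")
})
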