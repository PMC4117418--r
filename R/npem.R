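## Nonparametric multivariate finite mixture (kernel-density EM).
##
## Cells x_i (r markers) are modelled as a mixture of m components with
## conditionally independent coordinates whose univariate densities are left
## unspecified and estimated by posterior-weighted kernel density estimates.
## One iteration is M-step (mixing proportions = posterior column means),
## KDE-step (weighted KDE per component and marker, shared bandwidth), then
## E-step (posteriors proportional to lambda_j times the product of marker
## densities). The first iteration starts from a hard k-means partition.

DENSITY_FLOOR <- 1e-300

#' Hard k-means initial posteriors
#'
#' Deterministic given `seed`. The best of `nstart` k-means runs (total
#' within-cluster sum of squares) is used; a single random start routinely
#' lets one centre span two populations while several centres subdivide a
#' heavy one, and the mixture model inherits whatever the initial partition
#' joins.
#'
#' @param table an [expr_table] (or matrix).
#' @param m number of components, `1 <= m <= n`.
#' @param seed integer seed.
#' @param nstart k-means restarts (default 10).
#' @return An n x m 0/1 posterior matrix with exactly one 1 per row.
#' @export
kmeans_init <- function(table, m, seed, nstart = 10L) {
  x <- unclass(as_table(table))
  n <- nrow(x)
  if (m > n) stop("more components (", m, ") than cells (", n, ")")
  if (m < 1L) stop("'m' must be at least 1")
  P <- matrix(0, n, m)
  if (m == 1L) {
    P[, 1L] <- 1
    return(P)
  }
  set.seed(seed)
  km <- stats::kmeans(x, centers = m, nstart = nstart, iter.max = 50L)
  P[cbind(seq_len(n), km$cluster)] <- 1
  P
}

#' Pooled-data bandwidth rule
#'
#' Silverman's rule of thumb on the pooled vector of all `n * r` expression
#' values: `h = 0.9 * min(sd, IQR / 1.34) * N^(-1/5)` with `N = n * r`.
#'
#' @param table an [expr_table] (or matrix).
#' @return The bandwidth `h` (transformed-intensity units).
#' @export
bandwidth_rule <- function(table) {
  pooled <- as.vector(unclass(as_table(table)))
  spread <- min(stats::sd(pooled), stats::IQR(pooled) / 1.34)
  if (!is.finite(spread) || spread <= 0)
    stop("degenerate data for bandwidth")
  0.9 * spread * length(pooled)^(-1 / 5)
}

#' Weighted kernel density step
#'
#' For each component j and marker k, the density estimate is
#' `f_jk(u) = 1 / (n * lambda_j * h) * sum_i p_ij * K((u - x_ik) / h)` with
#' standard-normal kernel K and `lambda_j` the column mean of the
#' posteriors. Components whose mixing proportion falls below `1/n` are
#' dropped with a warning (the estimate divides by `lambda_j`).
#'
#' @param table an [expr_table] (or matrix).
#' @param posteriors n x m posterior matrix (rows summing to 1).
#' @param h positive bandwidth.
#' @return An object of class `npem_density` holding the data, weights,
#'   mixing proportions and bandwidth; evaluate with [npem_density()].
#' @export
npem_kde_step <- function(table, posteriors, h) {
  x <- unclass(as_table(table))
  posteriors <- as.matrix(posteriors)
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop("'h' must be a single positive bandwidth")
  n <- nrow(x)
  if (nrow(posteriors) != n) stop("posterior rows must match cells")
  lambda <- colMeans(posteriors)
  low <- lambda < 1 / n
  if (any(low)) {
    warning(sum(low), " component(s) with mixing proportion below 1/n dropped")
    posteriors <- posteriors[, !low, drop = FALSE]
    posteriors <- posteriors / rowSums(posteriors)
    lambda <- colMeans(posteriors)
  }
  structure(list(x = x, weights = posteriors, lambda = lambda, h = h),
            class = "npem_density")
}

#' Evaluate a component-marker density
#'
#' @param density an `npem_density` from [npem_kde_step()].
#' @param u numeric points at which to evaluate.
#' @param component component index j.
#' @param marker marker index k (column of the training data).
#' @return Density values `f_jk(u)`.
#' @export
npem_density <- function(density, u, component, marker) {
  stopifnot(inherits(density, "npem_density"))
  w <- density$weights[, component]
  xk <- density$x[, marker]
  n <- length(xk)
  h <- density$h
  vapply(u, function(ui)
    sum(w * stats::dnorm((ui - xk) / h)) / (n * density$lambda[component] * h),
    numeric(1))
}

#' Posterior (E) step
#'
#' `p_ij` proportional to `lambda_j * prod_k f_jk(x_ik)`, rows normalised to
#' one. Computed in the log domain with each factor floored at 1e-300 so a
#' single vanishing marker density cannot produce 0/0.
#'
#' @param table an [expr_table] (or matrix).
#' @param lambda mixing proportions (positive, summing to 1).
#' @param density an `npem_density` from [npem_kde_step()].
#' @return The n x m posterior matrix.
#' @export
npem_estep <- function(table, lambda, density) {
  x <- unclass(as_table(table))
  n <- nrow(x); r <- ncol(x); m <- length(lambda)
  logp <- matrix(rep(log(lambda), each = n), n, m)
  for (k in seq_len(r)) {
    for (j in seq_len(m)) {
      f <- npem_density(density, x[, k], j, k)
      logp[, j] <- logp[, j] + log(pmax(f, DENSITY_FLOOR))
    }
  }
  rowmax <- apply(logp, 1L, max)
  bad <- !is.finite(rowmax)
  if (any(bad))
    stop("zero mixture density at cell(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  p <- exp(logp - rowmax)
  p / rowSums(p)
}

#' Mixing-proportion (M) step
#'
#' @param posteriors n x m posterior matrix.
#' @return `lambda_j = mean_i p_ij`.
#' @export
npem_mstep <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  if (nrow(posteriors) == 0L || ncol(posteriors) == 0L)
    stop("empty posterior matrix")
  colMeans(posteriors)
}

#' Fit the nonparametric mixture
#'
#' Iterates M-step, KDE-step and E-step from a hard k-means partition.
#' Components die during iteration when their mixing proportion drops below
#' `1/n` or when they claim no cell under the posterior-maximum (MAP) rule;
#' without the latter, duplicate components that tie on a mode keep diffusing
#' posterior mass and eventually destabilise the boundary between distinct
#' modes. The fit stops when the MAP partition has been unchanged for
#' `stable_iter` consecutive iterations, or when the largest change in any
#' `lambda_j` and any `p_ij` falls below `tol`. Full posterior convergence is
#' deliberately not pursued: kernel-density mixtures exhibit a slow
#' mass-bridging degeneracy in which prolonged iteration merges neighbouring
#' modes through the kernel tails (see the methods vignette).
#'
#' @param table an [expr_table] (or matrix).
#' @param m initial number of components (>= 2).
#' @param max_iter iteration cap (default 500).
#' @param tol tolerance on `max(|d lambda|, |d p|)` (default 1e-8).
#' @param seed integer seed for the k-means initialisation.
#' @param stable_iter MAP-stability window (default 10 iterations).
#' @return An object of class `npem_fit` with elements `lambda`,
#'   `posteriors`, `density` (an `npem_density`), `bandwidth`, `labels`
#'   (MAP hard labels), `m` (surviving components), `n_iter`, `converged`,
#'   `objective_trace` and `dropped` (components removed during iteration).
#' @export
npem_fit <- function(table, m, max_iter = 500L, tol = 1e-8, seed = 1L,
                     stable_iter = 10L) {
  table <- as_table(table)
  x <- unclass(table)
  dimnames(x) <- NULL
  n <- nrow(x); r <- ncol(x)
  if (m < 2L) stop("'m' must be at least 2")
  P <- kmeans_init(x, m, seed)
  h <- bandwidth_rule(x)
  ## kernel cross-matrices: K[[k]][i, i'] = K((x_ik - x_i'k)/h)/h
  K <- lapply(seq_len(r), function(k) {
    d <- outer(x[, k], x[, k], "-")
    stats::dnorm(d / h) / h
  })
  lambda <- colMeans(P)
  zprev <- max.col(P, ties.method = "first")
  n_stable <- 0L
  dropped <- 0L
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    ## component death: MAP-empty or mixing proportion below 1/n
    z <- max.col(P, ties.method = "first")
    alive <- tabulate(z, ncol(P)) > 0L & lambda >= 1 / n
    if (!all(alive)) {
      dropped <- dropped + sum(!alive)
      P <- P[, alive, drop = FALSE]
      P <- P / rowSums(P)
      lambda <- colMeans(P)
      n_stable <- 0L
    }
    mm <- ncol(P)
    ## M + KDE + E, sharing the kernel matrices (equivalent to
    ## npem_mstep / npem_kde_step / npem_estep; asserted in the tests)
    logp <- matrix(rep(log(lambda), each = n), n, mm)
    for (k in seq_len(r)) {
      f <- K[[k]] %*% P
      f <- sweep(f, 2L, n * lambda, "/")
      logp <- logp + log(pmax(f, DENSITY_FLOOR))
    }
    rowmax <- apply(logp, 1L, max)
    if (any(!is.finite(rowmax)))
      stop("zero mixture density at cell(s) ",
           paste(utils::head(which(!is.finite(rowmax)), 5L), collapse = ", "))
    Pn <- exp(logp - rowmax)
    Pn <- Pn / rowSums(Pn)
    dp <- if (ncol(Pn) == ncol(P)) max(abs(Pn - P)) else Inf
    P <- Pn
    lambda_new <- colMeans(P)
    dl <- if (length(lambda_new) == length(lambda))
      max(abs(lambda_new - lambda)) else Inf
    lambda <- lambda_new
    trace <- c(trace, max(dp, dl))
    z <- max.col(P, ties.method = "first")
    n_stable <- if (length(z) == length(zprev) && all(z == zprev))
      n_stable + 1L else 0L
    zprev <- z
    if (max(dp, dl) < tol || n_stable >= stable_iter) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("npem_fit did not converge in ", max_iter, " iterations")
  if (dropped > 0L)
    message(dropped, " component(s) dropped during iteration; ",
            ncol(P), " remain")
  density <- structure(list(x = x, weights = P, lambda = lambda, h = h),
                       class = "npem_density")
  structure(list(lambda = lambda, posteriors = P, density = density,
                 bandwidth = h, labels = max.col(P, ties.method = "first"),
                 m = ncol(P), m_init = m, n_iter = iter,
                 converged = converged, objective_trace = trace,
                 dropped = dropped, seed = seed),
            class = "npem_fit")
}

#' @export
print.npem_fit <- function(x, ...) {
  cat(sprintf(
    "npem_fit: %d -> %d components after %d iteration(s)%s (h = %.4g)\n",
    x$m_init, x$m, x$n_iter,
    if (x$converged) "" else " [not converged]", x$bandwidth))
  cat("mixing proportions:", paste(signif(x$lambda, 3), collapse = " "), "\n")
  invisible(x)
}

#' Hierarchical clustering labels
#'
#' Agglomerative clustering on Euclidean distances, tree cut at `m`
#' clusters. An alternative to the mixture model; the downstream gating
#' machinery is clusterer-agnostic.
#'
#' @param table an [expr_table] (or matrix).
#' @param m number of clusters.
#' @param linkage `"ward"` (Ward D2), `"average"` or `"complete"`.
#' @return Integer hard labels in `1..m`.
#' @export
hclust_labels <- function(table, m, linkage = c("ward", "average", "complete")) {
  x <- unclass(as_table(table))
  linkage <- match.arg(linkage)
  if (m > nrow(x)) stop("more clusters (", m, ") than cells (", nrow(x), ")")
  method <- c(ward = "ward.D2", average = "average", complete = "complete")[linkage]
  hc <- stats::hclust(stats::dist(x), method = method)
  as.integer(stats::cutree(hc, k = m))
}
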