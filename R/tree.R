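## Conditional-inference gating tree.
##
## At every node the marker most associated with the cluster response is
## selected by a permutation-framework linear statistic (influence = raw
## marker values, response = class indicators), with conditional mean and
## covariance given by the Strasser-Weber moments and a quadratic-form
## chi-squared approximation. Growth stops at a node when the smallest
## Bonferroni-adjusted p-value exceeds alpha. The binary split point on the
## selected marker maximises the absolute standardised two-sample statistic
## over all cuts leaving at least `minbucket` cells on each side; cells with
## value <= split go left.

## eigen-based Moore-Penrose pseudo-inverse, returning the rank as attribute
pseudo_inverse <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), 0)
  rank <- sum(keep)
  inv <- if (rank == 0L) matrix(0, nrow(S), ncol(S))
  else e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
  attr(inv, "rank") <- rank
  inv
}

#' Permutation association test between one marker and the cluster labels
#'
#' The linear statistic is `T_j = sum_i w_i x_i 1(y_i = j)`. Its conditional
#' expectation and covariance under random permutation of `x` against the
#' labels are `mu_j = xbar * n_j` and
#' `Cov(T_j, T_k) = Vg * (n_j 1(j=k) - n_j n_k / w.) * w. / (w. - 1)` with
#' `Vg` the weighted population variance of `x`. The test statistic is the
#' quadratic form `(T - mu)' Sigma^+ (T - mu)` (Moore-Penrose
#' pseudo-inverse) with a chi-squared reference on `rank(Sigma)` degrees of
#' freedom. A constant marker gives statistic 0 and p-value 1.
#'
#' @param x numeric marker values.
#' @param labels cluster labels.
#' @param weights 0/1 case weights (default all 1).
#' @return A list with `statistic`, `p_value` and `df`.
#' @export
association_test <- function(x, labels, weights = NULL) {
  if (is.null(weights)) weights <- rep.int(1L, length(x))
  sel <- weights > 0
  x <- x[sel]; y <- labels[sel]
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("no association testable: one class only")
  n <- length(x)
  nj <- as.numeric(table(factor(y, levels = classes)))
  Tj <- vapply(classes, function(c) sum(x[y == c]), numeric(1))
  xbar <- mean(x)
  Vg <- sum((x - xbar)^2) / n
  if (Vg <= 0)
    return(list(statistic = 0, p_value = 1, df = 0L))
  mu <- xbar * nj
  Sigma <- Vg * (n / (n - 1)) * (diag(nj, nrow = length(nj)) - tcrossprod(nj) / n)
  inv <- pseudo_inverse(Sigma)
  d <- Tj - mu
  stat <- drop(t(d) %*% inv %*% d)
  df <- attr(inv, "rank")
  list(statistic = max(stat, 0),
       p_value = if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE),
       df = df)
}

#' Select the splitting marker (or stop)
#'
#' Runs [association_test()] for every marker, Bonferroni-adjusts the
#' p-values over the markers, and either selects the marker with the
#' smallest adjusted p-value or signals a stop when even the smallest
#' exceeds `alpha` (the global independence hypothesis cannot be rejected).
#'
#' @param table an [expr_table] (or matrix).
#' @param labels cluster labels.
#' @param weights 0/1 case weights.
#' @param alpha nominal level (default 0.05).
#' @return A list with `stop` (logical), `marker` (name or `NA`),
#'   `p_adjusted` (named vector over markers) and `p_value` (the selected
#'   marker's adjusted p-value).
#' @export
select_split_variable <- function(table, labels, weights = NULL, alpha = 0.05) {
  x <- unclass(as_table(table))
  r <- ncol(x)
  p <- vapply(seq_len(r), function(k)
    association_test(x[, k], labels, weights)$p_value, numeric(1))
  p_adj <- stats::setNames(pmin(1, p * r), colnames(x))
  if (min(p_adj) > alpha)
    return(list(stop = TRUE, marker = NA_character_, p_adjusted = p_adj,
                p_value = min(p_adj)))
  ## near-exact p-value ties (e.g. two markers separating the same clusters
  ## perfectly) resolve to the first marker in column order
  k <- which(p_adj <= min(p_adj) * (1 + 1e-8))[1]
  list(stop = FALSE, marker = colnames(x)[k], p_adjusted = p_adj,
       p_value = p_adj[[k]])
}

#' Best binary split on a marker
#'
#' Candidates are the observed values `v` leaving at least `minbucket`
#' weighted cells on each side of the partition `x <= v` / `x > v`. For
#' each candidate the two-sample linear statistic over the classes,
#' `T_j = #\{x <= v, y = j\}`, is standardised by its permutation moments
#' as the quadratic form `(T - mu)' Sigma^+ (T - mu)`; scoring the whole
#' class vector (rather than its single largest component) is what gives
#' the split profile a clear maximum in the density valley between
#' populations — a cut through one cluster's fringe inflates one class's
#' component but is penalised on the class it splits. The winning
#' candidate is the one with the largest statistic (ties toward the
#' smallest value); the reported split point is the midpoint between that
#' candidate and the next larger observed value, i.e. the centre of the
#' empty interval the cut passes through, which is where a physical
#' sorting gate belongs and keeps the estimate stable under resampling.
#'
#' @param x numeric values of the selected marker.
#' @param labels cluster labels.
#' @param weights 0/1 case weights.
#' @param minbucket minimum cells on each side of the cut.
#' @return A list with `split` (the chosen cut `c`) and `profile` (class
#'   `split_profile`: `candidates`, `statistics`, `argmax`).
#' @export
best_binary_split <- function(x, labels, weights = NULL, minbucket = 1L) {
  if (is.null(weights)) weights <- rep.int(1L, length(x))
  sel <- weights > 0
  x <- x[sel]; y <- labels[sel]
  n <- length(x)
  classes <- sort(unique(y))
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  ## cumulative class counts just below each distinct-value boundary
  last_of_value <- which(!duplicated(xs, fromLast = TRUE))
  nl <- last_of_value                      # cells with x <= candidate
  cand <- xs[last_of_value]
  ok <- nl >= minbucket & (n - nl) >= minbucket
  if (!any(ok)) stop("node unsplittable: no candidate leaves ", minbucket,
                     " cells on each side")
  nl <- nl[ok]; cand <- cand[ok]
  nj <- as.numeric(table(factor(ys, levels = classes)))
  ## Sigma(v) factorises as Vg(v) * (n/(n-1)) * H with a fixed class part
  ## H = diag(nj) - nj nj'/n, so one pseudo-inverse serves every candidate
  D <- vapply(seq_along(classes), function(j) {
    cum <- cumsum(ys == classes[j])[last_of_value][ok]
    cum - nl * nj[j] / n
  }, numeric(length(cand)))
  D <- matrix(D, nrow = length(cand))
  H <- diag(nj, nrow = length(nj)) - tcrossprod(nj) / n
  Hinv <- pseudo_inverse(H)
  Vg <- (n / (n - 1)) * (nl / n) * (1 - nl / n)
  score <- rowSums((D %*% Hinv) * D) / Vg
  ## near-ties (e.g. several cuts separating the classes perfectly all
  ## attain the chi-squared bound n - 1) resolve to the smallest candidate
  best <- which(score >= max(score) * (1 - 1e-8))[1]
  profile <- structure(list(candidates = cand, statistics = score,
                            argmax = best),
                       class = "split_profile")
  next_value <- min(xs[xs > cand[best]])
  list(split = (cand[best] + next_value) / 2, profile = profile)
}

new_node_env <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- list()
  e$counter <- 0L
  e
}

leaf_record <- function(id, y, classes, p_value = NA_real_) {
  comp <- table(factor(y, levels = classes))
  dom <- classes[which.max(comp)]          # tie -> lower cluster id
  list(id = id, kind = "leaf", marker = NA_character_, split = NA_real_,
       p_value = p_value, children = NULL,
       composition = stats::setNames(as.integer(comp), as.character(classes)),
       dominant = dom, purity = max(comp) / length(y), n = length(y))
}

#' Grow a gating tree
#'
#' Recursively selects a splitting marker ([select_split_variable()]),
#' computes the optimal binary cut ([best_binary_split()]), and recurses on
#' each side. A node becomes a leaf when the global independence test is
#' not rejected, the node is label-pure, it has fewer than `2 * minbucket`
#' cells, its depth reaches `max_height`, or no admissible cut exists.
#' Leaves record the cluster composition, the dominant (modal) cluster and
#' the purity (dominant fraction).
#'
#' @param table an [expr_table] (or matrix).
#' @param labels hard cluster labels (e.g. from [refine_labels()]).
#' @param alpha nominal level for the stopping test (default 0.05).
#' @param minbucket minimum cells in a daughter node; default
#'   `max(20, ceiling(0.01 * n))`.
#' @param max_height maximum number of edges root to leaf (default
#'   unlimited).
#' @return An object of class `gating_tree`.
#' @export
grow_tree <- function(table, labels, alpha = 0.05, minbucket = NULL,
                      max_height = Inf) {
  table <- as_table(table)
  x <- unclass(table)
  n <- nrow(x)
  if (length(labels) != n) stop("one label per cell required")
  if (is.null(minbucket)) minbucket <- max(20L, ceiling(0.01 * n))
  classes <- sort(unique(labels))
  env <- new_node_env()

  build <- function(rows, depth) {
    env$counter <- env$counter + 1L
    id <- env$counter
    y <- labels[rows]
    make_leaf <- function(p = NA_real_) {
      env$nodes[[id]] <- leaf_record(id, y, classes, p)
      id
    }
    if (length(unique(y)) < 2L || length(rows) < 2L * minbucket ||
        depth >= max_height)
      return(make_leaf())
    selection <- select_split_variable(x[rows, , drop = FALSE], y,
                                       alpha = alpha)
    if (selection$stop) return(make_leaf(selection$p_value))
    marker <- selection$marker
    cut <- tryCatch(
      best_binary_split(x[rows, marker], y, minbucket = minbucket),
      error = function(e) NULL)
    if (is.null(cut)) return(make_leaf(selection$p_value))
    left_rows <- rows[x[rows, marker] <= cut$split]
    right_rows <- rows[x[rows, marker] > cut$split]
    env$nodes[[id]] <- list(id = id, kind = "internal", marker = marker,
                            split = cut$split, p_value = selection$p_value,
                            children = c(NA_integer_, NA_integer_),
                            composition = NULL, dominant = NA,
                            purity = NA_real_, n = length(rows))
    left_id <- build(left_rows, depth + 1L)
    right_id <- build(right_rows, depth + 1L)
    env$nodes[[id]]$children <- c(left_id, right_id)
    id
  }
  build(seq_len(n), 0L)

  nodes <- env$nodes
  internal <- Filter(function(nd) nd$kind == "internal", nodes)
  height <- local({
    depth_of <- function(id, d) {
      nd <- nodes[[id]]
      if (nd$kind == "leaf") return(d)
      max(depth_of(nd$children[1], d + 1L), depth_of(nd$children[2], d + 1L))
    }
    depth_of(1L, 0L)
  })
  structure(list(nodes = nodes, root = 1L, height = height,
                 markers_used = unique(vapply(internal, `[[`, character(1),
                                              "marker")),
                 classes = classes, n = n, alpha = alpha,
                 minbucket = minbucket),
            class = "gating_tree")
}

#' Route cells through a gating tree
#'
#' Each cell starts at the root and moves to the left child when its value
#' on the node's marker is `<=` the split point, to the right child
#' otherwise, until it reaches a leaf.
#'
#' @param tree a `gating_tree`.
#' @param table an [expr_table] (or matrix) containing every marker the
#'   tree uses.
#' @return Integer leaf (node) id per cell.
#' @export
apply_tree <- function(tree, table) {
  table <- as_table(table)
  x <- unclass(table)
  missing <- setdiff(tree$markers_used, colnames(x))
  if (length(missing))
    stop("table is missing marker(s) used by the tree: ",
         paste(missing, collapse = ", "))
  leaf <- integer(nrow(x))
  route <- function(id, rows) {
    if (!length(rows)) return(invisible())
    nd <- tree$nodes[[id]]
    if (nd$kind == "leaf") {
      leaf[rows] <<- id
      return(invisible())
    }
    go_left <- x[rows, nd$marker] <= nd$split
    route(nd$children[1], rows[go_left])
    route(nd$children[2], rows[!go_left])
  }
  route(tree$root, seq_len(nrow(x)))
  leaf
}

#' Leaves of a gating tree
#'
#' @param tree a `gating_tree`.
#' @return The list of leaf node records.
#' @export
tree_leaves <- function(tree) {
  Filter(function(nd) nd$kind == "leaf", tree$nodes)
}

## path signatures: each node keyed by the sequence of (marker, side) edges
## from the root; the root's key is "(root)"
tree_signature <- function(tree) {
  out <- list()
  walk <- function(id, path) {
    nd <- tree$nodes[[id]]
    if (nd$kind != "internal") return(invisible())
    key <- if (nzchar(path)) path else "(root)"
    out[[length(out) + 1L]] <<- data.frame(
      path = key, marker = nd$marker, split = nd$split,
      stringsAsFactors = FALSE)
    prefix <- if (nzchar(path)) paste0(path, " / ") else ""
    walk(nd$children[1], paste0(prefix, nd$marker, "<="))
    walk(nd$children[2], paste0(prefix, nd$marker, ">"))
  }
  walk(tree$root, "")
  if (!length(out))
    return(data.frame(path = character(0), marker = character(0),
                      split = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Gate sequence for each leaf
#'
#' @param tree a `gating_tree`.
#' @return A named list (by leaf id) of data frames with columns `marker`,
#'   `threshold` and `side` (`"<="` or `">"`), in root-to-leaf order.
#' @export
gate_sequences <- function(tree) {
  out <- list()
  walk <- function(id, gates) {
    nd <- tree$nodes[[id]]
    if (nd$kind == "leaf") {
      out[[as.character(id)]] <<- gates
      return(invisible())
    }
    g <- function(side) rbind(gates, data.frame(
      marker = nd$marker, threshold = nd$split, side = side,
      stringsAsFactors = FALSE))
    walk(nd$children[1], g("<="))
    walk(nd$children[2], g(">"))
  }
  empty <- data.frame(marker = character(0), threshold = numeric(0),
                      side = character(0), stringsAsFactors = FALSE)
  walk(tree$root, empty)
  out
}

#' @export
print.gating_tree <- function(x, digits = 4, ...) {
  cat(sprintf("gating_tree: height %d, %d leaves, markers: %s\n", x$height,
              length(tree_leaves(x)), paste(x$markers_used, collapse = ", ")))
  rec <- function(id, indent, label) {
    nd <- x$nodes[[id]]
    pad <- strrep("  ", indent)
    if (nd$kind == "leaf") {
      cat(sprintf("%s%s[%d] leaf n=%d dominant=%s purity=%.3f\n", pad, label,
                  nd$id, nd$n, nd$dominant, nd$purity))
    } else {
      cat(sprintf("%s%s[%d] %s <= %s (p=%.3g)\n", pad, label, nd$id,
                  nd$marker, format(nd$split, digits = digits), nd$p_value))
      rec(nd$children[1], indent + 1L, "yes: ")
      rec(nd$children[2], indent + 1L, "no:  ")
    }
  }
  rec(x$root, 0L, "")
  invisible(x)
}
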