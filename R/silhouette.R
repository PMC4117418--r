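## Silhouette-based refinement of cluster assignments.
##
## A cell's silhouette s_i = (b_i - a_i) / max(a_i, b_i) contrasts its mean
## distance to its own cluster (a_i) with its mean distance to the nearest
## other cluster (b_i). Cells with negative silhouettes sit closer to a
## neighbouring cluster than to their own; reassigning them to that
## neighbour, recomputing, and iterating minimises the cost
## |sum of negative silhouettes| and typically reduces the cluster count
## when the clusterer was started with more components than the data
## supports.

## core computation on a precomputed distance matrix
sil_core <- function(D, labels) {
  ids <- sort(unique(labels))
  m <- length(ids)
  if (m < 2L) stop("silhouette undefined for a single cluster")
  n <- nrow(D)
  G <- vapply(ids, function(c) as.numeric(labels == c), numeric(n))
  counts <- colSums(G)
  S <- D %*% G                       # S[i, j] = total distance of i to cluster j
  own <- match(labels, ids)
  idx <- cbind(seq_len(n), own)
  a <- ifelse(counts[own] > 1, S[idx] / (counts[own] - 1), 0)
  Smean <- sweep(S, 2L, counts, "/")
  Smean[idx] <- Inf
  nb_col <- max.col(-Smean, ties.method = "first")  # lowest id on ties
  b <- Smean[cbind(seq_len(n), nb_col)]
  denom <- pmax(a, b)
  s <- ifelse(denom > 0, (b - a) / denom, 0)
  s[counts[own] == 1] <- 0           # singleton convention
  list(s = as.numeric(s), neighbor = ids[nb_col])
}

#' Silhouette values
#'
#' Euclidean-distance silhouettes for a hard clustering. Cells in singleton
#' clusters get `s = 0`; when `a = b = 0` (all coincident points) the
#' convention is also `s = 0`. The returned vector carries a `neighbor`
#' attribute: the cluster attaining `b_i` for each cell (ties broken toward
#' the lower cluster id).
#'
#' @param table an [expr_table] (or matrix).
#' @param labels integer hard labels; at least two non-empty clusters.
#' @return Numeric silhouettes in `[-1, 1]` with attribute `neighbor`.
#' @export
silhouette_values <- function(table, labels) {
  x <- unclass(as_table(table))
  if (length(labels) != nrow(x)) stop("one label per cell required")
  res <- sil_core(as.matrix(stats::dist(x)), labels)
  structure(res$s, neighbor = res$neighbor)
}

#' Refine cluster labels by silhouette reassignment
#'
#' Iteratively reassigns every negative-silhouette cell to its nearest
#' neighbouring cluster (the cluster attaining `b_i`), updates memberships,
#' recomputes silhouettes, and repeats. The cost at each iteration is the
#' absolute sum of the negative silhouette values; the loop stops when no
#' negative silhouettes remain, the first time the cost would fail to
#' decrease (the previous labels are kept), when fewer than two clusters
#' would remain, or at `max_iter`. Emptied clusters are removed, so the
#' refined clustering can have fewer clusters than the input.
#'
#' @param table an [expr_table] (or matrix).
#' @param labels integer hard labels from any clusterer.
#' @param max_iter iteration cap (default 100).
#' @return An object of class `cluster_labels` with elements `labels`
#'   (relabelled `1..m'`), `silhouettes`, `cost_trace`, `n_iter`,
#'   `converged` and `m`.
#' @export
refine_labels <- function(table, labels, max_iter = 100L) {
  x <- unclass(as_table(table))
  if (length(labels) != nrow(x)) stop("one label per cell required")
  D <- as.matrix(stats::dist(x))
  z <- as.integer(labels)
  cost_trace <- numeric(0)
  converged <- FALSE
  sil <- sil_core(D, z)
  for (iter in seq_len(max_iter)) {
    neg <- sil$s < 0
    cost <- abs(sum(sil$s[neg]))
    cost_trace <- c(cost_trace, cost)
    if (!any(neg)) {
      converged <- TRUE
      break
    }
    z_new <- z
    z_new[neg] <- sil$neighbor[neg]
    if (length(unique(z_new)) < 2L) {
      converged <- TRUE
      break
    }
    sil_new <- sil_core(D, z_new)
    cost_new <- abs(sum(sil_new$s[sil_new$s < 0]))
    if (cost_new >= cost) {        # would not decrease: keep current labels
      converged <- TRUE
      break
    }
    z <- z_new
    sil <- sil_new
  }
  ids <- sort(unique(z))
  structure(list(labels = match(z, ids), silhouettes = sil$s,
                 cost_trace = cost_trace, n_iter = length(cost_trace),
                 converged = converged, m = length(ids)),
            class = "cluster_labels")
}

#' @export
print.cluster_labels <- function(x, ...) {
  cat(sprintf(
    "cluster_labels: %d cluster(s), %d iteration(s), final cost %.4g%s\n",
    x$m, x$n_iter, x$cost_trace[length(x$cost_trace)],
    if (x$converged) "" else " [not converged]"))
  print(table(cluster = x$labels))
  invisible(x)
}
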