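## Tree purification: choose the pruning height L, then iterate
## filter-and-retrain until every leaf is pure.

#' Determine the pruning height L
#'
#' The smallest tree height at which every cluster label is the dominant
#' label of at least one leaf. If no height up to the unrestricted tree's
#' height achieves this, the full height is returned with a warning. A
#' single-cluster input needs no gate and yields `L = 0`.
#'
#' @inheritParams grow_tree
#' @return Integer height `L`.
#' @export
determine_L <- function(table, labels, alpha = 0.05, minbucket = NULL) {
  classes <- sort(unique(labels))
  if (length(classes) < 2L) return(0L)
  full <- grow_tree(table, labels, alpha = alpha, minbucket = minbucket)
  if (full$height == 0L)
    stop("clusters not separable by any gate: the unrestricted tree is a ",
         "single leaf but there are ", length(classes), " clusters")
  covers <- function(tree) {
    dom <- vapply(tree_leaves(tree), `[[`, FUN.VALUE = labels[1], "dominant")
    all(classes %in% dom)
  }
  for (L in seq_len(full$height)) {
    tr <- if (L == full$height) full
      else grow_tree(table, labels, alpha = alpha, minbucket = minbucket,
                     max_height = L)
    if (covers(tr)) return(L)
  }
  warning("no height makes every cluster dominant in a leaf; using the ",
          "unrestricted height ", full$height)
  full$height
}

#' Keep only each leaf's dominant-cluster cells
#'
#' Routes the cells through the tree and, per leaf, keeps the cells whose
#' cluster label equals the leaf's dominant label (dominance ties are broken
#' toward the lower cluster id at training time).
#'
#' @param tree a `gating_tree` trained on (`table`, `labels`).
#' @param table the training [expr_table].
#' @param labels the training cluster labels.
#' @return The retained event ids (see [event_ids()]).
#' @export
dominant_filter <- function(tree, table, labels) {
  table <- as_table(table)
  leaf <- apply_tree(tree, table)
  dom <- unlist(lapply(tree$nodes, function(nd)
    if (nd$kind == "leaf") nd$dominant else NA))
  keep <- labels == dom[leaf]
  event_ids(table)[keep]
}

#' Purify a gating tree by filter-and-retrain
#'
#' Determines the pruning height `L`, then loops: grow a height-`L` tree on
#' the retained cells, and if any leaf's purity is below the threshold,
#' remove all non-dominant cells ([dominant_filter()]) and retrain. The
#' loop ends when every leaf is pure (purity `>=` `purity_threshold`,
#' default exactly 1) or a round removes no cells. Removed cells are kept
#' in an extra bin, tagged with the round in which they were removed.
#'
#' @inheritParams grow_tree
#' @param purity_threshold leaf purity required to stop (default 1).
#' @param max_rounds guard on the number of filter-retrain rounds.
#' @return An object of class `gating_purification` with elements
#'   `final_tree`, `retained` (event ids), `extra_bin` (data frame
#'   `event_id`, `round`), `L`, `n_rounds`, `leaf_to_cluster` (named by
#'   leaf id), `leaf_assignment` (leaf id per retained cell) and the
#'   parameters used.
#' @export
purify <- function(table, labels, alpha = 0.05, minbucket = NULL,
                   purity_threshold = 1, max_rounds = 50L) {
  table <- as_table(table)
  n <- nrow(table)
  if (length(labels) != n) stop("one label per cell required")
  if (is.null(minbucket)) minbucket <- max(20L, ceiling(0.01 * n))
  classes <- sort(unique(labels))
  L <- determine_L(table, labels, alpha = alpha, minbucket = minbucket)

  keep_rows <- seq_len(n)
  extra <- data.frame(event_id = integer(0), round = integer(0))
  round <- 0L
  repeat {
    round <- round + 1L
    if (round > max_rounds)
      stop("purification did not converge in ", max_rounds, " rounds")
    sub <- restitch(unclass(table)[keep_rows, , drop = FALSE], table,
                    event_ids(table)[keep_rows])
    sub_labels <- labels[keep_rows]
    tree <- if (L == 0L) grow_tree(sub, sub_labels, alpha = alpha,
                                   minbucket = minbucket, max_height = 0L)
      else grow_tree(sub, sub_labels, alpha = alpha, minbucket = minbucket,
                     max_height = L)
    purities <- vapply(tree_leaves(tree), `[[`, numeric(1), "purity")
    if (all(purities >= purity_threshold)) break
    kept_ids <- dominant_filter(tree, sub, sub_labels)
    removed_ids <- setdiff(event_ids(sub), kept_ids)
    if (!length(removed_ids)) break
    extra <- rbind(extra, data.frame(event_id = removed_ids, round = round))
    keep_rows <- keep_rows[event_ids(sub) %in% kept_ids]
    lost <- setdiff(classes, unique(labels[keep_rows]))
    if (length(lost))
      stop("purification removed every cell of cluster(s) ",
           paste(lost, collapse = ", "),
           "; the clustering is not gateable at purity ", purity_threshold)
  }
  sub <- restitch(unclass(table)[keep_rows, , drop = FALSE], table,
                  event_ids(table)[keep_rows])
  leaves <- tree_leaves(tree)
  leaf_to_cluster <- stats::setNames(
    vapply(leaves, `[[`, FUN.VALUE = labels[1], "dominant"),
    vapply(leaves, function(nd) as.character(nd$id), character(1)))
  structure(list(final_tree = tree, retained = event_ids(sub),
                 extra_bin = extra, L = L, n_rounds = round,
                 leaf_to_cluster = leaf_to_cluster,
                 leaf_assignment = apply_tree(tree, sub),
                 alpha = alpha, minbucket = minbucket,
                 purity_threshold = purity_threshold),
            class = "gating_purification")
}

#' @export
print.gating_purification <- function(x, ...) {
  cat(sprintf(
    "gating_purification: L = %d, %d round(s), %d retained, %d in extra bin\n",
    x$L, x$n_rounds, length(x$retained), nrow(x$extra_bin)))
  cat(sprintf("final tree: %d leaves over markers %s\n",
              length(tree_leaves(x$final_tree)),
              paste(x$final_tree$markers_used, collapse = ", ")))
  invisible(x)
}
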