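## Strata-bootstrap stability of the gating tree: split-point ranges and
## hierarchy agreement across resampled datasets.

#' Strata bootstrap resamples
#'
#' Each resample draws cells with replacement *within each cluster
#' stratum*, preserving the per-cluster counts and the total sample size.
#' Resamples are generated sequentially under one seed, so the first `B'`
#' resamples of a `B >= B'` run are identical to a `B'` run with the same
#' seed.
#'
#' @param table an [expr_table] (or matrix).
#' @param labels cluster labels defining the strata.
#' @param B number of resamples.
#' @param seed integer seed.
#' @return A list of `B` resamples, each a list with `table`, `labels` and
#'   `idx` (the sampled row indices).
#' @export
strata_bootstrap <- function(table, labels, B, seed = 1L) {
  table <- as_table(table)
  if (B < 1L) stop("'B' must be at least 1")
  strata <- split(seq_len(nrow(table)), labels)
  if (any(!lengths(strata)))
    stop("empty stratum in 'labels'")
  set.seed(seed)
  lapply(seq_len(B), function(b) {
    idx <- unlist(lapply(strata, function(rows)
      rows[sample.int(length(rows), length(rows), replace = TRUE)]),
      use.names = FALSE)
    vals <- unclass(table)[idx, , drop = FALSE]
    list(table = expr_table(vals, markers = colnames(table),
                            event_ids = seq_along(idx) - 1L,
                            transformed = is_transformed(table)),
         labels = labels[idx], idx = idx)
  })
}

#' Bootstrap stability of the purified gating tree
#'
#' Reruns grow-and-purify on `B` strata-bootstrap resamples of the training
#' data, records every internal node's split point keyed by its path
#' signature (the sequence of marker/side edges from the root), and
#' summarises per-node empirical (min, max) split ranges plus the fraction
#' of replicate trees whose marker hierarchy is identical to the original
#' tree's. Ranges are reported as empirical min/max, not normal intervals:
#' split-point distributions are typically multi-modal. Replicates whose
#' hierarchy diverges contribute split samples only for the nodes they
#' share with the original tree.
#'
#' @inheritParams strata_bootstrap
#' @param alpha,minbucket,purity_threshold passed to [purify()].
#' @return An object of class `bootstrap_summary`: `B`, `per_node_ranges`
#'   (data frame `path`, `marker`, `split` (original), `min`, `max`,
#'   `n_samples`), `split_point_samples` (list keyed by path),
#'   `hierarchy_identical_fraction`, `n_failed`, and the original tree.
#' @export
bootstrap_stability <- function(table, labels, B = 200L, seed = 1L,
                                alpha = 0.05, minbucket = NULL,
                                purity_threshold = 1) {
  table <- as_table(table)
  original <- purify(table, labels, alpha = alpha, minbucket = minbucket,
                     purity_threshold = purity_threshold)
  orig_sig <- tree_signature(original$final_tree)
  orig_keys <- paste(orig_sig$path, orig_sig$marker)
  samples <- stats::setNames(vector("list", nrow(orig_sig)), orig_sig$path)
  identical_count <- 0L
  n_failed <- 0L
  resamples <- strata_bootstrap(table, labels, B, seed)
  for (rs in resamples) {
    fit <- tryCatch(
      suppressWarnings(purify(rs$table, rs$labels, alpha = alpha,
                              minbucket = minbucket,
                              purity_threshold = purity_threshold)),
      error = function(e) NULL)
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    sig <- tree_signature(fit$final_tree)
    keys <- paste(sig$path, sig$marker)
    if (length(keys) == length(orig_keys) && setequal(keys, orig_keys))
      identical_count <- identical_count + 1L
    hit <- match(keys, orig_keys)
    for (i in which(!is.na(hit)))
      samples[[hit[i]]] <- c(samples[[hit[i]]], sig$split[i])
  }
  ranges <- orig_sig
  ranges$min <- vapply(samples, function(s)
    if (length(s)) min(s) else NA_real_, numeric(1))
  ranges$max <- vapply(samples, function(s)
    if (length(s)) max(s) else NA_real_, numeric(1))
  ranges$n_samples <- lengths(samples)
  structure(list(B = B, per_node_ranges = ranges,
                 split_point_samples = samples,
                 hierarchy_identical_fraction = identical_count / B,
                 n_failed = n_failed, original = original),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf(
    "bootstrap_summary: B = %d, identical hierarchy in %.1f%% (%d failed)\n",
    x$B, 100 * x$hierarchy_identical_fraction, x$n_failed))
  print(x$per_node_ranges, row.names = FALSE)
  invisible(x)
}

#' Check a tree's split points against bootstrap ranges
#'
#' For every internal node of `tree`, reports whether its split point lies
#' within the bootstrap (min, max) range of the matching node (by path
#' signature and marker) in `summary`. Nodes of `tree` with no matching
#' node are flagged as divergent rather than raising an error.
#'
#' @param tree a `gating_tree`.
#' @param summary a `bootstrap_summary`.
#' @return A data frame with one row per internal node of `tree`: `path`,
#'   `marker`, `split`, `min`, `max`, `matched` and `within`.
#' @export
check_within_ranges <- function(tree, summary) {
  sig <- tree_signature(tree)
  ranges <- summary$per_node_ranges
  keys <- paste(ranges$path, ranges$marker)
  hit <- match(paste(sig$path, sig$marker), keys)
  sig$min <- ranges$min[hit]
  sig$max <- ranges$max[hit]
  sig$matched <- !is.na(hit) & !is.na(sig$min)
  sig$within <- sig$matched & sig$split >= sig$min & sig$split <= sig$max
  sig
}
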