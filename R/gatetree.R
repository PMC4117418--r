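#' Fit a gating strategy to single-cell data
#'
#' The main fitting function. The pipeline is: (1) identify candidate cell
#' subpopulations with the nonparametric kernel-density EM mixture
#' ([npem_fit()]) or hierarchical clustering ([hclust_labels()]); (2)
#' refine the hard assignments by silhouette reassignment
#' ([refine_labels()]); (3) grow a conditional-inference gating tree over
#' the markers, prune it to the smallest height at which every cluster
#' dominates a leaf, and purify it by the filter-retrain loop
#' ([purify()]). The result is a sortable gating strategy: an ordered
#' sequence of (marker, threshold, side) gates per target population.
#'
#' Start the clusterer with more components than you expect
#' (`components = 10` by default); posterior-maximum assignment and the
#' silhouette refinement reduce the count to the number the data support.
#'
#' @param x an [expr_table], matrix or data frame (cells x markers),
#'   already arcsinh-transformed (see [arcsinh_transform()]).
#' @param markers optional marker names to cluster and gate on (default:
#'   all columns).
#' @param clusterer `"npem"` (nonparametric EM mixture) or `"hclust"`.
#' @param components number of components to start the clusterer with.
#' @param labels optional precomputed hard cluster labels; skips the
#'   clustering step.
#' @param refine logical; run the silhouette refinement (default `TRUE`).
#' @param alpha nominal level of the node-wise independence tests.
#' @param minbucket minimum daughter-node size; default
#'   `max(20, ceiling(0.01 * n))`.
#' @param purity_threshold leaf purity at which purification stops
#'   (default exactly 1).
#' @param linkage linkage for `clusterer = "hclust"`.
#' @param seed integer seed (k-means initialisation).
#' @param ... passed to [npem_fit()].
#'
#' @return An object of class `gatetree` with components `tree` (the final
#'   `gating_tree`), `purification`, `labels` (refined cluster label per
#'   training cell), `cluster_fit`, `refinement`, `populations` (leaf ->
#'   cluster map), and the call/parameters. Methods: `print`, `summary`,
#'   `predict`, `plot`.
#'
#' @examples
#' sim <- simulate_cells(default_sim_spec(seed = 7))
#' fit <- gatetree(sim$table, components = 10, seed = 7)
#' fit
#' table(predict(fit, sim$table, type = "population"))
#' @export
gatetree <- function(x, markers = NULL,
                     clusterer = c("npem", "hclust"),
                     components = 10L, labels = NULL, refine = TRUE,
                     alpha = 0.05, minbucket = NULL, purity_threshold = 1,
                     linkage = "ward", seed = 1L, ...) {
  clusterer <- match.arg(clusterer)
  table <- as_table(x)
  if (!is.null(markers)) table <- select_markers(table, markers)
  cluster_fit <- NULL
  if (is.null(labels)) {
    if (clusterer == "npem") {
      cluster_fit <- npem_fit(table, m = components, seed = seed, ...)
      labels <- cluster_fit$labels
    } else {
      labels <- hclust_labels(table, m = components, linkage = linkage)
    }
  }
  initial_labels <- labels
  refinement <- NULL
  if (refine && length(unique(labels)) > 1L) {
    refinement <- refine_labels(table, labels)
    labels <- refinement$labels
  }
  purification <- purify(table, labels, alpha = alpha, minbucket = minbucket,
                         purity_threshold = purity_threshold)
  structure(list(tree = purification$final_tree,
                 purification = purification,
                 populations = purification$leaf_to_cluster,
                 labels = labels, initial_labels = initial_labels,
                 cluster_fit = cluster_fit, refinement = refinement,
                 clusterer = clusterer, components = components,
                 markers = colnames(table), n = nrow(table),
                 alpha = alpha, seed = seed, call = match.call()),
            class = "gatetree")
}

#' @export
print.gatetree <- function(x, ...) {
  cat("Gating strategy\n")
  cat(sprintf("  %d cells, %d cluster(s) after %s%s\n", x$n,
              length(unique(x$labels)), x$clusterer,
              if (is.null(x$refinement)) "" else " + silhouette refinement"))
  cat(sprintf("  pruning height L = %d, %d purification round(s), %d cell(s) binned\n",
              x$purification$L, x$purification$n_rounds,
              nrow(x$purification$extra_bin)))
  print(x$tree)
  invisible(x)
}

#' @export
summary.gatetree <- function(object, ...) {
  gates <- gate_sequences(object$tree)
  leaves <- tree_leaves(object$tree)
  pops <- do.call(rbind, lapply(leaves, function(nd) {
    g <- gates[[as.character(nd$id)]]
    data.frame(leaf = nd$id,
               cluster = object$populations[[as.character(nd$id)]],
               n = nd$n, purity = nd$purity,
               gates = if (nrow(g))
                 paste(sprintf("%s %s %.4g", g$marker, g$side, g$threshold),
                       collapse = ", ")
                 else "(none)",
               stringsAsFactors = FALSE)
  }))
  structure(list(populations = pops, markers_used = object$tree$markers_used,
                 L = object$purification$L,
                 n_rounds = object$purification$n_rounds,
                 n_binned = nrow(object$purification$extra_bin),
                 n = object$n),
            class = "summary.gatetree")
}

#' @export
print.summary.gatetree <- function(x, ...) {
  cat(sprintf("Gating strategy: %d populations on markers %s (L = %d)\n",
              nrow(x$populations), paste(x$markers_used, collapse = ", "),
              x$L))
  cat(sprintf("%d of %d cells removed to the extra bin over %d round(s)\n\n",
              x$n_binned, x$n, x$n_rounds))
  print(x$populations, row.names = FALSE)
  invisible(x)
}

#' Predict populations for new cells
#'
#' @param object a `gatetree` fit.
#' @param newdata an [expr_table] (or matrix) containing the tree's
#'   markers.
#' @param type `"leaf"` for terminal node ids, `"population"` for the
#'   cluster mapped to each leaf.
#' @param ... unused.
#' @return Integer leaf ids or cluster labels, one per cell.
#' @export
predict.gatetree <- function(object, newdata, type = c("leaf", "population"),
                             ...) {
  type <- match.arg(type)
  leaf <- apply_tree(object$tree, as_table(newdata))
  if (type == "leaf") return(leaf)
  object$populations[as.character(leaf)]
}

#' Plot a gating tree
#'
#' Simple base-graphics rendering: internal nodes show the gating marker
#' and threshold, leaves show the mapped cluster, size and purity.
#'
#' @param x a `gatetree` fit or a `gating_tree`.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.gatetree <- function(x, ...) {
  tree <- if (inherits(x, "gatetree")) x$tree else x
  leaves <- vapply(tree_leaves(tree), `[[`, numeric(1), "id")
  pos <- new.env(parent = emptyenv())
  counter <- 0
  layout <- function(id, depth) {
    nd <- tree$nodes[[id]]
    if (nd$kind == "leaf") {
      counter <<- counter + 1
      assign(as.character(id), c(counter, depth), envir = pos)
      return(counter)
    }
    xl <- layout(nd$children[1], depth + 1)
    xr <- layout(nd$children[2], depth + 1)
    xc <- (xl + xr) / 2
    assign(as.character(id), c(xc, depth), envir = pos)
    xc
  }
  layout(tree$root, 0)
  coords <- function(id) get(as.character(id), envir = pos)
  graphics::plot.default(NA, xlim = c(0.5, length(leaves) + 0.5),
                         ylim = c(-tree$height - 0.5, 0.5), axes = FALSE,
                         xlab = "", ylab = "", ...)
  draw <- function(id) {
    nd <- tree$nodes[[id]]
    p <- coords(id)
    if (nd$kind == "leaf") {
      graphics::text(p[1], -p[2],
                     sprintf("cluster %s\nn=%d (%.0f%%)", nd$dominant, nd$n,
                             100 * nd$purity), cex = 0.8)
      return(invisible())
    }
    for (side in 1:2) {
      q <- coords(nd$children[side])
      graphics::segments(p[1], -p[2] - 0.12, q[1], -q[2] + 0.2, col = "grey40")
    }
    graphics::text(p[1], -p[2],
                   sprintf("%s <= %.3g", nd$marker, nd$split), font = 2,
                   cex = 0.9)
    draw(nd$children[1]); draw(nd$children[2])
  }
  draw(tree$root)
  invisible(x)
}

#' @export
plot.gating_tree <- plot.gatetree

#' Run the full pipeline and write a run directory
#'
#' Executes transform/cluster/refine/purify/bootstrap/export end to end and
#' writes: `strategy.json` (the gating strategy), `labels.tsv` (per-cell
#' event id, cluster, leaf and retained flag), `bootstrap.json` (split
#' ranges and hierarchy stability, when `B > 0`), `report.json` (config,
#' seeds, config hash and headline numbers) and `run.log`. Outputs are
#' reproducible from the config and seed; only the log carries timestamps.
#'
#' @param input path to an FCS or delimited file, or an [expr_table];
#'   ignored when `spec` is given.
#' @param spec a [sim_spec] to simulate instead of reading a file.
#' @param out_dir output directory (created if needed).
#' @param cofactor arcsinh cofactor applied when the input is raw; `NULL`
#'   leaves the values untouched.
#' @param B bootstrap resamples (0 to skip).
#' @param format,markers,clusterer,components,alpha,minbucket,purity_threshold,linkage,seed
#'   as in [gatetree()] / [read_events()].
#' @return The `gatetree` fit, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(input = NULL, spec = NULL, out_dir,
                         format = NULL, markers = NULL,
                         clusterer = "npem", components = 10L,
                         cofactor = NULL, alpha = 0.05, minbucket = NULL,
                         purity_threshold = 1, linkage = "ward",
                         B = 0L, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                               sprintf(...), "\n", sep = "", file = log_path,
                               append = TRUE)
  cat("", file = log_path)
  true_labels <- NULL
  if (!is.null(spec)) {
    sim <- simulate_cells(spec)
    table <- sim$table
    true_labels <- sim$labels
    logline("simulated %d cells x %d markers (spec seed %d)", nrow(table),
            ncol(table), spec$seed)
  } else if (is.character(input)) {
    table <- read_events(input, format = format)
    logline("read %d cells x %d markers from %s", nrow(table), ncol(table),
            input)
  } else {
    table <- as_table(input)
  }
  if (!is.null(cofactor) && !is_transformed(table)) {
    table <- arcsinh_transform(table, cofactor)
    logline("arcsinh transform, cofactor %g", cofactor)
  }
  fit <- gatetree(table, markers = markers, clusterer = clusterer,
                  components = components, alpha = alpha,
                  minbucket = minbucket,
                  purity_threshold = purity_threshold, linkage = linkage,
                  seed = seed)
  logline("fit: %d clusters, L = %d, %d populations, markers %s",
          length(unique(fit$labels)), fit$purification$L,
          length(fit$populations),
          paste(fit$tree$markers_used, collapse = ","))
  export_strategy(fit, file.path(out_dir, "strategy.json"), seed = seed)

  leaf <- apply_tree(fit$tree, table)
  labels_df <- data.frame(
    event_id = event_ids(table), cluster = fit$labels, leaf = leaf,
    retained = event_ids(table) %in% fit$purification$retained)
  utils::write.table(labels_df, file.path(out_dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  boot <- NULL
  if (B > 0L) {
    boot <- bootstrap_stability(table, fit$labels, B = B, seed = seed,
                                alpha = alpha, minbucket = minbucket,
                                purity_threshold = purity_threshold)
    jsonlite::write_json(
      list(B = boot$B,
           hierarchy_identical_fraction = boot$hierarchy_identical_fraction,
           n_failed = boot$n_failed,
           per_node_ranges = boot$per_node_ranges),
      file.path(out_dir, "bootstrap.json"), auto_unbox = TRUE, digits = I(17),
      pretty = TRUE)
    logline("bootstrap: B = %d, identical hierarchy fraction %.3f", B,
            boot$hierarchy_identical_fraction)
  }
  config <- list(clusterer = clusterer, components = components,
                 cofactor = cofactor, alpha = alpha,
                 minbucket = fit$purification$minbucket,
                 purity_threshold = purity_threshold, linkage = linkage,
                 B = B, seed = seed, markers = fit$markers)
  report <- list(
    config = config,
    config_hash = fnv1a(paste(deparse(config), collapse = "")),
    seed = seed,
    n_cells = fit$n,
    n_clusters = length(unique(fit$labels)),
    n_populations = length(fit$populations),
    markers_used = fit$tree$markers_used,
    L = fit$purification$L,
    n_rounds = fit$purification$n_rounds,
    n_extra_bin = nrow(fit$purification$extra_bin),
    hierarchy_identical_fraction =
      if (is.null(boot)) NULL else boot$hierarchy_identical_fraction)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  logline("done")
  invisible(fit)
}
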