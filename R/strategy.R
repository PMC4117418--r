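## Gating-strategy serialisation and cross-condition signalling induction.

## tiny FNV-style rolling hash for config fingerprints (hex string);
## state kept below 2^31 so bitwXor stays in integer range
fnv1a <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 216613626
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Export a gating strategy
#'
#' Writes a self-contained JSON document describing the purified gating
#' tree: every node (markers by name, thresholds at full precision), and
#' per target population the ordered gate list (marker, threshold, side)
#' along its unique root-to-leaf path. Re-importing with
#' [import_strategy()] and re-applying reproduces leaf assignments exactly.
#'
#' @param result a `gating_purification` (or a `gatetree` fit).
#' @param path output file path.
#' @param seed optional seed(s) to record in the provenance block.
#' @return `path`, invisibly.
#' @export
export_strategy <- function(result, path, seed = NULL) {
  if (inherits(result, "gatetree")) {
    if (is.null(seed)) seed <- result$seed
    result <- result$purification
  }
  stopifnot(inherits(result, "gating_purification"))
  tree <- result$final_tree
  gates <- gate_sequences(tree)
  populations <- lapply(tree_leaves(tree), function(nd) {
    g <- gates[[as.character(nd$id)]]
    list(leaf = nd$id,
         cluster = result$leaf_to_cluster[[as.character(nd$id)]],
         n = nd$n, purity = nd$purity,
         gates = if (nrow(g)) g else list())
  })
  nodes <- lapply(tree$nodes, function(nd) {
    out <- list(id = nd$id, kind = nd$kind, n = nd$n)
    if (nd$kind == "internal") {
      out$marker <- nd$marker
      out$split <- nd$split
      out$children <- I(nd$children)
    } else {
      out$dominant <- nd$dominant
      out$purity <- nd$purity
      out$composition <- as.list(nd$composition)
    }
    out
  })
  config <- list(alpha = result$alpha, minbucket = result$minbucket,
                 purity_threshold = result$purity_threshold, L = result$L)
  doc <- list(
    format = "gating-strategy",
    version = as.character(utils::packageVersion("gatetree")),
    provenance = list(
      seed = seed, config = config,
      config_hash = fnv1a(paste(deparse(config), collapse = ""))),
    tree = list(nodes = nodes, root = tree$root, height = tree$height,
                markers_used = I(tree$markers_used),
                classes = I(tree$classes), n = tree$n,
                alpha = tree$alpha, minbucket = tree$minbucket),
    populations = populations)
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE, null = "null")
    TRUE
  }, error = function(e) stop("cannot write strategy to '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' Import a gating strategy
#'
#' @param path a file written by [export_strategy()].
#' @return A list with `tree` (a `gating_tree` usable with [apply_tree()]),
#'   `leaf_to_cluster` and `provenance`.
#' @export
import_strategy <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "gating-strategy"))
    stop("'", path, "' is not a gating-strategy document")
  nodes <- vector("list", length(doc$tree$nodes))
  for (nd in doc$tree$nodes) {
    rec <- list(id = as.integer(nd$id), kind = nd$kind, n = as.integer(nd$n),
                marker = if (is.null(nd$marker)) NA_character_ else nd$marker,
                split = if (is.null(nd$split)) NA_real_ else as.numeric(nd$split),
                children = if (is.null(nd$children)) NULL
                  else as.integer(unlist(nd$children)),
                dominant = if (is.null(nd$dominant)) NA else nd$dominant,
                purity = if (is.null(nd$purity)) NA_real_ else as.numeric(nd$purity),
                composition = if (is.null(nd$composition)) NULL
                  else unlist(nd$composition))
    nodes[[rec$id]] <- rec
  }
  internal <- Filter(function(nd) nd$kind == "internal", nodes)
  tree <- structure(list(
    nodes = nodes, root = as.integer(doc$tree$root),
    height = as.integer(doc$tree$height),
    markers_used = as.character(unlist(doc$tree$markers_used)),
    classes = unlist(doc$tree$classes), n = as.integer(doc$tree$n),
    alpha = as.numeric(doc$tree$alpha),
    minbucket = as.integer(doc$tree$minbucket)),
    class = "gating_tree")
  leaf_to_cluster <- stats::setNames(
    unlist(lapply(doc$populations, `[[`, "cluster")),
    vapply(doc$populations, function(p) as.character(p$leaf), character(1)))
  list(tree = tree, leaf_to_cluster = leaf_to_cluster,
       provenance = doc$provenance)
}

#' Cross-condition signalling induction
#'
#' Routes the cells of both conditions through the gating tree using the
#' tree's (surface) markers only, then reports, per population and
#' signalling marker, the difference of mean arcsinh intensities:
#' `mean(stimulated) - mean(unstimulated)`. Populations empty in either
#' condition get `NA`, not zero. Mode `"fold-change"` reports the
#' difference of absolute mean values instead.
#'
#' @param unstim,stim [expr_table]s for the unstimulated and stimulated
#'   conditions, both containing all tree markers and `signaling_markers`.
#' @param tree a `gating_tree` (trained on the unstimulated condition).
#' @param signaling_markers marker names to summarise; must not be used for
#'   routing.
#' @param mode `"mean-difference"` (default) or `"fold-change"`.
#' @return A populations x signalling-markers matrix with attributes
#'   `leaf_ids` and `mode`.
#' @export
signaling_induction <- function(unstim, stim, tree, signaling_markers,
                                mode = c("mean-difference", "fold-change")) {
  mode <- match.arg(mode)
  unstim <- as_table(unstim); stim <- as_table(stim)
  for (tab in list(unstim, stim)) {
    missing <- setdiff(signaling_markers, colnames(tab))
    if (length(missing))
      stop("signalling marker(s) missing: ", paste(missing, collapse = ", "))
  }
  leaf_u <- apply_tree(tree, unstim)
  leaf_s <- apply_tree(tree, stim)
  leaves <- vapply(tree_leaves(tree), `[[`, numeric(1), "id")
  out <- matrix(NA_real_, length(leaves), length(signaling_markers),
                dimnames = list(paste0("leaf", leaves), signaling_markers))
  stat <- if (mode == "mean-difference") function(s, u) mean(s) - mean(u)
    else function(s, u) abs(mean(s)) - abs(mean(u))
  for (i in seq_along(leaves)) {
    iu <- which(leaf_u == leaves[i])
    is_ <- which(leaf_s == leaves[i])
    if (!length(iu) || !length(is_)) next   # empty in a condition -> NA
    for (mk in signaling_markers)
      out[i, mk] <- stat(unclass(stim)[is_, mk], unclass(unstim)[iu, mk])
  }
  structure(out, leaf_ids = leaves, mode = mode)
}
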