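## Labelled synthetic cytometry mixtures. Components are specified by
## qualitative expression levels per marker; each level maps to a normal
## distribution on the arcsinh scale. A two-part level such as "low high"
## is an equal 50/50 mixture of the two named levels; the part is drawn
## once per cell and shared across all two-part markers of that component,
## so a "low high"/"low high" component sits at (low, low) or (high, high).

.level_means <- c("low" = 0, "low-mid" = 4, "mid" = 7, "high" = 10)
.level_sd <- 0.3

resolve_level <- function(level) {
  if (is.numeric(level)) {
    if (length(level) != 2L || level[2] <= 0)
      stop("numeric level must be c(mean, sd) with sd > 0")
    return(matrix(level, nrow = 1L))
  }
  parts <- strsplit(trimws(level), "[ /]+")[[1]]
  parts <- gsub("_", "-", parts)
  if (!all(parts %in% names(.level_means)))
    stop("unknown level '", level, "'; levels are ",
         paste(names(.level_means), collapse = ", "),
         " or a two-part combination such as 'low high'")
  if (length(parts) > 2L) stop("a level has at most two parts: '", level, "'")
  cbind(mean = .level_means[parts], sd = .level_sd)
}

#' Specify a synthetic cell mixture
#'
#' @param components list of components, each a list with `size` (number of
#'   cells) and `levels` (one level per marker). A level is a name among
#'   `"low"`, `"low-mid"`, `"mid"`, `"high"`, a two-part string such as
#'   `"low high"` (an equal mixture of the two named levels), or an explicit
#'   `c(mean, sd)` pair.
#' @param markers marker names, one per level position.
#' @param seed integer seed stored in the spec and used by
#'   [simulate_cells()].
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(components, markers, seed = 1L) {
  stopifnot(is.list(components), length(components) >= 1L)
  r <- length(markers)
  for (cmp in components) {
    if (is.null(cmp$size) || cmp$size < 1L)
      stop("every component needs size >= 1")
    if (length(cmp$levels) != r)
      stop("every component needs one level per marker")
    lapply(cmp$levels, resolve_level)  # validate
  }
  structure(list(components = components, markers = as.character(markers),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  sizes <- vapply(x$components, `[[`, numeric(1), "size")
  cat(sprintf("sim_spec: %d components, %d cells, markers %s (seed %d)\n",
              length(sizes), sum(sizes), paste(x$markers, collapse = ", "),
              x$seed))
  invisible(x)
}

#' The default five-component study design
#'
#' A mixture of 850 cells in five components of sizes 100, 300, 150, 100 and
#' 200 over three markers. Component patterns (markers 1, 2, 3):
#' celltype 1 low/low/high; celltype 2 "high low"/low-mid/high; celltype 3
#' mid/mid/high; celltype 4 "low high"/"low high"/high; celltype 5
#' high/high/high. Marker 3 is "high" in every component and therefore
#' uninformative for gating. The two-part components straddle two expression
#' states, so celltype 4 overlaps celltypes 1 and 5 in marker space.
#'
#' @param seed integer seed stored in the spec.
#' @return A [sim_spec].
#' @export
default_sim_spec <- function(seed = 1L) {
  sim_spec(
    components = list(
      list(size = 100L, levels = list("low",      "low",      "high")),
      list(size = 300L, levels = list("high low", "low-mid",  "high")),
      list(size = 150L, levels = list("mid",      "mid",      "high")),
      list(size = 100L, levels = list("low high", "low high", "high")),
      list(size = 200L, levels = list("high",     "high",     "high"))),
    markers = c("M1", "M2", "M3"),
    seed = seed)
}

#' Draw a labelled synthetic dataset
#'
#' Cells are drawn per component (label proportions are exactly the spec
#' sizes, not multinomial). For each cell of a component with two-part
#' levels, a single part (1 or 2, equal probability) is drawn and applied to
#' all two-part markers of that component.
#'
#' @param spec a [sim_spec].
#' @return A list with `table` (an [expr_table] on the arcsinh scale) and
#'   `labels` (integer true component per cell).
#' @export
simulate_cells <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  r <- length(spec$markers)
  blocks <- vector("list", length(spec$components))
  labels <- integer(0)
  for (ci in seq_along(spec$components)) {
    cmp <- spec$components[[ci]]
    n <- as.integer(cmp$size)
    part <- sample.int(2L, n, replace = TRUE)
    block <- matrix(0, n, r)
    for (k in seq_len(r)) {
      par <- resolve_level(cmp$levels[[k]])
      if (nrow(par) == 1L) {
        block[, k] <- stats::rnorm(n, par[1, 1], par[1, 2])
      } else {
        idx <- pmin(part, nrow(par))
        block[, k] <- stats::rnorm(n, par[idx, 1], par[idx, 2])
      }
    }
    blocks[[ci]] <- block
    labels <- c(labels, rep.int(ci, n))
  }
  values <- do.call(rbind, blocks)
  colnames(values) <- spec$markers
  list(table = expr_table(values, markers = spec$markers, transformed = TRUE),
       labels = labels)
}
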