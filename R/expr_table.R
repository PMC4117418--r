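#' Expression tables
#'
#' An `expr_table` holds one row per cell (event) and one column per marker.
#' It is a plain numeric matrix carrying two extra pieces of metadata: integer
#' event identifiers (rownames) and a flag recording whether intensities have
#' been arcsinh-transformed. All downstream functions address markers by
#' name, never by column position.
#'
#' @param values numeric matrix or data frame, cells x markers.
#' @param markers character vector of marker names (defaults to the column
#'   names of `values`). Must be unique.
#' @param event_ids integer identifiers, one per cell (default `0:(n-1)`).
#'   Must be unique.
#' @param transformed logical; `TRUE` once intensities are on the arcsinh
#'   scale.
#'
#' @return An object of class `expr_table`: a numeric matrix with attributes.
#' @export
expr_table <- function(values, markers = colnames(values),
                       event_ids = NULL, transformed = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("expression table needs at least one cell and one marker")
  if (is.null(markers))
    markers <- paste0("M", seq_len(ncol(values)))
  markers <- as.character(markers)
  if (length(markers) != ncol(values))
    stop("length of 'markers' does not match the number of columns")
  if (anyDuplicated(markers))
    stop("duplicate marker names: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  if (is.null(event_ids)) event_ids <- seq_len(nrow(values)) - 1L
  event_ids <- as.integer(event_ids)
  if (length(event_ids) != nrow(values) || anyDuplicated(event_ids))
    stop("'event_ids' must be unique, one per cell")
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  dimnames(values) <- list(as.character(event_ids), markers)
  structure(values,
            transformed = isTRUE(transformed),
            class = c("expr_table", "matrix", "array"))
}

#' @export
print.expr_table <- function(x, ...) {
  cat(sprintf("expr_table: %d cells x %d markers (%s)\n", nrow(x), ncol(x),
              if (is_transformed(x)) "arcsinh-transformed" else "raw"))
  cat("markers:", paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname expr_table
#' @param x an object.
#' @export
is_transformed <- function(x) isTRUE(attr(x, "transformed"))

#' @rdname expr_table
#' @export
event_ids <- function(x) as.integer(rownames(x))

## rebuild an expr_table from a row/column subset of an existing one
restitch <- function(values, parent, event_ids = NULL) {
  if (is.null(event_ids)) event_ids <- as.integer(rownames(values))
  expr_table(values, markers = colnames(values), event_ids = event_ids,
             transformed = is_transformed(parent))
}

as_table <- function(x) {
  if (inherits(x, "expr_table")) return(x)
  expr_table(as.matrix(x))
}

#' Read cytometry events
#'
#' Reads an event table from an FCS file (versions 2.0/3.0/3.1, list-mode,
#' data types F/D/I) or from delimited text with a header row of marker
#' names. Marker names for FCS files are taken from the $PnS keywords,
#' falling back to $PnN where $PnS is absent.
#'
#' @param path path to the input file.
#' @param format `"fcs"` or `"delimited"`. Defaults to `"fcs"` when the file
#'   extension is `.fcs` (case-insensitive), `"delimited"` otherwise.
#' @param sep field separator for delimited input; autodetected between tab
#'   and comma when `NULL`.
#'
#' @return An [expr_table] with `transformed = FALSE` and event ids
#'   `0:(n-1)` in file order.
#' @seealso [write_events()], [arcsinh_transform()]
#' @export
read_events <- function(path, format = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "delimited"
  format <- match.arg(format, c("fcs", "delimited"))
  if (format == "fcs") {
    parsed <- read_fcs(path)
    return(expr_table(parsed$data, markers = parsed$markers,
                      transformed = FALSE))
  }
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "")
  if (anyDuplicated(names(df)))
    stop("duplicate marker names in header: ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  expr_table(as.matrix(df), markers = names(df), transformed = FALSE)
}

#' Write an event table as delimited text
#'
#' Writes markers as a header row and one row per cell, at full double
#' precision so that a write/read round trip reproduces the values exactly.
#'
#' @param table an [expr_table].
#' @param path output path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_events <- function(table, path, sep = "\t") {
  table <- as_table(table)
  utils::write.table(format(unclass(table), digits = 17, trim = TRUE,
                            scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = colnames(table))
  invisible(path)
}

#' Arcsinh-transform intensities
#'
#' Applies the variance-stabilising transform `asinh(value / cofactor)`
#' element-wise. The transform is odd and strictly increasing, and handles
#' negative and zero intensities without truncation; zero point masses in
#' the raw data stay at exactly zero.
#'
#' @param table an [expr_table] with raw intensities.
#' @param cofactor positive scale divisor. Field convention is 5 for mass
#'   cytometry and 150 for fluorescence data.
#' @return The transformed [expr_table] (`transformed = TRUE`).
#' @export
arcsinh_transform <- function(table, cofactor = 5) {
  table <- as_table(table)
  if (is_transformed(table))
    stop("table is already arcsinh-transformed")
  if (!is.numeric(cofactor) || length(cofactor) != 1L || cofactor <= 0)
    stop("'cofactor' must be a single positive number")
  values <- asinh(unclass(table) / cofactor)
  expr_table(values, markers = colnames(table), event_ids = event_ids(table),
             transformed = TRUE)
}

#' Select markers by name
#'
#' Column-subsets an event table, preserving row order and event ids. The
#' result's columns follow the order of `names`.
#'
#' @param table an [expr_table].
#' @param names marker names to keep.
#' @return The subset [expr_table].
#' @export
select_markers <- function(table, names) {
  table <- as_table(table)
  missing <- setdiff(names, colnames(table))
  if (length(missing))
    stop("unknown marker(s): ", paste(missing, collapse = ", "),
         "; available: ", paste(colnames(table), collapse = ", "))
  restitch(unclass(table)[, names, drop = FALSE], table)
}
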