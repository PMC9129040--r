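#' Gridded raster layer
#'
#' A minimal planar raster: a matrix of cell values on a regular square grid,
#' with an explicit nodata mask. Row 1 is the southernmost row and column 1
#' the westernmost column; `origin` gives the (x, y) coordinate of the grid's
#' lower-left corner and cell values refer to the cell's full area (so counts
#' aggregate exactly by summation). Continuous grids hold numbers; categorical
#' grids hold integer codes into `labels`.
#'
#' @param values numeric (continuous) or integer-code (categorical) matrix.
#'   For categorical grids a character matrix of labels is also accepted.
#' @param cell_size positive cell edge length (abstract length units, e.g. km).
#' @param origin numeric length-2, (x, y) of the lower-left corner.
#' @param mask logical matrix, `TRUE` marks nodata cells; `NA` values are
#'   folded into the mask.
#' @param kind `"continuous"` or `"categorical"`.
#' @param labels character label set for categorical grids; codes in `values`
#'   index this vector. Ignored for continuous grids.
#'
#' @return An object of class `sgrid`.
#' @export
#' @examples
#' g <- sgrid(matrix(runif(12), 3, 4))
#' dim(g)
sgrid <- function(values, cell_size = 1, origin = c(0, 0), mask = NULL,
                  kind = c("continuous", "categorical"), labels = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (kind == "categorical") {
    if (is.character(values)) {
      if (is.null(labels)) labels <- sort(unique(as.vector(values[!is.na(values)])))
      codes <- match(values, labels)
      if (any(is.na(codes) & !is.na(values)))
        stop("categorical values outside the declared label set")
      values <- matrix(codes, nrow(values), ncol(values))
    }
    if (is.null(labels)) stop("categorical grids need a `labels` set")
    storage.mode(values) <- "integer"
  } else {
    storage.mode(values) <- "double"
    labels <- NULL
  }
  if (is.null(mask)) mask <- matrix(FALSE, nrow(values), ncol(values))
  if (!is.logical(mask) || !all(dim(mask) == dim(values)))
    stop("`mask` must be a logical matrix with the shape of `values`")
  mask <- mask | is.na(values)
  if (kind == "categorical" &&
      any(values[!mask] < 1L | values[!mask] > length(labels)))
    stop("categorical codes outside the declared label set")
  if (kind == "continuous" && any(!is.finite(values[!mask])))
    stop("continuous grids must have finite unmasked values")
  if (length(cell_size) != 1 || !is.finite(cell_size) || cell_size <= 0)
    stop("`cell_size` must be a positive scalar")
  if (length(origin) != 2 || !all(is.finite(origin)))
    stop("`origin` must be a finite (x, y) pair")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), mask = mask, kind = kind,
         labels = labels, meta = list()),
    class = "sgrid")
}

#' @export
dim.sgrid <- function(x) dim(x$values)

#' Test for the sgrid class
#' @param x object.
#' @return `TRUE` for `sgrid` objects.
#' @export
is_sgrid <- function(x) inherits(x, "sgrid")

#' @export
print.sgrid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<sgrid> %s, %d x %d cells, cell size %g, origin (%g, %g)\n",
              x$kind, d[1], d[2], x$cell_size, x$origin[1], x$origin[2]))
  if (x$kind == "categorical") {
    cat("  labels:", paste(x$labels, collapse = ", "), "\n")
  } else if (any(!x$mask)) {
    v <- x$values[!x$mask]
    cat(sprintf("  range [%g, %g], mean %g\n", min(v), max(v), mean(v)))
  }
  if (any(x$mask)) cat(sprintf("  %d masked cells\n", sum(x$mask)))
  invisible(x)
}

#' Grid geometry
#'
#' The geometric signature of a grid: shape, cell size and origin. Two grids
#' are aligned iff their geometries are equal.
#'
#' @param g an `sgrid`.
#' @return A list with `nrow`, `ncol`, `cell_size`, `origin`.
#' @export
grid_geometry <- function(g) {
  stopifnot(is_sgrid(g))
  list(nrow = nrow(g$values), ncol = ncol(g$values),
       cell_size = g$cell_size, origin = g$origin)
}

#' Are two grids on the same geometry?
#'
#' @param a,b `sgrid` objects.
#' @param tol numeric tolerance on cell size and origin.
#' @return Logical.
#' @export
is_aligned <- function(a, b, tol = 1e-9) {
  stopifnot(is_sgrid(a), is_sgrid(b))
  all(dim(a) == dim(b)) &&
    abs(a$cell_size - b$cell_size) <= tol * max(1, a$cell_size) &&
    all(abs(a$origin - b$origin) <= tol * max(1, a$cell_size))
}

#' Cell-centre coordinates
#'
#' @param g an `sgrid`.
#' @return List with vectors `x` (per column) and `y` (per row).
#' @export
cell_centres <- function(g) {
  stopifnot(is_sgrid(g))
  list(x = g$origin[1] + (seq_len(ncol(g$values)) - 0.5) * g$cell_size,
       y = g$origin[2] + (seq_len(nrow(g$values)) - 0.5) * g$cell_size)
}

#' Unmasked values of a grid
#'
#' @param g an `sgrid`.
#' @param labels for categorical grids, return labels instead of codes.
#' @return Vector of unmasked cell values.
#' @export
grid_values <- function(g, labels = TRUE) {
  stopifnot(is_sgrid(g))
  v <- g$values[!g$mask]
  if (g$kind == "categorical" && labels) v <- g$labels[v]
  v
}

# Build a grid sharing g's geometry/kind with new values (internal).
grid_like <- function(g, values, mask = NULL, cell_size = g$cell_size,
                      origin = g$origin) {
  out <- sgrid(values, cell_size = cell_size, origin = origin, mask = mask,
               kind = g$kind, labels = g$labels)
  out
}

#' @export
plot.sgrid <- function(x, main = NULL, ...) {
  cc <- cell_centres(x)
  v <- x$values
  v[x$mask] <- NA
  graphics::image(cc$x, cc$y, t(v), asp = 1, xlab = "x", ylab = "y",
                  main = main %||% paste0("sgrid (", x$kind, ")"),
                  col = grDevices::hcl.colors(24, "viridis"), ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
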