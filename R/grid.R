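#' Lightweight raster grid layers
#'
#' A grid layer is a numeric matrix with row 1 at the *bottom* of the map,
#' a square cell size in map units, and an origin at the lower-left corner.
#' `NA` cells are nodata. A [predictor_stack()] bundles several aligned
#' layers under predictor names. These containers are deliberately minimal:
#' everything downstream (index algebra, ESM prediction, richness stacking,
#' Lee's L) operates on aligned matrices.
#'
#' @param values numeric matrix of cell values (`NA` = nodata).
#' @param cell_size cell edge length in map units (default 30, i.e. metres
#'   for Landsat/Sentinel-scale work).
#' @param xmin,ymin coordinates of the lower-left corner of the grid.
#' @return An object of class `grid_layer` (a matrix with grid attributes).
#' @examples
#' g <- grid_layer(matrix(rnorm(100), 10, 10))
#' layer_coords(g)[1:2, ]
#' @export
grid_layer <- function(values, cell_size = 30, xmin = 0, ymin = 0) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (cell_size <= 0) stop("`cell_size` must be positive", call. = FALSE)
  structure(values,
            cell_size = cell_size, xmin = xmin, ymin = ymin,
            class = c("grid_layer", "matrix", "array"))
}

#' @rdname grid_layer
#' @param x a `grid_layer` or plain matrix.
#' @export
is_grid_layer <- function(x) inherits(x, "grid_layer")

grid_meta <- function(x) {
  list(cell_size = attr(x, "cell_size") %||% 30,
       xmin = attr(x, "xmin") %||% 0,
       ymin = attr(x, "ymin") %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cell-centre coordinates of every cell in a layer
#'
#' @param x a `grid_layer` or matrix (row 1 = bottom row).
#' @return A tibble with `row`, `col`, `x`, `y`, `value`, in column-major
#'   cell order.
#' @export
layer_coords <- function(x) {
  m <- grid_meta(x)
  idx <- expand.grid(row = seq_len(nrow(x)), col = seq_len(ncol(x)))
  tibble::tibble(
    row = idx$row, col = idx$col,
    x = m$xmin + (idx$col - 0.5) * m$cell_size,
    y = m$ymin + (idx$row - 0.5) * m$cell_size,
    value = as.vector(unclass(x))
  )
}

#' Map point coordinates to containing cells
#'
#' Cells are half-open intervals `[x0, x0 + cell_size)` so a point on a
#' shared border belongs to exactly one cell.
#'
#' @param layer a `grid_layer` (or any matrix with grid attributes).
#' @param x,y numeric vectors of point coordinates.
#' @return A tibble with `row` and `col` (`NA` for points off the grid).
#' @export
cell_index <- function(layer, x, y) {
  m <- grid_meta(layer)
  col <- floor((x - m$xmin) / m$cell_size) + 1L
  row <- floor((y - m$ymin) / m$cell_size) + 1L
  bad <- col < 1L | col > ncol(layer) | row < 1L | row > nrow(layer)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Bundle aligned layers into a predictor stack
#'
#' @param layers named list of matrices/`grid_layer`s sharing one grid shape.
#' @param cell_size,xmin,ymin grid georeferencing (taken from the first
#'   `grid_layer` if present).
#' @param standardized logical flag recording whether layers are z-scores.
#' @return An object of class `predictor_stack`.
#' @export
predictor_stack <- function(layers, cell_size = NULL, xmin = NULL, ymin = NULL,
                            standardized = FALSE) {
  if (!is.list(layers) || length(layers) == 0)
    stop("`layers` must be a non-empty named list", call. = FALSE)
  if (is.null(names(layers)) || anyNA(names(layers)) || any(names(layers) == ""))
    stop("all layers must be named", call. = FALSE)
  dims <- vapply(layers, function(l) dim(l), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all layers must share one grid shape", call. = FALSE)
  first <- layers[[1]]
  m <- grid_meta(first)
  structure(list(
    layers = lapply(layers, function(l) {
      l <- unclass(l); attributes(l) <- list(dim = dim(l)); l
    }),
    nrow = nrow(first), ncol = ncol(first),
    cell_size = cell_size %||% m$cell_size,
    xmin = xmin %||% m$xmin, ymin = ymin %||% m$ymin,
    standardized = standardized
  ), class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat("<predictor_stack> ", x$nrow, "x", x$ncol, " cells, cell size ",
      x$cell_size, "\n", sep = "")
  cat("  layers: ", paste(names(x$layers), collapse = ", "), "\n", sep = "")
  cat("  standardized: ", x$standardized, "\n", sep = "")
  invisible(x)
}

#' @export
dim.predictor_stack <- function(x) c(x$nrow, x$ncol)

#' @export
names.predictor_stack <- function(x) names(x$layers)

#' Extract predictor values at point coordinates
#'
#' @param stack a [predictor_stack()].
#' @param x,y point coordinates (cell containment is half-open).
#' @return A tibble with one column per predictor; rows off the grid or on
#'   nodata cells carry `NA`.
#' @export
extract_values <- function(stack, x, y) {
  lay <- grid_layer(stack$layers[[1]], stack$cell_size, stack$xmin, stack$ymin)
  idx <- cell_index(lay, x, y)
  lin <- idx$row + (idx$col - 1L) * stack$nrow
  out <- lapply(stack$layers, function(l) as.vector(l)[lin])
  tibble::as_tibble(out)
}

#' @export
as_tibble.predictor_stack <- function(x, ...) {
  base <- layer_coords(grid_layer(x$layers[[1]], x$cell_size, x$xmin, x$ymin))
  base$value <- NULL
  vals <- tibble::as_tibble(lapply(x$layers, as.vector))
  out <- dplyr::bind_cols(base, vals)
  tidyr::pivot_longer(out, cols = -c("row", "col", "x", "y"),
                      names_to = "predictor", values_to = "value")
}

#' Read or write a stack as long-format CSV
#'
#' The on-disk format is a plain CSV with columns
#' `row,col,x,y,<one column per predictor>`; portable and diff-friendly.
#'
#' @param stack a [predictor_stack()].
#' @param path file path.
#' @return `write_stack_csv()` returns `path` invisibly; `read_stack_csv()`
#'   returns a [predictor_stack()].
#' @export
write_stack_csv <- function(stack, path) {
  base <- layer_coords(grid_layer(stack$layers[[1]], stack$cell_size,
                                  stack$xmin, stack$ymin))
  base$value <- NULL
  vals <- tibble::as_tibble(lapply(stack$layers, as.vector))
  utils::write.csv(dplyr::bind_cols(base, vals), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stack_csv
#' @export
read_stack_csv <- function(path) {
  df <- utils::read.csv(path)
  nr <- max(df$row); nc <- max(df$col)
  cell <- if (nc > 1) (max(df$x) - min(df$x)) / (nc - 1) else 30
  pred_cols <- setdiff(names(df), c("row", "col", "x", "y"))
  ord <- order(df$col, df$row)
  layers <- lapply(df[pred_cols], function(v) matrix(v[ord], nr, nc))
  predictor_stack(layers, cell_size = cell,
                  xmin = min(df$x) - cell / 2, ymin = min(df$y) - cell / 2)
}
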