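#' Grid geometry of a raster landscape
#'
#' A `grid_spec` records the shape and (optional) georeferencing header of
#' the analysis grid. All layers and masks in one analysis must share the
#' same grid. Cells are addressed row-major from the top-left corner:
#' flat cell index `(row - 1) * n_cols + col` with `row = 1` the top row.
#' The georeferencing fields are carried through file I/O untouched; the
#' package never reprojects and treats every cell as equal-area.
#'
#' @param n_rows,n_cols positive integers, grid dimensions.
#' @param xllcorner,yllcorner,cellsize ESRI ASCII grid header values,
#'   passed through to files written from this grid.
#' @param nodata value used to encode missing cells on disk.
#' @return an object of class `grid_spec`.
#' @examples
#' g <- grid_spec(3, 4)
#' cell_index(g, 2, 1)   # first cell of the second row -> 5
#' @export
grid_spec <- function(n_rows, n_cols, xllcorner = 0, yllcorner = 0,
                      cellsize = 1, nodata = -9999) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stop_if(is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L,
          "grid dimensions must be positive integers")
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 xllcorner = xllcorner, yllcorner = yllcorner,
                 cellsize = cellsize, nodata = nodata),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells (cellsize %g, origin %g,%g)\n",
              x$n_rows, x$n_cols, x$cellsize, x$xllcorner, x$yllcorner))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

#' @rdname grid_spec
#' @param grid a `grid_spec`.
#' @param row,col 1-based row/column indices.
#' @export
cell_index <- function(grid, row, col) {
  stop_if(any(row < 1L | row > grid$n_rows | col < 1L | col > grid$n_cols),
          "row/col outside grid")
  (row - 1L) * grid$n_cols + col
}

#' @rdname grid_spec
#' @param cell flat cell index (row-major, 1-based).
#' @return `cell_rowcol` returns a two-column matrix of row and column.
#' @export
cell_rowcol <- function(grid, cell) {
  stop_if(any(cell < 1L | cell > n_cells(grid)), "cell index outside grid")
  cell0 <- cell - 1L
  cbind(row = cell0 %/% grid$n_cols + 1L, col = cell0 %% grid$n_cols + 1L)
}

same_grid <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$cellsize - b$cellsize) <= tol &&
    abs(a$xllcorner - b$xllcorner) <= tol &&
    abs(a$yllcorner - b$yllcorner) <= tol
}
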