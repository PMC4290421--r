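# ESRI ASCII grid reader/writer. The format is a 5-6 line header
# (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value) followed by
# n_rows * n_cols whitespace-separated values, rows top to bottom --
# which is exactly this package's row-major, origin-top-left cell order.

read_ascii_grid <- function(path) {
  stop_if(!file.exists(path), "cannot read raster file: ", path)
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1L)
    stop_if(length(line) == 0L, "unexpected end of file in header: ", path)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    key <- tolower(tok[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value")) {
      stop_if(length(tok) != 2L, "malformed header line: ", line)
      hdr[[key]] <- as.numeric(tok[2])
    } else {
      seek(con, pos)
      break
    }
  }
  stop_if(is.null(hdr$ncols) || is.null(hdr$nrows),
          "missing ncols/nrows header in ", path)
  grid <- grid_spec(hdr$nrows, hdr$ncols,
                    xllcorner = hdr$xllcorner %||% hdr$xllcenter %||% 0,
                    yllcorner = hdr$yllcorner %||% hdr$yllcenter %||% 0,
                    cellsize = hdr$cellsize %||% 1,
                    nodata = hdr$nodata_value %||% -9999)
  vals <- scan(con, what = numeric(), quiet = TRUE)
  stop_if(length(vals) != n_cells(grid),
          "expected ", n_cells(grid), " values, found ", length(vals),
          " in ", path)
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA_real_
  list(grid = grid, values = vals)
}

write_ascii_grid <- function(values, grid, path) {
  stop_if(length(values) != n_cells(grid),
          "value vector does not match grid size")
  hdr <- sprintf("ncols %d\nnrows %d\nxllcorner %.10g\nyllcorner %.10g\ncellsize %.10g\nNODATA_value %.10g",
                 grid$n_cols, grid$n_rows, grid$xllcorner, grid$yllcorner,
                 grid$cellsize, grid$nodata)
  out <- values
  out[is.na(out)] <- grid$nodata
  # %.17g round-trips doubles exactly through text
  rows <- vapply(seq_len(grid$n_rows), function(r) {
    paste(sprintf("%.17g", out[((r - 1) * grid$n_cols + 1):(r * grid$n_cols)]),
          collapse = " ")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read one occurrence-probability layer
#'
#' Reads a single ESRI ASCII grid holding per-cell occurrence
#' probabilities. Values must lie in \[0, 1\]; values outside the range by
#' more than `tol` are an error (out-of-range probabilities signal an
#' upstream scaling mistake and are never clamped silently), while values
#' within `tol` of the bounds are snapped to them. NODATA cells become
#' `NA` and mark territory outside the analysis -- distinct from
#' probability 0, which is an absent species in a still-rankable cell.
#'
#' @param path file path of an ESRI ASCII grid.
#' @param expected_grid optional `grid_spec`; an error is raised if the
#'   file's grid differs.
#' @param id layer id (defaults to the file name without extension).
#' @param tol numeric tolerance for the \[0, 1\] range check.
#' @return a single-layer [raster_stack].
#' @seealso [write_layer()], [assemble_stack()]
#' @export
read_layer <- function(path, expected_grid = NULL, id = NULL, tol = 1e-9) {
  r <- read_ascii_grid(path)
  if (!is.null(expected_grid))
    stop_if(!same_grid(r$grid, expected_grid),
            "grid of ", path, " does not match the expected grid")
  v <- r$values
  bad <- !is.na(v) & (v < -tol | v > 1 + tol)
  stop_if(any(bad), "values outside [0,1] in ", path, " (e.g. ",
          format(v[which(bad)[1]]), ")")
  v[!is.na(v)] <- pmin(pmax(v[!is.na(v)], 0), 1)
  id <- id %||% sub("\\.[^.]*$", "", basename(path))
  raster_stack(matrix(v, ncol = 1, dimnames = list(NULL, id)), r$grid)
}

#' Write one layer of a stack to an ESRI ASCII grid
#'
#' @param stack a [raster_stack].
#' @param path output file path.
#' @param layer layer id or index (default: the first layer).
#' @return `path`, invisibly.
#' @export
write_layer <- function(stack, path, layer = 1L) {
  stopifnot(inherits(stack, "raster_stack"))
  write_ascii_grid(stack$values[, layer], stack$grid, path)
}

#' Read or write an integer mask raster
#'
#' A mask assigns each cell a small nonnegative integer level encoding a
#' removal hierarchy (land tenure): during prioritization all cells of
#' level k are removed before any cell of level k+1, so high levels (for
#' example existing reserves) are forced into the top priorities. Levels
#' listed in `outside_levels` (conventionally 0 = cleared / outside the
#' analysis) are excluded from ranking altogether.
#'
#' @param path mask raster file (ESRI ASCII grid, integer-valued).
#' @param declared_levels integer vector of permitted levels; any other
#'   value in the file is an error.
#' @param grid optional `grid_spec` the mask must match.
#' @param outside_levels levels whose cells are outside the analysis.
#' @return an object of class `mask_grid` with fields `grid`, `level`
#'   (integer per cell, `NA` for NODATA), `levels`, `outside`.
#' @export
read_mask <- function(path, declared_levels, grid = NULL,
                      outside_levels = integer(0)) {
  r <- read_ascii_grid(path)
  if (!is.null(grid))
    stop_if(!same_grid(r$grid, grid), "mask grid does not match")
  v <- r$values
  stop_if(any(!is.na(v) & v != round(v)), "mask raster is not integer-valued")
  mask_grid(as.integer(round(v)), r$grid, declared_levels, outside_levels)
}

#' @rdname read_mask
#' @param level integer vector of per-cell levels (row-major).
#' @export
mask_grid <- function(level, grid, declared_levels,
                      outside_levels = integer(0)) {
  level <- as.integer(level)
  declared_levels <- sort(unique(as.integer(declared_levels)))
  stop_if(length(level) != n_cells(grid), "mask length does not match grid")
  undeclared <- setdiff(unique(level[!is.na(level)]), declared_levels)
  stop_if(length(undeclared) > 0,
          "undeclared mask level(s): ", paste(undeclared, collapse = ", "))
  stop_if(!all(outside_levels %in% declared_levels),
          "outside_levels must be declared levels")
  structure(list(grid = grid, level = level, levels = declared_levels,
                 outside = as.integer(outside_levels)),
            class = "mask_grid")
}

#' @export
print.mask_grid <- function(x, ...) {
  tab <- table(factor(x$level, levels = x$levels))
  cat(sprintf("<mask_grid> %d x %d; levels: %s\n", x$grid$n_rows,
              x$grid$n_cols,
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  if (length(x$outside))
    cat("  outside analysis: level(s)", paste(x$outside, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname read_mask
#' @param mask a `mask_grid`.
#' @export
write_mask <- function(mask, path) {
  write_ascii_grid(as.numeric(mask$level), mask$grid, path)
}
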