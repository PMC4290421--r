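#' Co-registered stack of probability layers
#'
#' A `raster_stack` holds one occurrence-probability layer per feature
#' (species or phylogeny branch) on a shared grid, as a cells x layers
#' matrix in row-major cell order. `NA` marks NODATA; a cell that is
#' NODATA in any layer is NODATA in all layers (the stack-level valid
#' mask is the intersection of per-layer coverage).
#'
#' @param values numeric matrix, `n_cells(grid)` rows by one column per
#'   layer; column names are the layer ids.
#' @param grid a [grid_spec].
#' @param ids optional character vector of layer ids (overrides column
#'   names).
#' @return an object of class `raster_stack` with fields `grid`, `ids`,
#'   `values`.
#' @export
raster_stack <- function(values, grid, ids = NULL) {
  values <- as.matrix(values)
  stop_if(nrow(values) != n_cells(grid),
          "values must have one row per grid cell")
  ids <- ids %||% colnames(values)
  stop_if(is.null(ids), "layer ids are required")
  stop_if(anyDuplicated(ids) > 0, "duplicate layer ids")
  stop_if(length(ids) != ncol(values), "one id per layer required")
  rng <- range(values, na.rm = TRUE)
  stop_if(is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1),
          "stack values must lie in [0,1]")
  colnames(values) <- ids
  structure(list(grid = grid, ids = as.character(ids), values = values),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<%s> %d layer(s) on a %d x %d grid; %d / %d valid cells\n",
              class(x)[1], length(x$ids), x$grid$n_rows, x$grid$n_cols,
              sum(stack_valid(x)), n_cells(x$grid)))
  invisible(x)
}

#' @rdname raster_stack
#' @param stack a `raster_stack`.
#' @return `stack_valid` returns a logical vector marking cells inside
#'   the analysis (non-NODATA in every layer).
#' @export
stack_valid <- function(stack) {
  rowSums(is.na(stack$values)) == 0L
}

#' Combine single-layer stacks into one aligned stack
#'
#' All layers must share one grid. NODATA is unioned: a cell missing in
#' any input layer is dropped from the analysis in all layers.
#'
#' @param layers list of [raster_stack] objects (any number of layers
#'   each).
#' @param ids optional character vector renaming the combined layers.
#' @return a [raster_stack].
#' @export
assemble_stack <- function(layers, ids = NULL) {
  stop_if(length(layers) == 0, "no layers given")
  grid <- layers[[1]]$grid
  for (l in layers)
    stop_if(!same_grid(l$grid, grid), "layers are not co-registered")
  values <- do.call(cbind, lapply(layers, `[[`, "values"))
  all_ids <- ids %||% unlist(lapply(layers, `[[`, "ids"))
  stop_if(length(all_ids) != ncol(values), "id count does not match layers")
  invalid <- rowSums(is.na(values)) > 0L
  values[invalid, ] <- NA_real_
  raster_stack(values, grid, ids = all_ids)
}

#' Read or write a stack via a manifest CSV
#'
#' The manifest has columns `id,path`, one row per layer; paths are
#' resolved relative to the manifest location.
#'
#' @param manifest path to a manifest CSV.
#' @param expected_grid optional [grid_spec] all layers must match.
#' @return [read_stack()] returns a [raster_stack].
#' @export
read_stack <- function(manifest, expected_grid = NULL) {
  m <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stop_if(!all(c("id", "path") %in% names(m)),
          "manifest needs columns id,path")
  dir <- dirname(manifest)
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", m$path), m$path,
                  file.path(dir, m$path))
  layers <- mapply(read_layer, paths, id = m$id,
                   MoreArgs = list(expected_grid = expected_grid),
                   SIMPLIFY = FALSE)
  assemble_stack(layers, ids = m$id)
}

#' @rdname read_stack
#' @param stack a [raster_stack].
#' @param dir output directory (created if needed); one `<id>.asc` file
#'   per layer plus `manifest.csv`.
#' @return `write_stack` returns the manifest path, invisibly.
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- paste0(gsub("[^A-Za-z0-9_.-]", "_", stack$ids), ".asc")
  for (k in seq_along(stack$ids))
    write_ascii_grid(stack$values[, k], stack$grid, file.path(dir, files[k]))
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(id = stack$ids, path = files),
                   manifest, row.names = FALSE)
  invisible(manifest)
}
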