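#' Configuration of the greedy cell-removal ranking
#'
#' @param rule marginal-loss rule: `"core_area"` (alias `"caz"`) scores
#'   a cell by the maximum over branches of its weighted proportional
#'   contribution to the branch's remaining representation;
#'   `"additive_benefit"` (alias `"abf"`) sums those contributions over
#'   branches. Core-area is the default reference rule.
#' @param warp number of cells removed per iteration between
#'   marginal-loss recomputations (default 100). Losses are evaluated
#'   once per batch and the `warp` lowest-scoring cells are removed
#'   together.
#' @param weights optional per-branch weights; defaults to the branch
#'   lengths carried by the branch stack, so greedy loss aligns with
#'   branch-length-weighted PD. Alternative weightings (e.g.
#'   down-weighting branches shared with neighbouring regions) can be
#'   supplied here.
#' @param ... unused; supplying unsupported options (cost layers,
#'   connectivity, ...) is an error rather than silently ignored.
#' @return a `prioritizer_config` list.
#' @export
prioritizer_config <- function(rule = c("core_area", "additive_benefit",
                                        "caz", "abf"),
                               warp = 100L, weights = NULL, ...) {
  extra <- list(...)
  stop_if(length(extra) > 0, "unsupported prioritizer option(s): ",
          paste(names(extra), collapse = ", "))
  rule <- match.arg(rule)
  rule <- c(core_area = "core_area", caz = "core_area",
            additive_benefit = "additive_benefit", abf = "additive_benefit")[[rule]]
  warp <- as.integer(warp)
  stop_if(is.na(warp) || warp < 1L, "warp must be a positive integer")
  stop_if(!is.null(weights) && (anyNA(weights) || any(weights < 0)),
          "weights must be nonnegative")
  structure(list(rule = rule, warp = warp, weights = weights),
            class = "prioritizer_config")
}

#' Representation state of a partially removed landscape
#'
#' Tracks, for every branch feature i, the representation remaining in
#' the landscape `S_i` (sum of the branch's occurrence probabilities
#' over remaining cells) and the initial representation `T_i` over all
#' analyzable cells.
#'
#' @param branches a `branch_stack` from [build_branch_stack()].
#' @param remaining_cells flat indices of cells still in the landscape
#'   (default: all valid cells).
#' @param weights per-branch weights (default: branch lengths).
#' @return a `prioritizer_state` list with fields `B`, `w`, `S`, `T`,
#'   `remaining` (logical per cell).
#' @export
prioritizer_state <- function(branches, remaining_cells = NULL,
                              weights = NULL) {
  stopifnot(inherits(branches, "raster_stack"))
  valid <- stack_valid(branches)
  stop_if(!any(valid), "no valid cells in the stack")
  remaining <- if (is.null(remaining_cells)) valid else {
    stop_if(any(!valid[remaining_cells]), "remaining cells must be valid")
    r <- rep(FALSE, length(valid)); r[remaining_cells] <- TRUE; r
  }
  B <- branches$values
  w <- weights %||% branches$weights %||% rep(1, ncol(B))
  stop_if(length(w) != ncol(B), "one weight per branch required")
  T0 <- colSums(B[valid, , drop = FALSE])
  S <- if (identical(remaining, valid)) T0
       else colSums(B[remaining, , drop = FALSE])
  structure(list(B = B, w = w, S = S, T = T0, remaining = remaining),
            class = "prioritizer_state")
}

#' Marginal conservation loss of removing a cell
#'
#' Under the core-area rule the loss is
#' \eqn{\max_i w_i B_{i,j} / S_i}; under the additive-benefit rule it is
#' \eqn{\sum_i w_i B_{i,j} / S_i}. A branch whose remaining
#' representation `S_i` is zero is already fully lost and contributes 0
#' (not infinity): a vanished feature cannot be harmed further.
#'
#' @param cells flat indices of cells to score (must be remaining).
#' @param state a [prioritizer_state].
#' @param config a [prioritizer_config].
#' @return nonnegative loss value per cell.
#' @export
marginal_loss <- function(cells, state, config = prioritizer_config()) {
  stopifnot(inherits(state, "prioritizer_state"))
  stop_if(any(!state$remaining[cells]), "cell not in the remaining set")
  fac <- ifelse(state$S > 0, state$w / state$S, 0)
  M <- state$B[cells, , drop = FALSE] * rep(fac, each = length(cells))
  unname(if (config$rule == "core_area") row_max(M) else rowSums(M))
}

#' Greedy complementarity ranking of landscape cells
#'
#' Ranks every analyzable cell by iterative removal: starting from the
#' full landscape, the cells with the least marginal loss (see
#' [marginal_loss()]) are removed `warp` at a time, branch
#' representations are updated, and the process repeats until the
#' landscape is empty. Cells removed late are the conservation
#' priorities. Because internal-branch layers are unions of their
#' descendant species layers, the branches remain linked through the
#' phylogeny at every step even though each is an independent feature.
#'
#' An optional mask imposes a removal hierarchy: all cells of the lowest
#' still-populated mask level are exhausted before any cell of the next
#' level is touched, which forces e.g. already-cleared land to rank
#' below remnant vegetation and existing reserves into the top ranks.
#' Ties in marginal loss are broken toward the lowest flat cell index so
#' runs are exactly reproducible.
#'
#' @param branches a `branch_stack` from [build_branch_stack()].
#' @param mask optional [mask_grid] on the same grid; its
#'   `outside` levels are excluded from the analysis entirely.
#' @param config a [prioritizer_config].
#' @return a `priority_result` with fields:
#'   `order` (flat cell indices in removal order, first removed first),
#'   `rank` (per-cell fraction of analyzed cells removed before it, so
#'   the best cell has rank near 1; `NA` outside the analysis),
#'   `level` (mask level per removed cell, `NA` if no mask),
#'   `batches` (data frame logging each iteration: step, mask level,
#'   cells removed, min/max marginal loss), and `n_analyzed`.
#' @export
prioritize <- function(branches, mask = NULL,
                       config = prioritizer_config()) {
  stopifnot(inherits(branches, "raster_stack"),
            inherits(config, "prioritizer_config"))
  valid <- stack_valid(branches)
  level <- NULL
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "mask_grid"))
    stop_if(!same_grid(mask$grid, branches$grid),
            "mask and stack grids differ")
    level <- mask$level
    valid <- valid & !is.na(level) & !(level %in% mask$outside)
  }
  stop_if(!any(valid), "no analyzable cells")
  B <- branches$values
  stop_if(anyNA(B[valid, ]), "NaN/NA probabilities inside the valid set")
  w <- config$weights %||% branches$weights %||% rep(1, ncol(B))
  stop_if(length(w) != ncol(B), "one weight per branch required")

  cells <- which(valid)
  n <- length(cells)
  S <- colSums(B[cells, , drop = FALSE])
  lev_of <- if (is.null(level)) rep(0L, n) else level[cells]
  ord <- integer(n)
  batches <- list()
  pos <- 0L; step <- 0L
  for (lv in sort(unique(lev_of))) {
    pool <- cells[lev_of == lv]          # ascending flat index
    while (length(pool) > 0L) {
      step <- step + 1L
      fac <- ifelse(S > 0, w / S, 0)
      M <- B[pool, , drop = FALSE] * rep(fac, each = length(pool))
      loss <- if (config$rule == "core_area") row_max(M) else rowSums(M)
      k <- min(config$warp, length(pool))
      sel <- order(loss, pool)[seq_len(k)]  # ties: lowest cell index first
      removed <- pool[sel]
      S <- S - colSums(B[removed, , drop = FALSE])
      S[S < 0] <- 0
      ord[pos + seq_len(k)] <- removed
      pos <- pos + k
      pool <- pool[-sel]
      batches[[step]] <- data.frame(step = step, level = lv, n_removed = k,
                                    loss_min = min(loss[sel]),
                                    loss_max = max(loss[sel]))
    }
  }
  rank <- rep(NA_real_, length(valid))
  rank[ord] <- (seq_len(n) - 1) / n
  structure(list(order = ord, rank = rank,
                 level = if (is.null(level)) NULL else level[ord],
                 batches = do.call(rbind, batches),
                 n_analyzed = n, grid = branches$grid, config = config),
            class = "priority_result")
}

#' @export
print.priority_result <- function(x, ...) {
  cat(sprintf("<priority_result> %d cells ranked (%s rule, warp %d, %d batches)\n",
              x$n_analyzed, x$config$rule, x$config$warp, nrow(x$batches)))
  invisible(x)
}

#' Export a priority ranking as a raster and removal log
#'
#' @param result a `priority_result`.
#' @param rank_path output ESRI ASCII grid of per-cell ranks.
#' @param log_path optional CSV logging each removed cell (position,
#'   row, col, mask level).
#' @return `rank_path`, invisibly.
#' @export
write_priority <- function(result, rank_path, log_path = NULL) {
  write_ascii_grid(result$rank, result$grid, rank_path)
  if (!is.null(log_path)) {
    rc <- cell_rowcol(result$grid, result$order)
    utils::write.csv(
      data.frame(position = seq_along(result$order), cell = result$order,
                 row = rc[, "row"], col = rc[, "col"],
                 level = result$level %||% NA),
      log_path, row.names = FALSE)
  }
  invisible(rank_path)
}
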