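branch_lengths_of <- function(branches, table = NULL) {
  L <- if (!is.null(table)) table$length else branches$table$length %||% branches$weights
  stop_if(is.null(L), "branch lengths unavailable: supply a branch_table")
  stop_if(length(L) != ncol(branches$values), "one length per branch required")
  L
}

#' Proportion of phylogenetic diversity retained by a cell set
#'
#' The PD-retention statistic: every branch contributes the fraction of
#' its spatial representation that falls inside the retained cells,
#' weighted by its branch length and normalized by total PD,
#' \deqn{PD_{ret} = \frac{\sum_i L_i \; \sum_{j \in q} B_{i,j} /
#'   \sum_{j \in Q} B_{i,j}}{\sum_i L_i},}
#' where q is the retained cell set and Q the initial landscape. With
#' the full landscape retained every branch is fully represented and the
#' statistic is exactly 1 (total PD is then simply the sum of all branch
#' lengths, i.e. Faith's PD); with nothing retained it is 0.
#'
#' @param remaining_cells flat indices of retained cells (subset of the
#'   initial cells).
#' @param branches a `branch_stack`.
#' @param table optional [branch_table] supplying lengths L_i (default:
#'   the table carried by the stack).
#' @param initial_cells flat indices defining the denominator landscape
#'   Q (default: all valid cells of the stack). The choice of Q is a
#'   real modelling decision -- e.g. all currently vegetated cells
#'   versus the full modelled distribution including cleared land -- and
#'   is echoed in the result's attributes.
#' @param zero_total how to treat a branch with zero representation in
#'   Q, whose retained fraction is undefined: `"error"` (default) or
#'   `"drop"` with a warning.
#' @return PD retained, in \[0, 1\], with attribute `n_initial`.
#' @examples
#' # two cells, two branches of length 1: branch 1 splits 0.5/0.5,
#' # branch 2 sits entirely in cell 1; dropping cell 2 keeps
#' # (0.5 + 1.0) / 2 = 0.75 of PD
#' @export
pd_retention <- function(remaining_cells, branches, table = NULL,
                         initial_cells = NULL,
                         zero_total = c("error", "drop")) {
  stopifnot(inherits(branches, "raster_stack"))
  zero_total <- match.arg(zero_total)
  valid <- stack_valid(branches)
  initial_cells <- initial_cells %||% which(valid)
  stop_if(any(!valid[initial_cells]), "initial cells must be valid cells")
  stop_if(any(!(remaining_cells %in% initial_cells)),
          "remaining cells must be a subset of the initial cells")
  L <- branch_lengths_of(branches, table)
  B <- branches$values
  T0 <- colSums(B[initial_cells, , drop = FALSE])
  S <- colSums(B[remaining_cells, , drop = FALSE])
  if (any(T0 == 0)) {
    if (zero_total == "error")
      stop("branch(es) with zero total representation: ",
           paste(which(T0 == 0), collapse = ", "), call. = FALSE)
    warning(sum(T0 == 0), " branch(es) with zero representation dropped")
    keep <- T0 > 0
    L <- L[keep]; S <- S[keep]; T0 <- T0[keep]
  }
  structure(sum(L * S / T0) / sum(L), n_initial = length(initial_cells),
            class = "pd_value")
}

#' @export
print.pd_value <- function(x, ...) {
  cat(sprintf("PD retained: %.4f (denominator: %d cells)\n",
              unclass(x), attr(x, "n_initial")))
  invisible(x)
}

#' PD-retention curve of a priority ranking
#'
#' Replays a removal order and records, after every batch, the
#' proportion of PD remaining in the landscape, using incremental
#' subtraction of the removed cells' branch probabilities. The curve
#' starts at (0, 1) and is non-increasing; when every branch has
#' positive representation it ends at (1, 0). Read top-fraction
#' performance from the right: the PD retained by the best fraction f of
#' the landscape is the curve value at 1 - f.
#'
#' @param result a `priority_result` from [prioritize()].
#' @param branches the `branch_stack` the ranking was computed from.
#' @param table optional [branch_table] supplying branch lengths.
#' @param scenario optional name stored in the curve's metadata.
#' @return a `pd_curve` data frame with columns `fraction_removed` and
#'   `pd_remaining`, and attributes `denominator` ("analyzed cells") and
#'   `scenario`.
#' @export
pd_curve <- function(result, branches, table = NULL, scenario = NULL) {
  stopifnot(inherits(result, "priority_result"),
            inherits(branches, "raster_stack"))
  stop_if(!same_grid(result$grid, branches$grid),
          "result and stack grids differ")
  L <- branch_lengths_of(branches, table)
  B <- branches$values
  ord <- result$order
  T0 <- colSums(B[ord, , drop = FALSE])
  stop_if(any(T0 == 0), "branch(es) with zero representation in the ",
          "analyzed landscape; curve undefined")
  S <- T0
  sizes <- result$batches$n_removed
  frac <- c(0, cumsum(sizes) / result$n_analyzed)
  pd <- numeric(length(sizes) + 1L); pd[1] <- 1
  pos <- 0L
  for (b in seq_along(sizes)) {
    removed <- ord[pos + seq_len(sizes[b])]
    S <- S - colSums(B[removed, , drop = FALSE])
    S[S < 0] <- 0
    pos <- pos + sizes[b]
    if (pos == result$n_analyzed) S[] <- 0   # empty landscape, exactly
    pd[b + 1L] <- sum(L * S / T0) / sum(L)
  }
  out <- data.frame(fraction_removed = frac, pd_remaining = pd)
  attr(out, "denominator") <- "analyzed cells"
  attr(out, "scenario") <- scenario
  class(out) <- c("pd_curve", "data.frame")
  out
}

#' Interpolate a PD curve at arbitrary removal fractions
#'
#' Curves are stored once per warp batch; values between stored points
#' are linearly interpolated.
#'
#' @param curve a `pd_curve`.
#' @param fraction_removed numeric vector in \[0, 1\].
#' @return interpolated `pd_remaining` values.
#' @export
pd_at <- function(curve, fraction_removed) {
  stopifnot(inherits(curve, "pd_curve"))
  stats::approx(curve$fraction_removed, curve$pd_remaining,
                xout = fraction_removed, rule = 2, ties = "ordered")$y
}

#' PD currently protected under a tenure mask
#'
#' Evaluates [pd_retention()] with the retained set equal to the cells
#' whose mask level is in `protected_levels` -- i.e. how much PD the
#' existing reserve configuration captures, against the denominator of
#' all analyzable cells.
#'
#' @param mask a [mask_grid].
#' @param protected_levels mask levels counted as protected.
#' @param branches a `branch_stack` on the same grid.
#' @param table optional [branch_table].
#' @return protected PD proportion in \[0, 1\].
#' @export
protected_pd <- function(mask, protected_levels, branches, table = NULL) {
  stopifnot(inherits(mask, "mask_grid"))
  stop_if(!same_grid(mask$grid, branches$grid), "mask and stack grids differ")
  stop_if(!all(protected_levels %in% mask$levels),
          "protected_levels must be declared mask levels")
  valid <- stack_valid(branches) & !is.na(mask$level) &
    !(mask$level %in% mask$outside)
  prot <- which(valid & mask$level %in% protected_levels)
  pd_retention(prot, branches, table, initial_cells = which(valid))
}

#' Evaluate a reserve-expansion scenario
#'
#' Given a ranking computed with existing protected areas forced last
#' (highest mask level), selects the best-ranked unprotected cells
#' amounting to `expansion_fraction` of the current protected area (by
#' cell count; cells are treated as equal-area) and reports the PD
#' protected before and after the expansion.
#'
#' @param result a `priority_result` whose mask put protected areas at
#'   the highest level.
#' @param mask the [mask_grid] used for the run.
#' @param protected_levels mask levels counted as protected.
#' @param expansion_fraction e.g. 0.05 to grow reserves by 5% of their
#'   current cell count.
#' @param branches the `branch_stack` of the run.
#' @param table optional [branch_table].
#' @param name scenario label for the report.
#' @return a `scenario_report` list: `pd_before`, `pd_after`, `pd_gain`,
#'   `expansion_cells` (flat indices), `n_protected`, `n_expansion`,
#'   `fraction_of_landscape` added.
#' @export
expansion_scenario <- function(result, mask, protected_levels,
                               expansion_fraction, branches, table = NULL,
                               name = "reserve expansion") {
  stopifnot(inherits(result, "priority_result"),
            inherits(mask, "mask_grid"))
  stop_if(expansion_fraction <= 0, "expansion_fraction must be positive")
  valid <- stack_valid(branches) & !is.na(mask$level) &
    !(mask$level %in% mask$outside)
  prot_set <- which(valid & mask$level %in% protected_levels)
  unprot <- which(valid & !(mask$level %in% protected_levels))
  n_exp <- ceiling(expansion_fraction * length(prot_set))
  stop_if(n_exp > length(unprot),
          "expansion exceeds the available unprotected cells")
  # best-ranked unprotected cells = removed latest within their level
  ranks <- result$rank[unprot]
  stop_if(anyNA(ranks), "ranking does not cover the unprotected cells")
  expansion <- unprot[order(ranks, decreasing = TRUE)][seq_len(n_exp)]
  init <- which(valid)
  before <- pd_retention(prot_set, branches, table, initial_cells = init)
  after <- pd_retention(sort(c(prot_set, expansion)), branches, table,
                        initial_cells = init)
  structure(list(name = name,
                 pd_before = as.numeric(before),
                 pd_after = as.numeric(after),
                 pd_gain = as.numeric(after) - as.numeric(before),
                 expansion_cells = expansion,
                 n_protected = length(prot_set), n_expansion = n_exp,
                 fraction_of_landscape = n_exp / length(init)),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario_report> %s\n", x$name))
  cat(sprintf("  protected PD %.4f -> %.4f (gain %.4f, +%.1f%% over current)\n",
              x$pd_before, x$pd_after, x$pd_gain,
              100 * x$pd_gain / x$pd_before))
  cat(sprintf("  %d cells added to %d protected (%.2f%% of the landscape)\n",
              x$n_expansion, x$n_protected, 100 * x$fraction_of_landscape))
  invisible(x)
}

#' Per-branch land-tenure exposure and vulnerability
#'
#' For every branch, computes the proportion of its total spatial
#' distribution falling in each mask category, and classifies its
#' vulnerability from the proportion lying in the designated protected
#' category: `outside_parks` if the branch has zero representation in
#' any park category, `lt_1pct` if under 1% of its distribution is
#' protected, `1_to_5pct` if between 1% and 5%, `gt_5pct` otherwise.
#' Proportions exactly at a threshold fall in the higher (less
#' vulnerable) class. The denominator is the branch's full distribution
#' over all mapped cells -- including e.g. cleared land -- so the
#' statistic reflects what remains protected of the original range.
#'
#' @param branches a `branch_stack`.
#' @param mask a [mask_grid]; all its declared levels are reported.
#' @param protected_levels levels counted as protected.
#' @param park_levels levels counted as inside parks (default: the
#'   protected levels; include development zones to distinguish
#'   "in a park but unprotected" from "outside parks").
#' @param thresholds the two class cutpoints, default `c(0.01, 0.05)`.
#' @param table optional [branch_table].
#' @return a `tenure_summary` data frame: `branch_id`, `length`,
#'   `is_tip`, `label`, one `prop_level_<k>` column per mask level,
#'   `prop_protected`, and `class`.
#' @export
tenure_summary <- function(branches, mask, protected_levels,
                           park_levels = protected_levels,
                           thresholds = c(0.01, 0.05), table = NULL) {
  stopifnot(inherits(branches, "raster_stack"), inherits(mask, "mask_grid"))
  stop_if(!same_grid(mask$grid, branches$grid), "mask and stack grids differ")
  stop_if(!all(protected_levels %in% mask$levels) ||
            !all(park_levels %in% mask$levels),
          "protected/park levels must be declared mask levels")
  stop_if(length(thresholds) != 2 || thresholds[1] >= thresholds[2],
          "thresholds must be two increasing proportions")
  tbl <- table %||% branches$table
  L <- branch_lengths_of(branches, tbl)
  valid <- stack_valid(branches) & !is.na(mask$level)
  B <- branches$values[valid, , drop = FALSE]
  lev <- mask$level[valid]
  tot <- colSums(B)
  stop_if(any(tot == 0), "branch(es) with zero total distribution: ",
          paste(which(tot == 0), collapse = ", "))
  props <- sapply(mask$levels, function(l)
    colSums(B[lev == l, , drop = FALSE]) / tot)
  props <- matrix(props, ncol = length(mask$levels),
                  dimnames = list(NULL, paste0("prop_level_", mask$levels)))
  in_parks <- rowSums(props[, paste0("prop_level_", park_levels),
                            drop = FALSE])
  prot <- rowSums(props[, paste0("prop_level_", protected_levels),
                        drop = FALSE])
  cls <- ifelse(in_parks == 0, "outside_parks",
         ifelse(prot < thresholds[1], "lt_1pct",
         ifelse(prot < thresholds[2], "1_to_5pct", "gt_5pct")))
  out <- data.frame(branch_id = seq_along(tot), length = L,
                    is_tip = if (!is.null(tbl)) tbl$is_tip else NA,
                    label = if (!is.null(tbl)) tbl$label else NA)
  out <- cbind(out, props)
  out$prop_protected <- prot
  out$class <- factor(cls, levels = c("outside_parks", "lt_1pct",
                                      "1_to_5pct", "gt_5pct"))
  class(out) <- c("tenure_summary", "data.frame")
  out
}
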