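#' Occurrence probability of a branch from its descendant species
#'
#' A branch of the phylogeny occurs in a grid cell if at least one of
#' its descendant species occurs there. Treating species occurrences as
#' independent within a cell, the branch occurrence probability is the
#' union probability
#' \deqn{B = 1 - \prod_{n=1}^{m} (1 - P_n),}
#' where \eqn{P_n} are the per-species occurrence probabilities. The
#' product is evaluated as `exp(sum(log1p(-P)))` so that probabilities
#' very close to 1 do not lose precision to cancellation.
#'
#' @param tip_probs numeric vector of descendant-species probabilities,
#'   each in \[0, 1\]; may be a matrix (cells x species), in which case
#'   the union is taken across columns for each row.
#' @return the union probability (per row for matrix input), in \[0, 1\].
#'   With a single descendant the input is returned unchanged.
#' @examples
#' branch_probability(c(0.5, 0.5))       # 0.75
#' branch_probability(c(0.2, 0.3, 0.5))  # 0.72
#' @export
branch_probability <- function(tip_probs) {
  if (is.matrix(tip_probs)) {
    stop_if(ncol(tip_probs) == 0L, "empty probability set")
    rng <- range(tip_probs, na.rm = TRUE)
    stop_if(is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1),
            "probabilities must lie in [0,1]")
    if (ncol(tip_probs) == 1L) return(tip_probs[, 1L])
    return(1 - exp(rowSums(log1p(-tip_probs))))
  }
  stop_if(length(tip_probs) == 0L, "empty probability set")
  stop_if(anyNA(tip_probs) || any(tip_probs < 0 | tip_probs > 1),
          "probabilities must lie in [0,1]")
  if (length(tip_probs) == 1L) return(tip_probs)
  1 - exp(sum(log1p(-tip_probs)))
}

#' Propagate species layers to every branch of the phylogeny
#'
#' Builds one occurrence-probability layer per branch of the tree from
#' the per-species layers: tip branches reuse the species layer
#' unchanged (bitwise identical), and each internal branch gets the
#' per-cell union probability over its descendant species (see
#' [branch_probability()]). Cells that are NODATA for any species stay
#' NODATA for every branch. Each layer carries the branch length as its
#' feature weight, so downstream ranking and PD accounting are
#' branch-length weighted by default.
#'
#' @param species a [raster_stack] with one layer per tip species,
#'   layer ids matching the tree's tip labels.
#' @param branches a [branch_table] from [enumerate_branches()].
#' @return a `branch_stack`: a [raster_stack] whose layer ids are the
#'   `branch_id`s, with extra fields `weights` (branch lengths) and
#'   `table` (the branch table).
#' @export
build_branch_stack <- function(species, branches) {
  stopifnot(inherits(species, "raster_stack"),
            inherits(branches, "branch_table"))
  all_tips <- unique(unlist(branches$tips))
  missing <- setdiff(all_tips, species$ids)
  stop_if(length(missing) > 0, "no species layer for tip(s): ",
          paste(missing, collapse = ", "))
  P <- species$values
  LP <- log1p(-P)  # shared across branches
  B <- matrix(NA_real_, nrow(P), nrow(branches))
  for (k in seq_len(nrow(branches))) {
    cols <- match(branches$tips[[k]], species$ids)
    B[, k] <- if (length(cols) == 1L) P[, cols]
              else 1 - exp(rowSums(LP[, cols, drop = FALSE]))
  }
  # union probabilities cannot exceed 1; guard rounding upward drift
  B[!is.na(B) & B > 1] <- 1
  out <- raster_stack(B, species$grid, ids = as.character(branches$branch_id))
  out$weights <- branches$length
  out$table <- branches
  class(out) <- c("branch_stack", class(out))
  out
}
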