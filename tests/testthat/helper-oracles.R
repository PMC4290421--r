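# Independent oracles and small fixtures shared across tests. These
# deliberately re-derive quantities by brute force (explicit loops,
# simulation) rather than calling the package's own fast paths.

# Monte-Carlo union-probability oracle: empirical frequency of "at least
# one descendant present" under independent Bernoulli draws. `U` is a
# draws x n_species matrix of shared uniforms; `tipsets` a list of
# species index vectors, one per branch.
mc_branch_freq <- function(P_cell, tipsets, U) {
  pres <- (sweep(U, 2, P_cell, "<")) * 1
  D <- vapply(tipsets, function(ix) {
    v <- numeric(length(P_cell)); v[ix] <- 1; v
  }, numeric(length(P_cell)))
  colMeans((pres %*% D) > 0)
}

# From-scratch re-evaluating greedy: recomputes every branch's remaining
# representation by full summation at every batch, scores each candidate
# cell with an explicit per-branch loop, and applies the same tie-break
# (lowest flat index) and warp batching as the engine under test.
naive_greedy <- function(B, w, rule = c("core_area", "additive_benefit"),
                         warp = 1L, level = rep(0L, nrow(B))) {
  rule <- match.arg(rule)
  n <- nrow(B)
  removed <- logical(n)
  ord <- integer(0)
  for (lv in sort(unique(level))) {
    pool <- which(level == lv)
    while (length(pool) > 0L) {
      S <- colSums(B[!removed, , drop = FALSE])
      # same multiplication association as the engine (B * (w/S)) so
      # that exactly tied cells stay exactly tied in floating point
      fac <- ifelse(S > 0, w / S, 0)
      loss <- vapply(pool, function(j) {
        contrib <- B[j, ] * fac
        if (rule == "core_area") max(contrib) else sum(contrib)
      }, numeric(1))
      k <- min(warp, length(pool))
      sel <- order(loss, pool)[seq_len(k)]
      ord <- c(ord, pool[sel])
      removed[pool[sel]] <- TRUE
      pool <- pool[-sel]
    }
  }
  ord
}

# Explicit evaluation of the PD-retention statistic by double loop.
eq_pd_oracle <- function(remaining, B, L, initial = seq_len(nrow(B))) {
  acc <- 0
  for (i in seq_along(L)) {
    T0 <- sum(B[initial, i])
    S <- if (length(remaining)) sum(B[remaining, i]) else 0
    acc <- acc + L[i] * S / T0
  }
  acc / sum(L)
}

# Recursive child-combination computation of branch layers: an internal
# branch's layer from its child branches' layers (disjoint subtrees),
# B_parent = 1 - prod(1 - B_child), independent of the tip-product path.
recursive_branch_layers <- function(tree, P) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  child <- tree$edge[, 2]
  ntip <- ape::Ntip(tree)
  B <- matrix(NA_real_, nrow(P), length(child))
  for (e in rev(seq_along(child))) {   # postorder-ish: children first
    v <- child[e]
    if (v <= ntip) {
      B[, e] <- P[, tree$tip.label[v]]
    } else {
      kids <- which(tree$edge[, 1] == v)
      B[, e] <- 1 - apply(1 - B[, kids, drop = FALSE], 1, prod)
    }
  }
  B
}

# tiny fixed fixture: 3-tip tree and a 3x3 probability stack
toy_tree <- function() parse_tree("((A:1,B:1):1,C:2);")

toy_stack <- function(seed = 11, tips = c("A", "B", "C"), n_rows = 3,
                      n_cols = 3) {
  set.seed(seed)
  g <- grid_spec(n_rows, n_cols)
  vals <- matrix(round(runif(n_cells(g) * length(tips)), 3),
                 ncol = length(tips), dimnames = list(NULL, tips))
  raster_stack(vals, g)
}

rand_instance <- function(seed, n_tips, n_rows, n_cols) {
  cfg <- sim_config(n_species = n_tips, n_rows = n_rows, n_cols = n_cols,
                    seed = seed)
  tree <- simulate_phylogeny(cfg)
  list(tree = tree, cfg = cfg,
       species = simulate_occurrences(tree, cfg),
       table = enumerate_branches(tree))
}
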