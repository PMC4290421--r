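make_branchless_stack <- function(B, weights = rep(1, ncol(B)),
                                  n_rows = NULL) {
  # wrap a bare matrix of feature probabilities as a branch_stack
  n_rows <- n_rows %||% nrow(B)
  g <- grid_spec(n_rows, nrow(B) / n_rows)
  colnames(B) <- as.character(seq_len(ncol(B)))
  st <- raster_stack(B, g)
  st$weights <- weights
  class(st) <- c("branch_stack", class(st))
  st
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("marginal_loss implements the core-area and additive rules", {
  # single branch, w = 1, S = 10, B_cell = 2 -> 0.2 under either rule
  st1 <- make_branchless_stack(matrix(rep(0.5, 10), ncol = 1), n_rows = 2)
  state <- prioritizer_state(st1)
  state$S <- 10; state$T <- 10
  state$B[1, 1] <- 2   # direct state surgery for the hand example
  expect_equal(marginal_loss(1, state, prioritizer_config("caz")), 0.2)
  expect_equal(marginal_loss(1, state, prioritizer_config("abf")), 0.2)

  # two branches, w = (1,1), S = (10,5), B_cell = (2,1)
  B2 <- matrix(0.5, 10, 2)
  st2 <- make_branchless_stack(B2, n_rows = 2)
  state2 <- prioritizer_state(st2)
  state2$S <- c(10, 5); state2$B[1, ] <- c(2, 1)
  expect_equal(marginal_loss(1, state2, prioritizer_config("core_area")), 0.2)
  expect_equal(marginal_loss(1, state2,
                             prioritizer_config("additive_benefit")), 0.4)

  # a cell with zero probabilities is removable for free
  state2$B[2, ] <- 0
  expect_equal(marginal_loss(2, state2, prioritizer_config("caz")), 0)
  # fully lost features contribute 0, not Inf
  state2$S <- c(0, 0)
  expect_equal(marginal_loss(1, state2, prioritizer_config("abf")), 0)
  # scoring a removed cell is an error
  state2$remaining[3] <- FALSE
  expect_error(marginal_loss(3, state2, prioritizer_config()), "remaining")
})

test_that("a single feature is removed in ascending probability order", {
  st <- make_branchless_stack(matrix(c(0.1, 0.2, 0.3, 0.4), ncol = 1),
                              n_rows = 2)
  res <- prioritize(st, config = prioritizer_config("caz", warp = 1))
  expect_identical(res$order, 1:4)
  expect_equal(which.max(res$rank), 4)       # highest-P cell ranked best
  res_abf <- prioritize(st, config = prioritizer_config("abf", warp = 1))
  expect_identical(res_abf$order, 1:4)
})

test_that("mask hierarchy overrides the greedy order", {
  set.seed(1)
  B <- matrix(runif(18), ncol = 2)
  st <- make_branchless_stack(B, n_rows = 3)
  lev <- rep(1L, 9); lev[4] <- 2L     # one forced-last cell
  m <- mask_grid(lev, st$grid, declared_levels = 1:2)
  res <- prioritize(st, m, prioritizer_config("caz", warp = 1))
  expect_equal(res$order[9], 4)       # removed last whatever its value
  expect_equal(res$level, c(rep(1L, 8), 2L))
})

test_that("warp batching and tie-breaks behave as configured", {
  st <- make_branchless_stack(matrix(rep(0.5, 9), ncol = 1), n_rows = 3)
  # all losses tie: removal order must fall back to lowest flat index
  res <- prioritize(st, config = prioritizer_config("caz", warp = 1))
  expect_identical(res$order, 1:9)
  # warp = all cells: one batch, same ordering convention within it
  res2 <- prioritize(st, config = prioritizer_config("caz", warp = 9))
  expect_equal(nrow(res2$batches), 1)
  expect_identical(res2$order, 1:9)
})

test_that("the engine matches a from-scratch re-evaluating greedy", {
  specs <- expand.grid(seed = c(2, 8), warp = c(1L, 5L),
                       rule = c("core_area", "additive_benefit"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(specs))) {
    inst <- rand_instance(seed = specs$seed[i], n_tips = 6,
                          n_rows = 8, n_cols = 8)
    bs <- build_branch_stack(inst$species, inst$table)
    cfg <- prioritizer_config(specs$rule[i], warp = specs$warp[i])
    res <- prioritize(bs, config = cfg)
    oracle <- naive_greedy(bs$values, bs$weights, specs$rule[i],
                           warp = specs$warp[i])
    expect_identical(res$order, oracle)
  }
})

test_that("the engine matches the oracle under a mask hierarchy too", {
  inst <- rand_instance(seed = 31, n_tips = 5, n_rows = 6, n_cols = 6)
  bs <- build_branch_stack(inst$species, inst$table)
  set.seed(77)
  lev <- sample(1:3, 36, replace = TRUE)
  m <- mask_grid(lev, bs$grid, declared_levels = 1:3)
  for (warp in c(1L, 5L)) {
    res <- prioritize(bs, m, prioritizer_config("caz", warp = warp))
    oracle <- naive_greedy(bs$values, bs$weights, "core_area",
                           warp = warp, level = lev)
    expect_identical(res$order, oracle)
  }
})

test_that("representation bookkeeping is conservative", {
  inst <- rand_instance(seed = 12, n_tips = 6, n_rows = 8, n_cols = 8)
  bs <- build_branch_stack(inst$species, inst$table)
  res <- prioritize(bs, config = prioritizer_config("caz", warp = 7))
  T0 <- colSums(bs$values)
  # replay: at every batch boundary, S(incremental) + removed = T
  removed <- integer(0)
  pos <- 0
  for (b in seq_len(nrow(res$batches))) {
    pos <- pos + res$batches$n_removed[b]
    removed <- res$order[seq_len(pos)]
    S_scratch <- colSums(bs$values[setdiff(seq_len(64), removed), ,
                                   drop = FALSE])
    expect_lt(max(abs(S_scratch + colSums(
      bs$values[removed, , drop = FALSE]) - T0)), 1e-9)
  }
  # removal order is a bijection on the analyzed cells
  expect_setequal(res$order, 1:64)
  # determinism
  expect_identical(res$order,
                   prioritize(bs, config = prioritizer_config("caz",
                                                              warp = 7))$order)
})

test_that("unsupported prioritizer options are rejected loudly", {
  expect_error(prioritizer_config(cost_layer = "x"), "unsupported")
  expect_error(prioritizer_config(warp = 0), "warp")
  expect_error(prioritizer_config(weights = c(-1, 1)), "nonnegative")
})
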