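toy_two_cell <- function() {
  # two cells, two branches of length 1: branch 1 splits 0.5/0.5,
  # branch 2 lies entirely in cell 1
  g <- grid_spec(1, 2)
  B <- matrix(c(0.5, 0.5, 1.0, 0.0), ncol = 2,
              dimnames = list(NULL, c("b1", "b2")))
  st <- raster_stack(B, g)
  st$weights <- c(1, 1)
  class(st) <- c("branch_stack", class(st))
  st
}

test_that("pd_retention evaluates the length-weighted retained fraction", {
  st <- toy_two_cell()
  expect_identical(as.numeric(pd_retention(1:2, st)), 1)    # full landscape
  expect_identical(as.numeric(pd_retention(integer(0), st)), 0)
  # drop cell 2: branch1 keeps 0.5, branch2 keeps 1.0 -> (0.5 + 1)/2
  expect_equal(as.numeric(pd_retention(1, st)), 0.75)
  expect_equal(as.numeric(pd_retention(2, st)), 0.25)
  expect_error(pd_retention(c(1, 3), st), "subset")
})

test_that("pd_retention agrees with an explicit double-loop evaluation", {
  inst <- rand_instance(seed = 40, n_tips = 7, n_rows = 9, n_cols = 9)
  bs <- build_branch_stack(inst$species, inst$table)
  set.seed(41)
  for (k in 1:5) {
    keep <- sample(81, sample(5:70, 1))
    expect_equal(as.numeric(pd_retention(keep, bs)),
                 eq_pd_oracle(keep, bs$values, bs$weights),
                 tolerance = 1e-12)
  }
})

test_that("branches with zero representation are an error unless dropped", {
  st <- toy_two_cell()
  st$values[, 2] <- 0
  expect_error(pd_retention(1, st), "zero total representation")
  expect_warning(v <- pd_retention(1, st, zero_total = "drop"), "dropped")
  expect_equal(as.numeric(v), 0.5)
})

test_that("a star tree with equal lengths reduces to the mean fraction", {
  tr <- parse_tree("(A:1,B:1,C:1);")
  sp <- toy_stack(seed = 6)
  bs <- build_branch_stack(sp, enumerate_branches(tr))
  keep <- c(1, 4, 7, 8)
  fracs <- colSums(sp$values[keep, ]) / colSums(sp$values)
  expect_equal(as.numeric(pd_retention(keep, bs)), mean(fracs))
})

test_that("PD curves are exact for a uniform single feature", {
  g <- grid_spec(2, 5)
  st <- raster_stack(matrix(rep(0.4, 10), ncol = 1,
                            dimnames = list(NULL, "b")), g)
  st$weights <- 1
  class(st) <- c("branch_stack", class(st))
  res <- prioritize(st, config = prioritizer_config("caz", warp = 1))
  cv <- pd_curve(res, st)
  # each cell holds an equal share: the curve is the line 1 - f
  expect_equal(cv$pd_remaining, 1 - cv$fraction_removed)
  expect_identical(cv$pd_remaining[1], 1)
  expect_identical(cv$pd_remaining[nrow(cv)], 0)
})

test_that("incremental curves match from-scratch retention", {
  inst <- rand_instance(seed = 50, n_tips = 8, n_rows = 10, n_cols = 10)
  bs <- build_branch_stack(inst$species, inst$table)
  res <- prioritize(bs, config = prioritizer_config("caz", warp = 3))
  cv <- pd_curve(res, bs)
  expect_true(all(diff(cv$pd_remaining) <= 1e-12))   # non-increasing
  expect_identical(cv$fraction_removed[1], 0)
  for (b in seq(1, nrow(cv) - 1, by = 10)) {
    removed <- res$order[seq_len(round(cv$fraction_removed[b + 1] * 100))]
    keep <- setdiff(res$order, removed)
    expect_equal(cv$pd_remaining[b + 1],
                 as.numeric(pd_retention(keep, bs)), tolerance = 1e-9)
  }
  # interpolation queries pass through the stored points
  expect_equal(pd_at(cv, cv$fraction_removed[5]), cv$pd_remaining[5])
})

test_that("protected_pd scores a tenure configuration", {
  st <- toy_two_cell()
  m_all <- mask_grid(c(2L, 2L), st$grid, declared_levels = 1:2)
  m_none <- mask_grid(c(1L, 1L), st$grid, declared_levels = 1:2)
  m_one <- mask_grid(c(2L, 1L), st$grid, declared_levels = 1:2)
  expect_identical(as.numeric(protected_pd(m_all, 2, st)), 1)
  expect_identical(as.numeric(protected_pd(m_none, 2, st)), 0)
  expect_equal(as.numeric(protected_pd(m_one, 2, st)), 0.75)
  expect_error(protected_pd(m_one, 7, st), "declared")
})

test_that("constraining to the unconstrained top set leaves curves intact", {
  inst <- rand_instance(seed = 60, n_tips = 6, n_rows = 8, n_cols = 8)
  bs <- build_branch_stack(inst$species, inst$table)
  cfg <- prioritizer_config("caz", warp = 1)
  free <- prioritize(bs, config = cfg)
  lev <- rep(1L, 64)
  lev[free$order[49:64]] <- 2L      # top 25% forced last
  m <- mask_grid(lev, bs$grid, declared_levels = 1:2)
  forced <- prioritize(bs, m, cfg)
  expect_identical(forced$order, free$order)
  expect_equal(pd_curve(forced, bs)$pd_remaining,
               pd_curve(free, bs)$pd_remaining)
})

test_that("expansion scenarios report self-consistent PD gains", {
  cfg <- sim_config(n_species = 5, n_rows = 20, n_cols = 20, seed = 70,
                    tenure_levels = c(1L, 2L),
                    tenure_fractions = c(0.9, 0.1))
  sim <- simulate_landscape(cfg)
  bs <- build_branch_stack(sim$species, enumerate_branches(sim$tree))
  res <- prioritize(bs, sim$mask, prioritizer_config("caz", warp = 10))
  sc <- expansion_scenario(res, sim$mask, 2, 0.05, bs)
  valid <- which(stack_valid(bs))
  prot <- which(sim$mask$level == 2)
  aug <- sort(c(prot, sc$expansion_cells))
  expect_equal(sc$pd_gain,
               eq_pd_oracle(aug, bs$values, bs$weights, valid) -
                 eq_pd_oracle(prot, bs$values, bs$weights, valid),
               tolerance = 1e-9)
  expect_gte(sc$pd_gain, 0)
  expect_equal(sc$n_expansion, ceiling(0.05 * length(prot)))
  # exhaustive expansion protects everything
  sc_all <- expansion_scenario(res, sim$mask, 2,
                               length(which(sim$mask$level == 1)) /
                                 length(prot), bs)
  expect_equal(sc_all$pd_after, 1)
  expect_error(expansion_scenario(res, sim$mask, 2, 100, bs), "exceeds")
})

test_that("tenure summaries partition distributions and classify risk", {
  g <- grid_spec(1, 4)
  # branch 1 wholly protected; branch 2 has 0.4% protected;
  # branch 3 sits outside parks entirely
  B <- cbind(b1 = c(0, 0, 0, 1),
             b2 = c(0.996, 0, 0.004, 0),
             b3 = c(1, 0, 0, 0))
  st <- raster_stack(B, g)
  st$weights <- c(1, 1, 1)
  class(st) <- c("branch_stack", class(st))
  m <- mask_grid(c(1L, 2L, 3L, 3L), g, declared_levels = 1:3)
  ts <- tenure_summary(st, m, protected_levels = 3, park_levels = 2:3)
  expect_equal(as.character(ts$class), c("gt_5pct", "lt_1pct",
                                         "outside_parks"))
  expect_equal(ts$prop_protected, c(1, 0.004, 0))
  # per-branch proportions across categories sum to 1
  props <- as.matrix(ts[, grep("^prop_level_", names(ts))])
  expect_equal(unname(rowSums(props)), rep(1, 3), tolerance = 1e-9)
})

test_that("threshold edge cases fall in the less vulnerable class", {
  g <- grid_spec(1, 2)
  mk <- function(p) {
    B <- matrix(c(p, 1 - p), ncol = 1, dimnames = list(NULL, "b"))
    st <- raster_stack(B, g); st$weights <- 1
    class(st) <- c("branch_stack", class(st)); st
  }
  m <- mask_grid(c(2L, 1L), g, declared_levels = 1:2)
  cls <- function(p) as.character(
    tenure_summary(mk(p), m, protected_levels = 2)$class)
  expect_equal(cls(0.01), "1_to_5pct")
  expect_equal(cls(0.05), "gt_5pct")
  expect_equal(cls(0.0099), "lt_1pct")
  expect_equal(cls(0.049), "1_to_5pct")
  # zero total distribution is an error
  st0 <- mk(0); st0$values[] <- 0
  expect_error(tenure_summary(st0, m, protected_levels = 2),
               "zero total distribution")
})
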