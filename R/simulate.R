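#' Configuration for the synthetic landscape generator
#'
#' Bundles the parameters of a simulated study system: a pure-birth
#' phylogeny, one spatially coherent occurrence-probability surface per
#' tip species, and an integer tenure mask partitioning the grid. The
#' defaults describe a heavily cleared temperate landscape of the kind
#' the method targets: 15 focal species on a 30 x 30 grid, about 40% of
#' the land still carrying native vegetation and about 43% of that
#' vegetation inside reserves (tenure fractions 0.60 cleared / 0.23
#' unprotected vegetation / 0.17 protected).
#'
#' @param n_species number of tip species (>= 2).
#' @param n_rows,n_cols grid dimensions.
#' @param seed integer seed; the seed fully determines every output.
#' @param birth_rate speciation rate of the pure-birth tree model.
#' @param p_max peak occurrence probability at a species' range centre.
#' @param range_width range decay scale (standard deviation of the
#'   Gaussian surface) in cell units: either a length-2 vector giving
#'   the uniform sampling interval, or a single value (possibly `Inf`,
#'   giving a flat layer at `p_max`) used for every species. The default
#'   spans narrow endemics to widespread species relative to the grid.
#' @param phylo_signal if `TRUE` (default) range centres evolve by
#'   Brownian motion along the tree, so closely related species have
#'   nearby, overlapping ranges and internal-branch layers show
#'   realistic nestedness; if `FALSE` centres are uniform on the grid.
#' @param prevalence optional target mean probability per layer; each
#'   layer is rescaled multiplicatively towards it (capped so no value
#'   exceeds 1), mimicking prevalence scaling of presence-only model
#'   output.
#' @param tenure_levels integer mask levels, lowest first; the first
#'   level absorbs the remainder of the grid.
#' @param tenure_fractions target area fraction per level (summing to
#'   at most 1).
#' @param contiguous if `TRUE` (default) tenure levels are grown as
#'   contiguous blobs; otherwise cells are assigned at random.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = 15L, n_rows = 30L, n_cols = 30L,
                       seed = 1L, birth_rate = 1,
                       p_max = 0.9, range_width = c(0.08, 0.25) * 30,
                       phylo_signal = TRUE, prevalence = NULL,
                       tenure_levels = c(0L, 1L, 2L),
                       tenure_fractions = c(0.60, 0.23, 0.17),
                       contiguous = TRUE) {
  stop_if(n_species < 2, "n_species must be at least 2")
  stop_if(length(tenure_levels) != length(tenure_fractions),
          "one fraction per tenure level required")
  stop_if(any(tenure_fractions < 0) || sum(tenure_fractions) > 1 + 1e-9,
          "tenure fractions must be nonnegative and sum to <= 1")
  stop_if(p_max < 0 || p_max > 1, "p_max must be in [0,1]")
  stop_if(any(range_width <= 0), "range_width must be positive")
  structure(list(n_species = as.integer(n_species),
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 seed = as.integer(seed), birth_rate = birth_rate,
                 p_max = p_max, range_width = range_width,
                 phylo_signal = isTRUE(phylo_signal),
                 prevalence = prevalence,
                 tenure_levels = as.integer(tenure_levels),
                 tenure_fractions = tenure_fractions,
                 contiguous = isTRUE(contiguous)),
            class = "sim_config")
}

#' Simulate a pure-birth phylogeny
#'
#' Draws a rooted, bifurcating tree with `n_species` tips under a Yule
#' (pure-birth) process with the configured speciation rate, giving
#' positive branch lengths throughout. Tips are labelled `sp01`,
#' `sp02`, ... in the tree's own order. Deterministic given the seed.
#'
#' @param config a [sim_config].
#' @return an `ape::phylo` tree passing [parse_tree()]'s invariants.
#' @export
simulate_phylogeny <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tr <- ape::rphylo(config$n_species, birth = config$birth_rate, death = 0)
  tr$tip.label <- sprintf("sp%02d", seq_len(config$n_species))
  validate_tree(tr)
}

# Brownian-motion range centres: diffuse (x, y) along the tree so the
# expected squared displacement between two tips grows with their
# patristic distance, then rescale into the central part of the grid.
bm_centres <- function(tree, n_rows, n_cols) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  xy <- matrix(NA_real_, nn, 2)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  xy[root, ] <- 0
  for (e in seq_len(nrow(tree$edge))) {  # cladewise order: parents first
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    xy[ch, ] <- xy[p, ] + stats::rnorm(2, sd = sqrt(tree$edge.length[e]))
  }
  tips <- xy[seq_len(n), , drop = FALSE]
  # affine map of each axis into the middle 70% of the grid
  scale_axis <- function(v, lim) {
    r <- range(v)
    if (diff(r) < 1e-12) return(rep(lim / 2, length(v)))
    0.15 * lim + 0.70 * lim * (v - r[1]) / diff(r)
  }
  cbind(row = scale_axis(tips[, 1], n_rows),
        col = scale_axis(tips[, 2], n_cols))
}

#' Simulate occurrence-probability surfaces for the tips of a tree
#'
#' Each species gets a unimodal, isotropic surface: probability `p_max`
#' at its range centre decaying as a Gaussian with the species' drawn
#' range width, `P(d) = p_max * exp(-d^2 / (2 * width^2))` for distance
#' d (in cells) from the centre. With phylogenetic signal on, centres
#' are produced by Brownian motion along the tree so sister species
#' have overlapping ranges. All cells are valid (no NODATA); layers lie
#' in \[0, 1\] by construction and are verified against the stack
#' invariants on assembly.
#'
#' @param tree the phylogeny whose tips are simulated (normally from
#'   [simulate_phylogeny()] with the same config).
#' @param config a [sim_config].
#' @return a [raster_stack] with one layer per tip, ids = tip labels.
#' @export
simulate_occurrences <- function(tree, config) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  n <- ape::Ntip(tree)
  nr <- config$n_rows; nc <- config$n_cols
  widths_max <- max(config$range_width)
  stop_if(is.finite(widths_max) && widths_max > 5 * max(nr, nc),
          "grid too small for the requested range widths")
  set.seed(offset_seed(config$seed, 1L))
  centres <- if (config$phylo_signal) bm_centres(tree, nr, nc)
             else cbind(row = stats::runif(n, 1, nr),
                        col = stats::runif(n, 1, nc))
  widths <- if (length(config$range_width) == 2L)
    stats::runif(n, config$range_width[1], config$range_width[2])
  else rep(config$range_width[1], n)
  rows <- as.numeric(cell_rowcol(grid_spec(nr, nc), seq_len(nr * nc))[, "row"])
  cols <- as.numeric(cell_rowcol(grid_spec(nr, nc), seq_len(nr * nc))[, "col"])
  vals <- sapply(seq_len(n), function(k) {
    d2 <- (rows - centres[k, "row"])^2 + (cols - centres[k, "col"])^2
    p <- if (is.infinite(widths[k])) rep(config$p_max, length(d2))
         else config$p_max * exp(-d2 / (2 * widths[k]^2))
    if (!is.null(config$prevalence)) {
      m <- mean(p)
      if (m > 0) p <- p * min(config$prevalence / m,
                              if (max(p) > 0) 1 / max(p) else Inf)
    }
    p
  })
  raster_stack(matrix(vals, ncol = n, dimnames = list(NULL, tree$tip.label)),
               grid_spec(nr, nc))
}

#' Simulate a land-tenure mask
#'
#' Partitions the grid into the configured tenure levels. Every level
#' except the first is allocated its target number of cells (highest
#' level first), either as contiguous blobs grown from random seed
#' cells by 4-neighbour region growth, or as simple random samples; the
#' first (lowest) level absorbs the remaining cells. Realized areas
#' match the targets within rounding.
#'
#' @param config a [sim_config].
#' @param grid optional [grid_spec] (default: the config's grid).
#' @return a [mask_grid] over the configured levels.
#' @export
simulate_tenure <- function(config, grid = NULL) {
  stopifnot(inherits(config, "sim_config"))
  grid <- grid %||% grid_spec(config$n_rows, config$n_cols)
  nc <- n_cells(grid)
  targets <- round(config$tenure_fractions * nc)
  stop_if(sum(targets) > nc, "infeasible tenure fractions")
  set.seed(offset_seed(config$seed, 2L))
  level <- rep(config$tenure_levels[1], nc)
  unassigned <- rep(TRUE, nc)
  for (k in rev(seq_along(config$tenure_levels))[-length(config$tenure_levels)]) {
    want <- targets[k]
    if (want == 0) next
    if (!config$contiguous) {
      open <- which(unassigned)
      pick <- open[sample.int(length(open), want)]
    } else {
      pick <- grow_blobs(grid, unassigned, want)
    }
    level[pick] <- config$tenure_levels[k]
    unassigned[pick] <- FALSE
  }
  mask_grid(level, grid, config$tenure_levels)
}

# contiguous allocation by seeded region growth; starts new blobs when
# the frontier is exhausted
grow_blobs <- function(grid, unassigned, want) {
  avail <- unassigned
  chosen <- integer(0)
  frontier <- integer(0)
  while (length(chosen) < want) {
    if (length(frontier) == 0L) {
      open <- which(avail)
      frontier <- open[sample.int(length(open), 1L)]
    }
    cell <- frontier[sample.int(length(frontier), 1L)]
    frontier <- setdiff(frontier, cell)
    if (!avail[cell]) next
    chosen <- c(chosen, cell)
    avail[cell] <- FALSE
    rc <- cell_rowcol(grid, cell)
    nb <- c(if (rc[1] > 1) cell - grid$n_cols,
            if (rc[1] < grid$n_rows) cell + grid$n_cols,
            if (rc[2] > 1) cell - 1L,
            if (rc[2] < grid$n_cols) cell + 1L)
    frontier <- union(frontier, nb[avail[nb]])
  }
  chosen
}

#' Simulate a complete synthetic study system
#'
#' Convenience wrapper running [simulate_phylogeny()],
#' [simulate_occurrences()] and [simulate_tenure()] with one config.
#'
#' @param config a [sim_config].
#' @return a list with elements `tree`, `species` (a [raster_stack]),
#'   `mask` (a [mask_grid]) and `config`.
#' @export
simulate_landscape <- function(config = sim_config()) {
  tree <- simulate_phylogeny(config)
  species <- simulate_occurrences(tree, config)
  mask <- simulate_tenure(config, species$grid)
  list(tree = tree, species = species, mask = mask, config = config)
}
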