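---
title: "Prioritizing landscapes for phylogenetic diversity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing landscapes for phylogenetic diversity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdprior)
```

## The problem

Reserve systems are usually evaluated and expanded species by species,
which treats a young local endemic and the sole survivor of an ancient
lineage as interchangeable units. Faith's phylogenetic diversity (PD) —
the summed branch length of the subtree spanning a set of taxa — values
areas by how much of the tree of life they retain. `pdprior` embeds PD
into spatial conservation prioritization: every branch of a phylogeny,
terminal or internal, becomes a conservation feature with its own
occurrence-probability raster, and a greedy complementarity engine ranks
grid cells by how much branch-length-weighted representation the
landscape loses when a cell is dropped.

The intended inputs are a rooted phylogeny with branch lengths and one
probability-of-occurrence raster per tip species, typically the output
of species distribution models (SDMs) fitted upstream. The package
deliberately does not fit SDMs, reproject rasters, or weight cells by
area: it consumes co-registered equal-area probability grids and an
optional integer land-tenure mask.

## From species rasters to branch rasters

Let $P_{n,j}$ be the probability that descendant species $n$ of branch
$i$ occurs in cell $j$. Treating occurrences as independent within a
cell, the branch occurs in $j$ if at least one descendant does:

$$B_{i,j} \;=\; 1 - \prod_{n=1}^{m} \left(1 - P_{n,j}\right),$$

with $m$ the number of descendant species of branch $i$. Tip branches
reuse the species layer unchanged. Two consequences are used as test
invariants: a parent branch's layer dominates each child's layer in
every cell (a union over a superset), and the same layer is obtained
whether the product runs over all descendant tips or recursively over
the branch's child subtrees.

The independence assumption is a modelling choice, not a fact about
co-occurrence; no covariance structure is offered because none is
identified by the inputs. Numerically the product is evaluated in
complement space, `1 - exp(sum(log1p(-P)))`, so species probabilities
close to 1 do not cancel catastrophically; the dual-route equivalence is
asserted to 1e-12.

Taxa lacking molecular data can be attached before propagation with
`graft_taxa()`: the new tip is added as a child of its assumed closest
relative's parent node (the stem node), by default with branch length 0.
The zero-length graft adds no PD — total branch length is unchanged
exactly — but the tip's occurrence raster still feeds every ancestral
branch's union, which is precisely the point of grafting: distribution
information enters even when the branch itself carries no length. An
alternative convention would bisect the sibling's branch with a new
zero-length node; we implement the stem-node polytomy because it is the
more literal reading, and the exposed `length` column lets users emulate
other placements.

## The greedy ranking engine

The engine starts from the fully protected landscape and iteratively
removes the cells whose loss harms the remaining representation least.
With $S_i$ the representation of branch $i$ summed over the remaining
cells and $w_i$ its weight (branch length by default), a candidate cell
$j$ is scored

* core-area rule (CAZ): $\delta_j = \max_i \; w_i B_{i,j} / S_i$
* additive-benefit rule (ABF): $\delta_j = \sum_i \; w_i B_{i,j} / S_i$

The core-area rule protects the worst-kept feature in each cell and is
the reference rule; the additive rule trades individual branches for
aggregate representation. The additive form is implemented with the
benefit exponent fixed at 1 (a plain sum of proportional losses). A
branch with $S_i = 0$ contributes 0, not infinity: a feature already
eliminated cannot be harmed further, and this choice keeps late-stage
scores finite.

Three engineering parameters matter:

* **warp** (default 100): cells removed per iteration. Marginal losses
  are computed once per batch and the `warp` lowest-scoring cells are
  removed together before recomputation; whether losses should be
  refreshed *within* a batch is not observable from the method
  description we follow, and batch-wise recomputation matches the
  stated purpose of the parameter (removal speed). Warp trades fidelity
  for speed; warp = 1 is the exact greedy.
* **tie-break**: equal scores are broken toward the lowest flat cell
  index (row-major from the top-left). Ties are not hypothetical —
  symmetric probability surfaces produce exactly equal cells — and an
  unspecified tie-break would make runs irreproducible.
* **mask hierarchy**: an integer mask forces all cells of level $k$ to
  be removed before any cell of level $k+1$, while representation sums
  always span *all* remaining cells regardless of level. This is how
  cleared land is ranked first, and existing reserves last, without
  changing the loss mathematics. Mask levels declared "outside"
  (conventionally 0) are excluded from the analysis entirely — distinct
  from probability 0, which is an absent species in a rankable cell.

The per-cell output rank is the fraction of analyzed cells removed
earlier, so the best cell has rank near 1.

## Scoring rankings and tenure scenarios

The PD-retention statistic evaluates any retained cell set $q$ against
an initial landscape $Q$:

$$\mathrm{PD_{ret}} \;=\;
  \frac{\sum_i L_i \left(\sum_{j \in q} B_{i,j} \,/\,
        \sum_{j \in Q} B_{i,j}\right)}{\sum_i L_i},$$

the branch-length-weighted mean of per-branch retained fractions. It is
1 exactly for the full landscape, 0 for the empty one, and reduces to
the plain mean of species retained fractions on a star tree with equal
branch lengths. `pd_curve()` traces it along a removal order (stored
once per warp batch, linearly interpolated in between by `pd_at()`);
`protected_pd()` evaluates it at the cells of designated mask levels;
`expansion_scenario()` grows the protected set by the best-ranked
unprotected cells and reports the PD gained.

Two denominator conventions coexist and are kept explicit rather than
merged. Ranking curves and protected-PD use the *analyzable* landscape
(e.g. currently vegetated cells) as $Q$: with everything vegetated
retained, every branch is fully represented. Per-branch tenure
vulnerability (`tenure_summary()`) instead divides by the branch's
*full* mapped distribution, including cells already cleared, because a
branch that lost most of its range to clearing is more exposed than its
share of remnant vegetation suggests. Each result carries its
convention; reports should always print it.

`tenure_summary()` classifies each branch by the proportion of its
distribution in the protected category: `outside_parks` when it has no
representation in any park category, `lt_1pct` below 1%, `1_to_5pct`
from 1% to 5%, `gt_5pct` otherwise. Proportions falling exactly on a
threshold go to the higher, less vulnerable class; the boundary
convention is stated here because the class definitions alone do not fix
it. Expansion scenarios count cells, not hectares: with equal-area
cells, expanding reserves "by 5%" means 5% more protected cells,
rounded up (`ceiling`), so any positive expansion adds at least one
cell.

## The synthetic study system

Real applications of this method hinge on proprietary SDM stacks and
tenure maps, so the package carries a seeded generator that emulates
their structure and makes every claim testable end to end:

* **Phylogeny**: pure-birth (Yule) trees with unit speciation rate —
  simple, fully bifurcating, positive branch lengths; no downstream
  computation needs ultrametricity.
* **Occurrence surfaces**: one unimodal isotropic surface per species,
  $P(d) = p_{\max} e^{-d^2 / 2\sigma^2}$ around a range centre, with
  $\sigma$ drawn uniformly between 8% and 25% of the grid side and
  $p_{\max} = 0.9$. Range centres evolve by Brownian motion along the
  tree, so sister species overlap and internal-branch layers are
  realistically nested (verified as a property over 50 seeds). Gaussian
  surfaces also give single-feature prioritization a closed-form answer
  — removal in ascending probability — used as an oracle. An optional
  prevalence rescale mimics the scaling applied to presence-only SDM
  output.
* **Tenure**: levels are grown as contiguous blobs by seeded region
  growth (or sampled at random), hitting target area fractions within
  rounding. The defaults — 15 species on a 30 × 30 grid, tenure
  fractions 0.60 cleared / 0.23 unprotected vegetation / 0.17
  protected — sketch a heavily cleared temperate landscape in which
  roughly 40% of land keeps native vegetation and roughly 43% of that
  vegetation is reserved, the regime the method was designed for. These
  grid sizes keep the full test suite and the acceptance pipeline at
  desk scale (seconds to a few minutes); the algorithms themselves are
  linear in cells × branches per batch and run on much larger grids.

What the generator does *not* emulate: real climatic covariate
structure, anisotropic or fragmented ranges, spatial autocorrelation of
SDM errors, observation bias, or any particular region's geography.
Passing tests on synthetic data therefore demonstrates the correctness
of the propagation, ranking and accounting machinery — not that any
ecological conclusion transfers to a particular landscape.

## Numerical and testing choices

* Union probabilities: complement/log1p space; tip layers are copied,
  not recomputed, so they are bitwise identical to the species layers.
* Representation updates are incremental (subtract removed cells) with
  clamping at 0; incremental and from-scratch accounting agree to 1e-9
  in tests, and the final curve point is pinned to exactly 0 when the
  landscape empties.
* Out-of-range raster values are errors, not clamps (they indicate
  upstream scaling mistakes); values within 1e-9 of the bounds are
  snapped.
* The greedy engine is validated against a brute-force re-evaluating
  greedy (exact order equality) on instances up to 100 cells × 18
  branches for both rules and warp ∈ {1, 5}. Exact equality requires
  the oracle to share the engine's floating-point association
  (`B * (w/S)`), because symmetric surfaces create exactly tied cells.
* Simulation-based checks compare branch layers with Monte-Carlo union
  frequencies (10^5 draws). Across the thousands of simultaneous
  comparisons this entails, a correct implementation still exceeds 3
  standard errors on about 0.27% of comparisons by chance, so the suite
  tests the family-wise equivalent: a Bonferroni-corrected
  per-comparison bound at the same confidence level, plus agreement of
  the observed 3-SE exceedance rate with its nominal value.

## Limitations

* Within-cell independence of species occurrences is assumed, not
  estimated; strong positive co-occurrence would make internal-branch
  probabilities optimistic.
* The greedy ranking is a heuristic; it carries no optimality
  guarantee, and integer-programming formulations can beat it on small
  problems.
* Cells are equal-area and costs are uniform; connectivity, condition
  and economic layers are out of scope and rejected loudly if supplied.
* Phylogenetic uncertainty is not propagated: one tree in, one ranking
  out. Running the pipeline over a posterior sample of trees is the
  obvious extension and is cheap at these problem sizes.

## A worked run

```{r example, eval = FALSE}
sim <- simulate_landscape(sim_config(seed = 1))
branches <- build_branch_stack(sim$species,
                               enumerate_branches(sim$tree))
veg_mask <- mask_grid(sim$mask$level, sim$mask$grid, sim$mask$levels,
                      outside_levels = 0L)
res <- prioritize(branches, veg_mask,
                  prioritizer_config("caz", warp = 10))
protected_pd(veg_mask, 2L, branches)
expansion_scenario(res, veg_mask, 2L, 0.05, branches)
```

`scripts/acceptance.R` runs exactly this pipeline (plus a four-level
development-zone variant) from a single seed and writes the resulting
quantities as JSON.
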