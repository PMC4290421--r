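# pdprior

Phylogenetic diversity in spatial conservation prioritization.

`pdprior` is for conservation planners and macroevolutionary ecologists
who want reserve rankings that preserve evolutionary history, not just
species counts. It links three standard ingredients — a dated or
molecular phylogeny, per-species occurrence-probability rasters from
species distribution models (SDMs), and an integer land-tenure map —
into a single pipeline that ranks every grid cell of a landscape by its
contribution to Faith's phylogenetic diversity (PD) and scores reserve
policies by the PD they retain.

## Method

Every branch *i* of the phylogeny (tips and internal branches alike) is
a conservation feature with its own raster. Tip layers are the SDM
probabilities; an internal branch occurs in cell *j* if any descendant
species does, so under within-cell independence

&nbsp;&nbsp;&nbsp;&nbsp;*B*<sub>i,j</sub> = 1 − ∏<sub>n=1..m</sub> (1 − *P*<sub>n,j</sub>),

where *P*<sub>n,j</sub> is the occurrence probability of descendant
species *n*. A Zonation-style greedy engine then removes cells from the
full landscape one batch (*warp* cells) at a time, always dropping the
cells with the least marginal loss — under the core-area rule
max<sub>i</sub> *w*<sub>i</sub>*B*<sub>i,j</sub>/*S*<sub>i</sub>, under
the additive-benefit rule the sum over branches — where *S*<sub>i</sub>
is the branch's remaining representation and the weights *w*<sub>i</sub>
default to branch lengths. Hierarchical masks force tenure categories to
be removed in order (cleared land first, reserves last). Rankings and
reserve scenarios are scored by the proportion of PD remaining,

&nbsp;&nbsp;&nbsp;&nbsp;PD<sub>ret</sub> = [ Σ<sub>i</sub> *L*<sub>i</sub> ·
(Σ<sub>j∈q</sub> *B*<sub>i,j</sub> / Σ<sub>j∈Q</sub> *B*<sub>i,j</sub>) ] / Σ<sub>i</sub> *L*<sub>i</sub>,

the branch-length-weighted mean of per-branch retained fractions over
the retained cells q relative to the initial landscape Q. Per-branch
tenure reports flag lineages with less than 1% (or 1–5%) of their full
distribution in protected zones. A seeded generator (pure-birth trees,
Gaussian range surfaces with phylogenetically correlated centres,
region-grown tenure mosaics) provides complete synthetic study systems.

See `vignettes/pd-prioritization.Rmd` for the model assumptions,
parameter meanings and numerical choices.

## Worked example

```r
library(pdprior)

sim      <- simulate_landscape(sim_config(seed = 1))   # 15 species, 30x30
branches <- build_branch_stack(sim$species, enumerate_branches(sim$tree))
veg_mask <- mask_grid(sim$mask$level, sim$mask$grid, sim$mask$levels,
                      outside_levels = 0L)             # level 0 = cleared
res      <- prioritize(branches, veg_mask, prioritizer_config("caz", warp = 10))

protected_pd(veg_mask, 2L, branches)
expansion_scenario(res, veg_mask, 2L, 0.05, branches)
```

which prints

```
<branch_stack> 28 layer(s) on a 30 x 30 grid; 900 / 900 valid cells
<priority_result> 360 cells ranked (core_area rule, warp 10, 37 batches)
PD retained: 0.2428 (denominator: 360 cells)
<scenario_report> reserve expansion
  protected PD 0.2428 -> 0.4028 (gain 0.1600, +65.9% over current)
  8 cells added to 153 protected (2.22% of the landscape)
```

Read: the 15-species phylogeny contributes 28 branch features; of the
360 vegetated cells, the 153 reserved ones happen to capture 24.3% of
the branch-length-weighted PD, and adding the 8 best-ranked unprotected
cells (a 5% growth in reserve area, 2.2% of the landscape) raises that
to 40.3% — small, well-placed additions buy disproportionate amounts of
evolutionary history, which is the phenomenon the method exists to
expose.

A command-line interface wrapping the same functions lives in
`exec/pdprior` (`simulate`, `branch-layers`, `prioritize`,
`evaluate-protected`, `tenure-report`).

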