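# conopr

Composite biostratigraphic sequences by constrained optimisation with an
evolutionary algorithm — plus the downstream chronology and
paleobiodiversity pipeline (age calibration, unbinned richness,
proportional origination/extinction rates, rarefaction, bootstrap
uncertainty, richness–environment correlation).

## Who this is for

Quantitative (bio)stratigraphers and paleobiologists who have taxon
occurrence records from many measured sections and want a single,
high-resolution composite ordering of all first- and last-appearance
datums (FADs/LADs), calibrated to numeric ages, from which diversity
dynamics can be read at sub-zonal resolution.

## The model

Every locally observed range is contained in its taxon's true range:
sections can miss a taxon near its endpoints, never observe it beyond
them.  A composite sequence is one total order of all 2T events (T taxa,
one FAD and one LAD each).  Fitting a composite to a section means placing
its observed events on the section's level grid so that placements are
monotone along the composite, a FAD moves only *down* and a LAD only *up*;
the misfit (penalty) is the minimal total range extension

&nbsp;&nbsp;&nbsp;&nbsp;pen(seq) = Σ_sections w_s · min Σ_events |placed − observed|,

computed by dynamic programming.  Feasible composites keep each FAD before
its own LAD and preserve every observed coexistence (if FAD_A lies at or
below LAD_B in some section, FAD_A precedes LAD_B in the composite).  The
search for the minimum-penalty feasible order is a steady-state
evolutionary algorithm: constrained neighbour swaps and block moves,
order-based crossover between parent sequences, replay of remembered
improving moves, rank-biased parent selection, and Metropolis acceptance
under a temperature annealed linearly to zero, with incremental (delta)
penalty evaluation of only the sections a move touches.

Downstream, zero-cost-swap runs of adjacent events collapse into discrete
temporal levels; a cross-validated monotone smoothing spline through dated
markers maps levels to ages (Ma) with a bootstrap envelope; richness is
counted per level without binning; origination/extinction rates use
0.2-Myr bins in per-lineage-per-Myr units; and richness–proxy association
is quantified by Spearman's rho with percentile-bootstrap intervals,
optional linear detrending, and VIF screening of collinear proxies.

## Worked example

A synthetic world with known truth (20 simulated taxa over 48–20 Ma, 8
sections, 50% preservation; 18 taxa survive sampling):

```r
library(conopr)

w <- simulate_world(seed = 1)
summary(w$dataset)
#> Stratigraphic dataset
#>   taxa:        18
#>   sections:    8
#>   occurrences: 193
#>   components:  1 (correlatable)
#>   independent events/section: 1.75

fit <- conop(w$dataset, ea_config(population_size = 12, steps = 100,
                                  trials = 20000, seed = 1))
fit
#> Composite sequence fit (evolutionary search)
#>   events:   36
#>   sections: 8
#>   penalty:  34.37206
#>   trials:   20000 (100 generations)

lv <- cluster_levels(fit$sequence, w$dataset)
am <- bootstrap_age_model(lv, w$markers, w$dataset, n_boot = 200, seed = 1)
am
#> <age_model> 27 levels, 45.16-20.92 Ma, spar = 0.7, 200 bootstrap reps

imputed_resolution(max(am$level_ages) - min(am$level_ages), lv$n_levels)
#> [1] 897.6268

head(unbinned_richness(lv, w$dataset, ages = am), 4)
#>   level   age_ma richness
#> 1     1 45.15835        2
#> 2     2 44.30358        3
#> 3     3 43.44881        3
#> 4     4 42.59405        3

order_recovery(fit, w)
#> [1] 0.9938224
```

Reading the numbers: the 36 recovered events order with Spearman 0.994
against the simulated truth; the 34.4 penalty is the total stratigraphic
thickness (in height units, weighted) by which observed local ranges must
be extended to reconcile all eight sections — nonzero even for the true
order, because coarse level grids can record nearly coeval events in
opposite orders in different sections.  The 36 events resolve into 27
temporal levels spanning 24.2 Myr, an imputed resolution of ~0.9 Myr per
level at this desk scale (the same arithmetic that gives 29.11 Kyr for a
28-Myr composite with 962 levels).

`run_pipeline()` chains everything (validation → markers → search →
calibration → diversity → correlation) and writes composite, series and a
JSON manifest; `exec/conopr` exposes the same steps as shell subcommands
(`validate`, `rank`, `simulate`, `optimize`, `calibrate`, `run`).

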