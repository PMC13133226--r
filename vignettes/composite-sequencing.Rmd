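---
title: "Composite biostratigraphic sequencing by evolutionary search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite biostratigraphic sequencing by evolutionary search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conopr)
```

## The problem

Each measured stratigraphic section observes a handful of taxa over a
limited time window, with incomplete preservation.  The locally observed
first-appearance datum (FAD) of a taxon is therefore never older, and the
local last-appearance datum (LAD) never younger, than the taxon's true
range.  Constrained optimisation of event sequences (the CONOP family of
methods) turns this asymmetry into an inference principle: find one total
order of all taxa's FAD and LAD events that can be reconciled with every
section by *extending* observed local ranges as little as possible, and
never contracting them.

`conopr` implements this as a model fit.  `conop()` is the fitting
function; it returns a `conop_fit` object with the usual `print()`,
`summary()`, `plot()` and `as.data.frame()` methods.  Downstream functions
cluster the fitted composite into discrete temporal levels, calibrate those
levels to numeric ages, and estimate richness, origination/extinction
rates and richness-environment correlations.

## The penalty (economy of fit)

For a candidate composite order and one section, every event of a taxon
observed in that section must be placed on the section's level grid such
that placements are non-decreasing along the composite, a FAD is placed at
or below its observed height, and a LAD at or above.  The section penalty
is the minimal summed |placed − observed| height over all such placements,
times the section weight; the total penalty sums over sections.  The
minimisation is a small dynamic programme over (events × levels) with a
running prefix minimum, implemented in C++ because it is evaluated once per
search trial.  Penalties are measured in height (thickness) units, the
classic "interval" economy of fit.

Two hard constraints define feasibility rather than cost: a taxon's FAD
must precede its own LAD, and whenever taxon A's local FAD lies at or below
taxon B's local LAD in some section, FAD(A) must precede LAD(B) in the
composite.  The second rule preserves every observed coexistence and
superpositional relation.  It also has a useful structural consequence:
since every constraint edge runs from a FAD to a LAD, the constraint graph
is bipartite and acyclic, so a feasible order always exists, and — as a
fuzz suite verifies — every feasible order admits an extension-only
placement in every section.  We treat the pairwise rule as a hard
constraint (not a penalised soft one); this is the stronger of the two
readings and guarantees the placement DP never fails.

## The evolutionary search

The search maintains a population of feasible composites (default 24) and
evolves it with:

* **small mutation** — swap one uniformly chosen pair of neighbouring
  datums;
* **large mutation** — move one datum to another position, shifting the
  intervening block by one place;
* **recombination** — order-based crossover: a contiguous window of one
  parent is reordered to match the relative order of those same events in a
  second parent.  Literal segment substitution would not preserve the event
  multiset; order-based crossover does, and because both parents are
  feasible and the window's event *set* is unchanged, the offspring is
  provably feasible without repair;
* **move memory** — improving mutations are pushed into a FIFO buffer
  (1024 entries) of (move type, event pair) and replayed with a small
  probability, skipping entries no longer applicable;
* **selection** — parents are drawn with a linear rank bias (the best
  member has twice the sampling weight of the worst).  A proposal is
  accepted against its parent by the Metropolis rule exp(−Δ/T); at T = 0
  only strict improvements are accepted.  An accepted offspring replaces
  the worst member when it beats it, otherwise it replaces its parent —
  the population therefore only accumulates its best individuals while
  each slot behaves as an annealing chain.

The temperature decays linearly from `start_temperature` (default 500) to
exactly zero over `steps` (default 700) equal stages of
`trials/steps` proposals each, `trials` defaulting to 40,000.  These three
defaults are the reference settings for comparative desk-scale runs; the
rates without an established value are package choices: recombination
probability 0.2, memory replay 0.1, large-vs-small mutation split 0.5.
Runs are bit-reproducible from `seed`.

Per-trial evaluation uses the incremental (delta) penalty: only sections
containing a taxon whose events moved are re-evaluated, and the cached
per-section penalties make `parent + delta` exactly equal to a full
recomputation (this identity is asserted over thousands of random moves in
the test-suite).

Initial populations are built constructively: the taxa of the top-ranked
section (ranking: summed dataset-wide occurrence counts of taxa shared
with other sections) are anchored in their locally observed order, and
every remaining taxon's FAD and LAD are inserted at the feasible position
that greedily minimises the penalty of the sections hosting that taxon.
Members are diversified by perturbing the insertion order and by sampling
among penalty-tied insertion positions.  Populations can instead be seeded
from prior composites (`init_from_sequences()`), which is also the
package's parallelism contract: independent seeded restarts are merged by
seeding a final run from their best sequences, replacing shared-memory
concurrency.

`compare_runs()` contrasts the full search with a degenerate configuration
(population 2, no recombination, no memory), i.e. plain simulated
annealing at the same trial budget.

## Levels, ages, resolution

Adjacent events whose swap is feasible and changes the penalty by exactly
zero are unresolved by the data; `cluster_levels()` merges such runs into
discrete temporal levels (the alternative, one level per event, is a
configuration choice).  The imputed temporal resolution is span/levels —
e.g. a 28-Myr composite resolved into 962 levels implies ≈29.11 Kyr per
level; `imputed_resolution()` is that arithmetic.

`fit_age_model()` maps level rank to age (Ma) with a cubic smoothing
spline through dated markers (index-taxon FADs/LADs and chron boundaries),
choosing the smoothing parameter by leave-one-out cross-validation over a
log-style grid, then projecting onto non-increasing ages with an isotonic
adjustment, because cross-validated splines are not intrinsically
monotone.  Leave-one-out (rather than k-fold) was chosen because marker
sets are small.  Beyond the terminal markers the natural spline
extrapolates linearly from the boundary slope and those levels are
flagged.  `bootstrap_age_model()` resamples markers with replacement;
each replicate re-selects its smoothing by generalised cross-validation so
that smoothing-parameter variability propagates into the 2.5–97.5%
envelope (refitting at the fixed full-data smoothing understates the
envelope and under-covers in simulation).  Degenerate resamples touching
fewer than four distinct levels are redrawn and counted.  The reported
envelope is clamped to contain the point estimate, matching the
"midpoint ± half-width" reporting convention.

Dated markers also constrain the *ordering* through a heavily weighted
virtual section (default weight 10; the multiplier is a configuration
choice).  Index taxa with both a FAD and a LAD age enter as two-level
ranges; chron boundaries enter as point-range pseudo-taxa (FAD = LAD at
one level), which is exact because a boundary is instantaneous.  A taxon
with only one dated event is used for calibration only: under an
occurrence data model a single-level entry would wrongly pin the taxon's
*other* datum to the same level.

## Diversity and rates

`unbinned_richness()` counts, at every composite level, the taxa whose
composite range spans it — equivalently a running sum of FADs minus LADs —
avoiding the resolution loss of binning.  Genus series collapse congeners
to one range (earliest FAD to latest LAD); taxa without a genus are
excluded with a message.  `binned_rates()` uses 0.2-Myr bins by default:
with D taxa whose age range intersects a bin (boundary-crossers included —
the "proportional" denominator; bin-crosser-only variants are an
alternative left to the user), O FADs and E LADs dated inside it, the
origination rate is O/(D·Δt) and extinction E/(D·Δt) in per-lineage-per-Myr
units; turnover is the sum and net diversification the difference.

`rarefy_richness()` draws n occurrences without replacement (1000
iterations by default) and reports mean and percentile interval; its mean
is validated against the closed hypergeometric form
E[Sₙ] = Σᵢ (1 − C(N−Nᵢ,n)/C(N,n)).  Occurrences are pooled per analysis
bin through `occurrence_ages()`, which interpolates each occurrence's age
from the section's placed-height-to-level-age map.

`bootstrap_richness()`/`bootstrap_rates()` propagate *age-model*
uncertainty: each bootstrap replicate of the level ages re-expresses the
series on a common age grid and pointwise percentiles form the envelope.
Taxon resampling is deliberately not the default: the envelopes are tied
to the age model's uncertainty.

## Richness-environment association

`align_series()` linearly interpolates two `(age, value)` series onto a
shared 0.2-Myr grid (matching the rate bins) over their overlap.
`spearman_cor()` computes rho on mid-ranks, a two-tailed p by the t
approximation, and a percentile bootstrap interval over paired i.i.d.
resamples (default 10,000 iterations).  P-values below the
double-precision floor are reported at 2.2 × 10⁻³⁰⁸ with a flag instead of
a literal zero.  A plain (not block) bootstrap is the default because the
reported intervals follow the plain percentile convention; autocorrelated
series make these intervals anti-conservative, which is a known
limitation.  `detrend_linear()` removes the least-squares line so that
interval-to-interval covariation can be separated from shared secular
trends, and `vif_screen()` computes 1/(1−R²) for each proxy regressed on
the others, flagging VIF > 10 as multicollinear.

## The synthetic world

`simulate_world()` generates the closed-loop test target: true ranges from
a constant-rate birth–death stand-in (origination ages uniform over the
span; durations exponential with rate `ext_rate`, clipped at the young
boundary), sections sampling random time windows (stratified-uniform level
ages, random per-section accumulation rate, per-taxon-level preservation
probability `sampling_prob`), markers as the true FAD/LAD ages of the most
frequently occurring taxa (mimicking index-species choice), and a proxy
equal to `coupling` × max-min-normalised true richness plus AR(1) noise.
The generator guarantees the containment invariant — every observed local
range lies inside the true range — which is the premise that makes the
extension-only penalty meaningful.

The default world (20 taxa, 8 sections, 12 levels per section, 50%
sampling over a 48–20 Ma span, extinction rate 0.15/Lmyr ≈ 6.7 Myr mean
duration, 6 marker taxa) is the standard validation fixture; a
conflict-rich variant (25 taxa, 10 sections, 8 levels, 30% sampling) is
used where the search must be distinguished from plain annealing.  What it
does *not* emulate: facies control, geographic endemism, taphonomic or
abundance structure, correlated sampling across levels, and marker-age
error.  Passing the closed-loop tests therefore demonstrates the
machinery's correctness under the containment premise, not performance on
real data.

One genuine subtlety the generator exposed: perfect per-level sampling
does **not** imply a conflict-free dataset.  A level grid coarser than the
true event spacing can record, in different sections, opposite orders for
nearly coeval events (a FAD rounded *up* to the next younger level, a LAD
rounded *down*), so the true order itself can carry a small positive
penalty.  Exactly conflict-free fixtures are therefore built on a shared
integer-age level grid, where clamping is monotone and the true order
provably scores zero.

## Numerical choices and degenerate inputs

* Placement DP ties are broken toward the smaller placed height; this
  affects only the placement witness, never the penalty value.
* Tied insertion positions at initialisation are sampled (seeded) for all
  but the first member.
* `delta_penalty()` returns `NA` as a rejection signal for an infeasible
  offspring rather than throwing.
* Empty rate bins (no standing taxa) yield missing rates, not zeros; bins
  with standing taxa but no events yield zero rates.
* Rarefaction with n larger than the pool emits a missing value with a
  warning.
* Constant series cannot be max-min normalised or rank-correlated; both
  raise errors.
* Bootstrap envelopes are clamped to bracket the point estimate.

## Problem sizes used in validation

The test-suite and the acceptance script run entirely on synthetic worlds
at sizes a desk machine handles in minutes: the standard 20-taxon world
with a 20,000-trial search (population 12, 100 stages), ten-seed
comparisons at 4,000 trials, 200-instance placement-oracle sweeps, 10⁴
random feasible composites for the placement-existence fuzz, 500
simulations for correlation coverage and 200 for age-envelope coverage.
These sizes were chosen as the package's own desk-scale validation
conditions; the method itself has no intrinsic size limit beyond the
per-trial DP cost.

## Known limitations

* The pairwise coexistence rule is enforced as hard; datasets whose
  conflicts argue for soft constraints would need a penalised variant.
* The move memory replays event pairs verbatim; it does not generalise
  across similar events.
* Rarefaction pools occurrences through model-derived occurrence ages, so
  its bins inherit age-model error.
* The plain bootstrap for correlations ignores serial dependence; a block
  bootstrap would be the conservative alternative.
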