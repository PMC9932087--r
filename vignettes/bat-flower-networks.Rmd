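---
title: "Models and methods for weighted bat-flower networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for weighted bat-flower networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nectarnet)
```

`nectarnet` analyses weighted bipartite networks between flower-visiting
bats and plants: a matrix **Y** whose cell Y_ij counts the *distinct
individuals* of bat species i found carrying pollen of plant taxon j. This
vignette explains the models behind each step, the tunable parameters, the
numerical decisions taken where the underlying literature leaves choices
open, and what the synthetic-data validation does and does not establish.

## From pollen records to a network

Raw data are long-format records (bat species, individual, pollen type,
grain count, site, month). Two filtering rules precede matrix construction:
a palynomorph with **five or fewer grains** in a sample is treated as
contamination (threshold configurable in `filter_pollen_records()`), and
**anemophilous taxa are removed regardless of grain number**, since
wind-borne pollen on fur is not evidence of a visit. `build_network()` then
counts distinct individuals per cell: an individual recaptured with the
same pollen taxon increments its cell once, because the matrix is defined
over individuals, not capture events. All-zero rows and columns cannot
arise; any function receiving a matrix re-validates these invariants.

Guild sub-networks (`subset_guild()`) retain the selected bats and drop
plant columns left without interactions; the nectarivore and
remaining-guild sub-networks therefore partition the total weight exactly.
Before likelihood analysis, plants whose probability covariates cannot be
measured are excluded (`drop_missing_covariates()`); bat rows emptied by
that exclusion are dropped with a message, since every metric is undefined
on all-zero rows.

## Trait indices

Per individual: body condition index BCI = mass (g) / forearm (mm), a
mass-per-size robustness proxy (the definition is a replaceable callable,
so residual-based condition indices can be swapped in); rostrum-skull ratio
RSR = rostrum / skull, a nectar-feeding specialisation proxy. The bat
specialisation index BSI_raw = RSR / BCI and the flower index FSI_raw =
FTL / COD (floral tube length over corolla outer diameter) are computed
**per individual, then averaged within species**, then min-max normalised
to [0, 1] across the species of the matrix under analysis. Normalising per
analysed matrix (rather than once globally) keeps every sub-network's
indices spanning the full unit interval, which is what the matching
probability P_ij = 1 − |BSI_i − FSI_j| assumes. Non-tubular flowers and
pseudanthia carry the conventional dummy FTL of 0.1 mm (with COD measured
as inflorescence width for pseudanthia), encoding "no tube, no
restriction". A side with a single species has no min-max range; it maps
to 0.5 with a warning rather than failing, placing the lone species
mid-scale.

## Macrostructure metrics

### Complementary specialisation H2′

H2′ = (H2max − H2) / (H2max − H2min), where H2 is the Shannon entropy of
the interaction frequencies and the bounds are taken over tables with the
observed marginal totals. The package computes **H2max from the
real-valued relaxation** — the maximum-entropy table under fixed marginals
is the independence (outer-product) table, the fixed point of iterative
proportional fitting — and **H2min from a greedy packing heuristic** that
repeatedly allocates min(remaining row, remaining column) to the cell
joining the largest remaining marginals. Values are clipped to [0, 1].

On balanced marginals (independence table integral) both bounds coincide
with the exact integer-matrix optima, and the test suite verifies this
against an exhaustive-enumeration oracle to 1e-9. On arbitrary *very
small* totals (m ≤ 8) the relaxation can exceed the integer maximum and
H2′ is then biased upward relative to an integer-exact definition; the
suite verifies the bound ordering (relaxation ≥ exact max, greedy ≥ exact
min) instead. At realistic m (hundreds of events) the relative gap is
negligible; at m ≤ 10 H2′ should not be interpreted finely under any
definition.

### Weighted nestedness WNODA and compound topology

The literature names the metric but implementations differ in tie and
zero-weight conventions, so the pairwise rule is isolated in one function
and stated here precisely. For two nodes of the same side ordered so the
richer one (larger marginal total) is u and the poorer v, the contribution
is 100 × #\{partners w : Y_vw > 0 and Y_uw > Y_vw\} / #\{w : Y_vw > 0\} —
the share of the poorer node's interactions strictly dominated by the
richer node's. Unlike weighted NODF, **equal marginal totals do not zero
the pair**; both orderings are evaluated and averaged. WNODA is the mean
over all row pairs and column pairs, reported on the 0–100 scale (an
option rescales to [0, 1]). `wnoda_compound()` averages the same pair
contributions separately for same-module and different-module pairs: high
within-module with low between-module nestedness is the compound-topology
signature. For a single-module partition the within component equals plain
WNODA and the between component is undefined (returned as `NA` with a
warning).

### Barber modularity and DIRTLPAwb+

Q_w = (1/m) Σ_ij (Y_ij − k_i d_j / m) δ(g_i, g_j). The search is the
DIRTLPAwb+ scheme: over `restarts` independent runs, (i) initialise row
labels (run 1: one label per row; later runs: a random number of random
labels, which diversifies the basins explored), (ii) propagate labels
alternately across the two sides, each node adopting the label maximising
its Q_w contribution, until Q_w stops increasing, then (iii) exhaustively
consider module-pair merges, greedily accepting the best Q_w-increasing
merge until none remains. Tie-breaking is deterministic: a node keeps its
current label when tied-best, otherwise takes the smallest label id; a
node whose best attainable contribution is negative opens a fresh module.
The result is never worse than the single-module partition (Q_w ≥ 0),
module ids are relabelled contiguously from 1, and the same seed always
returns the same partition. Default `restarts = 20`; the seed argument is
mandatory. On networks of up to 6+6 nodes the search is regression-tested
against exhaustive enumeration (row set-partitions with optimal column
assignment, which dominates all full partitions), where 20 restarts
recover the global optimum in well over 95% of random instances.

## The vaznull null model and Monte Carlo significance

A replicate preserves the observed dimensions, total weight m and link
count L while marginal totals vary. Cell probabilities are proportional to
the outer product of the observed marginals. A binary skeleton of exactly
L cells is drawn sequentially without replacement; whenever the number of
draws left equals the number of still-uncovered rows or columns, the
candidate set is restricted to cells that reduce that deficit. This simple
restriction guarantees termination and full row/column coverage without
rejection sampling. The remaining m − L events are then distributed
multinomially over the skeleton with the same probabilities. The
significance of a metric is p = #(metric(null) ≥ metric(observed)) / n —
upper-tailed, ties counting against the observed structure — with n = 1000
the default and p ≤ 0.05 the conventional threshold. Replicates whose
metric evaluation fails are regenerated (at most 10 attempts, logged).
Replicate seeds are derived from the ensemble seed by counter, so results
do not depend on evaluation order.

## Driver models and multinomial likelihood

Four single probability matrices are built from field tables, each
normalised to sum to one: **A** (outer product of relative abundances —
capture frequencies for bats, summed transect flowering counts for
plants), **M** (trait matching, above), **P** (number of calendar months
in which bat and plant were both recorded anywhere), **S** (total captures
of the bat at sites where the plant was registered, all months pooled).
Seven compounds (SP, AS, AP, APS, MS, MP, MPS) are element-wise products,
renormalised, and the benchmark Null is uniform. Zeros propagate through
products: a link forbidden by any factor stays forbidden.

The log-likelihood is the multinomial kernel Σ Y_ij ln p_ij (0·ln 0 = 0);
the multinomial coefficient is a model-independent constant, excluded by
default and available behind a flag — AIC *differences* are unchanged
either way, which the tests verify. A model with p_ij = 0 where Y_ij > 0
has likelihood −Inf and is reported as **unfittable** rather than patched
with a pseudo-count; an explicit epsilon would change the model being
tested, so none is applied.

AIC = −2 lnL + 2K with **K = rows + columns of the analysed network** (the
number of species whose attributes enter the probability matrices). K is
identical for all models of one network, so the AIC ranking within a
network equals the likelihood ranking; K still matters when comparing
across networks of different size. ΔAIC supports two references: the
best-fitting model of the set, and the *saturated* model p = Y/m (the
observed matrix itself, the maximum-likelihood ceiling of the kernel).
Guild sub-networks are refit as their own multinomial experiments: their
probability matrices are rebuilt and renormalised on the sub-network's own
species set, not sliced out of the full-network matrices.

## Community statistics

Chao1 uses the classic estimator S_obs + F1²/(2 F2) when doubletons exist
and the bias-corrected S_obs + F1(F1−1)/(2(F2+1)) when F2 = 0, with the
matching variance formula for a standard error; completeness is
100·S_obs/Chao1. Rarefaction is the exact hypergeometric expectation
(computed through `vegan::rarefy`). Module-wise trait comparisons follow
the usual module-as-functional-group logic: **individual-level** trait
values (RSR, BCI, FTL, COD) grouped by the module of their species, a
one-way ANOVA per variable, and Tukey HSD for pairwise module contrasts
(Bonferroni-corrected t-tests would be a defensible alternative; Tukey is
the standard companion and is what `module_trait_anova()` reports).

## The synthetic community generator

`generate_community()` emulates the statistical structure the analysis
assumes, at the scale of a one-year savanna study: 13 bat species — 4
nectarivores with long rostra and low body condition, 8 frugivores with
the reverse morphology, 1 insectivore — and 25 plant taxa (10 tubular, 10
open-flowered, 5 pseudanthium-forming, the latter two classes carrying the
dummy FTL), across 8 sites in three habitats (4 savanna, 2 edge, 2
forest) and 12 months. Species abundances are log-normal (σ = 1, the
strong dominance typical of bat assemblages); activity and flowering
windows are contiguous month runs (wrapping December to January, as in
tropical phenology) centred on guild-typical seasons; site occupancy
follows guild-typical habitat preferences (frugivores and pseudanthia
concentrated in forest, nectarivores and open flowers in savanna/edge).
Three knobs — `trait_separation`, `habitat_concentration`,
`season_concentration`, each in [0, 1] — scale these signals; at 0 the
corresponding structure vanishes, giving a no-signal control.

The generating probability model is assembled **with the same
probability-matrix constructors the inference uses**, and
`sample_network()` draws m = 302 events from the multinomial over its
cells — inverting exactly the distributional assumption of the likelihood
analysis. `recovery_experiment()` closes the loop: generate, sample, fit
all models, and record whether the generating model (or a compound built
only from its factors) ranks first.

What passing recovery tests shows: the likelihood machinery can identify a
known driver at the study's sample size when the signal is strong, and
does not invent structure when there is none (the Null-truth control).
What it does not show: that real communities separate this cleanly. Real
matrices carry observation error, taxonomic lumping, pollen from plants
outside the surveyed area, and drivers outside the model set (nectar
energetics, phylogeny), none of which the generator emulates — it emits
already-legitimate interaction events, so the contamination filter is
exercised by its own unit fixtures, not by the generator.

## Problem sizes and numerical choices

The test suite runs the vaznull constraint check over 1000 replicates of a
study-scale matrix, driver recovery and its no-signal control over 200
replicates each at 13 × 25 and m = 302, and the modularity regression over
200 random ≤ 6+6 networks — sizes chosen to match the scales at which the
methods are meant to operate while keeping a full run in tens of seconds.
Probability models are normalised to sum to one within 1e−12; partition
and Q_w comparisons use 1e−12 slack; H2′ is clipped to [0, 1]; seeds are
required everywhere randomness enters and derived sub-streams stay below
2^31 − 1. Degenerate inputs fail loudly: empty record lists, all-zero
probability products, single-species normalisation (warned, mapped to
0.5), rostrum ≥ skull, and infeasible vaznull targets (fewer links than
rows or columns) all raise informative conditions.

## Known limitations

* H2′ uses analytic entropy bounds; at very small totals it can exceed an
  integer-exact definition (see above). Metrics at m ≤ 10 are not
  interpretable anyway.
* The WNODA pairwise rule follows the stated convention; other
  implementations may treat ties differently, so cross-package numerical
  comparisons should fix the convention first.
* The vaznull skeleton sampler restricts candidates only when coverage
  becomes tight, which differs in low-order detail from
  rejection-sampling formulations while satisfying the same constraints.
* Driver models are fixed matrices with no free parameters; AIC here
  penalises only network size, so model-complexity arguments across
  same-network models reduce to likelihood ordering by construction.
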