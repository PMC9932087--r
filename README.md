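# nectarnet

Analysis of weighted bipartite pollen-transport networks between
flower-visiting bats (Phyllostomidae) and plants.

Interactions between nectar-feeding bats and the plants they visit are
recorded as a weighted adjacency matrix **Y**, where cell Y_ij counts the
individuals of bat species *i* found carrying pollen of plant taxon *j*.
`nectarnet` answers the two questions ecologists ask of such a matrix:

1. **What does the network look like?** (macrostructure) — weighted
   modularity Q_w (Barber's bipartite modularity, maximised with the
   DIRTLPAwb+ label-propagation search), complementary specialisation H2′,
   and the weighted nestedness metric WNODA, including its within- and
   between-module decomposition that diagnoses a *compound topology*
   (internally nested modules in a non-nested network). Significance comes
   from a Monte Carlo test against the *vaznull* null model, which fixes
   the observed connectance and total weight while letting marginal totals
   vary.
2. **What drives it?** (microstructure) — the observed matrix is compared,
   by multinomial likelihood and AIC, against interaction-probability
   matrices built from species **a**bundances (neutrality), **m**orphological
   specialisation (P_ij = 1 − |BSI_i − FSI_j|, with BSI = rostrum–skull
   ratio over body condition index and FSI = floral tube length over
   corolla diameter, both min–max normalised), **p**henological overlap
   (shared activity/flowering months) and **s**patial overlap (bat captures
   at the plant's sites), plus all seven element-wise products of these and
   a uniform benchmark null.

The package also provides Chao1 sampling completeness with individual-based
rarefaction, module-wise trait comparisons (one-way ANOVA + Tukey HSD), the
pollen-record contamination filter (≤ 5 grains, or any anemophilous taxon),
and a synthetic bat–flower community generator that samples interaction
matrices from a *known* driver model, so the whole pipeline can be validated
end-to-end by driver-recovery experiments.

It is aimed at community ecologists working on mutualistic networks,
particularly bat pollination in seasonal, habitat-heterogeneous systems.

## Worked example

Generate a study-scale synthetic community (13 bat species, 25 plant taxa,
302 interaction events drawn from a spatial-overlap driver), then analyse
it exactly as one would a field matrix:

```r
library(nectarnet)

cfg  <- community_config()                       # defaults: 13 x 25, m = 302
comm <- generate_community(cfg, seed = 42)
net  <- sample_network(comm, seed = 43)          # 13 x 24 after dropping
                                                 # unobserved taxa; m = 302
part <- dirtlpawb_plus(net, restarts = 20, seed = 44)
#> module partition: 4 modules, Qw = 0.2053 (restarts = 20, seed = 44)

h2prime(net)                                     #> 0.224
wnoda(net)                                       #> 32.5
wnoda_compound(net, part)                        #>  within between
                                                 #>   36.42   31.39
mc_pvalue(net, h2prime, n = 200, seed = 45)$p    #> 0.035

fits <- fit_all(net, comm$traits, comm$bat_occ, comm$plant_occ,
                reference = "best")
head(fits[, c("label", "loglik", "AIC", "delta_aic")], 4)
#>   label   loglik     AIC delta_aic
#> 1     S -1535.98 3145.96     0.000
#> 2     A -1666.59 3407.18   261.228
#> 3    AS -1687.95 3449.91   303.953
#> 4  Null -1734.39 3542.77   396.818
```

Reading the output: the sampled network is moderately modular (Q_w ≈ 0.21)
and weakly specialised (H2′ ≈ 0.22, but higher than almost all vaznull
replicates, p = 0.035); within-module nestedness exceeds between-module
nestedness, the signature of a compound topology. The driver comparison
correctly ranks the spatial-overlap model S first — it generated the data —
with ΔAIC > 260 to the runner-up, while phenology-containing models are
unfittable here (events fell on months the narrow windows forbid, a
'forbidden link' situation reported as `-Inf` likelihood rather than
papered over).

A thin command-line front end over the same functions ships in
`inst/cli/nectarnet.R` with subcommands `build`, `metrics`, `nulltest`,
`drivers`, `completeness`, `simulate` and `recover`.

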