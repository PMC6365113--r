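# hotspotdiv

Macroevolutionary assembly of biodiversity hotspots: a tested R pipeline
for asking *how* regions of exceptional diversity got their species —
faster in-situ speciation, net immigration from surrounding regions, or
earlier colonization — from gridded species ranges and a dated phylogeny.

The pipeline delineates hotspots on a grid (weighted endemism
WE(cell) = Σ<sub>species</sub> 1/range-size, top 20% of occupied cells;
richness and narrow-ranged-species rules as alternatives), contrasts
ancient vs recent lineage accumulation with the tip diversification
statistic DR (inverse equal splits: DR = 1/ES, ES = Σ<sub>j</sub>
l<sub>j</sub> 2<sup>−(j−1)</sup> along the tip-to-root path) and
quartile-richness regressions, then fits the six discrete-area
range-evolution models (DEC, DIVALIKE, BAYAREALIKE, each ± founder-event
parameter j) on a three-area state space — focal-realm hotspot H,
focal-realm non-hotspot N, elsewhere E, ranges of at most two areas —
compares them by AICc, samples biogeographic stochastic mappings under the
best model, and converts the sampled histories into 2-Ma-binned dispersal
and in-situ cladogenesis rate series on the 2–26 Ma window with
standardized hotspot-minus-non-hotspot differences (Δ).  A Thomas
cluster-process null controls for hotspot size and shape, and SAR error
models (y = Xβ + u, u = λWu + ε) contrast environments and residual
surfaces between hotspot classes with Bonferroni correction.

Everything runs end-to-end on a synthetic study system with known ground
truth (`sim_config()` / `simulate_dataset()`), so parameter recovery,
sampler calibration, and test calibration are all checkable — and checked,
in `tests/testthat/`.

## Worked example

```r
library(hotspotdiv)

set.seed(1)
tree <- simulate_tree(birth = 0.15, death = 0.05, n_tips = 200)
truth <- simulate_range_evolution(tree, d = 0.05, e = 0.02, family = "DEC")

fit <- fit_model(tree, truth$tip_states, "DEC",
                 condition_survival = TRUE)
fit
#> DEC fit: lnL = -283.201, AICc = 570.464
#>       d       e       j
#> 0.05467 0.01471 0.00000

maps <- sample_maps(tree, truth$tip_states, fit, n_maps = 50, seed = 2)
events <- extract_events(maps)
round(table(events$type) / 50, 1)
#>   dispersal extirpation    sympatry  vicariance
#>       110.8        17.1       174.7        24.3

counts_h <- lineage_counts(maps, "H")
nh <- dispersal_rate_series(events, counts_h, "N", "H",
                            n_maps = 50, lineage_floor = 3)
round(nh$median, 3)
#>  [1] 0.062 0.059 0.040 0.049 0.062 0.083 0.000 0.000 0.000 0.000    NA    NA
```

The fitted dispersal and extirpation rates sit near the simulated truth
(0.05, 0.02); the event table averages about 111 dispersal events per
sampled history; and the N→H dispersal series gives a per-lineage rate per
2-Ma bin, with bins lacking enough hotspot lineages reported as `NA`
rather than zero.

The `analysis/` directory holds the full workflow as numbered scripts
(simulate → hotspots → tip rates → model comparison → rate series →
spatial null → environment), each writing its tables under `results/`.

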