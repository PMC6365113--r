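---
title: "Macroevolutionary assembly of biodiversity hotspots: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Macroevolutionary assembly of biodiversity hotspots: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotdiv)
```

# The question and the workflow

Biodiversity hotspots — small regions holding disproportionate numbers of
species, especially narrow-ranged endemics — could have assembled along very
different macroevolutionary routes: faster in-situ speciation, net
immigration from surrounding regions, earlier colonization, or lower
extinction.  This package implements a complete, testable pipeline for
separating those routes on gridded species ranges and a dated phylogeny:

1. delineate hotspots on a grid (weighted endemism, richness, or
   narrow-ranged-species rules);
2. contrast the spatial accumulation of "ancient" and "recent" lineages
   (tip diversification rates, richness regressions, spatial error models);
3. fit discrete-area range-evolution models on a three-area state space
   (hotspot H / non-hotspot N / elsewhere E, per focal realm), compare them
   by AICc, and sample explicit range histories (biogeographic stochastic
   mapping);
4. turn sampled histories into time-binned dispersal and cladogenesis rate
   series and standardized hotspot-minus-non-hotspot differences;
5. control for hotspot size and shape with a fitted cluster point-process
   null, and contrast environments between the classes.

Every stage runs on synthetic data with known ground truth, so each claim
the pipeline makes is backed by a recovery or calibration experiment in the
test suite.  The `analysis/` scripts walk the same path on one bundled
synthetic study system.

# Hotspot delineation

Weighted endemism in a cell is the sum over resident species of the inverse
of their range size in cells, so each species contributes exactly one unit
spread across its range; the grid-wide sum equals the species count, an
identity the tests check exactly.  Hotspots default to the top 20% of
occupied cells by WE; cells with no species never enter the quantile
universe, and ties at the threshold break deterministically by cell id.
The alternative delineations are the top 20% by species richness and the
cells holding at least one narrow-ranged species (range at most
100,000 km², i.e. 10 cells of 100 km).  Overlaps between delineations are
reported as the shared fraction of the smaller hotspot set by default
(Jaccard is available): the compared sets differ slightly in size and the
smaller-set convention keeps the percentage symmetric.

# Tip rates and residual contrasts

The DR statistic is the inverse of the equal-splits measure: walking from a
tip to the root, each successive edge's length is halved before being
added, and DR is the reciprocal of the sum.  It is cheap, extinction-blind,
and high for tips embedded in recent rapid splitting.  Species are ranked
by DR and split into quartiles (ties broken by name; remainders fill the
lower quartiles first), Q1 richness and Q4 richness are regressed on total
richness across cells by ordinary least squares, and the residuals say
which cells hold an excess or deficit of ancient or recent lineages.
Hotspot/non-hotspot residual contrasts are summarized by the
Hodges-Lehmann estimate (the median of all pairwise differences,
enumerated exactly up to 10^6 pairs, seeded subsampling beyond) with a
rank-sum confidence interval, and by a spatial simultaneous autoregressive
(SAR) error model with the hotspot indicator as predictor.

# The range-evolution models

The state space has three areas — the focal realm's hotspot cells (H), its
non-hotspot cells (N), and everything else (E) — and ranges of at most two
areas, giving six states plus an absorbing null range.  Species are coded
by range fractions: a region with at least 20% of a species' cells scores
as present; if all three qualify the two largest fractions are kept (ties
resolved H > N > E and the coercion is logged); if none qualifies the
largest fraction wins.

Anagenetic evolution is a continuous-time Markov chain: single-area ranges
gain a second area at dispersal rate `d` per ordered area pair, every
occupied area is lost at extirpation rate `e`, and losing the last area is
absorbing.  Cladogenesis happens at nodes: `DEC` allows subset sympatry
and narrow vicariance at two-area parents, `DIVALIKE` vicariance only,
`BAYAREALIKE` copies the parent range to both daughters; single-area
parents always copy.  The founder (+J) variants add jump speciation — one
daughter moves to a single unoccupied area — with weight `j` against
weight 1 for each non-founder outcome, normalized within each parent's
outcome set (`describe_model()` prints the exact table).  The likelihood
is Felsenstein pruning with matrix exponentials on branches and the
cladogenetic distribution at nodes, rescaled per node; the root prior is
uniform over the six non-null states (configurable).  A brute-force
enumeration oracle pins the pruning implementation to machine precision on
all families for small trees.  AICc uses the tip count as sample size, and
the six fits are ranked with Akaike weights.

## Survival conditioning

A forward simulator of this process must do something when a lineage's
range dies before the present: ranges at the tips are observed, so the
generator redraws any branch whose range hits the null state (the redraw
count is reported).  That conditions every branch on range survival.  The
matched estimator must condition the same way — otherwise the data look
"too surviving" and the extirpation rate is driven to zero; we verified
the profile likelihood is monotone decreasing in `e` without conditioning
and peaks at the truth with it.  `condition_survival = TRUE` renormalizes
each branch's transition rows by one minus the null-state probability;
it is off by default (plain pruning, matching the oracle and the standard
convention) and switched on wherever data come from this package's own
generator.  Endpoint-conditioned branch path sampling is unaffected: given
non-null endpoints, paths never visit the absorbing null state.

# Stochastic mapping and rate series

Histories are sampled by a backward-forward pass: pruning stores the
conditional likelihood tables, joint node states and cladogenetic outcomes
are drawn root-to-tips, and branch paths conditional on their endpoint
states are drawn by uniformization (exact; no time discretization).  The
generator and the mapper share one history representation, so the event
extractor is identical for truths and maps — a conservation property the
tests exploit.

Events are binned into 2-Ma intervals on the 2-26 Ma window (younger bins
confound ongoing speciation; older bins hold too few lineages).  The
dispersal rate for a direction in a bin is the median event count across
maps divided by the median lineage count of the normalizing region in the
previous (older) bin; the normalizer defaults to the destination region,
with a source-normalized option.  Cladogenesis rates come in two
estimators: within-region event counts over previous-bin lineages, and the
time-weighted mean of per-branch speciation rates over the branch segments
assigned to the region (branch rates default to the mean tip DR below each
branch; externally estimated rates can be supplied by CSV).  Standardized
differences divide hotspot-minus-non-hotspot rates per map by the SD of
all rate values pooled over both series, bins and maps, and report the
across-map median with a 10th-90th percentile interval, per bin and
aggregated over the window.

Bins whose lineage denominator is at or below a floor are reported as
undefined, never zero.  The floor is configurable; 10 is the default for
paper-scale phylogenies (thousands of tips), while the bundled analyses
use 2-3 on their 120-200-tip trees — the floor should scale with how many
lineages the window can hold.

## What the directional-recovery experiments show

Destination-normalized dispersal rates measure per-capita immigration.  At
demographic equilibrium this inverts a raw rate asymmetry: a region fed by
threefold dispersal accumulates proportionally more lineages, deflating
its per-capita rate.  The recovery experiments therefore run in the
transient regime — hotspot colonization still ongoing inside the analysis
window (slow dispersal relative to tree depth, root in N) — which is also
the biologically relevant situation for recently assembled hotspots.  In
that regime the standardized difference recovers a simulated threefold
N-to-H excess and a simulated twofold hotspot speciation excess with the
correct sign in well over 90% of replicates (100-replicate experiments,
200- and 120-tip trees, 10-20 maps; both experiments root the clade in N,
the hotspot assembling from its surroundings, so that both regions hold
lineages throughout the window).  Away from that regime, per-capita
immigration rates of saturated regions are not expected to reflect the
underlying asymmetry, and conclusions should lean on the source-normalized
option.

# The spatial null and the environment

The size/shape control fits a Thomas cluster process (Poisson parents,
Gaussian-scattered offspring) to the hotspot cell centers by minimum
contrast on the translation-corrected Ripley K, using a coarse log-scale
grid search before a bounded polish — the contrast surface is multimodal
for blob-like patterns — with the parent intensity constrained to within a
factor ten of the point intensity so the fitted process stays simulable.
The offspring mean is set from the observed intensity.  Control hotspot
sets are simulated, snapped to grid cells, and repaired to the exact real
cell count (nearest-neighbor accretion, farthest-point trimming, ties by
cell id).  A statistic's rank among the controls is flagged outside the
two-sided 90% envelope; with 50 controls the exact flag rate for a
same-distribution statistic is 2 x 3/51, about 12%, which the calibration
test brackets.  Contiguity is each cell's median distance to same-class
cells within 1000 km, compared between classes by Welch's t test (a
perfect checkerboard yields t = 0 by convention).

Environmental predictors: terrain ruggedness (mean absolute difference
from the eight neighboring elevation pixels, averaged per cell),
climate-change velocity (temporal change over the local spatial gradient,
with the gradient floored at its first percentile so flat terrain cannot
blow up), and tectonic mobility (the pooled per-neighbor SD of
inter-cell distance series through time).  Variables with Spearman
correlation above 0.70 drop the later-listed member before modeling.  Each
remaining variable is centered, scaled, and fitted with the SAR error
model on the hotspot indicator; p values are Bonferroni-corrected across
the variable set.

## Neighbor radius and calibration

The 1000-km neighbor rule is meant for global grids.  On the synthetic
2000-km domain it connects half the grid, leaving the SAR autocorrelation
unidentified and the tests anti-conservative (measured type-I error 0.15
at nominal 0.05).  With first-order adjacency weights the same experiment
is calibrated (type-I 0.04; lambda recovered without bias), so the
synthetic analyses use adjacency-scale weights and the radius remains a
parameter for paper-scale data.  A related caveat: when the hotspot class
is one compact block, SAR contrasts are somewhat anti-conservative even
with adjacency weights (familywise rate near 0.09 at a nominal 0.05) —
few effectively independent spatial clusters carry the contrast — while a
scattered labeling is calibrated.  Fig.-4-style results on compact
hotspots should be read with that in mind.

# The synthetic study system

`sim_config()` fixes the study conditions: 150 species on a 20 x 20 grid
of 100-km cells split into two realm bands; a forward birth-death tree
(0.15 / 0.05 events per lineage per Ma, about 50 Ma root age) simulated
until the moment the (n+1)-th species would appear, which makes the mean
Yule root age equal the harmonic-sum expectation the tests check; DEC-type
range evolution with d = 0.05, e = 0.02; clustered hotspot blobs covering
20% of each realm grown by breadth-first accretion; lognormal range-patch
sizes with hotspot-restricted species drawn small (median 3 cells vs 8) so
weighted endemism concentrates where it should; and SAR-error environments
(lambda 0.5, innovation SD 1) with standardized hotspot effects of +1 on
productivity, +1 on ruggedness, -0.8 on climate-change velocity.  A joint
simulator with region-dependent speciation (`simulate_biogeo_tree()`)
provides ground truths where hotspot lineages genuinely speciate faster.

What the generator does not emulate: real continental geometry and
coastlines, spatially varying sampling effort, polygon-to-grid
rasterization artifacts, phylogenetic uncertainty (one fixed tree, not a
posterior set), and diversity-dependent feedbacks.  Passing tests
demonstrate that the estimators recover what this generative model plants,
not that any empirical pattern is correctly explained.

# Numerical choices

Matrix exponentials use scaling-and-squaring on the 7 x 7 generator;
pruning rescales per node and fails loudly on exactly-zero likelihoods.
ML fits run bounded L-BFGS-B on (d, e, j) in [1e-12, 5]^2 x [0, 3] with a
moderate fixed start, a nested-boundary start (j = 0) for founder models,
and optional jittered restarts; nesting violations beyond 0.01 log units
indicate a convergence failure, and the tests enforce that bound.  The SAR
profile likelihood searches lambda on the interval bounded by the
reciprocal extreme eigenvalues of the weights (computed once per weights
object through the symmetric similarity transform) and never forms a dense
(I - lambda W) during the search.  Uniformization caps the jump count at
10^4 per branch.  All generators are pure functions of their seed, and
per-stage seeds derive from the master seed by a fixed affine rule kept
below 2^31.

Problem sizes in the bundled experiments (100 replicates of 200-tip fits,
30 calibration datasets, 50 stochastic maps, 20-50 controls) were chosen
as the smallest sizes at which the statistical checks have comfortable
power; they are stated alongside each result the scripts print.

# Known limitations

Extirpation is weakly identified in these models even with matched
conditioning; expect wide uncertainty on `e` at a few hundred tips.  The
model-selection stage can prefer a mis-specified family when tip coding is
noisy (delineated rather than true hotspot membership) — the bundled
analysis shows exactly that, and it is a property of the method, not of
the implementation.  Destination-normalized dispersal series invert under
demographic equilibrium, as discussed above.  The cluster null degrades
to a flagged "weak clustering" fit when hotspots are a single compact
blob or near-Poisson scatter; control sets are still size-matched but
their spatial grain then comes mostly from the count-repair step.
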