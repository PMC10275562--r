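---
title: "Simulating temperature-dependent diversification: models, landscape, and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating temperature-dependent diversification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evospeed)
```

# The question

The evolutionary speed hypothesis (ESH) proposes that environmental kinetic
energy — temperature — raises rates of molecular and phenotypic evolution and
therefore rates of speciation, contributing to the latitudinal diversity
gradient. Correlations between present-day speciation-rate proxies and
temperature are weak and inconsistent, so `evospeed` takes the process-based
route: simulate clade diversification on a dynamic landscape under competing
assumptions about what drives population divergence, summarize the emergent
biodiversity patterns, and ask a classifier which assumption best explains a
given (pseudo-)empirical pattern.

# The eco-evolutionary model

Species are sets of populations on a gridded landscape; one population per
occupied cell. Each time step (nominally 170 kyr) applies, in a fixed order:

1. **Trait evolution.** Each population cluster carries a temperature
   optimum $T_i$ and a standardized body size $B_i$, both in $[0,1]$. The
   evolving unit is the *cluster*: gene flow homogenizes trait values within
   a contact cluster, which then receives one bounded-Brownian kick
   ($\mathcal{N}(0,\sigma)$, reflected into $[0,1]$; $\sigma_T$ and
   $\sigma_B$ independent). Evolving traits per isolated cell instead lets
   every cell adapt locally, producing indestructible generalist species
   that never fragment — the model only behaves as an allopatric-speciation
   model when connected populations share their trait values.
2. **Dispersal.** Each habitable unoccupied cell within the kernel's 0.999
   quantile of an occupied cell is colonized iff a Weibull(shape
   $\Psi = 2.5$, scale $\Phi$) draw is at least the planar distance to the
   nearest occupied cell; founders copy that source's traits and cluster.
3. **Clustering.** Population clusters are connected components of occupied
   cells at planar distance $\le d_c$. By default $d_c$ is the kernel mean
   $\Phi\,\Gamma(1 + 1/\Psi)$, floored at $\sqrt{2}\times$ the cell size so
   that diagonally adjacent populations always count as in contact
   (without the floor, small kernels fragment ranges into single-cell
   clusters purely through grid geometry).
4. **Divergence.** Isolated cluster pairs accrue genetic divergence $g$ per
   step:
   * M0 (time-only): $g = g_0$, drawn once per simulation from
     $U(0.01, 1)$;
   * M1 (temperature): $g = ((\hat T_i + \hat T_k)/2)^\lambda$ with
     $\hat T$ the mean standardized temperature across the cluster's range;
   * M2 (body size): $g = (((1-\hat B_i) + (1-\hat B_k))/2)^\lambda$;
   * M3 (both): each cluster's score is $((1-\hat B) + \hat T)/2$, and $g$
     is the pair mean of the scores raised to $\lambda$.

   Pairs returned to contact coalesce at 1 divergence unit per step,
   floored at zero, and merge when they reach zero (divergence to third
   clusters combined by the unweighted mean; max/min are available).
   A cluster that splits spatially yields fragments at divergence 0 from
   each other that inherit the parent's divergence to everyone else.
5. **Speciation.** Within a species, clusters are joined by edges wherever
   divergence $< S$; each connected component becomes a species. The
   largest-range component keeps the parent identity (ties to the lowest
   cluster label, for determinism).
6. **Abundance.** Site capacity $K = K_c e^{-A_j}$ with aridity $A_j$ and
   $K_c = 30{,}000$; thermal suitability gives
   $N_{ij} = K e^{-((T_i - T_j)/\omega)^2}$; the zero-sum rule rescales all
   populations in a site by $\min(N_j, K)/N_j$.
7. **Extirpation.** Deterministic at $\hat N_{ij} = 0$, otherwise with
   probability $1/(1 + e^{-\mu_d(\mu_t - \hat N_{ij})})$
   ($\mu_t = 500$, $\mu_d = 0.01$ by default — fixed across a campaign).
8. **Cleanup.** Species with no populations are logged extinct.

A run starts from one ancestral species at the first step and is *complete*
if it ends with 20–6000 extant species; global extinction or exceeding the
cap stop the run early.

Six parameters vary across a campaign, sampled with a six-dimensional Sobol
sequence: $S \in (2,10)$, $\lambda \in (2,5)$, $\omega \in (0.01, 0.035)$,
$\sigma_B \in (0.001, 0.02)$, $\sigma_T \in (0.001, 0.015)$,
$\Phi \in (330, 880)$ km.

## The ancestral species

The ancestor occupies one warm cell of the largest landmass — the cell
closest to the 0.85 temperature quantile rather than the absolute maximum,
because the hottest cell of the first step is the first climate to
disappear as the world cools. Its thermal optimum equals the cell's
temperature and its body size is 0.2: radiations typically start from
small-bodied, fast-life-history founders, and a mid-scale ancestor would
make body-size-dependent divergence (M2) unobservably slow at the run
lengths used here, starving the model-comparison of M2-class examples.

# The synthetic landscape

The generator emulates the structural features of Cenozoic
paleo-reconstructions without any external data:

* a **latitudinal cosine gradient** whose steepness grows through the run
  (default 22 to 44 degrees equator-to-edge): high latitudes cool while the
  tropics stay near a fixed equatorial temperature — the signature of
  Cenozoic gradient steepening;
* a **global anomaly curve**: a mild decline with multi-scale oscillations,
  slow enough that niches can track it by drift and range shifts;
* a static **zonal temperature wave** (default 3 degrees, wavenumber 2,
  slowly drifting) standing in for continental-scale climate asymmetry;
* random **terrain** under a 6.5 deg/km lapse rate;
* a standardized subtropical **arid belt** that lowers carrying capacity
  via $K = K_c e^{-A}$;
* a **continental ladder**: full-height meridional land strips separated by
  ocean channels of graded widths (default 2, 3 and 5 cells), with noisy
  coasts. Oceans are the decisive ingredient: on an all-land map the level
  sets of a smooth temperature field are connected curves, so ranges
  almost never fragment and allopatric speciation stalls. The graded
  widths matter because a channel only pumps speciation when it exceeds
  the contact distance *and* is still crossed occasionally — narrow
  channels serve small dispersal kernels, wide ones serve large kernels.
  Each strip spans all rows so species can track latitudinal climate
  shifts within their landmass (fragmenting the strips latitudinally
  produced mass extinction in development, because populations pinned on
  short landmasses cannot follow their climate).

Temperature and aridity are standardized to $[0,1]$ with bounds taken
jointly over *all* time steps (per-step bounds would erase the global
temperature curve that M1 and M3 depend on); a constant field maps to 0.5
by convention. Sea cells carry `NA` and are never habitable; there is no
ice mask and no plate tectonics. What the generator does **not** emulate:
real continental outlines and their drift, Koeppen-belt temperature
assignments, ice ages, orography-correlated aridity. Conclusions from
passing tests therefore concern the method, not the Earth.

# Summary statistics

`summarize_clade()` produces ~44 named statistics in the four classes used
for discrimination: Spearman correlations of per-tip metrics (equal-splits
ES, its inverse DR, fair-proportion ED, mean root distance MRD) with range
size, range temperature and body size; cell-level Spearman correlations of
richness, PD, MPD, MNTD and body-size moments with absolute latitude and
temperature, plus the |latitude| centroid of the cell-mean DR field;
moments of the body-size, temperature-niche and range-size distributions
with species-level trait correlations; and tree shape (Pybus–Harvey
$\gamma$, Sackin's index normalized by tip count, clade size). Conventions
that differ across the literature are fixed as: MRD counts the edges on
the root-to-tip path (root included, tip excluded); assemblage divergence
metrics need $\ge 2$ species per cell and are excluded pairwise otherwise;
correlations need $\ge 3$ complete pairs; latitude enters as absolute
latitude. Highly collinear statistics are pruned greedily at
$|r| > 0.90$ (the pair's worse member — larger mean absolute correlation —
is dropped first, ties alphabetically).

# Model selection

Classifiers are trained on the summary vectors of parameter sets whose
runs completed under *all four* models, so classes are balanced by
construction. Seven families are available through their native packages
(linear discriminant, CART, random forest, gradient-boosted trees, naive
Bayes, RBF-kernel SVM, single-hidden-layer network), behind one interface:
training-median imputation and centering/scaling fitted on the stratified
two-thirds training split only, hyperparameters tuned by repeated
stratified 10-fold cross-validation, and all reported metrics (confusion
matrix, accuracy, Cohen's $\kappa$, per-class sensitivity/specificity)
from the untouched test third. Per-clade class probabilities are combined
across algorithms weighted by holdout $\kappa$ (negative $\kappa$ floored
at zero; probabilities, not votes, are averaged). Variable importance uses
permutation importance as the common currency across families, scaled to
$[0,100]$ per algorithm and $\kappa$-averaged.

# Correlative baseline

Per clade with more than 20 species, four key Spearman coefficients
(richness ~ |latitude|, richness ~ temperature across cells; DR ~ body
size, DR ~ temperature across species) are Fisher-transformed
($z = \mathrm{atanh}\,\rho$, variance $1/(n-3)$, $|\rho| = 1$ clipped to
$1 - 10^{-6}$) and pooled with a random-effects model: $\tau^2$ by REML
(tolerance $10^{-10}$, $\le 100$ iterations, via metafor), inverse-variance
weights, normal reference distribution for the pooled $Z$ — matching the
reporting convention of $Z/P$ pairs. DerSimonian–Laird is the documented
fallback when REML fails.

# Numerical choices and problem sizes

* Bounded Brownian motion uses reflection, not truncation (truncation is a
  config option); reflection preserves the step-size distribution near the
  bounds.
* The dispersal search radius is capped at the kernel's 0.999 quantile
  (colonization mass beyond it is under 0.1%).
* The M0 rate is one $U(0.01, 1)$ draw per simulation, making M0 a
  rate-matched null whose $g$ is constant given state like M1–M3's; a
  per-step redraw is available (`m0_draw = "per_step"`).
* Sobol points are generated from the standard direction-number table with
  Gray-code ordering, starting at index 1 so every coordinate is strictly
  inside its range; scrambling is deliberately absent for reproducibility.
* Per-run seeds come from a documented multiplicative hash of
  (base seed, parameter id, model index), collision-checked per campaign.
* The test suite and the analysis scripts use a 36 x 18 landscape with 120
  steps and a 48-point Sobol design; these sizes keep a full campaign in a
  few minutes while still producing clades of tens to hundreds of species.
  The phylogenetic oracle suites use 100 random trees of up to 12 tips,
  where brute-force path enumeration is exact.

# Known limitations

* At this landscape scale, parameter sets with the largest dispersal
  kernels ($\Phi \gtrsim 700$ km) rarely complete: a 36-cell-wide map
  cannot hold many barriers wider than their contact distance, so their
  worlds stay effectively connected. The completeness filter removes such
  sets; at full scale the paper-sized campaign does not have this problem.
* Divergence-model discrimination at this scale rests on a few dozen
  training rows; holdout accuracy is tested against chance, not against
  the full-scale accuracy range.
* No within-cluster gene-flow structure, no population-size feedback on
  divergence rate, no founder effects beyond trait copying.
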