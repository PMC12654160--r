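---
title: "Methods: soil phosphorus, enzyme stoichiometry and microbiome analysis with soilpem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil phosphorus, enzyme stoichiometry and microbiome analysis with soilpem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilpem)
library(dplyr)
```

`soilpem` implements the complete computational chain used to analyse
long-term fertilization trials that ask how organic and inorganic phosphorus
sources shape soil bioavailable P, extracellular enzyme stoichiometry, the
soil microbiome, and ultimately crop yield. The package covers five
treatments — an unfertilized control (CK), optimized fertilization (OPT), and
its +50% N (OPTN), +50% P (OPTP) and straw-returning (OPTM) variants — in a
randomized design with four replicates, and it ships a seeded synthetic-data
generator so that every stage can be exercised and tested without access to
field data.

## The synthetic study

`generate_dataset(generator_config(seed = ...))` draws a full study:

* **Soil chemistry.** Per-treatment normal draws centred on the trial's
  published treatment means (pH, SOM, TN, TP, AK, AP, AN, WEOC, NO3-N, MBC,
  MBN, MBP). The published dispersions are standard errors with n = 4, so the
  generator uses SD = SE × √4. Draws are floored at zero (concentrations
  cannot be negative); when a mean is small relative to its SD — AP under the
  control, for instance — the floor shifts the realised mean up toward the
  truncated-normal expectation μΦ(μ/σ) + σφ(μ/σ), which is what the
  convergence tests compare against.
* **Enzyme activities** (BG, CBH, NAG, LAP, ALP, nmol h⁻¹ g⁻¹ dry soil).
  Log-normal draws parameterised by arithmetic mean and CV (default 0.08), so
  configured treatment-mean ratios hold exactly in expectation. The defaults
  encode the study's contrasts — OPTM/OPT ratios of 1.2274 (BG), 1.4090
  (CBH) and 1.1809 (NAG) — and ALP declining under fertilization. LAP means
  are *derived* from target mean vector angles (CK 24.67°, OPT 23.8°, OPTN
  23.4°, OPTP 21.86°, OPTM 22.9°) by inverting
  tan(angle) = (C + ALP)/(C + N); this pins the ecoenzymatic vector analysis
  to the reported angle window. A consequence of that anchoring is that the
  generator's LAP means rise slightly with fertilization: with the C pool
  growing and ALP falling, a sub-45° angle can only be preserved by a larger
  N-enzyme pool. We accepted this compromise because the angle window is
  quantitative while the LAP trend is qualitative; both cannot hold in this
  parameterisation.
* **P fractions** (CaCl₂-P, Citrate-P, Enzyme-P, HCl-P, mg kg⁻¹). Normal
  draws (CV 0.10) with flat CaCl₂-P and treatment contrasts for the other
  three (e.g. Citrate-P: CK 17.70 rising to 31.83 under OPTM; Enzyme-P
  OPTM/OPT = 1.6264). The published Enzyme-P range and its percent contrasts
  are mutually inconsistent; the percent contrasts win and the range is
  treated as advisory (defaults: CK 2.33, OPT 2.30, OPTN 2.50, OPTP 4.26,
  OPTM 3.74).
* **OTU tables.** Dirichlet-multinomial counts per sample (default depth
  10,000, concentration 200) over log-normal base compositions for 400
  bacterial, 160 fungal and 55 archaeal taxa — proportions chosen so pooled
  network nodes split roughly 65/26/9% across domains. A responsive 25% of
  taxa is amplified under fertilization (multipliers 1.0–1.6), and 50 rare
  bacterial taxa are switched on by fertilization (strongest under OPTM),
  which makes fertilized subnetworks larger — the qualitative behaviour the
  network stage is tested against.
* **Yield.** A linear model on centred SOM and AP, their interaction, a
  bacterial Shannon-diversity term, and Gaussian noise (defaults: intercept
  6, b_SOM 0.25, b_AP 0.015, b_int 0.004, b_div 0.4, σ 0.35; unitless scale,
  since no per-plot yields are published). The interaction default was chosen
  so that its sign is recoverable with power > 0.8 at the design's n = 20
  while keeping CK lowest and OPTM highest in expectation.

What the generator does *not* emulate: spatial field structure, temporal
dynamics of the 16-year trial, sequencing error, and compositional coupling
between chemistry and the microbiome beyond the yield model. Tests passing on
synthetic data therefore demonstrate correctness of the computations, not
field realism.

`spike_network_structure()` plants known co-occurrence modules: each group of
taxa shares a Gaussian latent factor whose loading is chosen by inverting the
Gaussian-copula rank-correlation identity ρ_s = (6/π)·asin(r/2), so the
population Spearman correlation within a group equals the requested strength.
(Sample Spearman at n = 20 is biased a few percent below the population
value; tests account for this.)

## Ecoenzymatic stoichiometry

For each sample, with C = BG + CBH, N = NAG + LAP, P = ALP:

* ratios: E_C:N = ln C / ln N, E_C:P = ln C / ln P, E_N:P = ln N / ln P.
  A pool sum ≤ 1 makes a log-ratio sign-unstable; such samples are flagged
  (NA) with a warning rather than silently transformed, and are excluded
  from group means.
* vector analysis: x = C/(C+P), y = C/(C+N), length = √(x²+y²), angle =
  two-argument arctangent of the point (x, y) from the x-axis, in degrees.
  The angle convention matters: with atan2(y, x), "angle > 45° means P
  limitation, < 45° N limitation" holds, because y > x exactly when the
  P-enzyme pool exceeds the N-enzyme pool relative to C. Longer vectors mean
  stronger C limitation. `vector_summary()` adds per-treatment means ± SE
  with Duncan letters and the angle~length regression.

`fluorescence_to_activity()` reduces a fluorometric plate: emission
coefficient from reference-standard wells (fluorescence per nmol), quench
coefficient = (quench standard − blank)/reference standard, net fluorescence
= assay − blank − negative control, scaled by incubation time, the
homogenate/aliquot volume ratio and dry soil mass. Negative net signal is
floored at zero and the exact assay constants are arguments, since plate
protocols vary.

## Treatment statistics

`one_way_anova()` is the classical fixed-effects decomposition (block is not
modelled as a factor; the design is treated as one-way). `duncan_letters()`
implements Duncan's multiple range test from studentized-range quantiles at
protection level 1 − (1 − α)^(span − 1), with the standard containment rule
and insert-and-absorb letter assignment; unbalanced groups use the harmonic
mean of group sizes, and ties in means are broken by input order so output is
deterministic. `duncan_from_summary()` reconstructs MSE = n·mean(SE²) from
printed tables under homoscedasticity, which is how letter patterns of
published summary tables are approximately reproduced.

## Diversity and ordination

Shannon (natural log), bias-corrected Chao1, and Bray–Curtis dissimilarity
are computed from raw counts; counts are used as relative abundances without
rarefaction by default (a seeded `rarefy_features()` is available). NMDS
delegates to `vegan::metaMDS` behind a seeded wrapper; stress is reported and
coordinates are identified only up to rotation. Bray–Curtis is used for
ordination throughout because no phylogenetic tree is available to the
package, so UniFrac-based ordination is out of scope.

## Co-occurrence networks

`correlation_screen()` pools the three domains, drops features present in
fewer than 20% of samples (rank-tie pathologies otherwise dominate), computes
pairwise Spearman correlations on relative abundances, takes p from the t
approximation with average ranks for ties, and retains |ρ| > 0.75 with
p < 0.01. The absolute-value reading keeps negative associations (with sign
retained as edge weight); `positive_only = TRUE` restores the literal
positive-only reading. No multiple-testing correction is applied by default,
matching the stated thresholds. At n = 5 the t approximation deviates from
the exact permutation null by up to ~0.08 in p; at the n = 20 design it is
adequate for a screening threshold.

Modules come from seeded multilevel (Louvain) modularity optimization on the
unweighted graph; modularity values are algorithm-dependent, so the algorithm
and seed are part of the reported metadata. Topology metrics: average degree
2E/N (the complexity measure), average path length and diameter on the
largest connected component, mean local clustering with degree ≤ 1 nodes
contributing zero. `zi_pi()` computes within-module degree z-scores (Zi = 0
when a module's degree SD is zero) and the participation coefficient
Pi = 1 − Σ(k_is/k_i)², and classifies peripherals (Zi < 2.5, Pi < 0.62),
connectors (Pi > 0.62), module hubs (Zi > 2.5) and network hubs (both), with
network hub taking precedence. Subnetworks are induced by node presence:
a treatment's subnetwork keeps nodes with nonzero total count in that
treatment's samples.

## Associations

`mantel_test()` is a permutation procedure: r correlates strictly-lower-
triangle entries (Pearson by default), the null permutes rows and columns of
the second matrix simultaneously, and p = (1 + #{r* ≥ r})/(n_perm + 1),
one-sided "greater" — the standard alternative for Mantel tests. An
exhaustive mode enumerates all n! relabellings for n ≤ 7 and is used as its
own oracle in tests. `mantel_panel()` tests community Bray–Curtis distance
against Euclidean distance on each z-scored environmental variable.
`correlation_panel()` maps p to stars exactly as *, **, *** for p < 0.05,
0.01, 0.001. `yield_glm()` fits Gaussian OLS of yield on centred SOM, AP and
their interaction; centring leaves the interaction coefficient unchanged
(asserted numerically in the tests) and is the default because it keeps main
effects interpretable.

## Latent models

`plspm_fit()` is an in-package implementation of PLS path modelling:
indicators standardized, mode A (reflective) outer updates, centroid inner
scheme by default (factorial available), Lohmöller iteration until the
maximum outer-weight change falls below 1e-7 (default cap 300 iterations,
non-convergence is fatal). Latent scores are unit-variance and sign-anchored
so each block's mean loading is positive — sign indeterminacy is otherwise
the main numerical hazard. Path coefficients are OLS fits of each endogenous
latent on its predecessors; GoF = √(mean communality × mean R²). Note that
PLS path estimates between composites are attenuated relative to true latent
structural coefficients when loadings < 1 (e.g. a true 0.7 with loadings 0.9
on three indicators fits near 0.65); the parameter-recovery tests use the
±0.1 band that this attenuation respects. `plspm_bootstrap()` resamples rows,
aligns each refit's latent orientation to the full-data fit via the
weight-vector dot product, and reports percentile intervals and a two-sided
percentile-of-zero p-value.

`rf_importance()` fits a regression forest (`randomForest`, mtry = ⌊p/3⌋,
1000 trees by default) and reports %IncMSE — the permutation increase in
out-of-bag MSE expressed as a percentage of the OOB MSE. Significance uses
response permutation: the forest is refit on permuted responses and the
observed standardized importance is located in its null distribution,
p = (1 + #{null ≥ obs})/(n_perm + 1). Under a null response this p-value is
exact by exchangeability; the calibration tests verify rejection near 0.05.

## Pipeline

`run_pipeline(pipeline_config(...))` chains the stages from one config,
refuses to run when validation finds fatal issues (missing samples, missing
or negative values), derives per-stage seeds from the global seed by a fixed
counter scheme (`stage_seed()`), and writes one TSV per result plus a
`manifest.yaml`; identical config and seed give byte-identical outputs. The
default PLS-PM block structure is fertilization doses → P fractions →
{enzymes, microbial community} → yield, fully overridable via
`plspm_spec()`.

## Problem sizes used in tests

The test suite and the acceptance script run the generator at 60–75 taxa and
3,000 reads per sample (enzyme and chemistry draws are unaffected by taxon
count), 100–200 replicates for convergence checks, 100–300 simulations for
null calibrations (n_perm = 99–199), and n = 500 for PLS-PM parameter
recovery. These sizes were chosen as the smallest at which the Monte-Carlo
error is well inside each check's tolerance.

## Known limitations

* Real-data mode expects complete tables; missing cells are fatal for ANOVA
  inputs and dropped pairwise in correlations.
* The Spearman screen's t-approximate p is anti-conservative at very small n.
* PLS-PM supports reflective (mode A) blocks only; no formative blocks or
  multi-group comparisons.
* No compositional correction (SparCC-style) in the network stage; Spearman
  on relative abundances is what the thresholds were defined for.

```{r example, eval = FALSE}
ds <- generate_dataset(generator_config(seed = 1))
vs <- vector_summary(ds$enzymes, ds$metadata)
vs$by_treatment

edges <- correlation_screen(ds$features)
net <- detect_modules(build_network(edges, ds$features), seed = 1)
glance(net)
keystone_report(zi_pi(net), ds$features)$domain_composition
```
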