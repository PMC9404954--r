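---
title: "Models and methods behind cercodent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cercodent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

cercodent implements an analysis chain for genotype:phenotype-mapped
dental traits in cercopithecid monkeys: trait computation from crown
metrics, pedigree heritability, phylogenetic signal and ANOVA, ancestral
state reconstruction (ASR), and the comparison of ancestral estimates with
fossil observations. This vignette records the models, the parameters that
matter, the numerical choices, and what the validation suite does and does
not establish.

## Trait computation

Four traits are derived from mesiodistal length (L) and buccolingual
breadth (W), in mm, of the maxillary P4 and M1–M3: 2D crown area (L × W,
mm²), MMC = L(M3)/L(M1), PMM = L(M2)/L(P4), and IC = area(M3)/area(M1)
(dimensionless ratios). Ratios are computed **within specimens** — both
component teeth measured on one side — and only then averaged. We chose
this over ratios of group means because the published per-trait sample
sizes for the ratio traits differ from the per-tooth area sample sizes,
which is only possible if each ratio was restricted to specimens
preserving both components. Side resolution is left-preferred per trait:
left values are used when every component tooth is present on the left,
otherwise the right side is used if complete there; sides are never mixed
within a trait (a property test drives random missingness patterns through
this rule).

Aggregation to taxa is two-level and unweighted: specimens → species mean
→ genus mean, so a heavily-sampled species cannot dominate its genus.
Geometric-mean size correction (each molar area divided by the geometric
mean of the three areas of that observation) is applied to the genus-level
area values entering the comparative analyses; the ratio traits are
already size-free. Kurtosis in descriptive summaries is the Pearson
(non-excess) moment ratio m₄/m₂², under which a normal sample is near 3
and any non-constant sample is ≥ 1. Interstitial wear is not modelled.

## Pedigree heritability

The additive relationship matrix A (twice the kinship coefficient) is
built by the tabular method: founders unrelated and non-inbred,
`A[i,i] = 1 + A[sire,dam]/2`, `A[i,j] = (A[j,sire] + A[j,dam])/2`.
The trait model is y ~ N(Xβ, σ²G·A + σ²E·I), fitted by **maximum
likelihood**, not REML — the halved-boundary likelihood-ratio framework we
mirror is ML-based. The known consequence is a small downward bias in σ²G
at modest sample sizes; the recovery suite bounds the mean bias of ĥ² by
0.05 at n = 600.

Numerically, A (restricted to phenotyped individuals) is eigendecomposed
once; in the rotated basis the covariance is diagonal in
h² = σ²G/σ²P, and β and σ²P have closed-form profiles, leaving a 1-D
bounded optimization over h² ∈ [0, 1) solved by Brent's method
(deterministic, no restarts, tolerance 1e-8). The standard error of h²
comes from the curvature of the profile likelihood (central differences,
step 1e-4) and is flagged unreliable within 0.02 of a boundary. If A has
no off-diagonal structure (≈ identity) the model is unidentifiable and the
fit says so.

Covariates (sex; age as a linear term, a rough proxy for wear) are
screened within the same likelihood by non-boundary χ²₁ LRTs at α = 0.05,
on the raw trait scale; the residuals of the retained mean model are then
rank-normalized (Blom offsets, `qnorm((r − 3/8)/(n + 1/4))`, mid-ranks for
ties) before the final variance decomposition. The source analysis does
not state whether screening preceded normalization; we screen first
because the transformation is explicitly described as applied to
*residuals*. The boundary LRT for h² halves the χ²₁ tail probability and
returns p = 0.5 at a zero statistic. The "proportion of variance due to
covariates" is 1 − var(residual)/var(raw), clamped to [0, 1] with a
warning.

## Comparative methods

All tree machinery works on `ape::phylo` chronograms (branch lengths in
Ma), validated on read: unique tips, non-negative branches, ultrametricity
to a relative tolerance of 1e-6 of tree depth (failure is a carried
warning flag, not an error, since published chronograms are often
near-ultrametric after rounding). Taxa missing from a molecular tree are
grafted onto a sister tip at a published split age (both daughter branches
equal to the split age, preserving ultrametricity). Polytomies are
resolved with zero-length branches, which leaves the Brownian covariance
unchanged.

**Blomberg's K** is computed exactly as the observed MSE₀/MSE ratio
(deviations about the GLS phylogenetic mean, ordinary vs
V-weighted) over its Brownian expectation `(tr(V) − n/Σ(V⁻¹))/(n − 1)`.
Significance comes from permuting tip values and comparing the variance of
standardized independent contrasts, `p = (1 + #{perm ≤ obs})/(1 + n_perm)`
— the +1 smoothing means 0 is never reported. Defaults: 999 permutations,
minimum 99. The implementation is cross-checked in tests against an
independent library computation of K, and calibrated on Brownian
simulations (mean K within [0.9, 1.1] at 500 replicates).

**Phylogenetic ANOVA** compares the ordinary one-way F of tip values by
genus against F statistics from Brownian simulations on the tree, with the
rate estimated from the data by independent contrasts (mean squared
standardized contrast). Per-genus p-values are not specified by the
original account; we implement them as two-sided simulation tests of each
genus mean's deviation from the grand mean, and flag this as an
interpretation. The p-value is invariant to affine transformation of the
trait (the F statistic and the simulated rate both scale away), which the
suite asserts.

**ASR** under Brownian motion: each internal node's ML estimate is the GLS
root mean of the tree re-rooted at that node, computed directly from the
node-to-tip path-length matrix as V_r(i,j) = (d(r,i) + d(r,j) − d(i,j))/2
— no tree surgery required. Estimation variance is σ̂²·(1ᵀV_r⁻¹1)⁻¹ with
σ̂² the ML Brownian rate at the original root; 95% CIs are ±1.96 SD. Tests
pin these estimates to a brute-force grid maximization of the joint BM
likelihood (and to a graph-Laplacian solve) on small trees, and to an
established implementation on larger ones. Because each estimate is a
convex combination of tip values, reconstructions cannot leave the extant
range — this is asserted directly on random trees, and it is the mechanism
behind the fossil-gap result: when a trait trended through time, ancestral
estimates built only from living taxa must miss the fossils.

Internal nodes are addressed by the MRCA of a tip set, never by node
numbers, which are an artifact of traversal order and not portable between
programs.

## The fossil gap

Pairings of ASR nodes with candidate fossil genera carry two explicit
subset flags rather than hard-coded rules: an 11-pairing mean subset (the
internal-node pairings, over which per-trait mean |ASR − fossil| is
reported) and a 12-pairing direction subset (tip pairings included, the
deepest pairing — the stem-cercopithecid one — excluded), because the
published "all but two are lower" count reconciles only under that
reading. Ties count as "not lower". Reported aggregates are rounded to 3
decimals half-up, matching the printed convention; unrounded values are
kept alongside.

## Synthetic data

The simulators define the validation conditions:

- **Pedigrees**: non-overlapping generations, random mating avoiding full-
  and half-sib pairs (colonies are managed against inbreeding), 2:1
  female:male offspring ratio, ages decreasing by generation. Each
  generation adds `mean_offspring` per accumulated member, so expected
  size is `n_founders (1 + m)^(g−1)`; validation uses 96 founders × 3
  generations ≈ 600 individuals, matching the scale of the pedigreed
  colony sample.
- **Traits on pedigrees**: breeding values by the Mendelian-sampling
  recursion (founders N(0, σ²G); offspring midparent plus a deviation of
  variance σ²G(½ − (F_s + F_d)/4)), which realises cov(g) = σ²G·A without
  factorizing A — full-sib covariance is verified against theory on 5000
  sib pairs. Sex and age effects enter in phenotypic-SD units.
- **Crown metrics**: specimens constructed to hit target MMC/PMM/IC
  exactly at zero noise, then perturbed by lognormal noise. The default
  coefficient of variation of 0.05 reflects typical odontometric
  repeatability; ratio targets near 1.0–1.8 match the observed genus
  ranges.
- **Clades**: one BM realization recorded at every node, fossils =
  true node state + observation noise − trend × node age, so truth is
  available for recovery tests. Zero trend gives centred ASR-fossil gaps;
  a negative trend (trait decreasing toward the present) reproduces the
  systematic under-estimation pattern.

What passing these tests shows — and does not. The simulators emulate the
covariance structure the estimators assume (additive genetic covariance,
Brownian motion, lognormal measurement error). They do not emulate
selection, rate heterogeneity, wear, taphonomic filtering, or correlated
sampling of museum collections; calibration under the model says nothing
about robustness to violations of it, which is precisely why the
fossil-gap comparison against real printed values matters.

## Problem sizes and determinism

Every generator and every Monte-Carlo routine is deterministic under
`set.seed()`. The validation suite uses: heritability recovery at n = 600
with 50 replicates per true h² in {0, 0.3, 0.6, 0.9}; null-p calibration
at 500 replicates; K calibration at 500 Brownian replicates on a 20-tip
chronogram; ANOVA type-I error over 200 replicates with 199-simulation
nulls; and 200 simulated clades per trend regime on a 16-tip tree. These
sizes give Monte-Carlo error comfortably inside the asserted tolerances
while keeping the full suite under a minute of compute.

## Known limitations

- ML variance components are biased low in σ²G for small n; REML is not
  provided.
- Shared-environment (cage/household) variance is not modelled; h² may be
  inflated when it matters.
- No Ornstein-Uhlenbeck or multi-rate Brownian models; K and the ASR both
  assume a single rate.
- Bivariate genetic correlations between traits are out of scope.
- The ANOVA per-genus p-values are an interpretation (see above), not a
  published formula.
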