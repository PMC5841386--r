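---
title: "Scoring individual cortical atrophy patterns: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring individual cortical atrophy patterns: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Alzheimer's disease (AD) thins the cortex in a characteristic spatial
pattern — medial temporal, temporoparietal, posterior cingulate and
precuneus regions more than elsewhere. Group studies establish that
pattern; the clinical question is individual: *how AD-like is this one
person's cortical thinning, today, and is it getting worse?* atroscore
implements a pipeline that answers this with a single interpretable score
per scan, built from per-vertex cortical thickness sampled on a
triangulated surface with vertex correspondence across subjects (the
situation produced by surface registration and resampling, e.g. 40,962
vertices per hemisphere). Surface reconstruction and registration
themselves are out of scope: inputs are assumed vertex-corresponded.

The pipeline has four modelling stages, each exposed as ordinary R
functions returning classed objects:

1. **Spectral denoising.** Thickness is noisy at the vertex scale. The
   manifold harmonic transform (MHT) expands the thickness field in
   eigenfunctions of the surface's Laplace–Beltrami operator; high-frequency
   coefficients are treated as noise and discarded, exactly as a Fourier
   low-pass filter would on a flat domain.
2. **Normative w-scores.** Filtered thickness is converted to
   `w = (observed − predicted) / residual SD`, where the prediction is a
   per-vertex ordinary least squares regression on age and years of
   education fitted on cognitively normal (CN) subjects only. A w-score of
   −2 means the cortex is two residual standard deviations thinner than
   expected for that person's demographics.
3. **PCA → LDA classification.** W-score vectors are reduced by PCA and a
   two-class Fisher discriminant separates AD from CN. The LDA axis is
   `Sw⁻¹(μ_AD − μ_CN)` in PCA space with a small ridge on the within-class
   scatter; it is oriented so AD projects above CN.
4. **Similarity score.** A subject's signed coordinate on that axis,
   affinely anchored so the CN training mean maps to 0 and the AD training
   mean to 100, is the AD-specific atrophy similarity. Scores are not
   clipped: atrophy more extreme than the AD training mean legitimately
   scores above 100.

Longitudinal validation uses random-intercept linear mixed models
(similarity × time on clinical outcomes; group × time on similarity) and
rule-based cohort labels (aMCI converters vs non-converters, AD fast vs
slow decliners).

## Discretization of the Laplace–Beltrami operator

The stiffness matrix uses cotangent weights,
`K_ij = −(cot α_ij + cot β_ij)/2` for the two angles opposite edge *(i,j)*,
with diagonal entries making rows sum to zero; the mass matrix is the
barycentric lumped one, `m_i = (1/3) Σ area(adjacent triangles)`. This is
the canonical discretization in the manifold-harmonics literature: it is
symmetric, positive semidefinite, exact for constants, and its generalized
eigenproblem `Kφ = λMφ` yields eigenfields orthonormal under the mass
inner product `⟨f,g⟩ = Σ m_v f_v g_v`. Degenerate (zero-area) triangles are
a hard error rather than being skipped: they indicate a broken mesh
upstream, and silently patching them would bias the operator.

**Eigensolver.** We solve the dense symmetric problem
`M^{-1/2} K M^{-1/2}` with LAPACK and keep the smallest *k* eigenpairs. At
the resolutions this package targets for testing and simulation (up to the
subdivision-4 icosphere, 2,562 vertices) a dense solve is exact, fast, and
avoids the convergence tuning an iterative shift-invert solver needs. The
cost is cubic in vertex count, so full-resolution (40,962-vertex) meshes
would want a sparse iterative eigensolver; the operator construction
already returns sparse matrices, so only `compute_basis()` would need the
alternative backend. Eigenvector signs are fixed by convention (constant
mode: positive mass-weighted sum; others: first non-negligible entry
positive) so spectral coefficients are reproducible across solvers and
platforms.

**How many modes to keep.** The number of retained harmonics is the one
genuinely free parameter of the denoising stage, and we deliberately expose
it (`k_keep`, CLI flag `--modes`) instead of hard-coding it. On the
642-vertex test spheres the pipeline default is 40 modes, which keeps
spatial wavelengths down to roughly the atrophy-patch scale while removing
vertex-level noise; at 40,962-vertex resolution a few hundred modes per
hemisphere plays the same role. The tests demonstrate the filter's
properties rather than a particular cutoff: idempotence, energy
non-increase, exact reconstruction at full basis, and lower RMS error than
the unfiltered map when a smooth signal is corrupted by white noise.

## Normative model choices

* Fitted on CN subjects only, never patients — the normative convention;
  including patients would absorb disease effect into the "normal" slope.
* Covariates are age and education only, entered linearly, per vertex,
  with residual SD on `n − 3` degrees of freedom. No spatial pooling: the
  simplest model consistent with a per-vertex w-score.
* Degenerate vertices (zero residual variance, possible in synthetic data)
  are flagged and their SD floored at 10⁻⁶ mm rather than producing
  infinite w-scores.
* Two identities make good tests and are asserted exactly: training
  w-scores have per-vertex mean 0, and a subject whose thickness equals its
  prediction scores exactly 0. The sample SD of training w-scores is
  `√((n−3)/(n−1))` — slightly below 1 because the residual SD uses the
  regression degrees of freedom.

## Classifier and similarity conventions

* **PCA dimension.** Default: the smallest dimension explaining ≥ 90% of
  training variance, capped at `n − 2`; an explicit dimension can be given.
  The cap keeps the within-class scatter invertible territory; the ridge
  `10⁻⁶·trace(Sw)/d` guards the boundary.
* **Decision threshold.** Midpoint of the class-mean projections, with a
  projection exactly on the threshold called CN — a documented,
  deterministic tie rule.
* **Similarity orientation.** A literal distance to the AD mean would
  *decrease* as a subject becomes more AD-like, inverting the intended
  reading. We therefore report the signed LDA coordinate anchored CN→0,
  AD→100. The anchoring makes the score invariant to any affine
  recalibration of the axis, and the raw coordinate is reported alongside
  for transparency.
* **Discriminative map.** The LDA axis composed back through the
  orthonormal PCA axes gives one weight per vertex. We flip its sign so a
  positive weight reads "thinning here pushes toward AD" (thinning lowers
  the w-score). The per-subject Z-map standardizes the vertex-wise product
  of the raw axis weight and the subject's w-score — each vertex's additive
  contribution to the LDA projection — to mean 0, SD 1 across vertices.
* **Cross-validation.** Folds are stratified by diagnosis, and the
  normative model, PCA and LDA are all refit inside each training fold with
  w-scores recomputed per fold. Refitting everything inside the fold is the
  only leakage-free reading of "train on 90%, test on 10%".

## Longitudinal models

Fixed effects are `[1, predictor, time, predictor × time]` with a random
intercept per subject, fit by REML through lme4. Time is coded in years
from baseline, uncentered; the similarity predictor enters as the subject's
baseline score (time-invariant), so the interaction is a subject-level
modifier of the outcome's rate of change. P-values are large-sample Wald
normal — an approximation we document rather than hide; with the visit
counts used here (hundreds of observations) it is close to the t reference,
and the type-I error simulation in the test suite checks the realized size
at α = 0.05 stays within its binomial band. A random intercept (no random
slope) is the minimal structure consistent with "patient as a random
effect"; with 2–4 visits per subject a random slope is weakly identified
anyway.

Labeling rules are pure functions of a subject's visit table: conversion
requires an AD diagnosis within the first follow-up year with no subsequent
reversion inside that window; fast decline requires the CDR-SB to rise by
*strictly* more than 5 points from baseline to the year-3 visit (a change
of exactly 5 is slow decline).

## What the synthetic cohorts emulate — and what they do not

`generate_cohort()` builds thickness as a shared smooth baseline field
(synthesized in the low-order harmonic span, 2.5 ± 0.3 mm) plus linear age
(−0.01 mm/y) and education (+0.002 mm/y) effects, a group-specific atrophy
patch (Gaussian geodesic falloff, depth 0.6 mm at severity 1, radius 50 mm
on an 80 mm sphere — about a tenth of the surface, comparable in extent to
the temporoparietal atrophy signature), per-subject smooth noise, and white
measurement noise (0.1 mm). Age and education distributions follow a
typical memory-clinic sample (CN 65.4 ± 9.0 y and 11.7 ± 4.9 y of
education; AD 73.0 ± 9.4 y and 9.4 ± 5.3 y). Geodesic distances are graph
shortest paths along mesh edges, adequate at icosphere resolutions; smooth
noise lives in the same harmonic span the filter retains, so the denoising
claim is tested on-model while the white component is off-model.

The longitudinal generator mirrors the two validation designs: 53
non-converters + 26 converters with baseline and year-1 visits (converters
diagnosed AD at year 1), and 14 slow + 13 fast decliners followed yearly to
year 3 with CDR-SB slopes of 0.8 vs 2.2 points/y (so the fast group's
three-year change of ≈6.6 clears the >5 rule at the simulated 0.3-point
visit noise).

What passing tests on these cohorts shows: the operators, transforms,
regressions, discriminant, score and models do what their definitions say,
recover known generating parameters, and hold their error rates under the
null. What it does not show: performance on real cortical surfaces — a
sphere has no folding geometry, no spatially varying vertex density, no
registration error, no scanner effects, and the real AD pattern is not a
single Gaussian patch. Published headline numbers from clinical cohorts
(e.g. accuracy near 91% for AD vs CN) depend on those private data and are
not reproducible from simulations; we therefore validate properties, not
clinical effect sizes.

## Problem sizes and numerical tolerances

Tests and the acceptance script use subdivision-2 and -3 icospheres (162
and 642 vertices) for cohort work and subdivision 4 (2,562 vertices) for
the sphere-spectrum check, with cohorts of 100 + 100 subjects and
longitudinal samples matching the design sizes above — small enough for a
laptop CPU, large enough that every statistical check has power. Exact
identities are asserted at 10⁻⁸–10⁻¹⁰; eigenvalue agreement with the
analytic unit-sphere spectrum `l(l+1)` is required within 5% for `l ≤ 3`
(the residual is polyhedral discretization error, which the tests show
shrinking with subdivision); Monte-Carlo checks use binomial 95% bands at
their stated replicate counts. Random draws always flow through
`with_seed()`, which scopes the RNG and restores the caller's state, so
identical seeds give bitwise-identical cohorts and reports.

## Known limitations

* Dense eigensolver: cubic scaling confines `compute_basis()` to meshes of
  a few thousand vertices; full-resolution hemispheres need an iterative
  sparse backend behind the same interface.
* Left/right hemispheres are processed as separate meshes and their
  feature vectors concatenated (left then right) before classification;
  joint spectral modelling of both hemispheres is not attempted.
* The w-score model is linear in age and education and has no site or sex
  terms.
* Wald normal p-values are anticonservative for small samples; with fewer
  than ~30 subjects per cohort, treat borderline interaction p-values with
  caution.
* GIFTI I/O is not implemented; FreeSurfer binary surface/curv and the
  package's plain-text formats are.
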