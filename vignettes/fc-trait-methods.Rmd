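---
title: "Methods: identifiability-optimized FC-trait extraction and screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifiability-optimized FC-trait extraction and screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, parameter choices and numerical
conventions behind `connica`, and states what the synthetic validation
does and does not demonstrate about real data.

## The model

The pipeline treats a cohort of resting-state functional connectomes as a
stack of edge vectors. For each subject and acquisition sequence
(monoband, multiband), the FC matrix is the R x R Pearson correlation of
ROI time series over retained frames; its upper triangle (row-major order
(1,2), (1,3), ..., (1,R), (2,3), ...; E = R(R-1)/2 edges) forms one row of
the M x E group matrix, M = 2 x subjects, rows subject-major with
monoband first. One fixed edge ordering is used everywhere so that
patterns, reconstructions and exports are interchangeable.

**Frame censoring.** A frame is censored when the Euclidean norm of the
first difference of the six realignment parameters (ENORM) exceeds 0.4 mm
or the despiked-voxel fraction exceeds 10%; both rules are strict
("larger than"), so values exactly at the limit are kept. Subjects lose
all data when strictly more than 20% of volumes are censored in either
session. Rotation parameters are consumed as provided and must already be
in mm-equivalent units; the despike fraction is an input column, since
voxel-level despiking happens upstream. Censored frames are deleted
before correlating, never interpolated.

**Differential identifiability.** With S subjects, the identifiability
matrix I has entry (i, j) = cor(monoband edge vector of subject i,
multiband edge vector of subject j), and

I_diff = (mean diagonal − mean off-diagonal) x 100.

The percent-like scaling keeps values on the conventional 0–100 scale.
The sweep reconstructs the column-mean-centered group matrix from its top
K singular components (no variance scaling — all edges share the
correlation scale), recomputes I_diff for every integer K in [2, M]
(a stride option trades resolution for speed), and keeps the K attaining
the maximum; ties break to the smallest K. Pearson correlation of edge
vectors is used as the FC similarity, the standard choice in the
connectome-fingerprinting literature.

**Trait extraction.** The reconstructed matrix X is modeled as X ≈ A S
with S (k x E) independent edge patterns and A (M x k) weights. Because
scale can move freely between A and S, patterns are unit L2-normalized
and all scale lives in the weights; the joint sign is fixed by making
each pattern's skewness positive (on an exact tie, the largest-|loading|
edge is made positive). The decomposition uses whitened fixed-point ICA
with the logcosh contrast and symmetric decorrelation (tolerance 1e-6,
at most 1000 iterations per run). ICA is restarted `n_runs` times
(default 100) from random orthonormal initializations; runs that fail to
converge are dropped but still count in the robustness denominator.
Components are matched to a reference run greedily by absolute pattern
correlation at or above 0.75, components recurring in at least 75% of
converged runs are retained as their sign-aligned centroid, and the
weights are then recomputed in a single least-squares step, so the
reported traits minimize Frobenius reconstruction error given the
retained patterns. The component count defaults to the sweep's optimal K.

**Screening.** Each trait's weights enter a mixed-design ANOVA with group
between subjects, sequence within, and age, gender and total grey matter
as covariates. The group F is computed in the between-subjects stratum:
ordinary least squares on per-subject session means, comparing the
covariates-only model against covariates + group. The sequence effect
comes from the paired monoband−multiband differences. This two-stage
scheme follows directly from the stated factors; no mixed-model
likelihood is invented, and the degrees of freedom are reported as
(groups − 1, subjects − covariates − groups). Benjamini–Hochberg
adjustment runs across the trait family, with the standard inclusive
step-up boundary (adjusted value at or below q rejects). Post-hoc
pairwise tests reuse the same covariate-adjusted model restricted to one
pair (the 1-df F equals the squared adjusted t); designs with fewer than
two subjects per group or no residual degrees of freedom return NA rather
than an unreliable number. Associations with cognitive and clinical
variables use nested ordinary least squares over the pooled M rows: a
baseline of age, sequence, average ENORM, TGM and eTIV against the
baseline plus one explanatory variable, reporting the partial F with
(1, M − 7) degrees of freedom and the augmented model's overall F. The
pooled-rows design mirrors the association convention of repeated-scan
cohorts; it does not carry a subject random effect, a known caveat.
Post-hoc and association significance defaults to p < 0.01; the FDR level
to q < 0.05.

**Cognition.** z = (raw − control mean) / control SD per test; each of
the five domains (attention/working memory, executive, memory, language,
visuospatial) is the unweighted mean of its two tests' z-scores. MCI
status requires z strictly below −1.5 on at least two of the ten tests,
within or across domains; missing scores raise an error rather than being
imputed. Scales not acquired in controls (e.g. the motor examination)
carry 0 for HC subjects, with a switch to exclude HC rows from clinical
regressions instead.

**Characterization.** The strongest edges are the round(pct/100 x E)
largest by absolute loading (minimum 1; ties break by edge index), so the
default 1% of a full-scale 408-ROI connectome (E = 83,028) keeps 830
edges. Nodal strength sums absolute normalized loadings of selected edges
per incident ROI; the default normalization is the z-score of loadings
over the whole pattern ("normalized FC values" is not pinned down by
convention, so the scheme is explicit and configurable: zscore, maxabs,
none). Network presence scores each network by the mean absolute loading
of edges touching it, divided by the trait's overall mean absolute
loading, so a uniform pattern scores exactly 1 everywhere; labels use
"−" below 1.0, "+" from 1.0 (inclusive) to 1.5, "++" at or above 1.5.
The thresholds are configurable and the rule is echoed in the run report;
they are an explicit surrogate for what is usually an expert judgment.
Every characterization step uses absolute loadings, so a global sign flip
of a trait changes nothing.

## The synthetic cohort generator

Clinical resting-state cohorts are rarely public, so validation runs on
simulated cohorts with known ground truth. The generator emulates the
study conditions the pipeline targets:

- three groups of 23 / 19 / 21 subjects (PD-MCI, PD-CN, HC), two sessions
  each (M = 126 rows);
- `n_traits` (default 5) planted edge patterns, each concentrated on 2–4
  randomly chosen within/between-network blocks of a Schaefer-style
  parcellation with half the block's edges active, unit-normalized, and
  re-drawn until all pairwise |cosines| are below 0.3;
- subject weights i.i.d. standard normal, with the effect trait's column
  shifted by 1.5 (a standardized mean difference) in the PD-MCI group,
  and independent N(0, 0.3^2) session jitter — the jitter, together with
  subject-specific weights, is what gives the cohort its fingerprint
  structure;
- edge vectors = weights x patterns + Gaussian edge noise, passed through
  tanh (monotone and bounded, keeping synthetic correlations in (−1, 1)
  while preserving the rank order of the latent mixture, so ICA recovery
  stays well-posed) and devectorized to symmetric unit-diagonal matrices.
  The noise SD defaults to the level at which the planted signal explains
  50% of per-edge variance, computed from the realized composite;
- optionally, T x R time series realizing each FC matrix, drawn from a
  multivariate normal whose correlation is the nearest positive-definite
  repair of the target (eigenvalue floor 1e-6, diagonal renormalized; the
  maximum entrywise correction is reported), plus realignment tables with
  a slow random walk and injected motion spikes sized to trip the 0.4
  censoring rule;
- covariates from group-wise distributions (ages and male fractions follow
  the printed demographics of the emulated cohort; grey-matter and
  intracranial volumes at realistic magnitudes), and cognitive/clinical
  variables that are linear in the subject's mean effect-trait weight:
  negative coefficients for cognition, positive for the motor score, raw
  test scores back-computed from z via stored control statistics.

The default R is 100 ROIs (E = 4950) for desk-scale runs; 408 matches the
full-scale parcellation.

What the generator does **not** emulate: voxel-level fMRI physics,
realistic head-motion spectra, scanner-sequence differences beyond weight
jitter, spatial autocorrelation among edges, non-Gaussian edge noise, or
nonlinear brain–behaviour links. Passing tests therefore show that the
pipeline recovers the model it assumes under calibrated noise — not that
real acquisitions satisfy that model.

## Validation design and problem sizes

The test suite checks, among others:

- recovery: on 20 cohorts at the default scale (63 subjects, R = 100,
  5 traits, signal R^2 ≈ 0.5), the planted group-effect trait must be
  matched with |pattern r| and |weight r| ≥ 0.9 in at least 90% of seeds;
- identifiability: the sweep optimum strictly beats the unreconstructed
  I_diff in at least 95% of 20 reduced cohorts (21 subjects, R = 60 — the
  property does not depend on scale), and full-rank reconstruction
  reproduces the input to 1e-8;
- screening calibration: under a 65-trait global null the any-flag
  proportion over 200 simulations stays at or below 0.08, and the default
  planted effect is flagged post-FDR (within its 5-trait family, the
  family the pipeline itself screens) in at least 90% of 20 seeds;
- exact agreement of every F statistic with independent RSS/matrix-algebra
  oracles on 50 random designs, of BH with a step-up oracle, and of the
  deterministic rules (censoring, MCI, z-scores, vectorization roundtrip,
  edge counts, handshake identity) with hand-computed fixtures;
- byte-identical outputs across two pipeline runs with the same
  configuration and seed.

Screening calibration is evaluated at the weight level (generated weights
plus clinical table): the property under test concerns the rmANOVA/FDR
stage, and routing 200 simulations through FC synthesis and ICA would add
cost without adding information about it.

## Known limitations

- The between-subjects F uses session means; with more than two sessions
  or missing sessions the design would need a proper mixed model.
- The pooled-row association design ignores within-subject correlation;
  its p-values are anti-conservative to the extent the two scans of a
  subject agree, which is precisely what high identifiability implies.
  The partial-F ranking of variables is unaffected.
- ICA assumes super-Gaussian (sparse) edge patterns via the logcosh
  contrast; traits that are dense and symmetric would be recovered less
  reliably.
- The network presence labels depend on two thresholds with defaults
  chosen so a uniform pattern sits at "+"; they are descriptive, not
  inferential.
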