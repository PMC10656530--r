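# connica

Independent functional connectivity traits from resting-state connectomes.

## What this package does

Resting-state fMRI studies of clinical populations often ask which patterns
of functional connectivity (FC) distinguish patient groups — for example,
Parkinson's disease patients with mild cognitive impairment (PD-MCI) from
cognitively normal patients (PD-CN) and healthy controls (HC). `connica`
implements an edge-level decomposition pipeline for exactly this question:

1. **FC construction.** Per subject and acquisition sequence (monoband /
   multiband), Pearson correlations between parcellated ROI time series,
   with motion-based frame censoring (ENORM > 0.4 mm or despiked-voxel
   fraction > 10% censors a frame; more than 20% censored volumes in
   either session excludes the subject).
2. **Group matrix.** The upper triangle of each R x R FC matrix is
   vectorized (E = R(R-1)/2 edges) and stacked into an M x E group matrix,
   M = 2 x subjects.
3. **Identifiability sweep.** For each number of principal components K,
   the group matrix is PCA-reconstructed and the *differential
   identifiability* computed:

   I_diff = (mean within-subject test-retest similarity −
             mean between-subject similarity) x 100,

   where similarity is the Pearson correlation between monoband and
   multiband edge vectors. The K maximizing I_diff is retained — the
   reconstruction that best separates subjects from each other.
4. **FC-traits.** The reconstructed matrix is decomposed by fixed-point
   ICA (logcosh contrast, repeated runs with component matching for
   robustness) as X ≈ A S: each row of S is an independent edge pattern
   (an *FC-trait*, unit norm), each column of A the per-scan weights
   quantifying how strongly that trait is expressed.
5. **Statistics.** Each trait's weights are screened with a
   covariate-adjusted repeated-measures ANOVA (group between subjects,
   sequence within, age/gender/TGM covariates) under Benjamini–Hochberg
   FDR across traits; significant traits get pairwise post-hoc tests and
   nested-model partial-F associations with cognitive domain z-scores and
   clinical scores against a baseline of variables of non-interest (age,
   sequence, average ENORM, TGM, eTIV).
6. **Characterization.** Significant traits are summarized by their 1%
   strongest edges, nodal strength of those edges on normalized loadings,
   and a per-network presence label (− / + / ++).

Because clinical cohorts of this kind are rarely public, the package ships
a seeded synthetic-cohort generator (`simulate_cohort()`) that plants
known FC-traits, a group effect on one trait's weights, session jitter,
calibrated edge noise, and covariates/cognition linearly linked to the
planted weights — so the full pipeline can be validated against ground
truth.

Cognition support includes control-referenced z-scoring
(z = (raw − control mean) / control SD), five two-test domain composites,
and Level-II-style MCI classification (z < −1.5 on at least two tests).

## Worked example

```r
library(connica)

co <- simulate_cohort(seed = 1)      # 23 PD-MCI / 19 PD-CN / 21 HC,
                                     # 100 ROIs, 5 planted traits
sw <- sweep_identifiability(co$group)
sw
#> identifiability sweep over 125 values of K
#>   original I_diff: 39.85
#>   optimal K = 5 with I_diff = 85.36

traits <- extract_traits(sw$reconstructed, n_components = sw$optimal_k,
                         n_runs = 10, seed = 101)
wm <- trait_weight_matrix(traits)
screen_traits(wm$weights, wm$index, co$subjects)
#>     trait         f            p     q_value significant
#> 1 trait_1 0.9215436 0.4037504838 0.672917473       FALSE
#> 2 trait_2 8.3396899 0.0006653858 0.003326929        TRUE
#> 3 trait_3 1.0772795 0.3473514275 0.672917473       FALSE
#> 4 trait_4 0.4261779 0.6550636666 0.766298947       FALSE
#> 5 trait_5 0.2674298 0.7662989475 0.766298947       FALSE
```

The sweep shows the PCA reconstruction roughly doubling differential
identifiability before trait extraction; screening then flags exactly one
trait — the one carrying the planted group effect. Matching against the
ground truth (`match_traits(traits, co$ground_truth$trait_patterns)`)
recovers the planted pattern with |r| = 0.989 and its weights with
|r| = 0.999.

For a file-based run, write a cohort and drive the pipeline from a config:

```r
cfg <- default_config(data_dir = "data", output_dir = "out", seed = 1)
simulate_to_disk(cfg)
report <- run_pipeline(cfg)   # censor -> FC -> sweep -> ICA -> stats -> characterize
```

or from a shell via the thin CLI wrapper:

```sh
Rscript inst/cli/connica.R simulate --config config.yaml
Rscript inst/cli/connica.R run --config config.yaml
```

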