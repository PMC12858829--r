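# plexuq

Uncertainty quantification for ensemble choroid plexus segmentation.

Deep-learning segmentation of the choroid plexus — the thin, bright,
curvilinear tissue inside the dark cerebral ventricles — is usually
served by an ensemble of deterministic networks that emits one binary
mask and no confidence statement. plexuq implements the evaluation
side of a probabilistic alternative: treat the ensemble stochastically
(K Monte Carlo dropout passes for each of M members, S = M·K samples
per subject), and turn the sampled voxel-wise probabilities into
uncertainty maps, consensus segmentations, accuracy metrics, and
cohort-level out-of-distribution screening. It is aimed at
neuroimaging methods researchers who have (or can emulate) a
stochastic predictor and want principled, testable uncertainty
reporting around it.

## The quantities it computes

For sampled probabilities `p_s(v)` with mean `p̄(v)` (all entropies in
nats):

- **Total predictive entropy** `H_total(v) = −p̄ ln p̄ − (1−p̄) ln(1−p̄)`
  — combined uncertainty.
- **Expected per-sample entropy** `E_s[H_s](v) = (1/S) Σ_s H(p_s(v))`
  — aleatoric proxy.
- **Mutual information** `MI = H_total − E_s[H_s]` — epistemic
  uncertainty, the BALD disagreement criterion.
- **Predictive SD** `σ(v) = sqrt((1/S) Σ_s (p_s − p̄)²)` — undecomposed
  dispersion.

Each map is aggregated per subject as `C = Σ U_i b_i / Σ b_i` over the
subject's consensus mask `b` (the mean map binarized at 0.5, strict
`≥` convention). Consensus accuracy against ground truth is scored
with Dice `2Σa_i m_i / (Σa_i + Σm_i)`, symmetric Hausdorff distance
(and HD95) in millimetres, volume similarity
`1 − |V_a − V_m| / (V_a + V_m)`, and Pearson volume correlation.
Cohorts are compared with Welch t-tests under joint Benjamini–Hochberg
FDR correction, and new subjects screened with Tukey IQR fences or the
KL divergence of their uncertainty distribution against a reference
cohort.

A synthetic module makes everything runnable without data: 3D phantoms
(bright tube in dark ellipsoidal ventricles, with ground truth), a
parametric stochastic predictor whose epistemic and aleatoric noise
are separately tunable on the logit scale, and a small trainable
MC-dropout voxel classifier.

## Worked example

The demo pipeline builds three synthetic cohorts — `local-like`
(in-distribution), `shifted-adult` (raised inter-member disagreement),
`shifted-child` (smaller, lower-contrast anatomy and the largest
epistemic spread) — runs the full 5×20 sampling scheme, and compares
the epistemic aggregate `C_MI` across cohorts:

```r
library(plexuq)
res <- run_pipeline(demo_config(out_dir = "demo_run", seed = 1))
summarize_groups(res$cohort_table, "C_mi")
#>           group n    mean      q1      q3
#> 1    local-like 4 0.00903 0.00879 0.00917
#> 2 shifted-adult 4 0.06399 0.06323 0.06511
#> 3 shifted-child 4 0.21451 0.21262 0.21610
res$comparison[, c("contrast", "mean_a", "mean_b", "t", "p_adj", "reject")]
#>                      contrast  mean_a mean_b      t    p_adj reject
#> 1    local-like:shifted-adult 0.00903  0.064  -57.5 5.92e-06   TRUE
#> 2    local-like:shifted-child 0.00903  0.215 -158.3 5.18e-07   TRUE
#> 3 shifted-adult:shifted-child 0.06399  0.215  -94.5 1.48e-09   TRUE
```

Reading: the in-distribution cohort carries an order of magnitude less
epistemic uncertainty (`C_MI ≈ 0.009` nats within the mask) than the
strongly shifted one (`≈ 0.215`), every pairwise contrast survives FDR
correction, and the in-distribution consensus masks reach Dice 1.0
against the phantom truth (column `dice` of `res$cohort_table`).
Per-subject mean maps, consensus masks and the four uncertainty maps
are written under `demo_run/` as NIfTI, next to `cohort_table.csv` and
`cohort_results.csv`. The same run is available from a shell via
`Rscript inst/cli/plexuq.R demo --seed 1`, alongside `simulate`,
`sample`, `uncertainty`, `evaluate`, `cohort` and `flag` subcommands.

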