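# plasmastab

Time-series stability analysis of the plasma metabolome under
sub-optimal freezing, from a deconvolved LC-MS feature table.

Plasma stored at −20 °C instead of −80 °C keeps changing: residual
enzymatic activity degrades metabolites and accumulates breakdown
products. Given a storage time course — pooled plasma aliquots frozen
away at regular intervals, profiled together with repeated QC
injections and a QC dilution series — `plasmastab` answers which
features are reliably measured, which change with storage time, and
whether storage time itself can be predicted from the profile.

The computational core is an elastic-net-penalised Poisson regression
of storage day on the autoscaled metabolite profile, fitted from
scratch:

```
min over (β₀, β) of  −(1/N) Σᵢ [ yᵢ(β₀ + xᵢ'β) − exp(β₀ + xᵢ'β) ]
                     + λ ( (1−α)‖β‖₂²/2 + α‖β‖₁ )
```

solved by outer IRLS (weights w = μ, working response
z = η + (y−μ)/μ) with inner cyclic coordinate descent and
soft-thresholding, warm starts down a log-spaced λ path from the
analytic λ_max, λ chosen by cross-validated Poisson deviance
(leave-one-out by default; both λ_min and λ_1se reported). Features
with nonzero coefficients, ranked by |β|, are the degradation markers.
Around that core: QC filtering (dilution-series response r² > 0.5, QC
%CV ≤ 30, ≤ 20% missing), preprocessing (KNN imputation, constant-sum
normalisation, generalised log, autoscaling), one-way repeated-measures
ANOVA with BH-FDR, paired t-tests versus day 0, and a moderated
one-sample Hotelling T² ranking of temporal profiles. A synthetic-data
generator emulates the full study design with per-feature ground truth,
so every stage is testable without any download.

## Worked example

```r
library(plasmastab)

cfg <- pipeline_config(
  synthetic = synthetic_config(seed = 42),  # 1500 features, 11 days x 10 reps
  alpha = 0.5, folds = "loo", lambda_rule = "1se", seed = 42)
report <- run_pipeline(cfg)
print(report)
#> stability_report
#>        stage entered retained removed
#>     dilution    1500     1200     300
#>        qc_cv    1200     1025     175
#>  missingness    1025     1025       0
#>   model: alpha = 0.5, lambda = 1.2304, 19 features selected
#>   train: RMSE 1.482, R2 0.978 | test: RMSEP 1.585, R2 0.977

score_recovery(report$selected_features$feature_id, report$truth)
#> $precision
#> [1] 1
#> $recall
#> [1] 0.3166667

head(report$selected_features, 3)
#>      feature_id coefficient rank
#> 1 4.72_458.8541  -0.1375114    1
#> 2 4.40_974.1219  -0.1090024    2
#> 3 3.66_234.8522  -0.1029050    3
```

Reading the output: the dilution filter removed the 300 features that
do not track the QC dilution series (background), the %CV filter the
175 technically irreproducible ones; nothing exceeded 20% missingness
after imputation-eligible filtering. On the training aliquots the model
predicts storage day with RMSE ≈ 1.5 days and holds that accuracy on
the 25% test split (R² ≈ 0.98) — storage time is genuinely encoded in
the profile. Every selected feature is a planted trending feature
(precision 1.0); recall is ~0.32 because the trending features are
mutually redundant and a sparse model does not need all of them (see
the vignette's "What recovery can and cannot show").

Per-stage tables (`anova.tsv`, `pairwise.tsv`, `meba.tsv`,
`cv_curve.tsv`, `selected_features.tsv`, `predictions.tsv`,
`heatmap.tsv`, `pca_scores.tsv`, `model.json`, …) are written when
`outdir` is set; `inst/scripts/run-pipeline.R` wraps the same call for
shell use.

## Acceptance script

`scripts/acceptance.R` re-runs the complete analysis from scratch —
simulates the default storage experiment at the given seed, applies
filters, preprocessing, the univariate and T² screens, cross-validated
model selection and the final fit, prints the report and the recovery
of the planted trending features — and writes its JSON summary to
`--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
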