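# radnorm

Scanner-bias auditing and regression-based harmonization of MRI radiomic
feature tables, with the downstream impact analyses needed to judge what a
normalization choice does to a study: cluster composition, cluster
stability under feature reduction, and prognostic modelling of
disease-specific survival.

## Who this is for

Radiomics studies that pool patients across scanners, field strengths or
protocol revisions. In MRI, acquisition settings (voxel geometry, TR, TE,
flip angle, field strength, diffusion b-values, ...) shift extracted
feature values. Per-feature z-scoring — the common default — rescales each
feature but leaves its correlation with protocol intact, so scanner
structure survives into clustering and modelling.

## The method

For each feature `f` and the acquisition covariates `x_1..x_m` of its
source MRI series, fit the multilinear model

```
f~ = b0 + b1 x1 + ... + bm xm
```

test it with the overall F test, and adjust p-values across all features
with the Benjamini–Hochberg FDR (α = 0.05). *LRM normalization* then
subtracts the fitted model from significantly associated features before
z-scoring, and plain-z-scores the rest:

```
N_LRM(f) = Nz(f - f~)   if the model is FDR-significant
           Nz(f)        otherwise
```

Two properties make the audit interpretable and are enforced by the test
suite: per-feature R² is invariant to prior z-scoring, and a re-audit
after LRM normalization flags zero features.

The package also ships: per-series design-matrix construction from DICOM
header attributes or CSV (with derived covariates voxel volume,
anisotropy, field of view, highest b-value, number of b-values), the
frozen 93-features-per-series + 13-shape-features catalog, k-medoids
cluster comparison with G1/G2/G3 change groups and scanning-parameter
enrichment tests, feature-shrinking stability curves, Kaplan–Meier /
log-rank analyses, and IPCW time-dependent AUC under random survival
forests and LASSO Cox over repeated 70/30 splits — plus a synthetic
multi-scanner cohort generator with known injected bias, latent clusters
and censored survival.

## Worked example

```r
library(radnorm)

cfg  <- synthetic_config(n_patients = 120, n_features_per_series = 30, seed = 7)
coh  <- gen_cohort(cfg)
coh
#> <synthetic_cohort> n = 120 patients, 60 features, 24 biased, 22 events

association_audit(coh$table, coh$designs)
#> <association_report> 60 features, 25 (42%) FDR-significant at alpha = 0.05
#>   per series: ADC 12/30, T2 13/30

norm <- lrm_normalize_table(coh$table, coh$designs)
association_audit(norm$table, coh$designs)
#> <association_report> 60 features, 0 (0%) FDR-significant at alpha = 0.05
#>   per series: ADC 0/30, T2 0/30

cz <- relabel_largest_first(kmedoids(zscore_normalize_table(coh$table), 2))
cl <- kmedoids(norm$table, 2)
align_and_compare(cz, cl)
#> <cluster_comparison> 49/120 (41%) patients changed cluster [G1 44, G2 27, G3 49]

eval_tdauc(norm$table, coh$survival, model = "RSF", folds = 10, seed = 7)
#> <tdauc_curve> RSF, 10 x 70/30 splits: mean tdAUC = 0.487
```

Reading: 24 features carried injected protocol bias and the audit flagged
25 (42%) before harmonization; after LRM normalization none remain
associated. The clusterings of the two normalizations disagree on 41% of
patients — protocol bias, not biology, was steering the z-score
clustering. The tdAUC near 0.5 is honest for this small cohort: with 22
events and a binary latent risk factor (hazard ratio 3, prevalence 0.3),
even oracle knowledge of cluster membership caps the tdAUC well below
published values on real cohorts, and a 60-feature forest at this event
count sits near that floor. Larger presets (`default_ec_like()`,
`default_cc_like()`) give richer cohorts.

A command-line dispatcher over the same functions is installed at
`system.file("cli", "radnorm", package = "radnorm")` with subcommands
`simulate`, `audit`, `compare-clusters`, `survival`.

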