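# mbmetab

Multiblock chemometrics for untargeted LC-MS metabolomics feature tables.

## The problem

Untargeted LC-MS metabolomics of plasma acquired in positive and negative
electrospray ionization (ESI+/ESI-) produces, after peak detection, one
feature table per mode: thousands of features (m/z-retention time pairs
with per-sample intensities) by a few dozen samples, plus periodic pooled
QC injections. Extracting trustworthy group differences from such tables —
here for a three-class comparative design (A/B/C, e.g. three age groups in
a developmental study) — requires a chain of statistical safeguards that
`mbmetab` implements end to end:

- **Matrix filtering** — drop isotope companion rows, features eluting
  before the injection peak (RT < 1 min), and features with QC %RSD > 20%
  (`filter_features()`).
- **QC drift correction** — per feature, a trend through the QC
  intensities vs injection order; every sample is divided by the trend at
  its own order and rescaled to the QC median (`qc_drift_correct()`).
- **PCA and consensus multiblock PCA (CPCA-W)** — each autoscaled block
  `X_b` is weighted by `1/sqrt(n_b)`; consensus *super scores* `t = T w`
  are extracted iteratively from the block scores `t_b = X_b p_b` and
  equal, up to sign, the PCA scores of the concatenated weighted blocks
  (`pca_fit()`, `mbpca_fit()`).
- **Validated PLS-DA** — NIPALS PLS2 on class indicators
  (`plsda_fit()`); stratified bootstrap out-of-bag validation (1000
  iterations) giving an average confusion matrix and correct
  classification rate (CCR), plus a label-permutation test (1000
  permutations) with the add-one p-value
  `p = (1 + #{null CCR >= observed}) / (1 + n_perm)`
  (`bootstrap_validate()`, `permutation_test()`).
- **Univariate significance cascade** — one-way ANOVA with
  Benjamini-Hochberg FDR (q < 0.001) → Tukey HSD all-pairs distinctness
  (A ≠ B ≠ C) → Lilliefors normality screen → Kruskal-Wallis (p < 0.001)
  for the non-normal features; final significant set = normal survivors +
  Kruskal-Wallis passes, with Up/Down/Other trend classes
  (`significance_cascade()`).
- **Cross-mode pairing and annotation support** — Pearson r > 0.8 plus
  co-elution within twice the maximum SST retention-time variability
  (`cross_mode_pairs()`, `rt_window_from_sst()`); IUPAC monoisotopic
  masses, adduct m/z (`[M+H]+`, `[M+Na]+`, `[M-H]-`, `[M+COOH]-`), ppm
  errors at the 5 ppm convention, and diagnostic fragment rules for
  lysophospholipid classes (`monoisotopic_mass()`, `adduct_mz()`,
  `ppm_error()`, `fragment_class_hints()`).
- **Synthetic two-block study generator** with ground truth
  (`generate_study()`), used by the entire test suite.

See the vignette (`vignettes/multiblock-chemometrics.Rmd`) for the models,
their assumptions, every tunable parameter and the design decisions.

## Worked example

```r
library(mbmetab)

design <- strong_separation_design(seed = 1)   # 3 x 12 samples, 2 blocks
study  <- generate_study(design)
study$pos
#> feature_table: 324 features x 43 samples (36 study, 7 QC)
#>   classes: A=12, B=12, C=12, QC=7
#>   rt range: 0.38-13.18 min; m/z range: 101.9665-999.5432

flt <- filter_features(study$pos, block = "ESI+")
flt$report
#> stage_report [ESI+] (filter)
#>   Input features                   324
#>   After isotope removal            300
#>   After RT < 1 min removal         287
#>   After QC %RSD > 20% removal      248

corrected <- qc_drift_correct(flt$table)
neg <- qc_drift_correct(filter_features(study$neg)$table)
mbpca_fit(list(`ESI+` = intensity_matrix(corrected, "study"),
               `ESI-` = intensity_matrix(neg, "study")), n_components = 2)
#> mbpca_model (CPCA-W): 36 samples, 2 blocks, 2 components
#>   block weights (1/sqrt(n)): ESI+=0.0635, ESI-=0.0716
#>   explained variance (%): 10.48, 8.78 | TEV: 19.26

set.seed(1)
bootstrap_validate(intensity_matrix(study$pos, "study"),
                   study_classes(study$pos), n_boot = 1000)
#> validation_result: 1000 stratified bootstrap iterations
#>   overall CCR: 0.7091
#>   average confusion matrix (rows = true class):
#>     predicted
#> true      A      B      C
#>    A 0.9338 0.0655 0.0007
#>    B 0.0973 0.3246 0.5781
#>    C 0.0000 0.1348 0.8652

significance_cascade(corrected, block = "ESI+")$report
#> stage_report [ESI+] (cascade)
#>   Total number after matrix filtering      248
#>   ANOVA and FDR                             25
#>   Post-hoc Tukey HSD (A != B != C)          25
#>   Fulfil normality                          23
#>   Do not fulfil normality                    2
#>   Kruskal-Wallis                             2
#>   Total significant features                25
```

What the numbers mean: the filter report tracks how many features survive
each rule; the MB-PCA block weights are the `1/sqrt(n_b)` dimensionality
equalizers; the confusion diagonal shows classes A and C allocated
correctly 93% and 87% of the time while the middle class B is masked (a
known property of indicator-based PLS-DA on monotone class structures —
hence the per-class reporting and the permutation safeguard); and the
cascade report's arithmetic always satisfies
`total significant = fulfil normality + Kruskal-Wallis` (23 + 2 = 25).
Against the generator's ground truth, 83% of the spiked features are
recovered with 0 false discoveries at these settings.

Mass annotation support, one line per worked Table-style check:

```r
theo <- adduct_mz(monoisotopic_mass(lyso_gpl_formula("LPC", 20, 4)), "[M+H]+")
abs(ppm_error(544.3400, theo))   # observed vs theoretical: 0.43 ppm
```

The full chain (filtering → correction → PCA/MB-PCA → validated PLS-DA →
cascade → cross-mode pairing), with all artifacts and a JSON run log, is
one call: `run_pipeline(design = design, out_dir = "run1")`.

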