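---
title: "Multiblock chemometrics for two-mode LC-MS metabolomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiblock chemometrics for two-mode LC-MS metabolomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbmetab)
```

## The analytical problem

Untargeted LC-MS metabolomics of plasma acquired in positive and negative
electrospray ionization (ESI+/ESI-) yields, after peak detection, one
feature table per mode: a few thousand features (m/z-retention time pairs)
by a few dozen samples. `mbmetab` implements the chemometric stages that
follow peak detection for a three-group comparative design (classes A, B, C
-- in the motivating application, newborn, infant and child subjects of an
animal model) with pooled QC samples injected at the start of the run and
then after every block of randomized study samples:

1. matrix filtering (isotopes, early eluters, QC-unrepeatable features);
2. QC-based correction of injection-order intensity drift;
3. per-feature scaling (autoscaling or log10);
4. unsupervised structure: PCA per block and consensus multiblock PCA
   (CPCA-W) across blocks;
5. supervised classification: PLS-DA with stratified bootstrap out-of-bag
   validation and a label-permutation test;
6. a univariate significance cascade with trend classification;
7. cross-mode feature pairing and mass-based annotation support.

Peak detection itself (XCMS-style), raw-format conversion and MS/MS
database search are out of scope: the pipeline starts at the feature
matrix, and the isotope annotation is accepted as an input column.

## The synthetic study generator

Because the pipeline's guarantees are statistical, the package ships a
generator (`generate_study()`) that produces two-block studies with known
ground truth, used by every downstream test.

**Intensity model.** Each feature has a log-normal baseline (log10 baseline
uniform on [4, 6], spanning the dynamic range typical of TOF detectors) and
multiplicative log-normal noise with coefficient of variation `noise_cv`
(default 0.1, the usual mid-range QC repeatability of a stable LC-MS run).
Group effects are multiplicative shifts of the class mean:
`effect_size` is the shift between adjacent classes in units of the
log-intensity noise SD. Trend patterns follow the three shapes relevant to
a monotone developmental contrast -- `Up` (A < B < C), `Down` (A > B > C)
and `Other` (B above A and C, with A and C still distinct) -- drawn in
proportions 40/40/20, matching the mix of regulation patterns the
motivating study reported among its significant features.

**QC samples.** A pooled QC's expected intensity is the arithmetic mean of
all study-sample expectations; QCs receive the same noise model but no
group effect, and are injected first (equilibration) and then after every
`qc_interval` (default 6) randomized study samples. With the default
3 x 12 study samples this yields 1 + 36/6 = 7 QCs.

**Drift.** Instrumental intensity drop is a smooth monotone
exponential-decay multiplier of injection order running from 1 to
`1 - drift_magnitude` (default 0.3) across the full sequence; the true
curve is part of the ground truth. Only this one drift curve is simulated
-- no multi-batch structure.

**Structure features.** A configurable fraction of features receives an
`[M+1]` isotope companion (m/z + 1.0034, fixed abundance ratio, perfectly
correlated with its parent) to exercise the isotope filter; a fraction of
null features receives inflated noise (CV 0.35) to exercise the QC %RSD
filter; `n_cross_pairs` spiked feature pairs span the two blocks, share
their trend, co-elute within `coelution_tol` and share most of their
per-sample noise (a common latent factor with an independent residual of
one quarter its weight, giving pair correlations around 0.94 on clean
data).

**Seeding.** One root seed is split into fixed per-phase sub-seeds (layout,
positive block, negative block), so, for example, resizing one block does
not perturb the other block's draws. Everything is reproducible bytewise.

**What the generator does not emulate** -- and hence what passing tests do
not certify about real data: peak shapes and integration artifacts,
missing values, retention-time misalignment between runs, correlated
metabolite modules beyond the explicit cross-mode pairs, batch effects
beyond one drift curve, and sex or covariate structure. Real feature
tables are messier in all of these ways.

## Preprocessing

**Filtering** (`filter_features()`) removes, in this order: features with a
non-empty isotope flag; features eluting before `min_rt` (default 1.0 min,
the injection-peak window); features whose percent relative standard
deviation across QC injections exceeds `max_qc_rsd` (default 20%). %RSD
uses the sample SD (n - 1 denominator); features with zero QC mean have
undefined %RSD and are treated as failing. The three rules are independent
predicates, so the surviving set does not depend on their order; only the
stage-count report does. Filtering precedes drift correction, and the
%RSD is computed on raw intensities; both choices are configurable in
spirit but fixed in the shipped pipeline because the stage counts are
meant to be reproducible.

**Drift correction** (`qc_drift_correct()`) fits, per feature, a trend to
QC intensity versus injection order, divides every sample by the trend at
its own order and rescales to the median QC intensity. The default trend
is piecewise-linear interpolation through the QC points with constant
extrapolation beyond the first and last QC. Because every QC is an
interpolation knot, corrected QC trajectories are exactly flat -- the
correction can never worsen QC repeatability -- but the trend inherits the
full measurement noise of each QC injection, which is transferred into the
corrected study samples (roughly a `sqrt(2)` inflation of the effective CV
at `noise_cv = 0.1`). The `method = "lowess"` alternative smooths the QC
trajectory first and transfers correspondingly less noise; it is the
better choice when enough QCs are available, and the linear default is
retained for its transparency and exact QC-flattening. The correction
factor depends only on injection order, never on class labels, so
between-class intensity ratios are preserved in expectation. Features
whose QC trajectory is all zero (or whose fitted trend is non-positive)
are left uncorrected and flagged.

**Scaling.** `autoscale()` centers and scales each feature to unit sample
variance (constant features become zero columns when tolerated);
`log10_scale()` takes elementwise log10 and refuses zeros unless an offset
policy is given -- the `"auto"` policy adds half the smallest positive
intensity and warns loudly. The shipped pipeline autoscales the ESI+ block
and log10-scales the ESI- block for classical PCA, and always autoscales
for multiblock PCA and PLS-DA, mirroring common practice for these data.

## PCA and consensus multiblock PCA (CPCA-W)

`pca_fit()` is the truncated SVD of the column-centered matrix; explained
variance per component is the squared singular value over the total sum of
squares.

`mbpca_fit()` implements the consensus PCA variant in which each
autoscaled block `X_b` (n_b variables) is weighted by `1/sqrt(n_b)` so
that no block dominates by dimensionality alone. Per component:

1. initialize the super score `t` from the concatenated column with the
   largest sum of squares (deterministic);
2. block loadings: `p_b = X_b' t`, normalized to unit length;
3. block scores: `t_b = X_b p_b`;
4. super weights: `w = T' t` normalized, where `T = [t_1 ... t_B]`;
5. new super score: `t = T w`; iterate 2-5 until the relative change of
   `t` falls below `1e-10` (at most 500 iterations, otherwise an error
   naming the component);
6. deflate every block by the super score.

With super-score deflation this algorithm is exactly equivalent to PCA of
the column-concatenated weighted blocks; the test suite asserts that
equivalence to `1e-6` on every seeded dataset, and also the corollary that
duplicating a block's columns four times leaves super scores unchanged
(the `1/sqrt(n_b)` weight cancels duplication). All score and loading
vectors, here and in PCA/PLS-DA, carry a fixed sign convention -- the
largest-magnitude element is positive -- so plots and regression tests are
reproducible.

## PLS-DA and its validation

`plsda_fit()` encodes classes as one indicator column each and fits a
NIPALS PLS2 model between the autoscaled features and the centered
indicators. The default of 2 latent variables matches the two-dimensional
score plots used to inspect these models; the count is overridable.
Centering and scaling always come from the training set only, and stored
parameters transform test samples, so validation carries no information
leak. Prediction assigns the class with the largest predicted indicator;
exact ties go to the first declared class and are flagged.

A known property of indicator-based linear classifiers with three or more
ordered classes is *masking*: when class means are nearly collinear (as
they are for monotone developmental trends), the middle class's indicator
is almost a quadratic function along the class axis and is fitted poorly,
so the middle class B shows markedly lower allocation rates than A and C
even when the score plot separates all three. This is intrinsic to the
method -- the motivating study likewise reported one weak class per
ionization mode -- and is the reason the validation reports per-class
rates, not only the overall rate.

**Bootstrap out-of-bag validation** (`bootstrap_validate()`, default 1000
iterations) draws a stratified bootstrap sample within each class
(preserving class sizes; pooled resampling could produce classless
training sets at n = 12 per class), trains on it and classifies the
out-of-bag samples. Per-iteration confusion matrices are row-normalized
and averaged over the iterations in which the class appeared; the overall
correct classification rate (CCR) is the mean fraction of out-of-bag
samples allocated correctly. Empty out-of-bag draws (probability
essentially zero at these sizes) are redrawn and logged.

**Permutation test** (`permutation_test()`, default 1000 permutations)
permutes the labels once per permutation and recomputes the CCR with the
same bootstrap procedure at a reduced inner iteration count (default 100;
the full 1000 x 1000 grid is quadratic and adds nothing but runtime --
the inner count only sets the Monte-Carlo error of each null draw). The
p-value uses the add-one estimator `p = (1 + #{null >= observed}) /
(1 + n_perm)`: it is never zero, and ties count against the model. The
smallest attainable p at 1000 permutations is therefore `1/1001`, i.e.
just under `1e-3`.

A subtlety worth recording: on *pure-noise* data with a fixed labeling,
bootstrap out-of-bag CCR is biased a few points *below* `1/k`, because
within a fixed finite sample the training-set noise deviations of a class
are anti-correlated with the class's held-out deviations (we reproduced
the same bias with an independent PLS implementation). Chance-level
behavior should therefore be judged on the mean of the permutation null
distribution -- which is centered at `1/k` on structured data -- rather
than on a single shuffled-label run of noise data.

## The univariate cascade

`significance_cascade()` runs, per feature, on the drift-corrected
unscaled intensities of the study samples (all four tests are invariant
to per-feature positive affine maps, so scaling would not change any
verdict -- the suite asserts this equivariance):

1. one-way fixed-effects ANOVA; Benjamini-Hochberg FDR across features;
   keep `q < 0.001`. The threshold is applied to the adjusted value by
   default (per-feature q-values are what the report lists); a flag
   switches to raw p for comparability with laxer conventions.
2. Tukey HSD on the pooled within-group mean square: keep features whose
   three classes are all mutually distinct (A != B != C) at family level
   0.05 (conventional; configurable).
3. Lilliefors normality screen on the pooled within-class-centered
   residuals (the residuals of the ANOVA model whose assumption is being
   checked) at level 0.05, using the published Dallal-Wilkinson
   approximation; the method is recorded in the output. At least 5
   residuals are required. A per-class variant is available by flag.
4. features failing the screen are re-tested by Kruskal-Wallis (rank H
   with tie correction, chi-square reference) at the same 0.001 threshold.

The significant set is the union of normal survivors and Kruskal-Wallis
passes, and the seven-row stage report enforces its own arithmetic --
normal + non-normal must partition the Tukey survivors, and the final
count must equal normal passes + Kruskal-Wallis passes. Each feature also
receives a trend class from its class means (`Up`, `Down`, or `Other`
with a recorded subtype), and the per-feature table (m/z to 4 decimals,
RT to 2) is exported alongside the report.

Degenerate inputs are handled explicitly: zero within-group variance with
a real between-group difference yields p = 0 with a `degenerate` flag;
all-tied values yield Kruskal-Wallis p = 1 with a flag; constant
residuals are flagged non-normal; an empty (fully filtered) table is
refused with an actionable error.

## Cross-mode pairing and annotation support

`cross_mode_pairs()` correlates candidate features (typically the
significant ones) against all features of the opposite block on the
autoscaled study-sample matrix (QCs excluded). A pair passes when Pearson
r exceeds 0.8 *and* the features co-elute: |RT difference| at most the
window derived from system-suitability-test compounds
(`rt_window_from_sst()`: twice the maximum RT range of any SST compound
across replicate injections; an SD-based variant sits behind a flag). One
candidate may legitimately pair with several partners -- adducts,
isotopes and in-source fragments of the same metabolite -- and all are
reported. Note that strong group effects alone can push the correlation
of two unrelated, like-trending features past 0.8; the co-elution gate is
what keeps the pairing specific, and the recovery tests are run at the
generator's default effect size where the two gates are both informative.

`monoisotopic_mass()` sums IUPAC monoisotopic element masses and handles
charge via the electron mass; `adduct_mz()` applies registry deltas for
`[M+H]+`, `[M+Na]+`, `[M-H]-` and the formate adduct `[M+COOH]-`, all
computed from the element table at load time; `ppm_error()` is the signed
relative error in parts per million, with a 5 ppm acceptance convention
for precursor annotation. `lyso_gpl_formula()` expands the lipid
shorthand for the two lyso-glycerophospholipid classes the fragment rules
can recognize: LPC C:D = C(8+C)H(2C-2D+18)NO7P and LPE C:D =
C(5+C)H(2C-2D+12)NO7P; general lipid nomenclature is out of scope.

`fragment_class_hints()` matches an MS/MS peak list against a small
editable rule table (shipped as `extdata/fragment_rules.tsv`): the
protonated phosphocholine fragment at 184.0733 (LPC/PC classes), the
acylcarnitine fragment at 85.0268, the phosphoethanolamine neutral loss
of 141.0191 (LPE) and the methyl formate loss of 60.0211 (formate-adduct
LPC). Fragment tolerance is deliberately looser than precursor tolerance
(20 ppm or 0.005 Th, whichever is larger) because printed and measured
fragment m/z routinely deviate from theory by around 10 ppm at
calibration level; neutral-loss tolerances are evaluated on the precursor
m/z scale, since a measured loss inherits the absolute error of two mass
measurements.

## Orchestration and reproducibility

`run_pipeline()` chains every stage on a pair of feature tables (or on a
freshly generated synthetic study), writes all artifacts as delimited
text plus a JSON run log (package version, seed, full configuration,
stage counts, CCR and p-value), and is bytewise reproducible for a given
configuration. `pipeline_config()` collects every threshold with its
default and validates domains; unknown fields are errors. The package is
a library-first design: the R functions *are* the command surface, and
the run log is the record a pipeline wrapper would otherwise print.

## Problem sizes and runtime choices

The validation and test scenarios use deliberately compact studies --
300/250 features per block for the strongly separated classification
scenario (`strong_separation_design()`, effect size 3), 550 features for
the cascade recovery scenario, 1000 bootstrap iterations and 1000
permutations with 100 inner iterations for the headline validation -- so
that the full suite and the reproduction script run in minutes on one
core while keeping the p >> n character of the real problem. These sizes
are the package's own choices; all counts are parameters, and nothing in
the implementation depends on them.

## Known limitations

- The generator's clean structure makes recovery tests easier than real
  data; see the generator section for what is not emulated.
- Indicator PLS-DA masks middle classes of monotone designs (discussed
  above); OPLS-DA or multinomial models are out of scope.
- Bootstrap out-of-bag CCR is slightly pessimistic on pure-noise fixed
  samples (anti-correlation effect above); permutation calibration is the
  intended remedy.
- The linear drift trend transfers QC noise into corrected samples; use
  `method = "lowess"` when QC density allows.
- Annotation support is rule-based class hinting plus exact-mass
  arithmetic; it does not search spectral libraries or generate formulas
  from mass.
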