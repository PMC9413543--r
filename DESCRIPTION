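Package: mbmetab
Title: Multiblock Chemometrics for Untargeted LC-MS Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric analysis of untargeted LC-MS plasma metabolomics
    feature tables acquired in two ionization modes. Provides feature-matrix
    filtering (isotopes, early eluters, QC relative standard deviation),
    QC-based injection-order drift correction, PCA and consensus multiblock
    PCA (CPCA-W) with block weighting, PLS-DA with stratified bootstrap
    out-of-bag validation and permutation testing, a univariate significance
    cascade (one-way ANOVA with Benjamini-Hochberg FDR, Tukey HSD all-pairs,
    Lilliefors normality screen, Kruskal-Wallis fallback) with trend
    classification, cross-ionization-mode feature pairing by Pearson
    correlation and co-elution, and mass-based annotation helpers
    (monoisotopic masses, adduct m/z, ppm error, diagnostic fragment rules
    for lysophospholipid classes). Includes a synthetic two-block feature
    table generator with ground truth for validating every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
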