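Package: mrpipe
Title: Two-Sample, Multivariable and Non-Linear Mendelian Randomisation Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A complete causal-inference toolkit for Mendelian randomisation (MR)
    studies of continuous exposures and binary disease outcomes: reading,
    validation, allele harmonisation and fixed-effect meta-analysis of GWAS
    summary statistics; the two-sample MR estimator stack (Wald ratio, IVW,
    MR-Egger, weighted median) with Cochran's Q heterogeneity diagnostics,
    Rucker model selection, MR-Steiger directionality and analytic power;
    multivariable MR and two-step mediation MR with product-of-coefficients
    proportion mediated and delta-method intervals; stratified non-linear MR
    with localized average causal effects, piecewise-linear and
    fractional-polynomial curves; EM mixture-model clustering of per-variant
    causal estimates into null, substantial and junk clusters; an
    observational arm with rank-based inverse-normal transformation, logistic
    models and fractional-polynomial closed-test selection; and a
    synthetic-data generator producing cohorts and two-sample GWAS summary
    statistics with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    mgcv,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
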