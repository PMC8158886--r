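Package: metabometa
Title: Multi-Cohort Meta-Analysis and Set Enrichment for Metabolomics of
    Insulin-Resistance Response
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for relating baseline blood metabolite levels to percent
    change in insulin resistance (HOMA-IR) across several weight-loss
    intervention cohorts. Provides per-cohort linear models (univariate and
    covariate-adjusted) of percent change in HOMA-IR on natural-log LC-MS
    metabolite abundances, inverse-variance fixed-effects and
    DerSimonian-Laird random-effects meta-analysis with Cochran Q, tau-squared,
    H and I-squared heterogeneity statistics and Benjamini-Hochberg FDR
    control, and a GSEA-style metabolite-set enrichment analysis over HMDB
    taxonomy subclasses with permutation p-values and normalized enrichment
    scores. A seeded synthetic-study generator emulates three weight-loss
    cohorts with planted homogeneous and cohort-heterogeneous metabolite
    effects so the full pipeline can be exercised and validated without
    access to patient-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    metafor,
    fgsea
Config/testthat/edition: 3
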