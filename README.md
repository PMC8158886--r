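# metabometa

Multi-cohort meta-analysis and set enrichment for metabolomics studies of
insulin-resistance response to weight loss.

## What it does, and for whom

Weight-loss interventions improve insulin resistance very unevenly across
individuals, and a central question in metabolic precision medicine is
whether the *baseline* blood metabolome predicts who will improve — and
whether some metabolites predict response differently under behavioral,
exercise or surgical interventions. metabometa implements the three-stage
statistical pipeline for that question, for analysts who have per-cohort
LC-MS metabolite panels and before/after phenotypes:

1. **Per-cohort regression.** For each metabolite *j* and cohort *c*,
   ordinary least squares of the percent change in HOMA-IR
   (glucose [mg/dL] × insulin [µU/mL] / 405) on the natural-log baseline
   peak area, either univariate or adjusted for age, sex, race, baseline
   clinical triglycerides and percent weight change. Subjects whose
   outcome lies more than 5 SD from the cohort mean are excluded once,
   before any model.
2. **Meta-analysis.** Inverse-variance fixed effects
   (β_F = Σwβ/Σw, w = 1/se²) and DerSimonian–Laird random effects
   (τ̂² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw)), weights 1/(se² + τ²)),
   with Cochran's Q, H = √(Q/df), I² = max(0, (Q−df)/Q), and
   Benjamini–Hochberg FDR across metabolites. Metabolites with pooled
   missingness ≥ 25% or without a known identity are filtered out first.
3. **Metabolite-set enrichment.** GSEA-style weighted running sum over the
   metabolite ranking (by random-effects z for association, by Cochran Q
   for heterogeneity), per-set enrichment scores calibrated against
   size-matched membership permutations, normalized enrichment scores,
   permutation p-values with +1 smoothing, and BH-FDR across the HMDB
   subclass sets (≥ 5 members required).

Because studies of this design rarely deposit patient-level data, the
package also ships a seeded synthetic-study generator
(`generate_study()`) that emulates three weight-loss cohorts
(n = 443/163/125; outcome ≈ −16±105, −16±42, −71±21 %ΔHOMA-IR) with
block-correlated lipid panels, planted homogeneous and cohort-heterogeneous
effects, injected missingness and extreme outcomes — so the entire pipeline
is testable end to end against known ground truth.

## Worked example

Simulate the flagship study (765 metabolites, 22 subclasses, three
cohorts, both planted effects), run the association analysis, and test the
subclass sets:

```r
library(metabometa)

cfg0  <- generator_config(seed = 42)
ann   <- generate_annotation(cfg0)              # deterministic given seed
cfg   <- generator_config(seed = 42, effects = default_planted_effects(ann),
                          n_outcome_outliers = 2)
study <- generate_study(cfg)

cohorts <- lapply(study$cohorts, apply_outlier_exclusion)  # 5-SD rule
meta <- run_meta(lapply(cohorts, fit_cohort, "univariate"),
                 annotation = study$annotation)
head(meta[order(meta$Pvalue_Adj_Random), c("Metabolite", "sub_class",
     "N_Samples", "Beta_Random", "SE_Random", "Pvalue_Adj_Random",
     "Direction")], 5)
```

```
 Metabolite          sub_class N_Samples Beta_Random SE_Random Pvalue_Adj_Random Direction
 TRIR01_024 Triradylcglycerols       713        -277     10.61         2.21e-147       ---
 TRIR01_129 Triradylcglycerols       709        -193      7.59         5.97e-140       ---
 TRIR01_011 Triradylcglycerols       708        -180      7.11         1.00e-139       ---
 TRIR01_057 Triradylcglycerols       708        -267     10.57         8.60e-139       ---
 TRIR01_051 Triradylcglycerols       707        -153      6.06         3.25e-138       ---
```

The top metabolites are all members of the planted triacylglycerol-like
block: negative `Beta_Random` means higher baseline levels predict a
larger drop in HOMA-IR (more improvement), in all three cohorts
(`Direction` "---"), and the planted block is strongly amplified by its
within-subclass correlation. `N_Samples` varies per metabolite because
each regression uses that metabolite's complete cases.

```r
enr <- run_enrichment(meta, study$sets, mode = "signed_z",
                      n_perm = 10000, seed = 42)
head(enr, 5)
```

```
                    pathway   pval   padj     ES   NES nMoreExtreme size
         Triradylcglycerols 0.0001 0.0022 -1.000 -1.55            0  130
                     Azoles 0.0213 0.1560  0.538  1.91            0   20
 Organic dicarboxylic acids 0.0213 0.1560  0.700  2.48            0   20
          Fatty acid esters 0.0336 0.1686 -0.766 -1.16          335   30
           Diradylglycerols 0.0383 0.1686 -0.763 -1.15          382   30
```

The planted subclass is the only set significant after FDR (padj =
0.0022 at 10,000 permutations, none more extreme), with the most negative
NES — i.e. the set is concentrated at the "improvement" end of the
ranking. Running `run_enrichment(..., mode = "q_stat")` on the full-model
meta-analysis recovers the planted sign-flipping amino-acid block as the
most heterogeneous set the same way.

`run_all(run_config(...))` chains every stage and writes the result
tables (meta-analysis and enrichment TSVs, volcano-plot exports, JSON
manifest) with provenance headers; `exec/metabometa` exposes
simulate/regress/meta/enrich/run-all as shell subcommands. See the
methods vignette (`vignettes/metabometa-methods.Rmd`) for the model,
its assumptions, and every tunable parameter.

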