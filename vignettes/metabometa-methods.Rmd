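---
title: "Methods: multi-cohort metabolomics meta-analysis of insulin-resistance response"
author: "metabometa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cohort metabolomics meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabometa)
```

## The scientific problem

Weight-loss interventions (behavioral, exercise, surgical) improve insulin
resistance on average, but individuals respond very unevenly. A natural
question is whether the baseline blood metabolome predicts who will
improve, and whether some metabolites predict response *differently* under
different intervention types. metabometa implements the corresponding
three-stage analysis:

1. within each cohort, regress the percent change in HOMA-IR
   (Homeostatic Model Assessment of Insulin Resistance,
   $\mathrm{HOMA\text{-}IR} = \mathrm{glucose}\ [\mathrm{mg/dL}] \times
   \mathrm{insulin}\ [\mu\mathrm{U/mL}] / 405$) on each baseline
   metabolite's natural-log LC-MS peak area;
2. pool the per-cohort coefficients across cohorts by inverse-variance
   meta-analysis, quantifying between-cohort heterogeneity;
3. ask whether whole chemical families (HMDB taxonomy subclasses) are
   concentrated at either end of the metabolite ranking, using a
   GSEA-style running-sum statistic calibrated by permutation.

Because the patient-level study data this design comes from are not
publicly deposited, the package ships a seeded synthetic-study generator
that reproduces the *statistical structure* of such a study — three cohorts
of 443/163/125 subjects, 765 metabolites in 22 subclasses, planted
homogeneous and cohort-heterogeneous effects — so every stage can be
exercised and validated end to end.

## Stage 1: per-cohort regression

The outcome is $y_i = 100 \cdot (\mathrm{HOMA}_{i,\mathrm{follow}} -
\mathrm{HOMA}_{i,\mathrm{base}}) / \mathrm{HOMA}_{i,\mathrm{base}}$.
Before any model is fit, subjects with $|y_i - \bar y| > k \cdot
\mathrm{SD}(y)$ are excluded once per cohort (default $k = 5$; mean and SD
are computed over all finite values *before* exclusion, in a single pass —
no re-iteration). Metabolite abundances enter as the natural log of the
peak area; zero abundances cannot be logged and are mapped to missing,
tracked separately ("zeroness") from true missingness.

Two model forms are fit per metabolite by ordinary least squares on
complete cases:

* **univariate**: $y \sim 1 + \log x_j$;
* **full**: $y \sim 1 + \log x_j + \mathrm{age} + \mathrm{sex} +
  \mathrm{race} + \mathrm{TG}_0 + \%\Delta\mathrm{weight}$,

with classical (homoscedastic) standard errors and two-sided $t$ inference
on $n - p$ degrees of freedom, matching `lm()`. Only the metabolite
coefficient is reported: its units are "percent change in HOMA-IR per
natural-log unit of metabolite". Design choices worth noting:

* complete-case analysis per metabolite — $n$ varies across metabolites
  and is reported per cohort; no imputation;
* sex and race enter as indicators with the cohort's largest category as
  the reference level; an indicator that is constant on the complete cases
  in use (e.g. a single observed race level) is dropped automatically,
  while any remaining rank deficiency is an error naming the offending
  columns;
* metabolites with fewer than 3 complete cases (or fewer than
  $p + 1$ for the full model) or zero variance are reported as absent for
  that cohort rather than failing the run, mirroring how a metabolite not
  detected by a cohort's LC-MS platform is carried through.

## Stage 2: meta-analysis

For metabolite $j$ with per-cohort estimates $(\hat\beta_i, s_i)$,
$i = 1 \dots k$, the fixed-effects summary uses weights $w_i = 1/s_i^2$:

$$\hat\beta_F = \frac{\sum w_i \hat\beta_i}{\sum w_i}, \qquad
  \mathrm{se}_F = \Big(\sum w_i\Big)^{-1/2},$$

with $z = \hat\beta_F/\mathrm{se}_F$ and two-sided normal p-values.
Heterogeneity is measured by Cochran's
$Q = \sum_i w_i (\hat\beta_i - \hat\beta_F)^2$, referred to
$\chi^2_{k-1}$; derived statistics are $H = \sqrt{Q/(k-1)}$ (not
truncated) and $I^2 = \max(0, (Q - (k-1))/Q)$. The random-effects summary
uses the DerSimonian–Laird moment estimator

$$\hat\tau^2 = \max\!\left(0,\;
  \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right),$$

and re-pools with weights $w_i^* = 1/(s_i^2 + \hat\tau^2)$. Inference is
z-based for both models (no small-sample Knapp–Hartung adjustment), and
the DL estimator is pinned as the package's $\tau^2$ estimator — it is the
historical default of the classic meta-analysis libraries this schema
follows; REML or Paule–Mandel could be slotted in behind the same
interface but are deliberately out of scope. $Q$ always uses
fixed-effects weights, the standard convention.

Multiplicity is handled by Benjamini–Hochberg FDR across all retained
metabolites within one model form; heterogeneity p-values are reported
nominally (the Q test at $k = 3$ has little power, and flagging candidates
is its purpose here). Before pooling, metabolites are filtered to those
with pooled missing fraction strictly below 25% across all cohorts'
samples *and* a known (named) identity; a metabolite absent from an entire
cohort counts as missing for all of that cohort's samples. Metabolites
observed in a single cohort are retained for association (their pooled
estimate is the cohort estimate, $\tau^2 = 0$) but have no defined
heterogeneity p-value and are dropped from Q-based rankings
($\mathrm{df} = 0$).

The association analysis consumes univariate-model estimates; the
heterogeneity analysis consumes full-model estimates, so that
between-cohort differences are assessed after a linear correction for age,
sex, race, baseline triglycerides and percent weight change.

## Stage 3: metabolite-set enrichment

Metabolites are ranked descending either by random-effects z-score
(association; signed) or by Cochran Q (heterogeneity; nonnegative), with
ties broken lexicographically by metabolite id so rankings are
reproducible. For a set $S$ with $n$ of $N$ ranked metabolites, the
running sum gains $|r_i|^w / \sum_{h \in S} |r_h|^w$ at each member and
loses $1/(N - n)$ at each non-member; the enrichment score (ES) is the
extremum of largest magnitude, sign retained, and the walk provably
returns to 0 at position $N$. The weight exponent defaults to $w = 1$
(the classic weighted GSEA statistic; $w = 0$ gives the unweighted
Kolmogorov–Smirnov walk). When the positive and negative extremes tie in
magnitude — possible only for discrete statistics or $w = 0$ — the
positive one is reported; the tie comparison carries a $10^{-9}$ relative
slack so it cannot be flipped by floating-point summation order.

Significance is calibrated by **membership permutation**: random
size-matched subsets of the ranked list, sharing one null sample across
all sets of equal size. The permutation unit is a deliberate design
choice: at this stage the pipeline holds one statistic per metabolite, so
subject-level (phenotype) permutation is not available, and the reported
`nMoreExtreme` count is defined against exactly this null. P-values are
one-sided in the direction of the observed ES against same-sign null
scores, $p = (n_{\mathrm{more\ extreme}} + 1)/(n_{\mathrm{same\ sign}} +
1)$, never zero (null scores within $10^{-9}$ relative of the observed
score count as ties, i.e. as "at least as extreme" — distinct memberships
can produce exactly equal extrema in exact arithmetic, and the slack keeps
the count independent of floating-point summation order); the normalized enrichment score is
$\mathrm{NES} = \mathrm{ES} / \mathrm{mean}(|\mathrm{ES}_{\mathrm{null}}|)$
over same-sign null scores. When the number of distinct memberships
$\binom{N}{n}$ does not exceed the permutation budget, the null enumerates
all memberships, making small cases exact. Sets need at least 5 members
present to be tested; BH-FDR is applied across tested sets. The default
permutation budget is 10,000 per set size — enough for set-level FDR at
$\sim$20 sets on a desktop — with the budget exposed up to $10^6$ for
final analyses. For the Q-ranked mode the statistic is nonnegative, so
enrichment is effectively one-directional; "least heterogeneous" sets are
those with the smallest-magnitude NES, not negative-ES sets.

A known limitation of any competitive enrichment test applies: when
member statistics are positively correlated within a set (as lipid species
in one subclass genuinely are), the membership-permutation null
understates the variance of set scores and the test is anticonservative.
The package's null-calibration checks therefore run the generator with
within-subclass correlation 0, which is the regime the permutation scheme
actually assumes; with correlated blocks the enrichment p-values should be
read as descriptive rankings rather than calibrated error rates.

## The synthetic-study generator

The generator is a first-class module, not a test fixture. It emulates:

* **Cohort structure** — three cohorts of 443/163/125 subjects whose
  percent-change outcomes have mean ± SD of $-16 \pm 105$, $-16 \pm 42$
  and $-71 \pm 21$ respectively, with matching covariate distributions
  (age, sex, race as AA/EA/other, baseline weight and weight change,
  clinical triglycerides), and baseline HOMA-IR drawn log-normal at each
  cohort's mean/SD (2.4 ± 1.6, 2.0 ± 1.5, 9.6 ± 5.8) so baselines stay
  positive.
* **Panel structure** — 765 metabolites in 22 HMDB-style subclasses,
  roughly half lipid-like; per-metabolite log-scale locations
  $\sim N(12, 3^2)$ and scales $\sim U(0.4, 1.6)$, CVs in $(0, 0.5]$.
* **Correlation** — log-levels within a subclass are exchangeable with
  correlation $\rho = 0.5$ by default (one common factor per block),
  mimicking the tightly correlated triacylglycerol block in real panels
  without modelling lipid chemistry; the common factor of neutral-lipid
  blocks loads 0.6 on standardized log clinical triglycerides, so lipid
  metabolites correlate with the triglyceride covariate as they do in
  real data.
* **Outcome model** — built additively on the percent-change scale:
  cohort mean + planted per-metabolite effects on centred log-abundances
  + small covariate terms + Gaussian residual at the cohort's outcome SD.
  This is exactly the scale and form the regressions fit, which keeps
  parameter-recovery tests sharp; it does not simulate glucose/insulin
  dynamics, so follow-up HOMA-IR (back-computed from the percent change)
  can occasionally be non-positive in the heaviest-tailed cohort — the
  analysis only consumes the percent change, and real studies handle such
  tails via the outlier rule.
* **Planted truth** — a homogeneous negative effect in a 30-member
  triacylglycerol-like block ($\beta = -16$ % per log-unit in every
  cohort, about 0.15 pooled-outcome-SD per typical metabolite log-SD) and
  a sign-flipping effect in a 14-member amino-acid-like block
  ($-4 / -8 / +12$ in the behavioral/exercise/surgical cohorts, echoing
  the magnitude and pattern of published heterogeneous amino-acid
  analogues). The generator echoes the effect list as a ground-truth
  ledger for recovery tests.
* **Messiness** — missing abundance cells completely at random (2%
  default; the real filter rule is about *pooled* missingness, and MCAR
  is the neutral mechanism absent any stated one), and optional extreme
  outcomes displaced to $\pm d \cdot \mathrm{SD}$ with $d$ solved so the
  displaced points still exceed the 5-SD threshold after inflating the SD
  themselves ($d^2 > k^2(n - m)/(n - 1 - k^2 m)$ for $m$ outliers, with a
  deterministic escalation loop and a post-hoc check) — so the exclusion
  rule fires on exactly the planted subjects.

What the generator does **not** emulate: raw spectra, retention times,
batch effects, skewed or heavy-tailed abundance distributions,
missingness that depends on abundance (censoring at the detection limit),
or longitudinal metabolite trajectories. Consequently, passing recovery
tests demonstrate that the *statistical machinery* is correct and
calibrated under its stated assumptions — not that those assumptions hold
in any particular real dataset.

## Numerical and reproducibility choices

* Every stochastic step is seeded; one master seed determines the whole
  study (per-cohort seeds are derived as seed + cohort index, the
  enrichment stream as seed + 101, per-size null streams as seed + size,
  generated in increasing size order so results cannot depend on set-file
  ordering).
* All outputs are TSV with `.` decimals and `NA` for missing, each
  carrying `#` header lines with the tool version, seed and a
  configuration hash; two runs with the same configuration are
  byte-identical, and the JSON manifest cross-checks row counts.
* Univariate fits use closed-form normal equations vectorized across
  metabolites; the full model uses `lm.fit` with SEs from the QR factor.
  Both paths are validated against `lm()` and a normal-equations oracle
  to $10^{-10}$ in the test suite; the meta-analysis layer is validated
  against an independent straight-from-formula oracle and against
  `metafor::rma(method = "DL")`, and the enrichment walk against
  `fgsea::calcGseaStat` and exhaustive enumeration.
* Degenerate inputs are contracts, not surprises: zero-SD outcomes
  exclude nobody; $k = 1$ studies return $Q = 0$, df $= 0$, missing
  heterogeneity p; all-zero member statistics with $w > 0$ are an error;
  an ES with no same-sign null yields a missing NES with a warning.

## Problem sizes used in validation

The shipped validation suite exercises: formula-oracle equivalence on
1,000 random study triples; exhaustive enrichment enumeration on 100
random lists of length up to 8 with all member subsets of size up to 3;
null calibration on 50 replicate three-cohort studies (200 metabolites,
20 sets, $n = 200/100/80$, 2,000 permutations); and planted-effect
recovery on 20 replicate full-scale studies (765 metabolites,
$n = 443/163/125$, 10,000 permutations) for both the association and the
heterogeneity analysis. These sizes were chosen so the whole suite runs
comfortably on a laptop while leaving the recovery checks enough
replicates to be binding.

## Known limitations

* DL-with-z inference is slightly anticonservative at $k = 3$ when
  $\tau^2 > 0$; this is the classical behavior of the estimator the
  schema pins, not a defect of the implementation.
* The enrichment test is competitive with a membership-permutation null;
  see the calibration caveat above.
* Race is generated and modelled as a small categorical (AA/EA/other);
  finer ancestry structure, and whether the original analyses entered
  race as binary or multi-level, is unknown — the encoding is
  configurable at the model layer, defaulting to multi-level with the
  largest category as reference.
* The generator treats the 765-metabolite panel as the post-filter panel;
  it does not attempt to reconstruct the larger pre-filter feature set
  from which unnamed and high-missingness features were removed.
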