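---
title: "Expression-based prescreening for CD30-positive tumors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-based prescreening for CD30-positive tumors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cd30screen)
library(dplyr)
```

## The screening model

`cd30screen` evaluates a two-stage biomarker screen. Stage one is cheap and
retrospective: every tumor in a consented clinical-genomic warehouse
already has an expression profile, so the target gene's expression can be
ranked across the whole collection at no marginal cost. Stage two is
expensive and prospective: confirmatory immunohistochemistry (IHC) on
archival FFPE tissue. The question the pipeline answers is how much stage
one enriches stage two — if we only stain RNA-high tumors, what fraction
will actually be protein positive, and how many protein positives do we
forfeit in the RNA-low and RNA-medium arms?

### Global Z-scores and trichotomization

Probe intensities are assumed to arrive summarized per sample (one value
per sample for the target gene). `scale_and_log()` multiplies a raw
intensity vector by the single factor that brings its trimmed mean to 500,
then takes log2 — the classic array scaling convention, which makes
samples comparable without altering relative (log-scale) differences.
`global_z()` standardizes the log2 values against the mean and standard
deviation of the *entire multi-tissue collection*:

$$ z_i = \frac{x_i - \bar{x}}{s}, \qquad
   s^2 = \tfrac{1}{n-1}\sum_i (x_i - \bar{x})^2 . $$

The deliberate choice of a *global* rather than per-tissue standardization
reflects the screening question: "which tumors, anywhere in the warehouse,
express this gene highly?" A per-tissue Z would erase exactly the
between-tissue differences the screen exploits. The cost is that the cutoff
behaves differently in tissues whose whole distribution sits high (lymph
nodes) or low (liver); a per-indication recalibration is out of scope here.

Samples are trichotomized at ±1 global SD: **low** (z ≤ −1), **medium**
(−1 < z < 1), **high** (z ≥ 1). Both boundaries belong to the outer
groups — exactly −1 is low and exactly +1 is high — and the three intervals
partition the real line, so `categorize_z()` is a pure function of z.

### The eligibility funnel

`apply_funnel()` applies the cohort filters in a fixed order — consented →
active consent → alive → FFPE available → expression available →
z ≥ threshold — each stage filtering the survivors of the previous one, so
counts are non-increasing by construction. Stage order matters only for the
intermediate counts, not for the final cohort (the filters commute); the
fixed order mirrors how a warehouse query would be refined in practice.

### Tissue-of-origin enrichment

For each tissue with at least `min_n = 50` samples,
`summarize_tissue_enrichment()` tests the 2×2 table

|            | z ≥ 1 | z < 1 |
|------------|-------|-------|
| tissue     | a     | b     |
| all others | c     | d     |

with a two-sided Fisher exact test. The background ("all others") is every
other sample *supplied to the function* — the caller decides whether
tissues below `min_n` contribute to the background by filtering the input
first. We kept this explicit because the reference summaries the package
calibrates to are reproducible under the 13,670-sample background of the
listed tissues (see `cd30_tissue_summary()` and the acceptance tests).

`fisher_exact_2x2()` computes the two-sided p by the minimum-likelihood
rule: conditioning on the margins, it sums the hypergeometric probabilities
of every table whose probability does not exceed the observed table's,
with the customary `1 + 1e-7` relative tolerance so that mathematically
tied tables (e.g. in symmetric margins) are included despite floating-point
rounding. This matches `stats::fisher.test()` — which the test suite uses
as an independent cross-check — but the vectorized enumeration here is
roughly an order of magnitude faster per table, which the exhaustive
oracle-equivalence test (every table with total ≤ 60) relies on. The
reported odds ratio is the sample odds ratio \(ad/bc\) (0 or ∞ with a zero
cell, no continuity correction): it only orients the `direction` column;
the p-value is the inferential quantity. No multiple-testing correction is
applied across tissues, matching how such screening tables are usually
reported; consumers comparing many tissues should adjust p-values
themselves (`p.adjust`).

### IHC H-scores and positivity

A staining profile gives the percent of cells at intensities 0, 1+, 2+, 3+
(summing to 100; fractional percentages allowed, since the formula is
defined on reals even though pathologists usually report integers). The
composite H-score is

$$ H = \sum_{i=0}^{3} i \cdot \mathrm{pct}_i \in [0, 300], $$

and \(H/100\) is the mean per-cell staining intensity. Two positivity
rules coexist: the trial-eligibility rule (≥ 10% of cells stained at any
intensity > 0) and the protein-expression-group rule (H ≥ 10). Because
every stained cell contributes intensity ≥ 1, \(H\) is at least the
stained percentage: fraction-positivity *implies* H-positivity, while the
converse fails (5% of cells at 3+ gives H = 15 but only 5% stained). The
concordance stage uses the H-score rule as protein truth by default
(`truth = "hscore"`), with the fraction rule available by configuration.
Staining compartments (membranous/cytoplasmic/Golgi) are pooled, not
modeled separately.

### Concordance metrics

`build_confusion()` treats RNA-high as the screen-positive call and pools
low + medium as screen-negative — the pooling under which the reference
per-tumor metrics reproduce. Metrics are standard:
accuracy = (tp+tn)/n, sensitivity = tp/(tp+fn), specificity = tn/(tn+fp),
PPV = tp/(tp+fp), NPV = tn/(tn+fn), reported as percents. A metric is `NA`
(never 0 or 100) when its denominator is zero *or* when the screen arm it
conditions on is empty: if nothing is screen-negative, a "specificity" of
tn/(tn+fp) = 0 would be an artifact of the degenerate partition, not an
estimate. Reported values are rounded half away from zero to integer
percent (`round_half_away()`), the convention under which 70.37 → 70 and
79.31 → 79; base R's round-half-to-even would disagree on exact halves.
`metric_ranges()` takes min/max per metric across strata after this
rounding.

## The synthetic warehouse

`simulate_warehouse()` draws, from a single seeded RNG stream:

* a tissue for each patient from `tissue_mix` (default: the 24-tissue
  mixture of `cd30_tissue_summary()`, proportional to its sample counts);
* one log2 expression value from the tissue's normal distribution
  (defaults: the per-tissue mean/SD of the reference summaries, used
  directly on the Z scale — legitimate because global Z-scores are
  invariant to any common location/scale change of the log2 values);
* four independent eligibility booleans with the per-stage retention
  probabilities (defaults: the stage ratios of `cd30_funnel_counts()`,
  e.g. active consent 99,241/120,887 ≈ 0.821);
* a latent protein-positivity flag per sample, Bernoulli with the
  configured probability for the sample's RNA group (defaults: 0, 1/39,
  12/39 for low/medium/high — the pooled reference screening rates), where
  groups come from trichotomizing the simulated warehouse's own global Z;
* a staining profile per sample consistent with the latent flag.

`simulate_staining()` is an exact inverse model of the scoring rules. For
a positive sample the stained fraction \(s\) is uniform on \([10, 100]\);
since \(H \ge s\), both positivity rules then hold. For a negative sample,
random intensity proportions give a mean stained-cell intensity
\(m \in [1, 3]\) and \(s\) is drawn uniform on \([0, 10/m)\), so
\(s < 10\) and \(H = s\,m < 10\) simultaneously. The round trip through
`score_ihc()` therefore reproduces the latent flags with zero error — a
property the suite asserts — which keeps the simulator honest about the
scorer's thresholds rather than approximately consistent with them.

Deliberate simplifications, and what they imply about test coverage:

* **Independent funnel stages.** Only marginal stage ratios are
  calibrated; in reality vital status, tissue availability and assay
  availability are correlated. Cumulative survival fractions are products
  of the per-stage rates, which is what the tests check; absolute
  stage counts of a real warehouse are *not* reproducible this way and are
  used only as rate calibration.
* **Group-conditional protein truth.** Latent IHC truth depends on the RNA
  group only, not continuously on Z, because group-level concordance rates
  are the only calibration available. A dose–response model would change
  within-group heterogeneity but not the group-level quantities the
  pipeline reports.
* **One sample per patient**, no longitudinal follow-up, no probe-level
  simulation: the funnel is patient-level and the scoring starts from
  per-sample values, so none of these would add testable behavior.
* **Normal per-tissue expression.** Real per-tissue Z distributions are
  skewed and sometimes multimodal (the reference summaries' means and
  medians differ); matching mean/SD suffices for threshold-crossing rates
  to first order but the simulator will not reproduce tail shapes. Passing
  tests therefore demonstrate correctness of the *pipeline arithmetic*
  under a known generative model, not distributional realism of any single
  tissue.
* `prop_metastatic = 0.2` labels a disease setting on each record for
  schema completeness; no downstream stage currently branches on it. The
  value is a round figure for a mixed primary/metastatic collection.

### Standardization scope

Whether a funnel's final-stage Z-scores should be standardized over the
whole warehouse or recomputed within the funnel survivors is genuinely
ambiguous in practice (the survivor set is what a trial would screen, but
the global set is what the warehouse ranks). `run_config(z_scope =
"global" | "survivors")` exposes both: under `"survivors"` the mean/SD
come from patients passing the four eligibility booleans and are applied
to every sample, so survivors are standardized within their own set while
non-survivors still receive comparable scores. The default is `"global"`.

## Numerical choices

* **Trim fraction 0.02 per tail** in `scale_and_log()` (the scaling
  convention for this normalization family; `mean(x, trim = 0.02)` drops
  `floor(0.02 n)` values per end). Scaled values are floored at 1 before
  log2 so zeros map to 0 rather than −∞; only degenerate inputs are
  affected.
* **Sample (n−1) standard deviation** for Z — the default of essentially
  all statistical software; at warehouse sizes the n vs n−1 distinction is
  far below the ±1 cutoff's resolution, but it is pinned down so results
  are bit-reproducible.
* **Fisher ties**: the `1 + 1e-7` relative tolerance when comparing table
  probabilities (see above), the mainstream convention.
* **KDE**: `tissue_density()` uses Gaussian kernels with per-tissue
  Silverman (`bw.nrd0`) bandwidths on one shared grid spanning the pooled
  data ± 3 × the largest bandwidth, so every curve integrates to 1 within
  1e-3 on the grid and curves are directly overlayable.
* **Determinism**: every stochastic operation takes or derives from a
  single integer seed via `withr::with_seed`, and `run_pipeline()` output
  is byte-identical across runs of the same config (the run log contains
  versions, seed, thresholds and row counts — no timestamps).

## Problem sizes in the test suite

Statistical recovery tests use warehouses of 50,000–60,000 patients (3
standard-error bands around configured rates), chosen so that binomial
standard errors are small enough to detect calibration errors of a few
percent while the whole suite stays fast; the exhaustive Fisher
oracle-equivalence test enumerates all ~6.4 × 10⁵ tables with total ≤ 60;
uniformity of per-group sampling uses 4,000 replicate draws with a
4-standard-error band to control the family-wise false-alarm rate across
100 simultaneous member frequencies.

## Known limitations

* The global-Z cutoff is not recalibrated per indication; tissues with
  uniformly high or low expression will see distorted within-tissue group
  splits (lymph nodes vs liver is the canonical contrast).
* Diagnostic metrics are point estimates without confidence intervals, and
  no ROC analysis over alternative Z cutoffs is provided — the pipeline
  evaluates the single published cut.
* The Fisher enrichment p-values are unadjusted across tissues.
* The simulator's independence and normality assumptions above mean its
  outputs validate the pipeline, not any particular clinical population.
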