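---
title: "Methods: copy-number-guided outcome signatures for germ cell tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number-guided outcome signatures for germ cell tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical procedure it
implements, the assumptions behind it, the parameters that matter, and the
design decisions taken where more than one reasonable convention exists.

## The analysis in one paragraph

Array-CGH log2-ratio profiles from a training cohort of non-seminomatous
germ cell tumors are segmented into regions of constant copy number, and
per-clone gain/loss calls are tested for association with two clinical
endpoints: two-year disease-free survival (2yDFS; poor = never disease
free, recurrence, or disease death within 24 months) and five-year
disease-specific survival (5yDSS; poor = dead of disease within 60 months;
patients censored alive earlier are ineligible). Significant clones chain
into genomic regions, expression probes inside those regions are screened
for dosage-driven differential expression, and the surviving genes build a
nearest-shrunken-centroid classifier whose predictions are evaluated on an
independent validation cohort — prediction rate, Kaplan-Meier separation,
log-rank test, and a multivariate model adjusting for IGCCCG clinical risk.

## Segmentation

`cbs_segment()` implements circular binary segmentation. For a profile
`x_1..x_n` the candidate change is the arc `(i, j]` maximizing the pooled
two-sample t statistic between the arc and its complement; circular
(wraparound) arcs are equivalent to complementary linear arcs because the
statistic is symmetric under group exchange, so the search runs in linear
index space (a small C++ kernel, `O(n²)` per evaluation). Significance is
assessed by permuting the profile and recomputing the maximal statistic;
the p-value uses the add-one estimator `(r + 1)/(B + 1)` so it can never be
exactly zero. When `p < alpha` the profile splits at the arc bounds and the
procedure recurses.

Numerical and design choices:

- **Per-node seeding.** Each recursion node draws its permutations from a
  seed derived deterministically from the node's bounds. Decisions at one
  node therefore never perturb the permutation stream of another, which
  makes segmentations reproducible and `alpha`-monotone: lowering `alpha`
  can only remove splits, never add them (a property the test suite
  checks).
- **Early stopping.** Permutation draws stop as soon as enough exceedances
  have accumulated that the final p-value cannot fall below `alpha`. This
  is a pure speed-up: the split decision is unchanged.
- **Zero-variance fallback.** If the pooled within-group variance is zero
  the statistic is `+Inf` when the means differ and `0` when they do not.
- **Merging.** Adjacent segments whose means agree to within 1e-9 are
  merged. The full "undo splits" pruning pass of classical CBS is out of
  scope; in practice the permutation gate at `alpha = 0.01` keeps spurious
  splits rare (the suite verifies the split rate on pure noise stays near
  `alpha`).
- **Calls.** Segment means at or beyond `±0.2` log2 become gain/loss calls,
  boundary inclusive. The threshold is configurable; ±0.2 sits between the
  single-copy expectations for gain (+0.58 in pure tumor) and the
  attenuation caused by normal-cell admixture.
- **Missing clones** are removed before segmentation and re-inserted as
  missing calls; they are never imputed.

## Clone association and regions

Each clone is tested with Fisher's exact test (`stats::fisher.test`
provides the exact two-sided p; the suite cross-checks it against a full
hypergeometric enumeration) on the 2x2 table of alteration status by
outcome, built over eligible patients with a non-missing call — margins
shrink with missingness. Gains and losses at the same clone are tested as
separate hypotheses. The odds ratio is the sample `ad/(bc)`: infinite with
an absent interval when no altered patient had good outcome, Woolf's log
interval otherwise (Haldane-Anscombe 0.5 correction when a cell is zero),
with the exact conditional interval available as an option. No clone-level
multiplicity correction is applied — a deliberate mirror of the original
analysis style and a documented limitation.

Significant clones (`p < 0.05`, two-sided) of one alteration type chain
into a region while each gap to the next significant clone is at most
11.5 Mb — a conservative cutoff that absorbs missing clones and
centromeric gaps. Region-level p, OR and altered-patient count are taken
from the minimum-p clone (ties broken by genomic position); the publication-style
report prints `INF`/`N/A` for the infinite-OR rows. Single-clone regions
are kept but flagged. Coordinates are Mb, intervals closed on both ends.

## Target-gene screen

Probes map into regions by a single genomic position (closed interval).
Within a region, tumors altered at the representative clone are compared
with tumors of normal copy number there (tumors carrying the opposite
alteration are excluded) using the SAM statistic
`d_i = (mean_alt − mean_normal) / (s_i + s0)`, where `s_i` is the pooled
two-group scatter and `s0` is the percentile of the `s_i` minimizing the
coefficient of variation of `d` across scatter-quantile windows (for panels
under 20 probes, where windows are undefined, `s0` falls back to the median
scatter). The null distribution comes from label permutations — exhaustive
whenever the number of distinct assignments fits the permutation budget.

**FDR estimator.** For threshold `t` on `|d|`, the estimate divides the
null exceedance count by the observed count. The package defaults to the
*mean* null count rather than the median: with the small per-region panels
screened here (tens of probes), the median count at the top threshold is
zero for roughly half of all null datasets, so a pure-noise screen would
"select" its top probe at an estimated FDR of zero. The mean keeps the null
expectation calibrated (null screens come back empty in ≥90% of runs, which
the suite verifies); both variants appear in the classical SAM literature
and `fdr_method = "median"` restores the other. The selected set uses the
smallest threshold whose FDR estimate is below 10% — the first point where
the FDR drops under the target — and an empty set is a valid outcome.

Fold-change filters are computed as ratios of anti-logged group means
(equivalently `2^` of the log2 mean difference) and *oriented*:
carrier-over-noncarrier for gains, noncarrier-over-carrier for losses, so
passing is always a single strict `>` comparison and a probe changing
against the alteration's expected direction can never pass. A probe is
retained if it exceeds 2x versus tumors without the alteration *or* 3x
versus normal testes (the table headers' "or"); both flags are reported so
conjunctive analyses remain possible. Per-endpoint gene sets are unions
over regions; the combined set is the union across endpoints with
provenance retained.

## Classifier

`nsc_train()` implements the nearest-shrunken-centroid model: standardized
class-versus-overall offsets `d_ik = (x̄_ik − x̄_i)/(m_k (s_i + s0))` with
pooled within-class scatter, `s0 = median(s_i)`, soft-thresholded by a
shrinkage `Δ` chosen by stratified cross-validated misclassification error
(ties resolved toward more shrinkage). We use `m_k = √(1/n_k − 1/n)` — the
variance-correct normalization for a class centroid contrasted with the
overall centroid; published descriptions differ on the sign of the `1/n`
term, and the choice only rescales the `Δ` axis. Class priors default to
training frequencies with a uniform option. Prediction minimizes the
squared standardized distance to the shrunken centroid minus `2·log π_k`;
ties break deterministically by class order. At `Δ = 0` the decisions
equal plain nearest-centroid classification under the same
standardization, and for `Δ` above the largest offset all centroids
collapse and the prior argmax wins — both limits are tested.

Cross-batch normalization (`median_match_normalize()`) rescales each gene
of the second validation batch so its median matches the reference batch,
multiplicatively on the linear scale; this is idempotent and exact (the
suite checks agreement to 1e-9). An additive-on-log2 variant is provided —
the two coincide except in how even-sample medians average across ties.

## Survival evaluation

Kaplan-Meier curves and the log-rank test delegate to the `survival`
package behind `km_estimate()`/`logrank_test()`; the test suite verifies
them against the empirical survivor function (no censoring) and an
independent O−E/V tabulation. The multivariate analysis fits the binary
poor-outcome indicator on the gene-model prediction and IGCCCG risk both
as a linear-probability model (plain linear regression on 0/1 outcome,
reproducing the original analysis style) and as a logistic regression,
with risk coded either continuously (good = 0, intermediate = 1, poor = 2)
or binarily (intermediate + poor merged); complete separation is detected
and flagged with a pointer to exact methods. One clinical note: the
five-year endpoint is referred to as disease-specific survival throughout,
treating "5-year overall survival" phrasing in figure legends of this
analysis style as the same endpoint.

## The synthetic cohort generator

`simulate_gct_cohort()` emulates the structure the pipeline needs, with
ground truth for benchmarking. Defaults define the study conditions:

| parameter | default | rationale |
|---|---|---|
| cohort sizes | 53 train / 54 validation / 10 normals | training and validation sizes mirror the study design; the normal-testis count is unstated there, 10 is a typical reference panel |
| clone map | 4 chromosomes x 55 clones, 1 Mb spacing | ~1 Mb BAC-array resolution at a desk-scale genome |
| planted regions | gain chr1 20-32 Mb (prev 0.25, log-odds +3.0); loss chr2 10-22 Mb (0.25, +3.0); gain chr3 30-40 Mb (0.15, +Inf) | anchored to the observed regime of the study's region tables: median ~15/53 carriers, finite ORs up to ~17.5, plus regions whose carriers all had poor outcome (infinite OR) |
| carrier correlation | unstable fraction 0.25, overlap 0.85 | large gains/losses co-occur in genomically unstable tumors; the study's tables show the same tumors carrying many regions. Marginal prevalence per region is preserved exactly, so per-region carrier counts stay binomial |
| segment shifts | +0.4 / −0.6 log2 | single-copy changes attenuated by admixture |
| aCGH noise | sd 0.15 log2 | typical BAC-array clone noise |
| missingness | 2% clone x sample, independent | "missing/excluded clones" without a stated model |
| dosage effect | fold 2.5, 8 probes/region | between the screen's 2x and 3x filters |
| expression noise | sd 0.5 log2 | typical probe-level variability |
| outcomes | baseline poor rate 0.10; logistic in carried effects; infinite effect = deterministic poor; 80% of poor-outcome patients die of disease within 5 years; 10% of good-outcome patients censored before 60 months | produces ~20-30% poor validation outcomes and a 5yDSS-ineligible fraction like the study's 49-of-54 |
| batch effect | per-gene log-normal factors, sd 0.2 log | motivates the median-matching step; exactly invertible by it |

An early version drew carriers independently per region; that made half
the cohort a carrier of something, pushed the poor fraction to ~40% and
capped attainable prediction accuracy near 70% — the correlated-carrier
structure above is both more faithful and restores the intended regime. A
power calculation drove the region effects: at n = 53 and α = 0.05, a
region with 0.20 prevalence and +2.2 log-odds gives only ~78% Fisher power
in isolation (less in the pipeline, where other regions inflate the
non-carrier poor rate), while 0.25 prevalence with +3.0 log-odds exceeds
98%.

What the generator does *not* emulate: histologic subtypes, serum markers,
focal amplifications, waviness/GC artifacts in aCGH profiles, probe-level
cross-hybridization, or real linkage between copy number and expression
beyond the planted dosage probes. Passing benchmarks on these cohorts
therefore demonstrates that the pipeline recovers the planted statistical
structure at study scale — not that it would reproduce any particular
result on the original tumors.

## Problem sizes

The test suite and the acceptance script run the full pipeline on
study-scale cohorts (53/54 patients, 220 clones, 260 probes) with 200
permutations per CBS test and SAM screen; standalone `cbs_segment()` and
`sam_screen()` default to 1000 permutations. The acceptance script
aggregates 50 seeded cohorts; the suite's end-to-end property uses 100.
These sizes were chosen so a complete run stays interactive on a single
CPU while keeping Monte-Carlo error well below the margins of the
properties being checked.

## Known limitations

- No clone-level multiple-testing correction and no permutation-based
  region significance (by design, mirroring the original analysis).
- The CBS "undo" pruning step is reduced to exact-tie merging.
- The printed ORs/CIs of the original study cannot be reverse-engineered
  into per-clone tables (missingness changed every margin), so agreement
  with them is assessed at the level of statistical regime, not values.
- The linear-probability specification can predict outside [0, 1]; the
  logistic fit is reported alongside it.
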