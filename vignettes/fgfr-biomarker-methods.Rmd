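---
title: "Methods: pan-cancer FGF/FGFR expression biomarker analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-cancer FGF/FGFR expression biomarker analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgfratlas)
```

## Scope and data model

The package analyzes cohort-structured bulk RNA-Seq abundance for the
fibroblast growth factor ligand and receptor families (FGF1–FGF23,
FGFR1–4). Expression is exchanged on the **linear** normalized-abundance
scale (the TCGA legacy RSEM convention) everywhere: positivity cutoffs are
meaningful only on that scale, so log transforms are applied inside each
analysis stage, never at I/O. A gene absent from a matrix is a hard error
rather than an NA — the intended input matrices are dense.

Sample metadata carries cohort code, tumor/normal status, optional matched
pair identifiers, and overall survival (days + event indicator, required
together). Sample IDs are matched exactly; any barcode normalization is
the caller's responsibility.

## Differential expression

Tumor vs normal within each cohort uses the Wilcoxon rank-sum test
(midranks for ties), switching from exact enumeration to the
tie-corrected, continuity-corrected normal approximation once either
group exceeds `exact_max_n = 25` — the branch cross-over where both
methods agree to well under 0.01 in p. A matched-pair mode runs the
signed-rank test on tumor−normal differences, zero differences dropped.
A pooled sample with no ordering information (all values identical) is
returned as degenerate with p = 1 rather than an error.

The effect size is `log2((mean(tumor)+1)/(mean(normal)+1))` on linear
values. Means rather than medians because the downstream interpretation is
of aggregate expression level, and a pseudocount of 1 (small relative to
abundances in the hundreds-to-thousands) keeps zero-mean groups finite and
the estimator antisymmetric under group swap.

Results are tiered on the raw p-value (`p_lt_05`, `p_lt_001`); no
multiplicity correction feeds the tiers, since the screening readout is
deliberately per-cell, but a BH-adjusted column is emitted alongside for
users who want grid-wide FDR. Cohorts with fewer than `min_normals`
(default 1 — cohorts with even a single normal, like skin melanoma in the
motivating atlas, stay in) are skipped with an explicit reason; cohorts
with no normal tissue at all can never be tested and are reported as such.

## Survival association

Per gene and cohort, tumor samples with complete (time, event, expression)
triples enter; "fully characterized" is operationalized as exactly that
completeness requirement. Records with under `min_days = 30` days of
follow-up are excluded (read inclusively: day 30 stays), removing
immediate post-operative deaths whose survival cannot reflect tumor
biology.

Dichotomization uses the **maximally selected log-rank statistic**: every
distinct observed expression value is a candidate threshold (low <
cutoff ≤ high), candidates leaving less than `min_prop = 0.1` of the
records on either side are discarded (the conventional guard of the
maximally-selected-rank approach), and the candidate maximizing the
two-group log-rank chi-square wins, ties broken toward the smaller
cutoff. The log-rank statistic itself is computed from the hypergeometric
observed-minus-expected table at each distinct event time; the test suite
cross-checks it against `survival::survdiff` and against the Cox score
test (to which it is identical on tie-free data).

Because the threshold is chosen to maximize the statistic, the reported
`logrank_p` is anticonservative — it is emitted with an explicit
`cutpoint_selected` flag, and a covariate-permutation p (`cutpoint_perm_p`,
seeded) is available that re-runs the full selection per permutation. The
permutation column is off by default in `survival_scan` (`n_perm = 0`)
because re-running the scan 1000 times per gene×cohort cell dominates the
cost of everything else in the pipeline; enable it for final tables.

Effect estimation is a univariate Cox fit of the high-vs-low indicator
with Efron tie handling (the more accurate of the standard tie
approximations, relevant because simulated and registry survival times
are day-rounded), 95% Wald intervals, and `direction` labelled adverse
(HR > 1) or favorable. Monotone-likelihood fits (all events on one side)
are flagged non-convergent with a signed infinite-HR sentinel instead of
pretending a finite estimate. Degenerate cells — constant covariate, zero
events, too few records — are reported with reason codes, never dropped.

## Drug sensitivity

Cell-line panels pair linear expression with natural-log IC50 (the GDSC
convention; lower = more sensitive) and binary mutation markers.
Expression is log2(x+1)-transformed before Pearson correlation — on the
linear scale a single high-expressing line would dominate r. Correlations
are computed pan-tissue and per tissue with at least `min_lines = 10`
lines; smaller tissues are listed as skipped. Correlation p-values are
raw.

Marker association is the classical two-group ANOVA of log-IC50 on mutant
vs wild-type (identical to the squared pooled-t; the suite checks the
identity to 1e-10), with the mutant-minus-wild-type mean difference as the
effect. Calls use the dual gate **P < 10⁻³ and BH FDR ≤ 25%**, with BH
applied within the marker family only; a negative effect is
`sensitizing`, positive `resistance`. Groups under 2 lines are flagged
not-computable and excluded from the BH family.

## Prevalence-calibrated positivity

A sample is positive for a gene set when **any** member gene meets the
cutoff; the per-sample score is therefore the maximum of the member
genes' linear expression, the only formalization of "FGFR1- or
3-positive" compatible with a single shared cutoff. Only tumor samples
participate (the calibrating trial screened patients' tumors).

Calibration enumerates every distinct observed score in the reference
cohort as a candidate cutoff and selects the one whose achieved positive
ratio is closest to the target prevalence, distance ties going to the
larger cutoff (the conservative, smaller-ratio side). For tie-free scores
this is exactly the k-th largest order statistic with k = round(target·n)
and the achieved ratio is k/n, within 1/(2n) of the target; a tie block
at rank k moves the achieved ratio to the nearest attainable value, which
is reported, never hidden. The cutoff is always an observed expression
value — no interpolation — which keeps the procedure distribution-free
and exactly reproducible. Positivity is inclusive (score ≥ cutoff), so
the calibrated reference count is exact for distinct values.

Per-gene report ratios (FGFR1–4 by default) reuse the single calibrated
cutoff; the output metadata records that assumption. Uncertainty on any
ratio is available by seeded percentile bootstrap over tumor samples.
Useful invariants, all property-tested: ratios are monotone non-increasing
in the cutoff; the set ratio lies between the largest member ratio and the
member sum; ratios are invariant to rescaling expression and cutoff by a
common positive factor; enlarging the gene set never lowers a ratio.

## Synthetic cohorts and panels

The generator exists to give every stage a ground truth, not to imitate
TCGA marginals. Expression is log2-normal (effects are naturally additive
on log2; thresholds live on the linear scale after exponentiation) with
per-gene baseline log2 means staggered over 6–12 so linear values span
the tens to thousands, SD 1.5 by default — dispersion in the range seen
for moderately variable human genes. The default panel is the 22 human
FGF ligand symbols plus FGFR1–4 (FGF15 exists only in rodents, so the
human symbol set skips it).

Survival times are exponential with hazard
`baseline · exp(log_hr_per_sd · z)`, z the standardized log2 expression of
one linked gene — proportional hazards by construction, baseline 1/730
events/day (≈ two-year median survival). Censoring is an independent
exponential whose rate is solved numerically (monotone bisection via
`uniroot`) so the expected censored fraction equals `censor_rate`
(default 0.3); independence keeps the Cox model's non-informative-censoring
assumption true in simulation. Times are rounded to whole days (minimum
1), which deliberately produces ties for the Efron handling to work on.

Matched tumor/normal pairs share a latent per-pair intercept (SD 0.5 on
log2 by default) added to all genes of both members, giving the paired
test genuine within-pair correlation to exploit. Cell-line panels draw
log-IC50 as `α + β·z(log2 expr) + Σ δ·marker + N(0, σ)` with Bernoulli
markers and deterministic largest-remainder tissue apportionment.

Everything is reproducible from the spec seed; the pipeline fans one
global seed into per-stage seeds by a polynomial hash of the stage name,
so adding a stage never shifts another's stream.

What the generator does **not** emulate: empirical per-gene abundance
distributions, gene–gene correlation beyond the pair intercept, batch
effects, copy-number or tumor mutation structure, or informative
censoring. Green tests therefore demonstrate that the statistics recover
what was planted under their own assumptions — not that real TCGA/GDSC
data satisfy those assumptions.

## Validation strategy and problem sizes

The suite pins every statistic to an independent oracle: exact Wilcoxon
p against full enumeration of label assignments (group sizes ≤ 8);
signed-rank against all 2ⁿ sign patterns; log-rank against a hand O−E
table (the 4-record fixture gives chi² = 2.882) and `survdiff`; the
cutpoint scan against brute-force maximization; Cox beta against a
1e-5-resolution grid search of the Efron partial likelihood; BH against
the hand step-up rule. Stochastic guarantees use fixed-seed simulations
sized for stable Monte-Carlo error within a fast default run: null
calibration over a 25-gene × 40-cohort all-null grid (1000 cells,
rejection at α = 0.05 within ±0.02) and 200 null panels of 100 lines
(|mean r| < 0.02); parameter recovery (planted log2 fold change 2, log
hazard ratio 0.7/SD, IC50 slope −0.8/SD, marker effect −1.0) at n =
250–500 within 3 standard errors.

## Limitations

- The cutpoint-selected log-rank p is biased small by design; treat it as
  a ranking score unless the permutation adjustment is enabled.
- Calibration transfers a prevalence measured by one assay (RNA-ISH) onto
  another scale (RNA-Seq abundance) assuming only a monotone
  relationship; the package quantifies nothing about assay concordance.
- The marker ANOVA is two-group only — no tissue or MSI covariates — so
  pan-tissue marker calls can reflect lineage confounding.
- No count-model differential expression (no dispersion estimation);
  the Wilcoxon approach needs no distributional model but pays power at
  small normal counts.
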