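---
title: "Methods: differential methylation analysis for hyperglycemia studies"
author: "glycomethyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation analysis for hyperglycemia studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycomethyl)
```

# The scientific problem

Sustained exposure to high blood glucose leaves marks on the epigenome.
This package implements a complete analysis chain for detecting such marks
in two tissues at two resolutions:

1. **Blood, array resolution.** A paired two-timepoint (stage 1 and
   stage 5, a decade apart) methylation-array study of case/control
   subgroups defined by an oral glucose tolerance test (OGTT): a
   high-glucose-response subgroup and a type-2-diabetes subgroup. The goal
   is a set of differentially methylated positions (DMPs) specific to the
   hyperglycemic cases.
2. **Pancreatic islets, single-base resolution.** Whole-genome bisulfite
   sequencing (WGBS) of donor islets, summarised over a genomic window
   centred on a target CpG, to ask whether the blood signal is echoed in
   the tissue that actually controls glucose.

Between the two sits a **trait-association layer**: derived insulin
indices (HOMA-IR, QUICKI), Welch's t-tests (computable from printed
summary statistics as well as raw data), and covariate-adjusted linear
regression of diabetic traits on target-CpG methylation.

# Beta values

Array methylation is expressed as the beta value
$$\beta = \frac{\max(M, 0)}{|U| + |M| + 100},$$
where $M$ and $U$ are the fluorescent intensities of the methylated and
unmethylated allele probes after background subtraction. Background is
estimated from negative-control probes (mean by default, median
configurable) and subtracted from every analytical intensity; the
subtraction may drive intensities negative, which the formula's max/abs
absorb. The +100 offset is part of the definition and is not exposed as a
parameter. The formula is total on the reals and maps into $[0, 1)$,
monotone increasing in $M$ and decreasing in $U$ — properties the test
suite asserts on grids and random draws.

# The DMP discovery cascade

The cascade runs per subgroup:

1. **Longitudinal gate.** Within each arm, every probe gets a two-sided
   paired t-test on the per-subject stage-5 minus stage-1 beta
   differences. P-values are nominal by design: the original procedure
   uses uncorrected p < 0.05, and we preserve that (a Benjamini–Hochberg
   FDR column is carried for information only). Probes with zero-variance
   differences or missing stage data are flagged and excluded.
2. **Top-k ranking.** Probes passing the gate are ranked by the absolute
   stage-5 case-minus-control mean beta difference and truncated to the
   top k (default 250). The gate is longitudinal and the ranking
   cross-sectional: the gate statistic and ranking key are deliberately
   distinct, and both defaults (alpha = 0.05, k = 250) are parameters.
   Ties are broken by (|delta| descending, p ascending, probe id), making
   selection deterministic.
3. **Case-specific subtraction.** The control-arm set is subtracted from
   the case-arm set (case \\ control). The published description of this
   step reads in the opposite direction, but the published counts (229 of
   250 and 153 of 250 surviving) are only consistent with case-minus-
   control, which is what we implement.
4. **Cross-subgroup overlap.** The case-specific sets of two subgroups are
   intersected; probes surviving both designs are the strongest
   candidates. Direction is annotated from the sign of the case-control
   contrast (hypo = cases lower).

Whether ranking should use the signed or absolute contrast is not
specified in the source procedure; we default to the absolute value
(`rank_by = "abs"`), with the signed variant available.

# Trait association

* **HOMA-IR** $= \mathrm{Ins0} \times \mathrm{Glu0} / 405$ with insulin in
  uU/mL and glucose in mg/dL. The source text prints "mg/mL" in one spot;
  405 is the standard mg/dL constant and the published cohort values agree
  with mg/dL (`homa_ir(8.34, 92.23)` = 1.90 against a printed 1.91), so
  mg/dL is adopted.
* **QUICKI** $= 1 / (\log_{10} \mathrm{Ins0} + \log_{10} \mathrm{Glu0})$.
  The logarithm base is unstated in the source; base 10 is the index's
  standard definition and reproduces the published magnitudes. Note that a
  cohort's mean QUICKI is the mean of per-subject indices, not the index
  of the mean inputs (Jensen's inequality): `quicki(8.34, 92.23)` = 0.3465
  against a printed cohort mean of 0.3522.
* **Welch's t-test** is provided in raw-vector and summary-statistics
  forms, algebraically identical; the summary form exists because
  published tables print only mean ± SD and n, and the test suite checks
  both forms against `stats::t.test`.
* **Covariate-adjusted regression** fits trait ~ methylation + age + sex +
  BMI + WBC + RBC by OLS. The trait is the response and methylation the
  predictor: published coefficient magnitudes (e.g. about −4 mg/dL of
  fasting glucose per percentage point of methylation) are only plausible
  on that orientation. When the analysed trait is itself a covariate
  (BMI), it is dropped from the covariate set. Sex enters as a single
  indicator with "female" as the reference level. Exactly collinear
  designs are rejected with the offending column named.

# WGBS methylation calling

Per-cytosine calls follow ratio-caller conventions: the methylation ratio
is \#C / effective CT count, where the effective count includes only C
(methylated) and T (bisulfite-converted) observations. Three rules matter:

* **Mate overlap.** Where both ends of a read pair cover a position, only
  one mate contributes (mate 1 by default, configurable) — overlapping
  ends must not be double-counted. Pairs with mates on different
  chromosomes are skipped with a message.
* **Reliability.** A call is reliable iff its effective CT count is
  strictly greater than 10 (threshold configurable; the strictness
  follows the stated rule). The filter is idempotent and
  order-preserving.
* **Context.** Cytosines are classified CG / CHG / CHH from the two
  downstream bases on their own strand; minus-strand contexts are read on
  the reverse complement. The two strands of a CpG are always separate
  records — merging is never implicit, because the downstream window
  analysis treats strand records as distinct sites.

Coordinates are 1-based inclusive throughout; bedGraph export converts to
0-based half-open. `count_calls()` operates on simplified per-position
read observations; it exists to make the counting rules testable against
a brute-force tally, not to replace a bisulfite aligner, and the primary
on-disk input is the per-cytosine ratio TSV.

# The windowed DMR analysis

`extract_window()` builds a site × donor percent-methylation matrix from
reliable calls in a 1-based inclusive window; `summarize_window()` then
computes, per stratification of the donors:

* a per-site two-sided **Mann–Whitney U** p-value. For designs where all
  $\binom{n}{n_1}$ group assignments are enumerable (up to 20,000 — this
  covers both the 16-vs-2 disease split, 153 assignments, and all designs
  with ≤ 8 per group) the p-value is exact, computed by full enumeration
  with midranks handling ties; larger designs use the normal
  approximation with tie correction. With 16 vs 2 donors the smallest
  attainable two-sided p is 2/153 ≈ 0.013, and the exact test is
  conservative at alpha = 0.05 (attainable level 6/153 ≈ 0.039);
* **direction tallies** by the sign of the mean change. The change sign
  convention is control minus case (so case hypo-methylation is a
  positive change); published windowed summaries are only internally
  consistent under this convention, and flipping it negates the mean and
  swaps the tallies, which is property-tested;
* the **sDMP count** (sites with p < 0.05) and the **mean change over all
  sDMPs** — all of them, not only the hypo-methylated ones, matching the
  single-row summary convention;
* a **percentile bootstrap CI** of that mean, resampling donors within
  each group (1,000 replicates, seeded) with the sDMP site set held
  fixed. The CI method is a design choice: the asymmetric published
  intervals suggest resampling, and donor resampling (rather than site
  resampling) reflects that donors, not sites, are the exchangeable
  units. Because the site set is fixed while donors are resampled, the
  interval can in principle exclude the point estimate.

Donor stratifications: disease (non-T2D vs T2D), age (young < 40 vs old
≥ 40 — exactly 40 goes to "old", a documented boundary choice), sex, and
sex-matched disease (restricted to the cases' sex, which must be uniform,
otherwise an error). All schemes reuse the same machinery. Sites lacking
a donor in either group are excluded from tallies and counted.

# The synthetic-data generators

The generators exist so that every stage is testable without the
access-controlled cohort data. Their defaults are the study conditions:

* **Array study**: 8+8 subjects per subgroup (5+5 for the second,
  T2D-like subgroup in the drivers), ~1,000 probes at desk scale,
  baseline betas Uniform(0.2, 0.8), measurement noise SD 0.03 on the beta
  scale, planted case effects of −0.11 beta — the blood effect size at
  the strongest replicated CpG. Noise is logit-normal: drawn on the logit
  scale with SD scaled by the delta method (`noise_sd / (mu (1 - mu))`)
  so the beta-scale SD is approximately `noise_sd` at every baseline
  level; this keeps draws in (0, 1) and reproduces the mean-dependent
  heteroscedasticity of real betas. Genome-scale probe counts (~485k) are
  out of scope; no claim of genome-scale fidelity is made.
* **Trait table**: 220 per arm; per-arm trait means and SDs chosen to
  resemble a middle-aged cohort with diabetic cases; a configurable
  linear methylation-trait slope, centred on cohort-mean methylation.
  Strictly positive traits are resampled on non-positive draws (at most
  100 attempts, then clamped to 0.1 with a warning).
* **WGBS panel**: a 10 kb window centred on chr17:55484635 with geometric
  CpG gaps of mean 34 bp, 16 control vs 2 T2D donors (the cases male, 8
  males and 5 under-40 donors in the panel, so all four stratification
  schemes are exercised), 30X Poisson coverage per strand, binomial
  methylated counts, between-donor SD 0.05, and a planted 16-point case
  hypo-methylation — the islet contrast scale. Both strands of each CpG
  are emitted as separate records.

All generators are pure functions of (config, seed): sub-streams are
derived from the master seed by a documented hash (`substream_seed`), so
adding a draw never perturbs existing ones and identical configs
reproduce byte-identical output.

## What passing the synthetic checks does and does not show

The generators emulate the *statistical structure* the analysis assumes —
paired longitudinal design, arm-specific effects, binomial counting noise
at realistic coverage — not real data's probe-specific biases, cell-type
heterogeneity, batch structure, or genomic correlation between
neighbouring CpGs (sites are independent given their group means).
Recovery and calibration results on synthetic data therefore validate the
machinery, not the biology.

Two subtleties the validation experiments respect:

* **Selection bias in the sDMP mean.** With only 2 case donors at 30X,
  conditioning on per-site p < 0.05 selects sites whose noise exaggerates
  the contrast, inflating the sDMP-restricted mean (about 22 points for a
  planted 16). The sDMP-mean recovery check therefore runs under a
  low-noise configuration (donor SD 0.02, 100X) where nearly every site
  is significant and no selection occurs; at the study conditions the
  *all-site* mean change recovers the planted contrast within a fraction
  of a point, and both measurements are asserted.
* **Confounding in slope recovery.** Case and control arms differ in both
  methylation and trait means, so a pooled regression conflates the
  planted within-arm slope with the between-arm contrast. Slope-recovery
  experiments fit within the control arm; the pooled fit is still
  reported by the drivers as what it is — an association estimate.

# Problem sizes and numerical choices

The shipped experiments use desk-scale sizes chosen to keep the full
validation suite fast while leaving all statistics in their asymptotically
valid regimes: 500–1,000 probes, 8+8 subjects, 18 donors, ~580 window
records, 20 seeds for calibration and recovery estimates, 50 seeds for
slope coverage, 1,000 bootstrap replicates for production CIs (reduced in
tests). Exact Mann–Whitney enumeration is capped at 20,000 assignments.
Zero-variance paired differences and all-identical rank vectors are
flagged rather than silently propagated; empty windows, unpaired
subjects, mixed-sex sex-matching, and collinear designs are hard errors.

# Known limitations

* No probe-type correction, dye-bias normalisation, or detection p-values
  on the array side; background subtraction is the only signal
  correction, as in the emulated procedure.
* No multiple-testing correction in the cascade (faithful to the nominal-p
  design); the FDR column is informational.
* The WGBS path starts from per-cytosine counts or simplified read
  observations; alignment, trimming, and duplicate marking are upstream
  and out of scope.
* Cell-type composition of blood is addressed only through WBC/RBC
  covariates, as in the emulated analysis.
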