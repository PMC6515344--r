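---
title: "Quantifying circular-to-linear ratios as disease biomarkers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying circular-to-linear ratios as disease biomarkers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circlin)
```

## The problem

Circular RNAs (circRNAs) arise from back-splicing: a downstream splice donor
joins an upstream acceptor, producing an exonuclease-resistant closed loop.
In spliceopathies such as myotonic dystrophy type 1 (DM1), where expanded
CUG-repeat RNA sequesters splicing regulators (MBNL proteins among them),
circRNA production may be dysregulated independently of the host gene's
overall transcription. The quantity of interest is therefore not circRNA
abundance alone but the **circular-to-linear ratio** — how much of a gene's
splicing output is diverted into the circle — and whether that ratio, alone
or aggregated into a per-sample score, separates patients from controls and
tracks clinical severity.

`circlin` implements this analysis end to end for two measurement arms:

1. **RNA-seq arm.** Back-splice junction reads (CIRI2-style per-sample
   tables) are normalized per million to each library size, filtered on
   group-wise detection, and divided by the read count of the *most
   abundant* linear splice junction sharing the back-splice donor or
   acceptor site. Comparing junction reads to junction reads keeps
   numerator and denominator the same kind of biological observation.
2. **qPCR arm.** Relative expression by the comparative Ct method
   (2^−ΔΔCt, normalized to averaged reference-gene Cts), and circular
   fractions from the raw Ct difference between circular and linear
   assays of the same gene: `log2(circ/lin) = −(Ct_circ − Ct_lin)` under
   the efficiency-2 assumption.

Because the patient data behind this kind of study are not published and
the sequencing arm requires alignment at a scale beyond a desk machine,
the package ships a synthetic-cohort generator that reproduces the
*statistical structure* of such a cohort, with ground truth, so every
downstream claim is tested as a recovery or calibration property.

## The ratio rule in detail

For a back-splice event on the + strand, the donor site is the event's 3'
(end) coordinate and the acceptor its 5' (start) coordinate; the roles swap
on the − strand, and events with unknown strand match in either
orientation. Candidate linear junctions are those on the same chromosome
(strand equal unless either is ".") whose donor equals the event's donor
*or* whose acceptor equals the event's acceptor. The denominator is the
maximum candidate count in that sample. Degenerate cells never produce a
division by zero: a back-splice with no expressed linear partner is
reported `no_linear_partner` ("circular only"), zero circular reads over a
live linear junction give ratio 0 (`zero_circ`), and doubly-zero cells are
`both_zero`. Ties for the maximal linear junction do not change the ratio;
the reported partner is chosen deterministically (smallest donor, then
acceptor, position).

Two readings of the detection filter ("present in at least 70% of either
group") are implemented: `mode = "either"` (kept when either group reaches
the threshold — the default, more permissive reading) and `mode = "both"`.
Presence means raw count > 0: the filter is about detection, not abundance.
Candidate lists can be intersected at event level or gene level; a
gene-level key returns every back-splice isoform of the gene, since
distinct circRNAs of one gene (two isoforms of the same host are common)
are tracked separately.

## Statistical testing

Differential testing per feature follows a normality-gated policy: when
both groups have n ≥ 8 and pass the D'Agostino–Pearson omnibus test
(skewness + kurtosis, K² against χ² with 2 df) at α = 0.05, a two-tailed
pooled-variance Student t-test is used (Welch available by flag, matching
the convention of common GraphPad-style multiple t-test workflows);
otherwise a two-tailed Mann–Whitney test, exact for small samples without
ties and normally approximated with tie correction otherwise. Groups below
n = 8 always use Mann–Whitney, because the omnibus normality test is not
defined there. The D'Agostino–Pearson test is implemented from the standard
moment approximations (D'Agostino 1970; Anscombe & Glynn 1983) since no
installed R package provides it; unit tests pin it to reference values from
an independent implementation.

Multiplicity is controlled with the adaptive **two-stage
Benjamini–Krieger–Yekutieli** procedure at Q = 1% by default: stage 1 is
Benjamini–Hochberg at q′ = q/(1+q); the rejection count r₁ estimates the
number of true nulls m₀ = m − r₁; stage 2 re-runs BH at q′·m/m₀ (nothing is
rejected when r₁ = 0, everything when m₀ = 0). The implementation is
sandwiched by construction between BH at q′ and BH at q′·m/m₀, a property
the tests assert on random inputs, alongside frozen flags from an
independently coded reference for fixed p-value sets. Each analysis
(expression features, ratio features) is treated as its own testing family.

Fold changes are computed on the log2 scale as differences of group means —
ΔCt-derived quantities are natively log2 — so a planted two-fold odds
change appears as a log2 fold change of 1.

## The circular-to-linear score and biomarker evaluation

The per-sample score is the mean, over the significantly modulated feature
set, of per-sample log2 fold changes versus the feature's control-group
mean (equivalently a geometric-mean reference on the linear scale). The
control group is therefore centred at score 0 by construction, and the
score is linear in its feature set: scoring the union of disjoint sets
equals the size-weighted mean of the separate scores (tested exactly).

Discrimination is summarised by the ROC curve with AUC computed as the
Mann–Whitney pair statistic (ties count half), making the AUC invariant
under strictly monotone transforms of the score — so whether ratios enter
on the linear or the log2 scale is immaterial for AUC. The positive class
is the case group, and higher scores are expected in cases; polarity
auto-detection is deliberately not performed. Correlations with clinical
covariates (MRC megascore for muscle strength, percent exon exclusion for
splicing events) use Pearson's r with the conventional t-transform
p-value; |r| = 1 yields p = 0 by convention and zero-variance inputs are
flagged undefined rather than propagated. Disease stages (MIRS 1–5) are
compared as low (≤ 3) versus high (≥ 4) strata of cases with a pooled
t-test; the stratum boundary mirrors the clinical contrast between
ambulatory-proximal and more severe stages, and stage-1 patients are
typically absent from adult biopsy cohorts. For inclusion-type splicing
assays the exported covariate is still *percent exclusion*, so all splicing
events share one axis; the assay direction is kept as metadata.

## The synthetic cohort: what it emulates and what it does not

Per gene g, baseline expression e_g ~ LogNormal(log 50, 1) (reads per
million) and a baseline circular share f_g ~ Beta(2, 8) (mean 20%). Sample
i draws a library size L_i ~ LogUniform(5–20 million reads). Back-splice
counts are negative binomial with mean L_i·e_g·f_gi·10⁻⁶ and dispersion
0.1 (variance μ + 0.1 μ²); total linear reads, NB with the complementary
mean, are split over 2–4 linear junctions (alternately sharing the event's
donor or acceptor site) by per-gene Dirichlet weights, so the
"highest-expressed linear junction" rule faces a non-trivial choice.
Circular and linear expected reads always sum to the gene's budget
L_i·e_g·10⁻⁶: the circular fraction reallocates splicing output rather
than adding transcription.

The planted effect multiplies the circular-to-linear *odds* f/(1−f) of
case samples at designated genes by θ^(1−c+c·s_i), with θ the ratio fold
change (default 2), s_i ~ Uniform(0,1) a latent per-case severity, and c
the severity coupling (default 0.5). Acting on the odds makes the planted
fold analytically equal to the circular-to-linear ratio fold, which the
recovery tests exploit. Severity also drives the clinical covariates: MRC
megascore = 130 − 20·s_i + N(0, 2²) clipped at the control baseline
(controls sit exactly at 130), and MIRS stage = severity quartile mapped
to stages 2–5.

Two noise layers act on the measured fractions:

* **biological**: per gene × sample log2-odds jitter with SD
  `fraction_bio_sd` = 0.65 (≈1.6-fold person-to-person spread of the
  circular share). Without inter-individual variability a qPCR cohort of
  59 samples separates perfectly at θ = 2; 0.65 was chosen once, from the
  analytic AUC formula Φ(shift/σ_eff√2), so that a default cohort yields
  score AUCs in the plausible high-0.8/low-0.9 range reported for
  muscle-biopsy circRNA panels, while severity coupling remains detectable.
* **technical**: Gaussian Ct noise with SD `ct_sigma` = 0.25 cycles,
  typical SYBR replicate-level noise. Ct values are generated as
  `intercept − log2(size_factor × abundance) + noise`; reference genes
  carry abundance equal to the per-sample size factor alone, so
  reference-averaged ΔCt is an unbiased readout of −log2(abundance).

Splicing tables follow percent = baseline + slope·s_i + noise for cases
(baseline + noise for controls), clipped to [0, 100], and also emit the
implied inclusion/exclusion band-intensity pair so gel quantification
round-trips exactly.

**What passing tests do and do not show.** The generator captures
count-level sampling noise, library-size variation, biological spread of
circular fractions, severity coupling, and the coupling of Ct values to
the same ground truth as the counts. It does not simulate reads or
alignment artifacts, CTG-repeat genetics, batch effects, RNA quality
gradients, reference-gene instability, or primer-specific efficiency
deviations — so green tests certify the *statistical machinery* (ratio
rule, test calibration, FDR control, score/ROC behavior, severity
recovery), not performance on any real patient cohort. Library sizes
default to 5–20 million reads, a deliberate desk-scale stand-in for the
much deeper ribo-depleted libraries such studies use; at these depths
per-event counts are smaller, which the abundance filter and status codes
absorb.

## Numerical and design choices

* **Sub-streamed seeding.** One master seed; each table (severity,
  clinical, library sizes, genes, counts, linear split, Ct, splicing)
  derives its own stream, so regenerating one table never perturbs
  another, and every output is byte-reproducible for a fixed config.
* **Determinism at the edges.** Event ordering is (chrom, start, end,
  strand) regardless of input row order; max-linear ties break by
  coordinates; duplicate CIRI2 rows are summed (lossless) with a warning;
  missing Cts are dropped per record, never imputed.
* **Degenerate inputs.** Identical groups give p = 1; all-tied ranks fall
  back to p = 1 rather than NaN; p-values are floored at the smallest
  positive double before FDR so downstream validation (p ∈ (0, 1]) holds.
* **Efficiency correction.** Primer efficiencies (10^(−1/slope) from a
  dilution series, with R²) are reported for assay QC only; quantification
  assumes efficiency 2, as the ΔΔCt convention does once assays pass the
  ≥1.9 check — a slope of −3.9 (efficiency ≈ 1.8) is the canonical flag
  level.
* **Interface.** The R API is the primary interface; `run_pipeline()`
  orchestrates simulate → quantify → test → score → evaluate with a
  manifest (config snapshot, per-stage row counts, md5 digests) and a
  markdown report, and a thin Rscript wrapper (`inst/scripts/circlin`)
  exposes `simulate`, `run`, `quantify`, and `qpcr` subcommands.

## Problem sizes used in the shipped checks

Calibration and recovery properties are exercised at the cohort design the
package defaults to (30 cases / 29 controls): 200-feature null cohorts
over 50 seeds for false-discovery calibration; 5 planted two-fold effects
among 50 nulls over 25 seeds for power and effect-size recovery (with
biological jitter disabled so the only noise is the technical Ct sigma and
the planted log2 fold change is exactly 1); 25 seeds at full severity
coupling for the clinical-correlation pattern; 100 random fixtures for
oracle equivalence of the ratio and AUC computations; and 1000 replicates
for p-value uniformity plus a 1000-vs-1000 Normal-shift cohort for the
analytic AUC limit Φ(1/√2) ≈ 0.7602.

## Known limitations

* The ratio denominator uses a single best linear junction; genes whose
  linear output is spread across many junctions will look more "circular"
  than a summed-denominator definition would suggest. This matches the
  junction-to-junction comparison philosophy but is a definitional choice.
* The qPCR arm assumes perfect doubling; systematic efficiency deviations
  bias fractions multiplicatively (they cancel in case/control fold
  changes but not in absolute fractions).
* FDR control is assessed under independent features; strongly correlated
  circRNA panels (shared regulators) can behave differently.
* The MIRS mapping from severity quartiles guarantees balanced strata in
  simulation, which real cohorts do not have.
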