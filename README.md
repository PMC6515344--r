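# circlin

Circular-to-linear ratio analysis for circRNA biomarker studies.

## What it is for

Circular RNAs (circRNAs) are closed-loop transcripts produced by
back-splicing. In spliceopathies such as myotonic dystrophy type 1 (DM1),
the interesting question is not whether a circRNA is abundant but whether
the **share of a gene's splicing output diverted into the circle** changes
with disease — and whether that change can serve as a biomarker of
diagnosis and severity. `circlin` is for analysts working with:

* per-sample back-splice junction tables (CIRI2 output dialect) plus
  linear splice-junction tables (generic TSV or STAR `SJ.out.tab`), and/or
* long-format qPCR Ct tables with circular and linear assays per gene and
  reference genes,

together with sample metadata (case/control, MRC megascore muscle
strength, MIRS disease stage) and RT-PCR splicing tables (percent exon
exclusion).

## The statistics at its core

* **Circular-to-linear ratio (RNA-seq).** For back-splice event *b* with
  junction count `c_b(i)` in sample *i*, the denominator is the most
  abundant linear junction sharing the event's donor or acceptor site:
  `L*(b, i) = max { count of linear junction j : donor(j) = donor(b) or
  acceptor(j) = acceptor(b) }` and `ratio = c_b / L*` — junction reads
  compared to junction reads. Counts are normalized per million to each
  library size; events detected in fewer than 70% of both groups
  (configurable: either/both) are filtered out.
* **Circular fraction (qPCR).** `log2(circ/lin) = −(Ct_circ − Ct_lin)`;
  relative expression by the comparative Ct method `2^(−ΔΔCt)` against
  averaged reference genes.
* **Differential testing.** Per feature: D'Agostino–Pearson
  normality-gated choice between a pooled t-test and Mann–Whitney;
  across features: two-stage Benjamini–Krieger–Yekutieli FDR at Q = 1%.
* **Circular-to-linear score.** Per sample, the mean log2 fold change
  (versus the control-group mean) over the significantly modulated
  fractions; evaluated by ROC/AUC (Mann–Whitney pair statistic, ties count
  half), Pearson correlation with MRC and percent exon exclusion, and a
  t-test between MIRS stage strata (2–3 vs 4–5).
* **Synthetic cohorts.** Negative-binomial junction counts with per-sample
  library sizes, Beta-distributed baseline circular shares, a planted fold
  change on the circular-to-linear odds coupled to a latent severity, and
  Ct/splicing tables generated from the same ground truth — with the truth
  returned for recovery tests.

## Worked example

```r
library(circlin)
cfg <- simulation_config(seed = 7)   # 30 cases / 29 controls, 50 genes,
                                     # 5 planted two-fold ratio effects
run <- run_pipeline(cfg, verbose = TRUE)
print(run)
```

```
simulate: 50 events x 59 samples
presence filter: 50 of 50 events kept
differential: 4 of 9 fractions significant at q = 0.01
biomarker: score AUC 0.903
# circlin run report

- seed: 7
- cohort: 30 cases / 29 controls
- back-splice events simulated: 50
- events after presence filter: 50 (removed 0)
- circular fractions tested: 9; significant at q: 4

## Differential circular fractions

| feature | test | p | q-flag | log2FC |
|---|---|---|---|---|
| GENE004 | t | 4.75e-06 | yes | 0.93 |
| GENE001 | t | 1.58e-05 | yes | 0.84 |
| GENE003 | t | 0.000438 | yes | 0.78 |
| GENE005 | t | 0.0062 | yes | 0.61 |
| GENE002 | t | 0.102 | no | 0.27 |
...

## Circular-to-linear score

- features averaged: GENE004, GENE001, GENE003, GENE005
- ROC AUC (case vs control): 0.903
- MIRS high (4-5) vs low (2-3): mean 0.85 vs 0.75, p = 0.491

## Score vs covariates

| covariate | r | p | n |
|---|---|---|---|
| mrc_megascore | -0.551 | 6.21e-06 | 59 |
| INSR_e11 | 0.617 | 1.89e-07 | 59 |
| CAPZB_e8 | 0.610 | 2.91e-07 | 59 |
| NFIX_e11 | 0.632 | 7.73e-08 | 59 |
```

Reading this: 4 of the 5 planted genes were recovered at Q = 1% (GENE002's
effect was diluted by its severity coupling in this draw); their estimated
log2 fold changes sit below 1 because the planted two-fold odds change is
scaled per patient by latent severity. The score built from the four
significant fractions separates cases from controls with AUC 0.90,
correlates negatively with muscle strength (stronger patients have lower
scores) and positively with percent exon exclusion of the three splicing
events. The MIRS stratum contrast is positive but not significant at this
default coupling; it sharpens as `severity_coupling` approaches 1.

Passing `out_dir =` to `run_pipeline()` additionally writes all simulated
input tables, result TSVs (schema-versioned), `report.md`, and a
`manifest.json` with the config snapshot, per-stage row counts, and md5
digests; identical config + seed reproduce byte-identical outputs. A thin
CLI wrapper with `simulate`, `run`, `quantify`, and `qpcr` subcommands is
installed at `inst/scripts/circlin`.

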