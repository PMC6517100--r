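# gammscope

Quantitation and pro-inflammatory scoring of glioblastoma-associated
microglia and macrophages (GAMMs).

Glioblastoma (GBM) carries a massive innate-immune infiltrate whose size
and activation state differ between the prognostically favorable
IDH-mutant and the IDH-wild type disease. Measuring that infiltrate from
tissue requires an automated, per-cell immunofluorescence protocol:
nuclei and Iba1-positive cells are segmented from multi-channel images,
positivity thresholds are calibrated against no-primary-antibody controls,
per-tumor marker frequencies are aggregated, and the activation indicators
are combined into a composite score whose median split stratifies overall
survival. `gammscope` implements that whole pipeline — together with a
synthetic-data generator with known ground truth, so every stage is
testable end to end without any patient data — plus the companion
single-cell expression analysis (Ward clustering and curated gene-list
enrichment) that attributes pro- and anti-inflammatory phenotypes to
microglia versus macrophages.

It is written for computational biologists who want either (a) the
pipeline functions (`R/`), or (b) the numbered analysis scripts
(`analysis/`) that reproduce the study-style figures-as-tables on
simulated cohorts.

## The statistics at the core

For each tumor, from segmented cells in QC-passing sites:

- **GAMM content** = `# Iba1+ cells / # total nuclei × 100%`
- **Marker frequency** = `# marker & Iba1 double-positive / # Iba1+ × 100%`
  (undefined when a tumor has no Iba1+ cells; propagated as missing)
- **Positivity thresholds**: for each fluorophore, the smallest intensity
  at which at most 5% of no-primary-control cells score positive.
- **Inflammatory profile** = mean(CD68, HLA-A/-B/-C, TNF frequencies) −
  mean(CD163, IL10, TGFB2 frequencies)
- **Composite score** = Σ of cohort-wise min-max-scaled {profile, Iba1
  intensity, mean cell area}, each scaled so the cohort minimum is 0 and
  maximum 100 → score ∈ [0, 300] "pro-inflammatory units". Tumors are
  split at the cohort median score and overall survival compared by
  two-tailed Student's t-test (lost-to-follow-up excluded).
- **Enrichment**: per expression cluster, upregulated genes (one-vs-rest
  test, BH FDR < 1e-20, ≥ 2-fold) are scored against each curated list by
  the upper-tail hypergeometric probability
  `P(X ≥ overlap)` with the tested genes as the universe, BH-corrected
  across all cluster × list pairs.

## Worked example

```r
library(gammscope)

cohort <- generate_cohort(cohort_config(seed = 20260920))
scores <- composite_score(cohort)
mut <- scores$genotype == "IDH_MUT"
compare_groups(scores$score[mut], scores$score[!mut])
compare_survival(scores)
```

prints (via `analysis/03_score_survival.R`):

```
Composite score: MUT 217.2±47.1 vs WT 70.9±43.0 units (p = 0.000184)
Median split: high 877±235 days (n=6) vs low 246±180 days (n=6), p = 0.000385
MUT tumors in the high group: 4 of 4
```

i.e. on this simulated 13-tumor cohort the mutant tumors score much
higher in pro-inflammatory units, and the high-scoring half of the cohort
survives roughly 630 days longer — the qualitative pattern the score was
designed to expose. The imaging stage that produces such per-tumor values
from pixels is exercised by `analysis/02_segmentation_recovery.R`:

```
Content:  slope 0.993, r 0.9999 over 12 sites of 300 cells
Marker:   slope 0.985, r 0.9997
```

— estimated content and marker frequencies regress on the generator's
ground truth with unit slope. `analysis/05_enrichment.R` runs the
single-cell stage: planted pro-inflammatory-microglia and
anti-inflammatory-macrophage clusters are recovered by Ward D2 clustering
and labeled correctly from their curated-list enrichments (e.g.
`cluster1 vs microglia, 12.0% of list, FDR = 2.3e-05`).

Run all five drivers from the repository root with
`for f in analysis/0*.R; do Rscript $f; done`; tables land under
`results/`.

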