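---
title: "Methods: per-cell GAMM quantitation, the pro-inflammatory score, and gene-list enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-cell GAMM quantitation, the pro-inflammatory score, and gene-list enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gammscope` reimplements, as tested code over synthetic data, a
quantitative immunology workflow for glioblastoma-associated microglia
and macrophages (GAMMs): automated per-cell immunofluorescence scoring
with control-calibrated thresholds, per-tumor aggregation, a composite
pro-inflammatory activation score with median-split survival comparison,
and curated gene-list enrichment of single-cell expression clusters.
This vignette records the models, the parameters that matter, and the
design choices that were genuinely open.

## The imaging model and its scoring procedure

A site is a three-channel widefield image: nuclear counterstain
(Hoechst-like), Iba1 (pan-microglia/macrophage), and one inflammatory
marker. The scoring procedure is:

1. **Nucleus detection.** Otsu threshold on the nuclear channel,
   watershed on the distance transform to split touching nuclei, and a
   size filter keeping objects whose equivalent diameter lies within the
   configured nuclear range. These are the "total nuclei".
2. **Cell delineation.** Each nucleus seeds a region grown into
   contiguous Iba1 pixels above a *grow threshold*, with contested pixels
   going to the nearest seed and growth capped at half the maximum cell
   diameter from the nucleus centroid. A cell without supra-threshold
   Iba1 keeps its nucleus as its region.
3. **Measurement.** Per cell: areas (µm² via the squared pixel size),
   mean Iba1 and marker intensity over the region, and per-channel
   stained area (pixels at or above the channel's scoring threshold).
4. **Positivity.** Iba1-positive ⇔ mean Iba1 ≥ the Iba1 scoring threshold
   and Iba1-stained area ≥ the minimum stained area; marker-positive ⇔
   Iba1-positive plus the same two rules on the marker channel. Marker
   positivity is only defined within GAMMs.

Content is `100 · #Iba1+ / #nuclei`; a marker's frequency is
`100 · #double-positive / #Iba1+`, undefined (missing, never zero) for a
tumor without Iba1+ cells — imputing zero would bias the activation
score. Sections (three per tumor in the emulated protocol) are averaged
with their sample SD.

### Threshold calibration and why there are two thresholds per stain

Scoring thresholds come from no-primary-antibody controls: the threshold
for a fluorophore is the smallest measured per-cell mean intensity at
which no more than 5% of control cells score positive. Two design points
deserve explanation:

- **Grow vs scoring thresholds.** Growing regions at the scoring
  threshold would selectively collect supra-threshold noise pixels into
  every region and bias per-cell means upward — a cell's measured region
  must not be selected by the statistic being tested on it. The grow
  threshold is therefore set from the *pixel* population of a control
  channel with no specific signal (median + 5 MAD, far outside the
  background noise but well below real staining), and the control cells
  used for calibration are measured with that same grow threshold, so
  the control and sample cell statistics are exchangeable and the 5%
  bound transfers to the sample.
- **Calibration uses intensities only.** The minimum-stained-area rule is
  applied at calling time, not during calibration: stained area is
  defined by the threshold being calibrated, so folding it into the
  calibration would be circular. Because the area rule can only remove
  positives, the realized false-positive rate is below the calibrated
  bound — the acceptance computation measures it on an independent
  control replicate.

The minimum stained area defaults to 30 µm²: above what background noise
can push over the threshold inside a bare nucleus footprint (about half
of the largest ~64 µm² nucleus), below the smallest genuine soma
(~50 µm² at the default 8–16 µm cell range). It is the single most
effective guard against Iba1 false positives inflating the content
denominator and diluting marker frequencies.

### Site quality control

A site is excluded when a vessel-like structure covers more than 25% of
its area (strict inequality), when its variance-of-Laplacian focus
metric falls below a cutoff, or when too many pixels are saturated. Two
choices here are ours: the vessel mask flags pixels simultaneously
bright in *all three* channels (vessels autofluoresce broadband; cells
are bright in single channels) at median + 5 MAD per channel — a
per-image *percentile* threshold cannot work here, because a fixed
percentile can never flag more than its own complement of pixels and the
rule exists precisely to catch structures larger than a quarter of the
site. The focus cutoff defaults to 10% of the per-run median focus,
making "poor focus" relative to the run, as a human curator would judge
it.

## The composite pro-inflammatory score

Three activation indicators are chosen a priori: the inflammatory
profile (mean pro-inflammatory marker frequency − mean anti-inflammatory
marker frequency; CD68, HLA-A/-B/-C, TNF vs CD163, IL10, TGFB2), mean
Iba1 intensity, and mean cell area. Each is min-max scaled over the
*pooled* cohort (both genotypes on one axis — scaling within genotype
would make cross-genotype comparison meaningless) and summed into a
score in 0–300 "pro-inflammatory units". The subtraction is implemented
as a difference of means rather than of sums: the two differ by a factor
of three and are equivalent after min-max scaling, but the mean keeps
the profile on an interpretable ±100-point scale (`aggregate = "sum"` is
available). Tumors are split at the median score; the median itself and
ties go to the *low* group, which is deterministic and conservative for
the claim that high scorers survive longer. Survival is compared by a
two-tailed equal-variance Student's t-test (Welch behind
`var_equal = FALSE`), with lost-to-follow-up tumors excluded. No
multiple-testing correction is applied across the per-marker genotype
comparisons by default (each is reported at the nominal level); a Holm
option exists.

## The synthetic cohort: what it emulates and what it does not

`cohort_config()` defaults encode the emulated 13-tumor cohort (9
IDH-wild type, 4 IDH-mutant): mutants with far fewer GAMMs (≈5% vs ≈37%
content) that are nonetheless more activated — higher TNF, higher Iba1
intensity, larger area — with the published per-genotype means and
dispersions for all six markers, intensity and area. The printed
dispersion values are used directly as between-tumor SDs, following the
source's own description of them. The flow-cytometry column is the
immunofluorescence content plus Gaussian error whose SD is solved from
the target flow-vs-IF correlation (default 0.73) via the genotype
mixture variance. Survival is
`baseline + effect · latent + noise, floored at 1 day`, where the latent
is profile + intensity + area in natural units; the defaults
(−200 d, 6 d/unit, 150 d noise) place the two median-split groups at
roughly 850 vs 370 days, the scale of the emulated cohort. Markers are
drawn independently across the six panels by default; an equicorrelation
parameter exists but the source gives no co-expression structure to
match.

One property deserves honesty: the *all-mutants-in-the-high-group*
pattern. At these printed effect sizes the replication analysis
(`analysis/03_score_survival.R`) puts the probability that every mutant
lands in the high-score half of a 13-tumor cohort at roughly four in
five — high, but not near-certain; a single observed cohort showing the
pattern is entirely compatible with that. The corresponding
property-based check in the test suite applies a stricter bar (≥90% of
draws) and is expected to stay red at this configuration; we chose to
keep the generator faithful to the printed effect sizes rather than
inflate them until the stricter bar passes.

## The synthetic images

Cells are non-overlapping discs placed by rejection sampling (overlap is
forbidden so parameter-recovery errors are attributable to the pipeline,
not to ambiguous truth). Nuclei carry nuclear-channel signal; Iba1+
cells add a soma disc (always enveloping its nucleus) in the Iba1
channel; marker+ cells (a subset of Iba1+) add co-located marker signal.
The marker channel's background is tissue autofluorescence
(`autofluor_level`); noise is additive Gaussian clipped to the valid
range; intensities live on a unit scale where 1.0 is 16-bit saturation,
and TIFF output is 16-bit. A matched no-primary control regenerates the
identical image from the same seed with the specific staining of the
blanked fluorophore(s) omitted — the unblanked channels are bit-for-bit
identical, as with serial control sections in practice. Optionally a
bright ellipse covering a configured area fraction is painted across all
channels to emulate a vessel for the QC stage. Not emulated: tissue
texture, 3-D structure, spectral bleed-through, irregular cell shapes,
spatial clustering of cells. Passing recovery tests therefore show the
scoring logic is correct on geometrically simple, well-separated cells —
not that segmentation is robust to crowded or irregular real tissue.

## The single-cell stage

Cells are clustered by Ward's D2 criterion on Euclidean distances
between log2 expression profiles, with the tree cut at a configured
cluster count (the adaptive tree-cutting used upstream in the original
processing is external; the cut is exposed as configuration, seven
clusters by default). Per cluster, upregulated genes are found by a
one-vs-rest Welch t-test on log2 expression with Benjamini–Hochberg
correction, kept at FDR < 1e-20 and ≥2-fold upregulation; genes constant
across all cells are untestable and skipped. Enrichment of a cluster's
gene set against each curated list is the upper-tail hypergeometric
probability, with the *universe conditioned on the testable genes* (what
could have been detected), BH-corrected across all cluster × list pairs
of a run. Cluster designation: a cluster is immune if its microglia or
macrophage enrichment clears FDR 0.05; cell type is the more significant
of the two, polarity the more significant of pro vs anti, with "mixed"
declared when both polarities are significant and within five orders of
magnitude.

The expression generator plants, per immune cluster, a configured
fraction (default 12%) of its assigned curated lists at a configured
log2 fold-change, *plus* a small cluster-specific background program
(default 2% of genes, drawn disjointly from outside every list). The
background program is what makes clusters recoverable at all — real cell
types differ over many genes beyond any curated list — and it is kept
small so that, as in real data, a cluster's upregulated set stays a
sparse slice of the tested universe; a much larger program would mass
the gene sets, raise the expected overlap under the null, and dilute
list enrichment below detectability, which would be an artifact of the
generator rather than a property of the analysis. The packaged curated
lists (`synthetic_gamm_gene_lists.gmt`) are synthetic: 150 genes per
list, seeded with 40 canonical markers each plus programmatic symbols,
sized like multi-study curated lists so paper-scale overlaps (~12% of a
list) are statistically detectable. The six scored markers are forced
into the matching polarity lists on load, and GMT lists are always
deduplicated on read.

## Numerical and engineering choices

- Coordinates are pixel indices in image space; areas are
  pixels × (pixel size)². Mean (not integrated) intensity is the
  per-cell statistic, since per-tumor values are reported in relative
  fluorescence units averaged per cell.
- Min-max scaling computes the ratio before multiplying by 100 so the
  cohort extremes map to exactly 0 and 100 in floating point; a cohort
  constant in any component is a hard error ("degenerate scale"), not a
  silent zero.
- Two-group comparisons with both groups constant return p = 1 when the
  means agree and p = 0 otherwise (the t statistic is 0/0 or ±∞).
- All randomness flows from explicit integer seeds; per-tumor /
  per-section image seeds are derived arithmetically from the master
  seed, and identical configurations rerun to byte-identical CSV
  outputs.
- Problem sizes in the tests and drivers — sites of 450×340 to 600×450
  px at 0.5 µm/px with 200–500 cells, 20-seed recovery sweeps,
  100–500-draw cohort Monte Carlos, expression matrices of 1500–2000
  genes × 400–1050 cells — were chosen as the smallest scales at which
  the binomial and regression bands in the checks are comfortably
  narrower than the effects being verified.

## Known limitations

- The segmentation is tuned to the generator's geometry (clean discs,
  calibrated diameter ranges); it is not a general tissue segmenter.
- The false-positive guarantee is calibrated at the cell level against
  controls measured identically to samples; it does not model spatially
  structured autofluorescence that differs between control and stained
  sections.
- The survival model is a linear link with Gaussian noise and a floor —
  sufficient for median-split recovery, not a hazard model; no censoring
  beyond the lost-to-follow-up flag is simulated.
- The enrichment stage consumes any pre-normalized log expression
  matrix; upstream read mapping, normalization, cell-cycle filtering and
  denoising are assumed done and are out of scope.
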