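---
title: "Quantifying salivary gland fibrosis and its molecular correlates"
author: "rifaquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying salivary gland fibrosis and its molecular correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rifaquant)
```

# The RIFA score

Interstitial fibrosis on a Masson's trichrome-stained labial salivary
gland section is summarised by the relative interstitial fibrosis area:

$$\mathrm{RIFA} = \frac{\text{total interstitial fibrosis area}}
                       {\text{total gland area}},\qquad
  \text{fibrosis area} = \sum \text{green areas} - \sum \text{yellow areas},$$

where green outlines delimit fibrosis and yellow outlines delimit
non-fibrotic regions that lie inside them. Two details make the score
well defined:

* **The 50 µm² rule.** An enclosed non-fibrotic object smaller than
  50 µm² is *not* subtracted — at typical scan resolutions such specks are
  staining artefacts or single shrunken cells, not tissue compartments.
  The boundary case is not self-evident from the verbal rule ("less than
  50 µm² … not excluded"); the package subtracts an object of exactly
  50 µm² (subtraction iff area ≥ 50 µm²), and the constant is exposed as
  `minIslandUm2` everywhere.
* **What counts as enclosed.** On rasters, a non-fibrotic connected
  component is an island iff every pixel bordering it (4-neighbourhood)
  is fibrosis; components touching the image border or non-gland tissue
  are exterior stroma and are never subtracted. On polygons, a yellow
  outline must fall inside a green outline; a non-contained yellow
  polygon triggers a warning (and is ignored under strict containment).

Areas travel px → µm² → mm² using the µm-per-pixel metadata; a missing
pixel size is a hard error rather than a guessed default, because RIFA's
island rule is resolution dependent. The gland denominator is taken as
all tissue inside the gland outline, including lumina and adipose space
(the alternative — subtracting unstained intra-gland space — is not
well defined on every section and is not what outline-based measurement
produces).

## Two measurement paths

The *annotation path* (`rifaFromAnnotations`) is the faithful
re-implementation of outline-based measurement: shoelace polygon areas,
exact arithmetic, no segmentation. The *automated path*
(`rifaFromImage`) replaces the human outlines: Beer–Lambert optical
densities, least-squares colour deconvolution onto two published
Masson-trichrome stain vectors (collagen blue vs cytoplasm red,
overridable when a scanner is calibrated differently), Otsu thresholding
of the collagen channel inside the gland mask (with a small
optical-density floor so blank tiles yield empty masks), and
luminance-based gland segmentation with hole filling. Both paths share
one RIFA arithmetic (`rifaFromMasks` / `rifaFromAnnotations`), so the
subtraction rule cannot drift between them. Vector/raster agreement on a
rasterised worked example is part of the test suite (tolerance 0.005,
the rasterisation error of a 1000×1000 scene).

# Expression screens

Microarray-style intensities (linear scale, genes × samples) are quantile
normalised (via limma; tied values receive the mean of the reference
values across their rank span), then filtered to genes carrying a
Present or Marginal detection flag in at least 4 of 20 samples
(generalised as ⌈0.2·n⌉ when the sample count differs). Differential
expression reports the fold change as the **ratio of group means on the
linear scale** (a flag converts log2 input first) and a two-sided
Student's t-test — pooled variance by default, since that is what
"Student's t test" denotes, with Welch as an option. Selection is strict:
fold change > 1.5 (or < 1/1.5 for down-regulation) *and* p < 0.05; a
gene at exactly 1.5 is excluded. No multiple-testing correction is
applied by default, mirroring the raw-p design of the original screens.

The RIFA screen computes a per-gene Pearson correlation against the
per-sample RIFA vector, with p from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom, and selects
genes with $r > 0$ and $p < 0.05$ — a positive-only selection on a
two-sided p, so the null selection rate is ~2.5%, which the test suite
verifies over 200 null simulations.

Two calibration facts are worth stating because the tests rely on them:

* Under the generator's null (log-normal noise, no planted effects), the
  DE *t-test* fires at its nominal ~5%, but the joint rule
  (FC > 1.5 **and** p < 0.05) is strictly more conservative and fires at
  ~1% at this noise level; the joint rate can never exceed the t-test
  rate, so the suite asserts ≈5% for the t component and ≤5% for the
  joint rule.
* Quantile normalisation of a *small* panel in which many genes share one
  covariate attenuates the shared signal: forcing every sample to a
  common distribution removes part of a shift that 16 of 200 genes carry
  together (measured here as a drop from ~15.5 to ~11.8 of 16 recovered).
  The planted-recovery property is therefore evaluated on the screen's
  own input contract (the generated matrix); the pipeline still
  normalises first, as a real analysis would, and with genome-scale
  panels the attenuation is negligible.

# Cell-type attribution

Single-cell counts are QC-filtered with deliberately asymmetric
strictness taken from the source protocol: cells are kept with strictly
*more than* 200 and strictly *fewer than* 2500 unique features, and
removed when strictly *more than* 15% of counts are mitochondrial (a
cell at exactly 15% is retained). Normalisation is
$\ln(1 + 10^4\,c_{gi}/\sum_g c_{gi})$. Per-cell-type averages are taken
on the de-logged scale ($e^x - 1$), matching the average-expression
convention of the standard single-cell toolchain (an arithmetic mean of
logs is available behind a flag). The percent-of-total statistic then
divides a gene's average in each cell type by its sum over all types
(×100), which weights every gene equally regardless of absolute level.

The enrichment question — "is this gene list concentrated in
fibroblasts?" — is answered with a two-sample t-test of the target
type's per-gene percents against the pooled percents of all other types.
The comparison family is not fully determined by a single reported
Bonferroni p per cohort, so the package's primary report multiplies by
the number of cell types (each type could have been the target) and also
emits every target-vs-single-type test corrected by (types − 1); the
output labels this interpretation. When a cohort column is present the
analysis runs per cohort, mirroring two-cohort designs. Clustering and
marker-based labelling are out of scope: cell-type labels are an input.

# Promoter accessibility and motifs

A promoter is the 1000 bp upstream of a transcription start site. With
0-based half-open coordinates, a + strand TSS at $t$ gives
$[t-1000, t)$; for a − strand TSS the package takes the 1000 bases 3′ of
the position in genome coordinates, $[t+1, t+1001)$ — upstream in the
gene's own orientation. Promoters are clipped at chromosome bounds (and
flagged), and overlapping or book-ended promoters are merged regardless
of strand — a merged region may serve genes on both strands, because
regions, not genes, are merged. Per-base depth comes from read
intervals (optional coordinate-identity deduplication; true
optical-duplicate logic belongs to upstream tooling), and a region's
coverage is its mean depth **including zero-depth bases** (an option
excludes them). Region sets are compared with a two-sided t-test and a
Bonferroni multiplier equal to the number of comparisons in the run.

One estimation detail: in the package's toy genomes, the "openness
ratio" of a planted gene set is estimated against the *background*
(non-set) promoter mean. With only 60 promoters, the 16 open ones
contaminate an all-promoter denominator (the ratio would converge to
~1.9 rather than the planted 3); at genome scale the two denominators
coincide, so the background mean is the consistent estimator at any
scale.

Motif scanning is a plain log-odds PWM scanner rather than an external
tool: $\mathrm{pwm}_{b,i} = \log_2\frac{(\mathrm{pfm}_{b,i} +
\epsilon\,q_b)/(\sum_b \mathrm{pfm}_{b,i} + \epsilon)}{q_b}$ with
pseudocount $\epsilon = 0.25$ and background $q$. Both strands are
scanned (reverse complement), N scores as background, and a window is a
hit when its score reaches a fraction (default 0.8) of the maximum
attainable score. This fraction-of-max threshold replaces the p-value
threshold of external scanners; an exact score-distribution p-value
(dynamic programming on a discretised score lattice, for motifs up to
~15 columns) is provided for users who want the p-value view.
Transcription factors are ranked by the number of *distinct* gene
promoters hit — duplicate hits in one promoter count once — with ties
broken lexicographically.

# The synthetic-data layer

The generators are first-class, tested code; their defaults encode the
study conditions end to end:

* **Slides** (`simulateTrichromeImage`): an elliptical gland, fibrosis
  grown from quasi-disc seeds to a target area fraction, enclosed
  non-fibrotic islands of *exact pixel areas* carved into per-island
  fibrotic anchors (guaranteeing enclosure), rendered through two stain
  vectors in optical-density space with Gaussian sensor noise
  (σ = 0.01). The recorded truth applies the island rule to the final
  masks — random growth can enclose accidental small holes beyond the
  planted islands — and the suite recomputes it with an independent
  flood-fill pixel-count oracle.
* **Expression** (`simulateExpressionData`): 20 samples in four
  microscopic groups of five; per-group RIFA means 0.06/0.27/0.32/0.60
  with SDs equal to the corresponding SEMs × √5; log-normal baseline
  intensities so the fold-change-of-means is well defined; planted genes
  follow $E[x] = \text{baseline} + \text{slope}\cdot\mathrm{RIFA}$, and
  `noise_sd = NA` calibrates the noise to the realised RIFA spread for a
  planted correlation of ~0.66 — the effect size at which a two-sided
  0.05 test has ~0.9 power at n = 20. Saliva flow is generated as a
  negative linear function of RIFA with noise sized for an expected
  r² of ~1/3.
* **Single cell** (`simulateCellCounts`): negative-binomial counts
  (size 2) over nine cell types — fibroblast, ductal, acinar,
  myoepithelial, endothelial, T, B, plasma, other — with 400 genes and
  per-cell mitochondrial fractions drawn from 2–8% (optionally planted
  high to exercise the QC filter); enrichment multiplies a gene's
  expected counts in its target type.
* **Genome** (`simulateGenomeCoverage`): two 200-kb chromosomes, 60
  genes, background depth 3 reads/base from 50-bp reads, open promoters
  receiving multiplier × background extra reads, and motif consensus
  strings written into promoter sequences at stated offsets.

What the generators deliberately do **not** emulate: histological
texture, stain variability between scanners, pyramidal whole-slide
formats, array probe effects, ambient RNA, doublets, or alignment
artefacts. Passing tests therefore demonstrate correctness of the
arithmetic and the statistical behaviour of the screens under their
stated models — not robustness to the full messiness of real slides and
libraries. On clean synthetic tiles the automated RIFA path recovers the
truth almost exactly; on real material the stain vectors and thresholds
will need inspection against the QC overlays.

# Problem sizes, numerics and degenerate inputs

The test suite and the acceptance script use 160×192-px tiles at
1 µm/px, 200-simulation null batches, 100-seed enrichment batches, and
50-slide recovery sweeps — sizes chosen so each property is estimated
with comfortable Monte-Carlo margins while a full run stays in the
minutes range. Other numerical choices:

* Degenerate t-tests (zero variance on both sides) return t = 0, p = 1
  for equal means and p = 0 otherwise, instead of erroring.
* Zero-variance genes, genes with a zero group-B mean, samples with
  missing RIFA, unknown chromosomes and list genes absent from a matrix
  are dropped with a logged message, never silently.
* Quantile-normalisation ties take the mean of the tied reference
  values; an island of exactly the threshold area is subtracted; a cell
  at exactly the mitochondrial threshold is retained; a fold change of
  exactly the threshold is not selected. Each boundary is pinned by a
  test.
* The exact PWM p-value uses a lattice of 10⁻³ score units with a
  half-lattice-per-column tolerance on the tail boundary.
* Missing expression values are not imputed: rows are dropped with a
  message at import.

# Limitations

RIFA is a section-level summary; it does not distinguish peri-ductal
from diffuse fibrosis and inherits any bias in the gland outline. The
automated path assumes two dominant stains; slides with heavy
haematoxylin nuclei may need a third vector. The enrichment test treats
genes as exchangeable replicates, which overstates confidence if the
gene list is internally correlated. The fraction-of-max motif threshold
is not calibrated to a false-positive rate; use the exact p-value for
that. The pipeline's promoter stage takes TSS annotations as given and
records their provenance rather than choosing a canonical set itself.
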