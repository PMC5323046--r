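---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctascreen)
```

`punctascreen` implements the analysis chain of an image-based RNAi
screen that scores punctate marker phenotypes per cell — spot number and
integrated spot signal (ISS) — across a 384-well plate format, from raw
two-channel well images (or pre-quantified well tables) through plate
normalization, hit calling, cytotoxicity filtering and four-oligo
deconvolution validation, together with the supporting quantitative
assays such screens lean on: qPCR relative quantification, ChIP
percent-input, AP-MS interaction scoring and expression fold-change
gating. This vignette documents the statistical models, the tunable
parameters and the places where the design was genuinely open.

## The synthetic world

All tests run against data from the package's own generator, so every
"truth" is known and recoverable. The generator states one fixed world;
none of its defaults are revisited per test.

**Well model.** A well seeds 1500 cells (Poisson). Per-cell spot counts
are negative binomial (dispersion size 4) around a per-marker baseline —
WIPI2 15, ATG12 12, LC3B 20, GABARAP 18, STX17 8 spots/cell, reflecting
that late markers decorate fewer structures. Per-spot intensities are
gamma (mean 500 AU, shape 2), so ISS/cell is a compound gamma. A
multiplicative log-normal well effect with CV 0.05 models plate-level
technical variation; with ~1500 cells per well this term dominates the
SD of per-well means and therefore sets the width of the non-targeting
control band used by the SD hit criterion (typical automated
high-content assays with this cell count show per-well CVs of a few
percent). Sums over cells and spots use NB and gamma additivity, so each
well is drawn in O(1) while remaining distributionally identical to the
per-cell model.

**Effects.** A gene effect is a pair of fold-changes (spots/cell,
ISS/cell); the per-spot intensity scale carries the residual ISS effect
so both folds are honored independently. Positive controls use fold 2.5
on both parameters (a strong autophagy-inducing knockdown); negative
controls leave spot counts near baseline (0.9) while collapsing ISS
(0.35), mimicking conjugation-machinery knockdowns that dim rather than
remove puncta. Treatments multiply the spot baseline (Torin1 1.8, BafA1
2.5).

**Deconvolution oligos.** Individual siRNAs carry a residual-mRNA
fraction; the phenotypic fold is attenuated as `fold^e` with
`e = (1 - residual) / 0.75` clamped to [0, 1]. Unlisted oligos are
effective with probability 0.95 (residual U(0.10, 0.45)); ineffective
oligos have residual U(0.8, 1). The 0.95 figure states the
reproducibility of a *strong, genuine* phenotype across independent
oligos of a current commercial library — the separate observation that
~75% of oligos pass a strict mRNA-level QC gate (below 0.65 residual) is
modeled in the qPCR generator, not here, because an oligo can pass the
phenotype criterion while narrowly missing the mRNA gate and vice
versa.

**Images.** Cells are placed by rejection sampling with a
minimum-distance constraint; nuclei are bright ellipses inside dimmer
cytoplasm disks (channel 1), spots are isotropic Gaussians with sigma
1–3 px planted in the cytoplasm (channel 2), over a constant offset, a
low-frequency illumination field (±15%) and Gaussian read noise.
Planted spots of the same cell keep a minimum separation of 8 px
(~2.5 × the maximum sigma, a Rayleigh-style margin): the recovery
contract is defined per planted spot, and closer spots are physically
indistinguishable, which would make per-spot attribution ill-posed
rather than merely hard. What a green recovery test establishes is that
detection and integration are unbiased on resolvable puncta over a
smooth background; it does not establish performance on overlapping
puncta, textured cytoplasm autofluorescence, or debris — real-data
features the generator deliberately omits.

## Image quantification

Segmentation starts from the nuclei: Otsu on the full stain channel
separates background from cells, Otsu within the cell foreground
separates cytoplasm from nuclei. Nucleus components under 20 px² are
dropped; touching nuclei are split by seeding at distance-transform
maxima (minimum seed separation 6 px) and growing the seeds
geodesically — a marker-based watershed. Cytoplasm is assigned by
growing nucleus labels through the stain foreground. Cells touching the
image border are kept by default (well-level averaging dilutes the
bias); an exclusion flag is provided.

Spot detection runs on a flat-field-corrected (block-median estimate of
the illumination profile, divided out) and 3×3-box-smoothed copy of the
marker channel: candidate maxima above `background + 3 × noise SD`
(robust median/MAD estimates) with minimum separation 3 px define the
candidates; raw-threshold pixels are assigned to their nearest maximum,
which splits touching spots while keeping the raw-pixel meaning of
"area". Each spot's integrated intensity is the sum of
background-corrected pixels over an adaptive disk sized from the
smoothed support, with two guards that matter numerically: pixels
contested by another maximum are excluded (Voronoi guard), and the
median background annulus excludes both the smoothed spot support and
contested pixels — without the latter, neighbor-spot tails inflate the
annulus and bias integrals low by 10–20% on dense fields. Contrast is
`(mean − background) / (mean + background)`; filters on area, corrected
peak intensity and contrast act on a fixed candidate set, which makes
detection counts monotone under threshold increases by construction.
Coordinates are 0-based (row, col) pixels; centroids are
intensity-weighted.

The default colocalization radius is 3 px (the underlying coalescence
distance is not standardized; it is a parameter everywhere it is used).

## Plate statistics and hit calling

Replicate wells (quadruplicates by default) are averaged first, then
divided by the same plate's non-targeting (sicon) mean. The dispersion
attached for thresholds is the SD of per-well normalized sicon values,
pooled per marker by default; per-plate SDs are available
(`sd_scope = "plate"`) but 12 sicon wells per plate make a noisy scale
estimate, and pooling matches the practice of deriving one band per
marker. The hit band is additive on the fold scale, `1 ± k·SD`, with
per-marker multipliers k = 3 (WIPI2, ATG12) and k = 2 (LC3B, GABARAP,
STX17); a hit must clear the band on *both* spot parameters in the same
direction. z-score (median/MAD or mean/SD) and B-score (Tukey median
polish, residuals over scaled MAD) normalizations are computed side by
side; the pipeline does not claim one canonical union of the three
candidate lists — the SD criterion on sicon-normalized values is the
primary caller, and the alternatives are reported for comparison. Note
that Tukey's polish iterates rows before columns, so B-scores of a
plate and of its transpose agree only to the convergence scale, not
bit-for-bit.

Ranking uses `max(|log fold|)` over the two parameters; the top ten per
marker are kept, ties at rank ten keep all tied genes, and genes hitting
two or more markers are added regardless of rank. Decrease-direction
candidates travel through the cascade unless a direction filter is set.

**Toxicity.** An oligo is cytotoxic when the robust z of its
replicate-mean exceeds 3 on any of five observables (cell count,
nucleus/cytoplasm intensity and area). The center is the plate's sicon
median; the scale is the MAD of sicon deviations from their plate
medians *pooled across plates* — a per-plate MAD from 12 wells is so
unstable that healthy oligos would exceed 3 several percent of the
time. Because each oligo appears on one plate per marker, per-plate z
values are aggregated by the *median* across plates: a genuine
cytotoxic phenotype reproduces on every plate, while an "any plate
exceeds" rule at five observables × five plates false-flags through
multiplicity alone. Genes with more than one toxic oligo are
excluded.

**Deconvolution.** With four oligos per gene: validated iff ≥3 of 4
non-toxic oligos pass; with exactly one toxic oligo, ≥2 of the
remaining 3; two or more toxic oligos exclude the gene. The
implementation is checked against a brute-force enumeration over all
2⁴ × 2⁴ pass/toxicity patterns.

## qPCR and ChIP

Relative expression is `E^(−Ct)` normalized to the geometric mean of
three reference genes (ACTB, HMBS, TBP), as a ratio of condition over
control; replicates are averaged on the Ct scale (the standard ΔΔCt
convention; linear averaging is an option). Efficiency defaults to 2.0
(perfect doubling) and may be set per gene. Adding a constant to every
Ct of a sample cancels exactly. With replicate noise of 0.1 cycles and
4 replicates, error propagation puts the SD of a recovered fold at
~6%, so single draws can exceed ±10%; the tests therefore assert the
median over fixed seeds within ±10% and every draw within ±20%.
Knockdown QC passes an oligo iff its relative level is strictly below
0.65.

ChIP percent input is
`100 × 2^((Ct_input − log2(1/input_fraction)) − Ct_IP)` — the input Ct
is first adjusted for the chromatin fraction it represents — and is
divided by the matched control IP (MOCK for tagged-construct ChIP, IgG
for endogenous ChIP, selected by argument).

## AP-MS interaction scoring

Spectral counts are aggregated per bait–prey as APSM (mean over the
bait's runs, zeros counted for undetected runs) and reproducibility `p`
(runs detected). With `K` background baits and prey frequency `f`, the
D-score is `sqrt(APSM × (K/f)^p)`; the weighted variant multiplies
`K/f` by `w = max(1, sd/mean)` of the prey's APSM across retrieving
baits (bait-unique preys get `w = 1`), and WD^N divides by the 98th
percentile of WD scores so that 1.0 is the high-confidence boundary.
The weight form and the percentile are parameters: the upstream
platform's exact constants are not published alongside the screens that
use it, so they are declared rather than inferred. A pair is an HCIP
iff `WD^N ≥ 1` and `APSM ≥ 2`. On very small tables the percentile
normalization is intentionally harsh (only the top ~2% of pairs can
pass); recovery guarantees are stated for realistic backgrounds
(≥ 10–20 baits with shared background preys).

## Expression gating

Per-gene ratios from three independent experiments are averaged on the
linear scale (geometric averaging is an option); genes with a
between-experiment CV above 0.5, or a single experiment, are flagged by
QC. The fold gates are strict: up iff mean > 1.3, down iff mean < 0.7
(inclusive mode available). A curated panel table subsets the
classified ratios in the panel's order, marking unmeasured genes.

## Determinism and seeds

Every generator takes a master seed and derives fixed substreams
(plates, images, oligo efficacies) from it; identical inputs give
bit-identical tables, images and files. RNG state of the calling
session is saved and restored around every draw.

## Known limitations

* The imaging model has no autofluorescence texture, no debris, no
  out-of-focus fields; segmentation thresholds are bimodal-Otsu and
  would need retuning for dim stains.
* Per-spot intensity recovery at the 5× noise floor carries ~10–25%
  per-spot noise for the smallest spots; well-level ISS is the robust
  statistic.
* B-scores are order-dependent at the convergence margin (see above).
* The CompPASS normalization percentile and weight are declared
  parameters, not reproductions of any specific platform instance.
* On-disk images are plain-text PGM (one file per channel with a JSON
  truth sidecar) rather than multi-page TIFF, keeping the package free
  of binary I/O dependencies; the in-memory contract is unchanged.
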