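---
title: "Methods: DAB positive-cell quantification and lipid-mediator profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DAB positive-cell quantification and lipid-mediator profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resolvequant)
```

resolvequant implements two quantitative readouts used in human
skin-blister studies of inflammation resolution: (i) a fully specified
digital-pathology algorithm that counts DAB-positive cells per square
micrometer of tissue in brightfield immunohistochemistry, and (ii) a
lipid-mediator (LM/SPM) profiling stage covering LC-MS/MS identification
rules, internal-standard calibration, PLS-DA of mediator time courses,
and nonparametric time-course testing. Because studies of this kind
deposit no raw images or concentration tables, the package ships
ground-truthed synthetic generators for both arms; every claim the test
suite makes is a property checked against planted truth, not a
reproduction of any cohort's numbers.

## 1. The IHC quantification algorithm

### 1.1 Tissue identification

The slide is an 8-bit RGB raster with a physical pixel size (default
0.45 µm/px). Tissue segmentation operates on the *darkest-channel*
composite — the per-pixel minimum over R, G, B — because tissue absorbs
in at least one channel while glass transmits everything. The stage
runs, in order:

1. mean filter with a square 25×25 px sliding window (the window mean is
   assigned to the central pixel);
2. initial threshold `T = P99 − 15` on the 8-bit scale; tissue is the
   darker side (`value < T`);
3. background refinement `T2 = P10(background) − 10`; tissue brighter
   than `T2` is reclassified as background;
4. area cleanup: 8-connected tissue and background components smaller
   than 50 µm² are flipped to the surrounding class, then tissue
   components smaller than 1% of total tissue area are removed.

Decisions the algorithm statement leaves open, and what this package
does:

* **Threshold direction.** Only an "initial separation" is specified;
  brightfield physics dictates that tissue is darker than glass, and the
  synthetic forward model asserts this choice end to end.
* **Percentile convention.** Linear interpolation between order
  statistics (R's default type 7), with strict inequalities at both
  thresholds.
* **Border policy.** The mean filter uses mirror (symmetric) padding.
  Replicate or circular padding would darken borders and bias the
  percentile thresholds; reflection is neutral.
* **Working resolution.** The original workflow segmented tissue at half
  the magnification of stain detection. A single input raster is used
  here, with the tissue stage block-averaging by an integer factor
  (default 2) before filtering and rescaling the mask back; all area
  rules are stated in µm² so the physical thresholds are unaffected.
* **Cleanup order.** Small tissue islands are flipped first, then small
  background holes, then the 1% rule; the order is fixed and tested.

A note on fixture geometry: the `P10(background) − 10` refinement
assumes background is dominated by uniform glass, as it is on a whole
slide. On a small synthetic raster with a thin glass margin, the blurred
tissue-glass boundary band can dominate the background percentile and
erode the mask boundary. The bundled tissue-accuracy fixtures therefore
use slides whose glass area is several times the tissue area
(500×400 px, 100 px margin), emulating the whole-slide regime; mask IoU
against planted truth is ≥ 0.95 there, typically ≈ 0.97.

### 1.2 Region selection

The manual "4 regions of interest" step is automated as a 2×2 grid over
the tissue bounding box, each tile intersected with tissue; user-drawn
ROI label rasters are accepted verbatim. Empty tiles are dropped with a
warning. Densities are insensitive to ROI permutation by construction.

### 1.3 Stain detection in HSD space

Per-channel optical density is `d = −ln((v + 1)/(i0 + 1))` (the +1
regularizes a zero grey level; `i0` defaults to 255). The HSD transform
splits the three channel densities into overall density
`D = (d_R + d_G + d_B)/3` and chromatic coordinates
`cx = d_R/D − 1`, `cy = (d_G − d_B)/(√3 D)`; chroma separates hue from
stain amount, which is what makes HSD suited to transmitted-light stain
quantification. Pixels with `D < 10⁻⁶` are treated as achromatic.

The algorithm statement requires "a raster image of the intensity of
each color of interest (brown and blue)" without defining the map from
HSD to per-stain intensity. This package uses density-weighted angular
proximity to fixed reference hues: the reference hue of each stain is
the chromatic angle of its optical-density vector (Ruifrok–Johnston
constants for haematoxylin and DAB, normalized to mean 1 and shared with
the synthetic generator), and the weight is a raised cosine
`w = (1 + cos(π·Δθ/half_angle))/2` for angular distance `Δθ` below
`half_angle` (default π/3), zero beyond. The raised cosine has zero
slope at an exact hue match, so 8-bit quantization of a dense pure-stain
pixel barely perturbs its recovered intensity; with a linear falloff the
round-trip error at `D ≈ 2` approaches 0.03 AU, with the raised cosine
it stays ≈ 0.014 AU (quantization-limited). The haematoxylin and DAB
reference hues are ≈ 137° apart, beyond the half-angle, so pure stains
never leak into each other's raster. This weighting is a documented
stand-in validated through the synthetic forward model, not a
reconstruction of the original rule set.

Derived rasters, exactly as specified: `brown+ve = brown − blue`
per pixel (may be negative; all downstream comparisons are strict), and
*normalized blue* = mean₃(blue) − mean₁₀₁(blue), kept only where the
difference exceeds 0.05 AU (strict), which subtracts the local
background level of blue and enhances the real peaks representing
nuclei.

### 1.4 Cells and positivity

* Nuclei: candidate pixels with normalized blue > 0.1 AU inside tissue;
  8-connected components with area > 10 µm² are kept.
* Merged nuclei are split by watershed on the distance transform
  (EBImage), with a tolerance acting as an h-maxima depth (default 1 px)
  to suppress spurious splits of convex nuclei; fragments below the
  nucleus area floor are merged back into their largest neighbour. The
  operator is a fixed point: re-running it changes nothing.
* "Large nuclear shapes" are excluded as artifacts; no ceiling is
  printed in the algorithm statement, so the default is 150 µm²,
  configurable and applied after splitting.
* Cell bodies: each nucleus is surrounded by body to a depth of 7 px at
  0.45 µm/px via geodesic dilation within tissue. At other pixel sizes
  the depth is `round(7 × 0.45 / pixel_size)` px, preserving the
  ≈ 3.15 µm physical halo. Pixels reachable from several nuclei go to
  the Euclidean-nearest nucleus, ties to the lower label.
* Positivity: pixels with brown+ve > 0.1 AU are DAB; a body with > 20%
  DAB coverage is a positive body, a nucleus with > 40% coverage a
  positive nucleus, and a cell with a positive nucleus and/or body is a
  positive cell. Every comparison is strict, exactly as written, and a
  per-pixel brute-force oracle in the tests agrees with the vectorized
  implementation bit for bit, including fixtures planted exactly at the
  20% and 40% boundaries.
* The report is positive cells per µm² of ROI tissue, averaged over the
  ROIs (a cell belongs to the ROI containing its nucleus centroid; cells
  outside every ROI stay in the cell table but not in densities).

## 2. The synthetic slide model

Slides are generated by a Beer–Lambert forward model: per channel,
`I = I0 · exp(−A_hema·e_hema − A_dab·e_dab)`, with additive Gaussian
noise (default sd 2 grey levels; 0 in the fixtures that claim noiseless
properties) applied *before* 8-bit quantization and clipping. The
extinction vectors are the same mean-normalized Ruifrok–Johnston
constants the stain stage uses, so a planted amount of *a* AU is exactly
the overall HSD density the inversion should recover — the round trip is
a genuine inversion test, not a shared-code identity.

Planted geometry: an elliptical tissue region on glass; elliptical
nuclei (default 3 µm semi-axes, area ≈ 28 µm², comfortably above the
10 µm² floor) placed by rejection sampling with a minimum centroid
distance (default 11 µm); haematoxylin 0.9 AU in nuclei and 0.10 AU in
stroma; DAB 0.8 AU on a 5 px cytoplasmic ring for positive cells (an
optional nucleus-DAB amount exists for fixtures exercising the 40%
rule). With these amounts the stroma's darkest channel sits ≈ 30 grey
levels below glass — a pale, haematoxylin-counterstained skin section —
which is the contrast regime in which the fixed −15/−10 offsets of the
segmentation behave as intended. A merged-pair mode plants pairs of
nuclei 5.5 µm apart — overlapping (2r ≈ 6 µm) yet separable — to
exercise the watershed split; the distance was chosen from the split
operator's geometry (the peak-to-saddle drop must exceed ≈ 2 px for the
default tolerance once the normalized-blue halo inflates blobs to ≈ 8 px
radius). Overcrowded specifications fail placement after bounded retries
with an explicit capacity error.

What the generator does *not* emulate: out-of-focus blur, uneven
illumination, stain co-localization gradients, tissue texture,
compression artifacts, or gigapixel scale. Passing tests demonstrate
that the algorithm is implemented as specified and recovers known truth
under ideal optics; they do not certify accuracy on real slides.

## 3. Lipid-mediator profiling

### 3.1 Identification and quantification

A feature is identified as a library mediator iff its retention time
matches within a tolerance (default 0.1 min; tolerances are not printed
in the source methods, so both are config-exposed) *and* at least 6
diagnostic ions of that entry appear in its MS/MS ion list (m/z
tolerance 0.01). Among multiple qualifying entries the one with the most
matched ions wins, ties resolved by retention-time distance. The bundled
standards library is a synthetic fixture (ten mediators, eight ions
each, retention times spaced > 1 min); its values are plausible but not
measured reference data.

Calibration is ordinary least squares of response (peak area over the
paired deuterated internal standard's area) on amount over the standard
series 0.78–200 pg; quantification inverts the line and floors negative
amounts at zero with a warning. On noiseless series the slope and
intercept are recovered to numerical precision; with 2% multiplicative
noise the mean r² across replicates stays ≥ 0.98, mirroring the r²
range such calibrations typically report.

### 3.2 PLS-DA

`plsda()` is a NIPALS PLS2 against the centred one-hot indicator of
group membership. Predictors are centred and autoscaled by default
(the metabolomics convention; pareto and no scaling are options since
the original scaling choice is unknowable). Missing values are imputed
as half the per-mediator minimum, with a message. Scores are mean-zero
by construction; the reported loadings are the unit-norm NIPALS weight
vectors, which is the quantity whose magnitudes rank discriminating
mediators. Extraction stops early, with a message, if the predictor
residual is exhausted (e.g. rank-1 data). Per-group 95% confidence
ellipses come from the eigendecomposition of each group's 2-component
score covariance scaled by the χ²(2 df) 0.95 quantile. `autoplot()`
draws the score plot with ellipses; `plot_loadings()` the loading plane.
An independent implementation (mixOmics) agrees with the component-1
scores to |r| > 0.99 in the test suite.

### 3.3 Temporal testing

The omnibus test per mediator is the tie-corrected Kruskal–Wallis test
across time points (base R's `kruskal.test`). The source methods pair it
with "Dunnet's test", which is a parametric many-to-one procedure
defined for ANOVA; the only internally consistent nonparametric reading
is Dunn's rank-based many-to-one comparison, so that is what is
implemented: `z = (R̄_t − R̄_ref)/sqrt(s²(1/n_t + 1/n_ref))` with the
tie-corrected variance `s² = N(N+1)/12 − Σ(t³−t)/(12(N−1))`, against the
baseline time, Holm-adjusted by default (the correction is
configurable). Being rank-based, results are invariant to monotone
transformations of concentration.

The Monte-Carlo check of the omnibus test's level runs at 5 groups × 20
observations. `kruskal.test`'s null is the asymptotic χ² distribution;
at the study-like n = 6 per group the exact level is conservative
(≈ 0.037 at nominal 0.05), so the 0.05 ± 0.01 level property is checked
in the regime where the asymptotic null is in force (5×20 gives
≈ 0.046–0.049). Users testing n = 6 designs should expect the omnibus
test to be slightly conservative, not anticonservative.

### 3.4 The synthetic mediator model

`generate_mediator_table()` draws long-format donor × time × mediator
tables: concentration = baseline × temporal effect × mean-1 lognormal
noise (default CV 0.3), so the expected value at each time equals
baseline × effect exactly and all values are nonnegative. The default
panel has 20 mediators across the three fatty-acid metabolomes with the
directional structure reported for this inflammation model: onset
eicosanoids (PGE2, PGF2α, TxB2, LTB4 and the 20-OH/20-COOH LTB4 further
metabolites) peaking 4 h after challenge, LXB4 peaking with them, RvE3
peaking at 8 h, LXA4 rising late, and MaR1 dipping to a minimum at 8 h
before recovering above baseline by 24 h. Sampling times are 0, 4, 8,
14, 24 h with 6 donors per time, matching the study design scale.
Magnitudes are illustrative only: the source reports no machine-readable
concentration table, so the generator encodes directions, not calibrated
levels — which is also why no acceptance check compares simulated
concentrations to published ones.

## 4. Numerical choices and degenerate inputs

* Strict `>` at every stated threshold (0.05 AU blue floor, 0.1 AU
  normalized blue, 0.1 AU brown+ve, 10 µm², 20%, 40%); `≤` for the
  retention-time and m/z tolerances (a feature *matching* the tolerance
  matches).
* 8-connectivity for all component labelling (EBImage's 4-connected
  `bwlabel` plus a diagonal union-find merge).
* Empty regions: a cell with an empty body gets coverage 0 with a
  warning; ROIs without tissue are excluded with a warning; a slide with
  no tissue returns an empty report rather than an error; an empty
  background skips refinement with a warning.
* All generators are deterministic given (spec, seed); pipelines write
  byte-identical CSVs on re-runs, and a JSON manifest snapshots every
  threshold actually used.

## 5. Problem sizes used by the test and acceptance runs

End-to-end IHC recovery runs one 900×700 px noiseless slide with 60
positive and 40 negative cells (≈ 10 s); tissue accuracy runs twenty
500×400 px slides; the classification oracle 100 random 64×64 fixtures;
identification 1000 labelled features; PLS-DA recovery 100 seeds of a
40 × 20 design; the level check 5000 Kruskal–Wallis replicates. These
sizes were chosen to exercise every rule at meaningful scale while
keeping a full run of suite plus acceptance script in a few minutes on
one CPU.

## 6. Known limitations

* The stain-intensity weighting is a self-consistent stand-in for an
  unpublished commercial rule set; only the synthetic forward model
  validates it.
* ROI automation replaces a manual expert step; on real slides the four
  grid tiles are not the four regions an expert would draw.
* The nucleus-artifact ceiling (150 µm²) and the identification
  tolerances are defaults without a published reference value; they are
  exposed in configuration objects and recorded in run manifests.
* Published per-donor densities and concentrations cannot be reproduced
  without the underlying images and exudates; the package reproduces
  procedures and validates them on synthetic truth.
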