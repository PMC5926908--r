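# resolvequant

Quantification of inflammation-resolution markers in human skin-blister
studies: a brightfield immunohistochemistry (IHC) arm that counts
DAB-positive cells per square micrometer of tissue, and a lipid-mediator
(LM/SPM) profiling arm covering LC-MS/MS identification, calibration,
PLS-DA of mediator time courses and nonparametric time-course testing.
Both arms come with ground-truthed synthetic generators, so every stage
is testable end to end without any external data.

## Who this is for

Groups quantifying receptor or marker expression on
formalin-fixed skin biopsies with DAB + haematoxylin staining, and
groups running targeted LM metabololipidomics on blister exudates or
similar matrices, who want a scriptable, fully specified, reproducible
version of the analysis chain — plus simulation tools to validate it.

## The algorithms

**IHC arm.** Tissue is segmented on the darkest-channel composite
(min over R, G, B): a 25×25 px mean filter, an initial threshold at the
99th centile − 15 grey levels, refinement at the 10th centile of the
background − 10, then removal of components < 50 µm² and of tissue
pieces < 1% of total tissue. Stain separation uses the
hue–saturation–density (HSD) transform: per-channel optical density
`d = −ln((v+1)/(i0+1))`, overall density `D = mean(d_R, d_G, d_B)`,
chroma `cx = d_R/D − 1`, `cy = (d_G − d_B)/(√3 D)`. Per-stain intensity
is `D` weighted by angular proximity of the pixel's hue to the stain's
reference hue. Two derived rasters drive cell analysis:
`brown+ve = brown − blue`, and normalized blue
`= mean₃(blue) − mean₁₀₁(blue)` where that difference exceeds 0.05 AU.
Nuclei are components > 10 µm² with normalized blue > 0.1 AU, split by
distance-transform watershed, surrounded by a 7 px cell body
(0.45 µm/px); pixels with brown+ve > 0.1 AU are DAB, a body with > 20%
coverage or a nucleus with > 40% coverage makes a positive cell, and the
report is positive cells per µm² of tissue averaged over 4 regions of
interest.

**LM arm.** A feature is identified when its retention time matches a
standard within tolerance *and* ≥ 6 of the standard's diagnostic MS/MS
ions are present. Quantification inverts a linear calibration of
response (area / deuterated internal standard area) on the 0.78–200 pg
standard series. Group structure over time is explored with NIPALS
PLS-DA (autoscaled, with per-group 95% confidence ellipses) and tested
per mediator with the tie-corrected Kruskal–Wallis test followed by
Dunn's many-to-one rank comparisons against baseline (Holm-adjusted).

## Worked example

Simulate a noiseless slide with 60 DAB-positive and 40 negative cells,
run the full IHC pipeline, and read the density report:

```r
library(resolvequant)

spec <- slide_spec(n_positive = 60, n_negative = 40)
gen  <- generate_ihc_slide(spec, optical_model(noise_sd = 0), seed = 7)
res  <- run_ihc_pipeline(gen$slide)
res$report
#> IHC density report: 100 cells (60 positive), 4 ROI(s)
#> mean positive-cell density: 0.000835901 cells/um^2 tissue
tidy(res$report)
#> # A tibble: 5 x 4
#>     roi positive_cells tissue_area_um2 density_per_um2
#>   <int>          <int>           <dbl>           <dbl>
#> 1     1             11          17839.        0.000617
#> 2     2             12          18490.        0.000649
#> 3     3             21          17746.        0.00118
#> 4     4             16          17885.        0.000895
#> 5    NA             60          71960.        0.000836
```

All 100 planted cells are recovered and exactly the planted 60 are
called positive; the last row is the mean over the four ROIs — the
positive-cells-per-µm² figure such studies report. The per-ROI counts
differ because cells scatter unevenly over the ROI grid.

Simulate a mediator time course (0, 4, 8, 14, 24 h; 6 donors per time
point) and profile it:

```r
tab <- generate_mediator_table(mediator_sim_spec(), seed = 7)
lm_res <- run_lm_pipeline(tab)
lm_res$plsda
#> PLS-DA: 30 samples, 20 mediators, 5 groups, 2 components
#> explained X variance: comp1 36.6%, comp2 11.0%
temporal_test(tab, "PGE2")
#> Kruskal-Wallis time course for PGE2: H = 22.46, p = 0.000162
#> Dunn many-to-one vs 0 h (holm-adjusted):
#>  time_h          z    p_value p_adjusted
#>       4  2.8200511 0.00480160  0.0192064
#>       8  1.9674775 0.04912819  0.1473846
#>      14 -0.2951216 0.76790097  0.7679010
#>      24 -1.2132778 0.22502363  0.4500473
```

The simulated PGE2 onset peak at 4 h is detected against baseline
(adjusted p = 0.019) and the later times are not, matching the planted
profile. `autoplot(lm_res$plsda)` draws the score plot with 95%
ellipses; the largest component-1 loading magnitudes
(`tidy(lm_res$plsda, "loadings")`) are the onset eicosanoids that drive
the 4 h separation — LTB4, 20-COOH-LTB4, TxB2, 20-OH-LTB4 — as planted.

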