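Package: resolvequant
Title: Quantification of Inflammation-Resolution Markers in Skin Blister
    Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two quantitative readouts of human skin
    inflammation-resolution studies. A brightfield immunohistochemistry
    arm reproduces a fully specified DAB positive-cell quantification
    algorithm: darkest-channel tissue segmentation with percentile
    thresholds and area cleanup, hue-saturation-density (HSD) stain
    separation into brown-positive and normalized-blue rasters, nucleus
    detection with watershed splitting of merged nuclei, cell-body
    growth, strict DAB-coverage positivity rules, and positive-cell
    density per square micrometer of tissue averaged over regions of
    interest. A lipid-mediator profiling arm implements LC-MS/MS
    identification rules (retention-time match plus at least six
    diagnostic ions), internal-standard calibration and quantification,
    NIPALS partial least squares discriminant analysis with 95%
    confidence ellipses, and Kruskal-Wallis time-course testing with
    Dunn many-to-one post-hoc comparisons. Ground-truthed synthetic
    generators (Beer-Lambert slide model, mediator time-course tables,
    MS/MS feature fixtures) make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
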