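Package: nucmorph
Title: Nuclear Morphometry, Lamina Surface Strain and Mechanosensitive
    Lamin Quantification for Epithelial Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the link between apico-basal cell
    compression, nuclear flattening and Lamin A/C levels in epithelial
    tissues. Implements dimensionless cell and nuclear deformation
    indices, a volume-conserving spheroid model of nuclear surface-area
    strain, 3D fluorescence image quantification (nuclear segmentation,
    projection morphometry, shell intensity measures, junction-based
    apical areas), permutation-based false-discovery-rate testing of
    correlations with binned-scatter and LOESS summaries, and Hertz/
    Sneddon fitting of atomic-force-microscopy indentation curves.
    Ships a synthetic-data generator with known ground truth (tissue
    archetypes, strain-linked Lamin levels, rendered image stacks and
    force curves) and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
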