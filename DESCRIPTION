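Package: pnpolarity
Title: Planar Polarity and Morphometry of Posterior Neuropore Closure Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification of planar cell polarity and tissue biomechanics in
    confocal images of the closing mouse posterior neuropore (PNP). Implements
    surface-band extraction ("surface subtraction") of the outermost cell layer
    from 3D stacks, per-cell shape and orientation morphometry, cell-division
    orientation from daughter-nucleus centroids, mediolateral-versus-rostrocaudal
    junctional F-actin enrichment scoring with supracellular enriched-border
    profile detection, neural-fold elevation and basal:apical morphometry,
    laser-ablation recoil measurement, and the accompanying statistical tests
    (angular chi-square against a random distribution, t-tests, one-way ANOVA
    with Bonferroni post hoc, and regression slope comparisons). Includes a
    ground-truthed synthetic image generator (curved epithelial sheet phantoms,
    division, cross-section and ablation phantoms) so the whole pipeline is
    testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
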