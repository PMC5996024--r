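Package: centripatch
Title: Quantification of Centriolar Patches, Basal-Body Orientation and
    Cilia Beating in Multiciliated Ependymal Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An image-quantification stack for multiciliated ependymal
    cells: detection and counting of centrioles in 3D fluorescence stacks
    by Gaussian/Laplacian-of-Gaussian filtering and local-maximum
    extraction, centriolar-patch geometry (convex-hull area,
    nearest-neighbour spacing, density-based patch boundaries), basal-body
    orientation by minimum-cost assignment of centrin to Cep164 puncta
    with circular statistics and the two-sample Watson U2 test,
    actin (phalloidin) patch/cytoplasm intensity ratios on z-band sum
    projections, cilia beat frequency and amplitude from 250-fps
    recordings with kymographs, and a slender-cylinder drag model for the
    forces a beating cilium exerts on its centriole.  A synthetic-scene
    generator with exact ground truth makes the whole pipeline testable
    without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    utils,
    jsonlite,
    tiff
Suggests:
    ggplot2,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
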