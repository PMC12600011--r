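Package: azstorm
Title: Eye-Specific Synapse Detection and Spatial Analysis for Volumetric
    Super-Resolution Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects retinogeniculate synapses in aligned four-channel
    volumetric super-resolution (STORM) image stacks of the developing
    dorsal lateral geniculate nucleus, classifies each input as single- or
    multi-active-zone by counting Bassoon/Homer1 release sites around its
    VGluT2 vesicle cluster, assigns eye of origin from CTB tracer signal,
    and quantifies like-eye spatial clustering against a position-shuffled
    null model. Includes a synthetic scene generator that renders
    ground-truth volumes with the same statistical structure, segmentation
    based on per-section histogram normalization, two-level Otsu
    thresholding and anisotropic watershed splitting, OPTICS-based
    pre/postsynaptic pairing, and replicate-level paired statistics with
    Benjamini-Hochberg false discovery rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tools,
    mclust,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
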