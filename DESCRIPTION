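Package: clickmap3d
Title: Atlas-Registered Quantification of Proliferating Nuclei in Cleared
    Brain Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of 3D click-chemistry (EdU) imaging of
    cleared mouse brains: nucleus detection from light-sheet intensity
    volumes (background subtraction, random-forest pixel classification,
    connected-component filtering with a three-voxel noise rule, and
    marker-controlled watershed splitting of touching nuclei), mapping of
    nuclear coordinates into a reference label atlas through an affine
    transform used inversely plus a deformation field applied directly,
    custom atlas annotations (a one-voxel subventricular-zone layer, a
    vote-based consensus region, and hemisphere-split region IDs), and
    region-resolved statistics (counts, densities, voxel-collision ratios,
    marker colocalization, hemisphere comparison, heatmap volumes). A
    synthetic-data generator provides toy atlases, simulated nuclear
    scenes with Poisson-Gaussian noise, and ground-truth transforms so the
    whole pipeline is testable without raw microscopy data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ranger,
    jsonlite,
    RNifti,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'utils.R'
    'atlas.R'
    'volume.R'
    'transform.R'
    'synthgen.R'
    'render.R'
    'detect.R'
    'quantify.R'
    'io.R'
    'pipeline.R'
    'benchmark.R'
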