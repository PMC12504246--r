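Package: sectionatlas
Title: Registration, Warping and Atlas-Based Quantification of Serial Brain Sections
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for anchoring 2D histological brain section images in a 3D
    volumetric label atlas and quantifying features against atlas regions.
    Sections are placed in atlas space by an affine cut plane (an origin and
    two in-plane spanning vectors); anchorings can be propagated across a
    serial series by section number, refined in-plane with piecewise-linear
    landmark warps (Delaunay triangulation with barycentric sampling), and
    used to extract per-section atlas label maps. Binary segmentations are
    quantified per atlas region with a collapsible region hierarchy,
    per-hemisphere masking from the atlas midline, systematic-sampling
    quality-control statistics, and extraction of 3D atlas-space point
    clouds. A synthetic-atlas simulator generates complete test fixtures
    with known ground truth, and a command-line interface exposes the
    pipeline as subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    RNifti,
    png,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'anchoring.R'
    'atlas.R'
    'quantify.R'
    'warp.R'
    'synth.R'
    'qc.R'
    'points.R'
    'cli.R'
    'sectionatlas-package.R'
    'utils.R'
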