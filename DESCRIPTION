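Package: headmesher
Title: Surface-Based Tetrahedral Meshing of Segmented Head Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts multi-label or probabilistic tissue segmentations of
    the human head (scalp, skull, CSF, gray and white matter, air cavities)
    into a nested multi-layer triangular surface model and a labeled,
    quality-bounded tetrahedral mesh. Implements morphological gap insertion
    between adjacent tissue layers (cubic max/min filters), iso-surface
    extraction at a probability threshold with per-layer density control,
    Laplacian, Laplacian+HC and low-pass (Taubin) surface smoothing,
    quadric-error-metric surface decimation, a background-lattice
    tetrahedralizer with radius-edge and element-volume bounds, boundary
    recovery by element relabeling, and mesh quality / volume-conservation
    metrics (Joe-Liu quality, radius-edge ratio, per-tissue volume ratios).
    Ships a synthetic layered-head phantom generator with analytically known
    volumes for end-to-end validation, plus readers and writers for NIfTI,
    OFF, PLY, STL, legacy VTK, Gmsh MSH and TetGen node/ele formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: C++17
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'volume-utils.R'
    'io-nifti.R'
    'io-surface.R'
    'io-tetmesh.R'
    'phantoms.R'
    'preprocess.R'
    'surface-ops.R'
    'tetmesh.R'
    'quality.R'
    'pipeline.R'
    'cli.R'
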