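#' @useDynLib headmesher, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats pnorm quantile median runif
#' @importFrom utils head tail
NULL

# ---------------------------------------------------------------------------
# VolumeGrid
# ---------------------------------------------------------------------------

#' VolumeGrid: a scalar field on a regular voxel grid
#'
#' Container for a 3-D scalar field sampled on a regular grid with millimetre
#' spacing.  Voxel centre \code{(i,j,k)} (0-based) maps to millimetre
#' coordinates \code{origin + (i*sx, j*sy, k*sz)}.  The \code{kind} slot
#' distinguishes probability maps (values in [0,1]), integer label masks and
#' binary masks.
#'
#' @slot values 3-D numeric array.
#' @slot spacing numeric(3); voxel edge lengths in mm, strictly positive.
#' @slot origin numeric(3); mm coordinates of the centre of voxel (0,0,0).
#' @slot kind one of \code{"probability"}, \code{"label"}, \code{"binary"}.
#' @export
setClass("VolumeGrid",
  representation(values = "array", spacing = "numeric", origin = "numeric",
                 kind = "character"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), kind = "probability"))

setValidity("VolumeGrid", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3-D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 strictly positive numbers")
  if (length(object@origin) != 3L) return("origin must have length 3")
  if (!object@kind %in% c("probability", "label", "binary"))
    return("kind must be probability, label or binary")
  if (object@kind == "probability") {
    rng <- range(v)
    if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6)
      return("probability values outside [0,1]: not a probability map")
  } else if (object@kind == "label") {
    if (any(v < 0) || any(v != round(v)))
      return("label values must be non-negative integers")
  } else {
    if (!all(v %in% c(0, 1))) return("binary values must be 0 or 1")
  }
  TRUE
})

#' Construct a VolumeGrid
#'
#' @param values 3-D numeric array.
#' @param spacing voxel spacing in mm (length 1 or 3).
#' @param origin mm coordinates of voxel (0,0,0) centre.
#' @param kind \code{"probability"}, \code{"label"} or \code{"binary"}.
#' @return A \linkS4class{VolumeGrid}.
#' @export
VolumeGrid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       kind = "probability") {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (kind == "probability") {
    # tolerate tiny numerical overshoot, clamp it away
    values[values > 1 & values <= 1 + 1e-6] <- 1
    values[values < 0 & values >= -1e-6] <- 0
  }
  new("VolumeGrid", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), kind = kind)
}

# ---------------------------------------------------------------------------
# TissueStack
# ---------------------------------------------------------------------------

#' TissueStack: ordered per-tissue segmentations
#'
#' An ordered set of tissue \linkS4class{VolumeGrid}s from innermost (e.g.
#' white matter) to outermost (scalp), with optional air-cavity masks and,
#' for synthetic phantoms, the analytic tissue volumes in cubic mm.
#'
#' @slot layers named list of \linkS4class{VolumeGrid}, innermost first.
#' @slot airMasks named list of binary \linkS4class{VolumeGrid}; names give
#'   the host layer.
#' @slot analyticVolumes named numeric (mm^3), empty unless synthetic.
#' @export
setClass("TissueStack",
  representation(layers = "list", airMasks = "list",
                 analyticVolumes = "numeric"),
  prototype(airMasks = list(), analyticVolumes = numeric()))

setValidity("TissueStack", function(object) {
  if (length(object@layers) < 1L) return("at least one tissue layer required")
  if (is.null(names(object@layers)) || any(names(object@layers) == ""))
    return("layers must be named by tissue")
  if (!all(vapply(object@layers, is, logical(1), "VolumeGrid")))
    return("all layers must be VolumeGrid objects")
  d <- dim(object@layers[[1]]@values)
  for (l in object@layers)
    if (!identical(dim(l@values), d)) return("layer grids are not congruent")
  for (m in object@airMasks)
    if (!identical(dim(m@values), d)) return("air mask grid not congruent")
  TRUE
})

#' Construct a TissueStack
#' @param layers named list of VolumeGrid, innermost tissue first.
#' @param airMasks named list of binary VolumeGrid (name = host layer).
#' @param analyticVolumes optional named numeric of exact tissue volumes.
#' @return A \linkS4class{TissueStack}.
#' @export
TissueStack <- function(layers, airMasks = list(), analyticVolumes = numeric()) {
  new("TissueStack", layers = layers, airMasks = airMasks,
      analyticVolumes = analyticVolumes)
}

# ---------------------------------------------------------------------------
# TriSurface
# ---------------------------------------------------------------------------

#' TriSurface: a closed oriented triangle mesh
#'
#' Triangle surface in mm coordinates with a tissue tag.  Faces are stored
#' 1-based.  Surfaces produced by the pipeline are closed 2-manifolds with
#' outward-oriented faces (positive enclosed volume).
#'
#' @slot vertices n x 3 numeric matrix (mm).
#' @slot faces m x 3 integer matrix, 1-based vertex indices.
#' @slot tag tissue name.
#' @export
setClass("TriSurface",
  representation(vertices = "matrix", faces = "matrix", tag = "character"),
  prototype(tag = ""))

setValidity("TriSurface", function(object) {
  if (ncol(object@vertices) != 3L) return("vertices must be n x 3")
  if (ncol(object@faces) != 3L) return("faces must be m x 3")
  if (nrow(object@faces) > 0) {
    if (min(object@faces) < 1L || max(object@faces) > nrow(object@vertices))
      return("face indices out of range")
    keys <- apply(object@faces, 1L, function(f) paste(sort(f), collapse = "-"))
    if (anyDuplicated(keys)) return("duplicate faces")
  }
  TRUE
})

#' Construct a TriSurface
#' @param vertices n x 3 numeric matrix of mm coordinates.
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param tag tissue name.
#' @return A \linkS4class{TriSurface}.
#' @export
TriSurface <- function(vertices, faces, tag = "") {
  storage.mode(faces) <- "integer"
  new("TriSurface", vertices = as.matrix(vertices), faces = faces, tag = tag)
}

# ---------------------------------------------------------------------------
# TetMesh
# ---------------------------------------------------------------------------

#' TetMesh: a labeled tetrahedral mesh
#'
#' Node coordinates in mm, 4-node elements (1-based indices, positively
#' oriented) and one tissue label per element.  \code{regions} carries the
#' connected-region id assigned during tessellation, which the relabeling
#' step consumes.
#'
#' @slot nodes n x 3 numeric matrix (mm).
#' @slot elements m x 4 integer matrix, 1-based.
#' @slot labels character vector, one tissue (or \code{"air"}) per element.
#' @slot regions integer vector of preliminary region ids (may be empty).
#' @export
setClass("TetMesh",
  representation(nodes = "matrix", elements = "matrix", labels = "character",
                 regions = "integer"),
  prototype(regions = integer()))

setValidity("TetMesh", function(object) {
  if (ncol(object@nodes) != 3L) return("nodes must be n x 3")
  if (ncol(object@elements) != 4L) return("elements must be m x 4")
  if (nrow(object@elements) > 0) {
    if (min(object@elements) < 1L || max(object@elements) > nrow(object@nodes))
      return("element indices out of range")
    if (length(object@labels) != nrow(object@elements))
      return("one label per element required")
  }
  if (length(object@regions) > 0 &&
      length(object@regions) != nrow(object@elements))
    return("regions must be empty or one per element")
  TRUE
})

#' Construct a TetMesh
#'
#' Elements are reordered to positive signed volume.
#'
#' @param nodes n x 3 numeric matrix of mm coordinates.
#' @param elements m x 4 integer matrix of 1-based node indices.
#' @param labels character vector of per-element tissue labels.
#' @param regions optional integer region ids.
#' @return A \linkS4class{TetMesh}.
#' @export
TetMesh <- function(nodes, elements, labels, regions = integer()) {
  storage.mode(elements) <- "integer"
  nodes <- as.matrix(nodes)
  if (nrow(elements) > 0) {
    sv <- .tetSignedVolumes(nodes, elements)
    neg <- sv < 0
    if (any(neg)) elements[neg, c(3, 4)] <- elements[neg, c(4, 3)]
  }
  new("TetMesh", nodes = nodes, elements = elements,
      labels = as.character(labels), regions = as.integer(regions))
}

# ---------------------------------------------------------------------------
# parameter holders
# ---------------------------------------------------------------------------

#' GapParams: gap-insertion settings
#'
#' Controls the thickening/thinning operators that separate adjacent tissue
#' layers.  \code{epsilon} is the half-edge length (in voxels) of the cubic
#' filter neighborhood; \code{strategies} maps the inner layer of each
#' adjacent pair to \code{"thicken_outer"} or \code{"thin_inner"}.
#'
#' @slot epsilon integer >= 1, gap width in voxels.
#' @slot strategies named character; name = inner layer of the pair.
#' @export
setClass("GapParams",
  representation(epsilon = "integer", strategies = "character"),
  prototype(epsilon = 1L, strategies = character()))

setValidity("GapParams", function(object) {
  if (object@epsilon < 1L) return("epsilon must be >= 1")
  if (length(object@strategies) &&
      !all(object@strategies %in% c("thicken_outer", "thin_inner")))
    return("strategies must be thicken_outer or thin_inner")
  TRUE
})

#' @param epsilon gap width in voxels (integer >= 1).
#' @param strategies named character vector of per-pair strategies.
#' @rdname GapParams-class
#' @export
GapParams <- function(epsilon = 1L, strategies = character()) {
  new("GapParams", epsilon = as.integer(epsilon), strategies = strategies)
}

#' SurfaceCriteria: surface extraction and processing settings
#'
#' @slot rmax named numeric: per-layer bound (mm) on the circumradius of any
#'   surface triangle; a single unnamed value applies to all layers.
#' @slot iso iso-value for surface extraction (default 0.5).
#' @slot smoothMethod \code{"laplacian"}, \code{"laplacian_hc"},
#'   \code{"lowpass"} or \code{"none"}.
#' @slot smoothIterations number of smoothing iterations.
#' @slot smoothParams method parameters (alpha / beta / lambda / mu).
#' @slot keepLargest drop all but the largest connected component
#'   (removes segmentation noise islands).
#' @export
setClass("SurfaceCriteria",
  representation(rmax = "numeric", iso = "numeric", smoothMethod = "character",
                 smoothIterations = "integer", smoothParams = "list",
                 keepLargest = "logical"),
  prototype(rmax = 2, iso = 0.5, smoothMethod = "lowpass",
            smoothIterations = 10L,
            smoothParams = list(alpha = 0.5, beta = 0.6,
                                lambda = 0.5, mu = -0.53),
            keepLargest = TRUE))

setValidity("SurfaceCriteria", function(object) {
  if (any(object@rmax <= 0)) return("rmax must be positive")
  if (object@iso <= 0 || object@iso >= 1) return("iso must be in (0,1)")
  if (!object@smoothMethod %in% c("laplacian", "laplacian_hc", "lowpass", "none"))
    return("unknown smoothing method")
  TRUE
})

#' @param rmax per-layer triangle circumradius bound in mm.
#' @param iso extraction threshold.
#' @param smoothMethod,smoothIterations,smoothParams smoothing settings.
#' @param keepLargest keep only the largest surface component.
#' @rdname SurfaceCriteria-class
#' @export
SurfaceCriteria <- function(rmax = 2, iso = 0.5, smoothMethod = "lowpass",
                            smoothIterations = 10L,
                            smoothParams = list(), keepLargest = TRUE) {
  defaults <- list(alpha = 0.5, beta = 0.6, lambda = 0.5, mu = -0.53)
  smoothParams <- modifyList(defaults, smoothParams)
  new("SurfaceCriteria", rmax = rmax, iso = iso, smoothMethod = smoothMethod,
      smoothIterations = as.integer(smoothIterations),
      smoothParams = smoothParams, keepLargest = keepLargest)
}

#' MeshingCriteria: tetrahedralization settings
#'
#' \code{q} bounds the radius-edge ratio (circumsphere radius over shortest
#' edge) of every element; the regular tetrahedron attains the optimum
#' sqrt(6)/4, so values below that are unattainable.  \code{vmax} bounds the
#' element volume globally, \code{vmaxPerLabel} per tissue, and
#' \code{sizingField} (a function of an n x 3 matrix of mm points returning a
#' local volume bound) spatially.  \code{cellSize} is the pitch of the
#' background lattice from which the mesh is carved; \code{NA} chooses it
#' from the volume bounds.
#'
#' @slot q radius-edge bound, dimensionless (default 1.414).
#' @slot vmax global element volume bound, mm^3 (default 30).
#' @slot vmaxPerLabel named numeric of per-tissue overrides.
#' @slot sizingField function or NULL.
#' @slot cellSize background lattice pitch in mm, or NA for automatic.
#' @export
setClass("MeshingCriteria",
  representation(q = "numeric", vmax = "numeric", vmaxPerLabel = "numeric",
                 sizingField = "ANY", cellSize = "numeric"),
  prototype(q = 1.414, vmax = 30, vmaxPerLabel = numeric(),
            sizingField = NULL, cellSize = NA_real_))

setValidity("MeshingCriteria", function(object) {
  if (object@q < sqrt(6) / 4)
    return("q below sqrt(6)/4 is unattainable (regular-tet optimum)")
  if (object@vmax <= 0) return("vmax must be positive")
  if (!is.null(object@sizingField) && !is.function(object@sizingField))
    return("sizingField must be NULL or a function")
  TRUE
})

#' @param q radius-edge quality bound.
#' @param vmax global max element volume (mm^3).
#' @param vmaxPerLabel named per-tissue volume bounds.
#' @param sizingField optional function(points) -> local volume bound.
#' @param cellSize background lattice pitch (mm); NA = automatic.
#' @rdname MeshingCriteria-class
#' @export
MeshingCriteria <- function(q = 1.414, vmax = 30, vmaxPerLabel = numeric(),
                            sizingField = NULL, cellSize = NA_real_) {
  new("MeshingCriteria", q = q, vmax = vmax, vmaxPerLabel = vmaxPerLabel,
      sizingField = sizingField, cellSize = cellSize)
}

# ---------------------------------------------------------------------------
# LayeredModel
# ---------------------------------------------------------------------------

#' LayeredModel: nested extraction volumes after gap insertion
#'
#' The preprocessed form of a \linkS4class{TissueStack}: one cumulative
#' extraction volume per layer (innermost first) whose 0.5-level sets are
#' strictly nested, plus air masks and the record of voxels altered by the
#' thickening/thinning operators (consumed by boundary recovery).
#'
#' @slot extractionVolumes named list of \linkS4class{VolumeGrid},
#'   innermost first; entry i is the cumulative map of layers 1..i.
#' @slot airMasks named list of binary \linkS4class{VolumeGrid}.
#' @slot altered named list (one entry per processed pair) of linear voxel
#'   indices whose values were changed.
#' @slot alteredMask logical array marking all altered voxels.
#' @export
setClass("LayeredModel",
  representation(extractionVolumes = "list", airMasks = "list",
                 altered = "list", alteredMask = "array"))

#' QualityReport: mesh quality and volume-conservation metrics
#'
#' @slot joeLiu per-element Joe-Liu quality in [0,1].
#' @slot radiusEdge per-element radius-edge ratio.
#' @slot volume per-element volume (mm^3).
#' @slot vRel named per-tissue volume ratios (mesh over segmentation).
#' @slot summary list of aggregate statistics.
#' @export
setClass("QualityReport",
  representation(joeLiu = "numeric", radiusEdge = "numeric",
                 volume = "numeric", vRel = "numeric", summary = "list"))
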