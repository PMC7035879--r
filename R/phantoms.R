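# Synthetic layered-head phantoms with analytically known volumes.  Every
# pipeline stage is validated against these: concentric spheres (or
# ellipsoids) emulate the nested scalp/skull/CSF/GM/WM anatomy, with
# controllable inter-layer separation, merged boundaries, air cavities and
# noise islands.

#' PhantomSpec: synthetic layered-head phantom definition
#'
#' Layer radii are outer radii, strictly decreasing from the outermost
#' (scalp-like) to the innermost (WM-like) layer; each layer occupies the
#' shell between its radius and the next.  Adjacent layers share a boundary
#' unless a positive \code{separation} (in voxels) carves a background gap
#' between them by shrinking the inner layer.  Probability maps are built by
#' passing the signed distance to each interface through a Gaussian CDF of
#' width \code{blurSigma}, so the 0.5-level set sits exactly on the analytic
#' interface; \code{blurSigma = 0} gives hard binary maps.
#'
#' @slot shape \code{"sphere"} or \code{"ellipsoid"}.
#' @slot layerRadii named numeric, outer radii in mm, strictly decreasing.
#' @slot gridSize integer(3) voxels.
#' @slot spacing numeric(3) mm.
#' @slot blurSigma mm; 0 for binary maps.
#' @slot separation numeric, per-pair background gap in voxels (length
#'   nlayers - 1, outermost pair first), default all 0 (shared boundaries).
#' @slot offsets named numeric, per-layer centre offset along z in mm.  An
#'   offset large enough to push a layer against its outer neighbour gets
#'   clipped, producing a cap where the two boundaries coincide exactly --
#'   the merged-boundary pathology the gap-insertion operators exist for.
#' @slot axesScale numeric(3), ellipsoid semi-axis multipliers.
#' @slot cavity optional list(center, radius, host).
#' @export
setClass("PhantomSpec",
  representation(shape = "character", layerRadii = "numeric",
                 gridSize = "integer", spacing = "numeric",
                 blurSigma = "numeric", separation = "numeric",
                 offsets = "numeric", axesScale = "numeric", cavity = "ANY"),
  prototype(shape = "sphere", blurSigma = 0.5, offsets = numeric(),
            axesScale = c(1, 1, 1), cavity = NULL))

setValidity("PhantomSpec", function(object) {
  r <- object@layerRadii
  if (length(r) < 1) return("at least one layer required")
  if (is.null(names(r))) return("layerRadii must be named by tissue")
  if (any(diff(r) >= 0)) return("layer radii must be strictly decreasing")
  if (length(object@separation) != max(length(r) - 1, 0))
    return("separation needs one entry per adjacent pair")
  ext <- (object@gridSize - 1) * object@spacing
  if (any(2 * r[1] * object@axesScale > ext - 4 * object@spacing))
    return("outer layer does not fit in the grid with a 2-voxel margin")
  if (length(object@offsets) &&
      !all(names(object@offsets) %in% names(r)))
    return("offsets must be named by layer")
  if (!is.null(object@cavity)) {
    if (!all(c("center", "radius", "host") %in% names(object@cavity)))
      return("cavity needs center, radius, host")
    if (!object@cavity$host %in% names(r)) return("cavity host not a layer")
  }
  TRUE
})

#' @param layerRadii named outer radii (mm), decreasing outermost first.
#' @param gridSize voxels per dimension (length 1 or 3).
#' @param spacing mm per voxel (length 1 or 3).
#' @param blurSigma Gaussian CDF width in mm (0 = binary).
#' @param separation per-pair background gap in voxels.
#' @param offsets named per-layer z-offsets in mm (merged-boundary caps).
#' @param shape \code{"sphere"} or \code{"ellipsoid"}.
#' @param axesScale ellipsoid semi-axis multipliers.
#' @param cavity optional list(center, radius, host) for an air cavity.
#' @rdname PhantomSpec-class
#' @export
PhantomSpec <- function(layerRadii, gridSize = 96L, spacing = 1,
                        blurSigma = 0.5, separation = NULL, offsets = numeric(),
                        shape = "sphere", axesScale = c(1, 1, 1),
                        cavity = NULL) {
  if (length(gridSize) == 1L) gridSize <- rep(gridSize, 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(separation)) separation <- rep(0, max(length(layerRadii) - 1, 0))
  new("PhantomSpec", shape = shape, layerRadii = layerRadii,
      gridSize = as.integer(gridSize), spacing = as.numeric(spacing),
      blurSigma = blurSigma, separation = as.numeric(separation),
      offsets = offsets, axesScale = axesScale, cavity = cavity)
}

#' Named phantom presets
#'
#' \describe{
#'   \item{five-layer}{Concentric spheres with radii 40/36/33/31/27 mm on a
#'     96^3 1 mm grid (scalp/skull/CSF/GM/WM), all boundaries shared --
#'     the layer thicknesses bracket adult head values.}
#'   \item{five-layer-separated}{Thicker shells (radii 40/34/28/22/16 mm)
#'     with a 2-voxel background gap carved between all layers.}
#'   \item{merged-csf-gm}{The five-layer phantom with the GM (and WM)
#'     centre shifted 3 mm so the GM sphere is clipped against the CSF
#'     boundary: over the contact cap the CSF/GM boundaries merge.}
#'   \item{three-layer}{Radii 40/30/20 mm, shared boundaries (fast tests).}
#'   \item{cavity}{A five-layer phantom with a thickened skull shell
#'     (radii 40/36/24/22/18 mm) hosting a 4 mm-radius air cavity.}
#' }
#'
#' @param name preset name.
#' @param gridSize,spacing grid overrides.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomPreset <- function(name = c("five-layer", "five-layer-separated",
                                   "merged-csf-gm", "three-layer", "cavity"),
                          gridSize = 96L, spacing = 1) {
  name <- match.arg(name)
  five <- c(scalp = 40, skull = 36, csf = 33, gm = 31, wm = 27)
  switch(name,
    "five-layer" = PhantomSpec(five, gridSize, spacing),
    "five-layer-separated" = PhantomSpec(c(scalp = 40, skull = 34,
                                           csf = 28, gm = 22, wm = 16),
                                         gridSize, spacing,
                                         separation = rep(2, 4)),
    "merged-csf-gm" = PhantomSpec(five, gridSize, spacing,
                                  offsets = c(gm = 3, wm = 3)),
    "three-layer" = PhantomSpec(c(scalp = 40, skull = 30, wm = 20),
                                gridSize, spacing),
    "cavity" = PhantomSpec(c(scalp = 40, skull = 36, csf = 24, gm = 22,
                             wm = 18), gridSize, spacing,
                           cavity = list(center = c(0, 0, 30), radius = 4,
                                         host = "skull")))
}

# signed distance to the layer interface (positive inside), sphere or
# ellipsoid (scaled radius approximation for the ellipsoid)
.phantomInsideProb <- function(coords, radius, spec, zoff = 0) {
  s <- spec@axesScale
  rho <- sqrt((coords$x / s[1])^2 + (coords$y / s[2])^2 +
              ((coords$z - zoff) / s[3])^2)
  d <- radius - rho
  if (spec@blurSigma > 0) stats::pnorm(d / spec@blurSigma) else as.numeric(d >= 0)
}

# volume of the intersection of two spheres (outer radius R centred at 0,
# inner radius r centred a distance d away)
.sphereIntersectionVolume <- function(R, r, d) {
  if (d + r <= R) return(4 / 3 * pi * r^3)
  if (d >= R + r) return(0)
  pi * (R + r - d)^2 *
    (d^2 + 2 * d * r - 3 * r^2 + 2 * d * R + 6 * r * R - 3 * R^2) / (12 * d)
}

.phantomCoords <- function(spec) {
  n <- spec@gridSize
  sp <- spec@spacing
  cen <- (n - 1) * sp / 2
  x <- (0:(n[1] - 1)) * sp[1] - cen[1]
  y <- (0:(n[2] - 1)) * sp[2] - cen[2]
  z <- (0:(n[3] - 1)) * sp[3] - cen[3]
  list(x = array(rep(x, times = n[2] * n[3]), dim = n),
       y = array(rep(rep(y, each = n[1]), times = n[3]), dim = n),
       z = array(rep(z, each = n[1] * n[2]), dim = n),
       center = cen)
}

#' Generate a layered phantom
#'
#' Builds one probability map per layer plus the analytic shell volumes.
#' Maps of adjacent layers with zero separation share their 0.5-level set
#' exactly (merged boundary); positive separation leaves a background gap.
#' An air cavity is carved out of its host layer and returned as an air
#' mask.  For \code{blurSigma = 0} the maps are binary and mutually
#' exclusive.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return A \linkS4class{TissueStack} (layers innermost first) with
#'   \code{analyticVolumes} filled in.
#' @export
makeLayeredPhantom <- function(spec) {
  validObject(spec)
  co <- .phantomCoords(spec)
  r <- spec@layerRadii         # outermost first
  nl <- length(r)
  sep_mm <- spec@separation * max(spec@spacing)  # gap above layer i+1
  # a separated pair carves the gap out of the inner layer: layer i's outer
  # radius shrinks by the separation of the pair above it
  rout <- r - c(0, sep_mm)
  zoff <- rep(0, nl)
  names(zoff) <- names(r)
  if (length(spec@offsets)) zoff[names(spec@offsets)] <- spec@offsets
  axprod <- prod(spec@axesScale)
  # per-layer "inside" fields, clipped against the enclosing layer so the
  # model stays nested; an offset layer pressed against its neighbour gets a
  # merged-boundary cap
  G <- vector("list", nl)
  vols_ball <- numeric(nl)
  for (i in seq_len(nl)) {
    f <- .phantomInsideProb(co, rout[i], spec, zoff[i])
    if (i == 1) {
      G[[i]] <- f
      vols_ball[i] <- 4 / 3 * pi * rout[i]^3 * axprod
    } else {
      G[[i]] <- pmin(f, G[[i - 1]])
      # analytic clipped volume: intersection with the immediate outer ball
      vols_ball[i] <- .sphereIntersectionVolume(rout[i - 1], rout[i],
                                                abs(zoff[i] - zoff[i - 1])) *
        axprod
    }
  }
  layersOut <- vector("list", nl)
  vols <- numeric(nl)
  for (i in seq_len(nl)) {
    p <- if (i < nl) pmax(G[[i]] - G[[i + 1]], 0) else G[[i]]
    vols[i] <- vols_ball[i] - if (i < nl) vols_ball[i + 1] else 0
    layersOut[[i]] <- VolumeGrid(array(p, dim = spec@gridSize),
                                 spacing = spec@spacing, kind = "probability")
  }
  names(layersOut) <- names(r)
  names(vols) <- names(r)
  airMasks <- list()
  if (!is.null(spec@cavity)) {
    cav <- spec@cavity
    host <- match(cav$host, names(r))
    rho <- sqrt((co$x - cav$center[1])^2 + (co$y - cav$center[2])^2 +
                (co$z - cav$center[3])^2)
    d <- cav$radius - rho
    cp <- if (spec@blurSigma > 0) stats::pnorm(d / spec@blurSigma)
          else as.numeric(d >= 0)
    hv <- layersOut[[host]]@values
    if (!any(hv >= 0.5 & cp >= 0.5))
      stop("cavity does not intersect its host layer")
    # the cavity must sit strictly inside the host shell
    outside_host <- (cp >= 0.5) & (hv < 0.5)
    if (any(outside_host))
      stop("cavity extends outside its host layer")
    layersOut[[host]]@values <- pmax(hv - cp, 0)
    airMasks <- list(VolumeGrid(array(cp, dim = spec@gridSize),
                                spacing = spec@spacing, kind = "probability"))
    names(airMasks) <- cav$host
    vols[host] <- vols[host] - 4 / 3 * pi * cav$radius^3
    vols <- c(vols, air = 4 / 3 * pi * cav$radius^3)
  }
  # innermost-first ordering for the stack
  TissueStack(rev(layersOut), airMasks = airMasks, analyticVolumes = vols)
}

#' Inject misclassified noise islands
#'
#' Adds \code{n} disjoint small foreign-tissue blobs, emulating
#' segmentation noise: inside a randomly chosen host layer, a cubic blob of
#' \code{size} voxels is switched to a randomly chosen other tissue.
#' Deterministic for a given \code{seed}; the blobs stay clear of layer
#' boundaries and of each other.
#'
#' @param stack a \linkS4class{TissueStack}.
#' @param n number of islands (0 returns the stack unchanged).
#' @param size island edge length in voxels.
#' @param seed RNG seed.
#' @return The modified stack; attribute \code{"islands"} records host,
#'   tissue and position of each island.
#' @export
addNoiseIslands <- function(stack, n, size = 2L, seed = 1L) {
  stopifnot(n >= 0)
  if (n == 0) return(stack)
  layers <- stack@layers
  nl <- length(layers)
  if (nl < 2) stop("need at least two layers to misclassify")
  dims <- dim(layers[[1]]@values)
  if (size >= min(dims) / 4) stop("island larger than its layer")
  set.seed(seed)
  placed <- list()
  occupied <- array(FALSE, dims)
  attempts <- 0
  while (length(placed) < n && attempts < 2000 * n) {
    attempts <- attempts + 1
    host <- sample.int(nl, 1)
    other <- sample(setdiff(seq_len(nl), host), 1)
    hv <- layers[[host]]@values
    # candidate corner; require the whole blob + 1-voxel margin deep in host
    lo <- vapply(dims, function(d) sample.int(d - size - 2L, 1) + 1L, 0L)
    sl <- lapply(seq_len(3), function(k) (lo[k] - 1L):(lo[k] + size))
    blk <- hv[sl[[1]], sl[[2]], sl[[3]]]
    if (!all(blk >= 0.5)) next
    if (any(occupied[sl[[1]], sl[[2]], sl[[3]]])) next
    core <- lapply(seq_len(3), function(k) lo[k]:(lo[k] + size - 1L))
    layers[[host]]@values[core[[1]], core[[2]], core[[3]]] <- 0
    layers[[other]]@values[core[[1]], core[[2]], core[[3]]] <- 1
    occupied[sl[[1]], sl[[2]], sl[[3]]] <- TRUE
    placed[[length(placed) + 1]] <- list(host = names(layers)[host],
                                         tissue = names(layers)[other],
                                         corner = lo, size = size)
  }
  if (length(placed) < n)
    stop("could not place all islands; layers too small")
  out <- TissueStack(layers, airMasks = stack@airMasks,
                     analyticVolumes = stack@analyticVolumes)
  attr(out, "islands") <- placed
  out
}
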