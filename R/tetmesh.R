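# Volumetric meshing: carve a labeled tetrahedral mesh out of a BCC
# background lattice so that it conforms to a nested set of closed surfaces,
# under radius-edge and element-volume bounds.  See the methods vignette for
# the engine design.

.surfBBox <- function(surfaces) {
  lo <- Reduce(pmin, lapply(surfaces, function(s) apply(s@vertices, 2, min)))
  hi <- Reduce(pmax, lapply(surfaces, function(s) apply(s@vertices, 2, max)))
  list(lo = lo, hi = hi)
}

# effective global element-volume bound from vmax, per-label overrides and
# the sizing field sampled over the domain
.effectiveVmax <- function(criteria, surfaces) {
  v <- criteria@vmax
  if (length(criteria@vmaxPerLabel)) v <- min(v, criteria@vmaxPerLabel)
  if (!is.null(criteria@sizingField)) {
    bb <- .surfBBox(surfaces)
    gx <- seq(bb$lo[1], bb$hi[1], length.out = 12)
    gy <- seq(bb$lo[2], bb$hi[2], length.out = 12)
    gz <- seq(bb$lo[3], bb$hi[3], length.out = 12)
    pts <- as.matrix(expand.grid(gx, gy, gz))
    sv <- criteria@sizingField(pts)
    if (any(sv <= 0)) stop("sizing field must be positive")
    v <- min(v, min(sv))
  }
  v
}

#' Tetrahedralize a nested surface model
#'
#' Fills the regions bounded by a nested set of closed, pairwise
#' non-intersecting surfaces with tetrahedra.  A body-centered-cubic
#' background lattice is imprinted with each surface in turn (outermost
#' inward): lattice vertices whose incident edge cuts would fall too close
#' to them are snapped onto the surface, remaining crossed elements are
#' split along the interpolated signed-distance zero set, and interface
#' vertices are projected back onto the exact surface.  A mesh-improvement
#' loop (guarded Laplacian smoothing with tangential reprojection, short-edge
#' collapse, edge removal and long-edge split) then drives every element to
#' the radius-edge bound \code{q}.  The element volumes partition the meshed
#' domain exactly, so the summed element volume equals the enclosed volume of
#' the mesh's outer boundary to rounding error.
#'
#' @param surfaces named list of closed \linkS4class{TriSurface}s, innermost
#'   first (the \linkS4class{TissueStack} order).
#' @param criteria a \linkS4class{MeshingCriteria}.
#' @param airSurfaces optional list of closed cavity surfaces; regions inside
#'   them are labeled \code{"air"}.
#' @param verbose print stage progress.
#' @return A \linkS4class{TetMesh} whose labels name, for every element, the
#'   innermost enclosing tissue surface (or \code{"air"}), and whose
#'   \code{regions} slot holds connected-region ids.
#' @export
tetrahedralize <- function(surfaces, criteria = MeshingCriteria(),
                           airSurfaces = list(), verbose = FALSE) {
  if (is(surfaces, "TriSurface")) surfaces <- list(region1 = surfaces)
  if (is.null(names(surfaces)) || any(names(surfaces) == ""))
    names(surfaces) <- paste0("region", seq_along(surfaces))
  n <- length(surfaces)
  say <- function(...) if (verbose) message(sprintf(...))
  for (nm in names(surfaces))
    if (!isClosedSurface(surfaces[[nm]]))
      stop("surface '", nm, "' is not closed")
  for (s in airSurfaces)
    if (!isClosedSurface(s)) stop("air surface is not closed")
  # pairwise non-intersection, innermost-first order
  allS <- c(surfaces, airSurfaces)
  if (length(allS) > 1) {
    for (i in seq_len(length(allS) - 1))
      for (j in (i + 1):length(allS))
        if (surfacesIntersect(allS[[i]], allS[[j]]))
          stop(sprintf("input surfaces %d and %d intersect", i, j))
  }
  outerFirst <- rev(surfaces)             # outermost first for cutting
  vmaxEff <- .effectiveVmax(criteria, surfaces)
  h <- criteria@cellSize
  bb <- .surfBBox(outerFirst[1])
  ext <- bb$hi - bb$lo
  if (is.na(h)) {
    # resolve the largest extent with ~50 cells, but never refine below
    # 0.8 mm: mm-resolution segmentations carry no finer boundary detail
    h <- min((12 * vmaxEff)^(1 / 3) * 0.999, max(ext) / 48)
    h <- max(h, min(0.8, (12 * vmaxEff)^(1 / 3) * 0.999))
  }
  if (h^3 / 12 > vmaxEff)
    stop("cellSize incompatible with the element volume bound")
  lo <- bb$lo - 1.5 * h
  ncell <- pmax(as.integer(ceiling((ext + 3 * h) / h)), 2L)
  say("lattice: pitch %.3f mm, %d x %d x %d cells", h, ncell[1], ncell[2],
      ncell[3])
  lat <- cpp_bcc_mesh(lo, ncell, h)
  V <- lat$vertices
  T <- lat$tets
  vsurf <- rep(-1L, nrow(V))
  depth <- rep(0L, nrow(T))               # number of tissue surfaces containing
  airIdx <- rep(0L, nrow(T))              # 0 = not in a cavity
  cutList <- c(outerFirst, airSurfaces)
  nTissue <- n
  for (k in seq_along(cutList)) {
    s <- cutList[[k]]
    SV <- s@vertices
    SF <- s@faces - 1L
    sd <- cpp_signed_distance(V, SV, SF, 3 * h)
    sn <- cpp_snap_for_cut(V, T, sd$distance, sd$closest, 0.3, 1e-9 * h)
    V <- sn$vertices
    vsurf[sn$snapped & vsurf == -1L] <- k - 1L
    cut <- cpp_cut_by_field(V, T, sn$distance, 1e-9 * h, 1e-16)
    newVerts <- nrow(cut$vertices) - nrow(V)
    V <- cut$vertices
    T <- cut$tets
    vsurf <- c(vsurf, rep(k - 1L, newVerts))
    depth <- depth[cut$parent]
    airIdx <- airIdx[cut$parent]
    if (k <= nTissue) depth[cut$side == 1L] <- k
    else airIdx[cut$side == 1L] <- k - nTissue
    if (k == 1L) {                        # discard everything outside
      keep <- cut$side == 1L
      T <- T[keep, , drop = FALSE]
      depth <- depth[keep]
      airIdx <- airIdx[keep]
    }
    # project the new interface vertices onto the exact surface
    iface <- which(vsurf == k - 1L)
    if (length(iface)) {
      sd2 <- cpp_signed_distance(V[iface, , drop = FALSE], SV, SF, 2 * h)
      dfull <- numeric(nrow(V))
      dfull[iface] <- sd2$distance
      cpfull <- matrix(NA_real_, nrow(V), 3)
      cpfull[iface, ] <- sd2$closest
      elig <- logical(nrow(V))
      elig[iface] <- TRUE
      pr <- cpp_snap_vertices(V, T, dfull, cpfull, 0.9 * h, elig)
      V <- pr$vertices
    }
    say("surface %d/%d: %d elements, %d vertices", k, length(cutList),
        nrow(T), nrow(V))
  }
  # preliminary labels: innermost containing tissue surface, or air
  outerNames <- names(outerFirst)
  labels <- outerNames[pmax(depth, 1L)]
  labels[depth == 0L] <- outerNames[1]    # cannot happen after outer drop
  labels[airIdx > 0L] <- "air"
  # quality loop
  surfL <- lapply(cutList, function(s)
    list(vertices = s@vertices, faces = s@faces - 1L))
  labInt <- match(labels, unique(labels))
  q <- criteria@q
  prevBad <- Inf
  for (round in seq_len(10)) {
    m <- cpp_tet_metrics(V, T)
    nbad <- sum(m$radius_edge > q)
    say("quality round %d: %d above q, max %.3f", round, nbad,
        max(m$radius_edge))
    if (nbad == 0) break
    if (nbad >= prevBad) {
      # structural operations stalled; polish the remaining clusters by
      # local pattern search, then give the loop one more chance
      po <- cpp_polish_clusters(V, T, vsurf, surfL, q, 4L, 2.5 * h, 0.3 * h)
      V <- po$vertices
      m <- cpp_tet_metrics(V, T)
      nbad2 <- sum(m$radius_edge > q)
      say("polish: %d moves, %d above q, max %.3f", po$n_moved, nbad2,
          max(m$radius_edge))
      if (nbad2 == 0 || po$n_moved == 0) break
    }
    prevBad <- nbad
    cl <- cpp_collapse_slivers(V, T, labInt, vsurf, surfL, q, 3L, 2.5 * h,
                               0.45 * h, vmaxEff)
    V <- cl$vertices; T <- cl$tets; labInt <- cl$label; vsurf <- cl$vsurf
    er <- cpp_remove_edges(V, T, labInt, vsurf, q, 3L, vmaxEff)
    T <- er$tets; labInt <- er$label
    sp <- cpp_split_long_edges(V, T, labInt, vsurf, surfL, q, 2L, 2.5 * h)
    V <- sp$vertices; T <- sp$tets; labInt <- sp$label; vsurf <- sp$vsurf
    im <- cpp_improve_quality(V, T, vsurf, surfL, q, 4L, 2.5 * h)
    V <- im$vertices
  }
  labels <- unique(labels)[labInt]
  # drop unreferenced vertices and build the mesh
  used <- sort(unique(as.vector(T)))
  remap <- integer(nrow(V))
  remap[used + 1L] <- seq_along(used)
  Tm <- matrix(remap[T + 1L], ncol = 4)
  Vm <- V[used + 1L, , drop = FALSE]
  regions <- cpp_tet_regions(Tm - 1L, match(labels, unique(labels)))
  mesh <- TetMesh(Vm, Tm, labels, regions = regions)
  attr(mesh, "cellSize") <- h
  mesh
}

#' Point-in-surface test
#'
#' Parity ray casting with a deterministic perturbation schedule, so points
#' close to (or on) faces resolve reproducibly.
#'
#' @param point numeric(3) mm coordinates, or an n x 3 matrix.
#' @param surface a closed \linkS4class{TriSurface}.
#' @return logical, one value per point.
#' @export
pointInSurface <- function(point, surface) {
  if (is.null(dim(point))) point <- matrix(point, ncol = 3)
  as.logical(cpp_points_in_mesh(point, surface@vertices, surface@faces - 1L))
}

#' Assign tissue labels to mesh regions
#'
#' Each connected region is labeled by the innermost surface that contains a
#' representative interior point (the centroid of the region's
#' largest-volume element); regions inside an air surface are labeled
#' \code{"air"}.
#'
#' @param mesh a \linkS4class{TetMesh} with region ids.
#' @param surfaces named list of \linkS4class{TriSurface}s, innermost first.
#' @param airSurfaces optional list of cavity surfaces.
#' @return the relabeled \linkS4class{TetMesh}.
#' @export
assignRegionLabels <- function(mesh, surfaces, airSurfaces = list()) {
  if (length(mesh@regions) == 0)
    stop("mesh carries no region ids; run tetrahedralize first")
  vols <- abs(.tetSignedVolumes(mesh@nodes, mesh@elements))
  cent <- (mesh@nodes[mesh@elements[, 1], ] + mesh@nodes[mesh@elements[, 2], ] +
           mesh@nodes[mesh@elements[, 3], ] + mesh@nodes[mesh@elements[, 4], ]) / 4
  regs <- sort(unique(mesh@regions))
  reps <- t(vapply(regs, function(r) {
    idx <- which(mesh@regions == r)
    cent[idx[which.max(vols[idx])], ]
  }, numeric(3)))
  labels <- rep(NA_character_, length(regs))
  for (a in seq_along(airSurfaces)) {
    inside <- pointInSurface(reps, airSurfaces[[a]])
    labels[is.na(labels) & inside] <- "air"
  }
  for (nm in names(surfaces)) {           # innermost first
    inside <- pointInSurface(reps, surfaces[[nm]])
    labels[is.na(labels) & inside] <- nm
  }
  if (anyNA(labels))
    stop("region not contained in any surface; inconsistent input")
  out <- mesh
  out@labels <- labels[match(mesh@regions, regs)]
  out
}

# original tissue of each query point: innermost tissue whose cumulative
# original map is >= 0.5 there, or air where an air mask dominates
.originalTissueAt <- function(points, stack) {
  g <- stack@layers[[1]]
  dims <- dim(g@values)
  ijk <- sweep(sweep(points, 2, g@origin), 2, g@spacing, "/")
  ijk <- round(ijk)
  ijk <- pmin(pmax(ijk, 0), matrix(rep(dims - 1L, each = nrow(points)),
                                   ncol = 3))
  lin <- 1 + ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3])
  out <- rep(NA_character_, nrow(points))
  for (an in names(stack@airMasks)) {
    hit <- stack@airMasks[[an]]@values[lin] >= 0.5
    out[is.na(out) & hit] <- "air"
  }
  cum <- array(0, dims)
  for (nm in names(stack@layers)) {       # innermost first
    cum <- pmin(cum + stack@layers[[nm]]@values, 1)
    hit <- cum[lin] >= 0.5
    out[is.na(out) & hit] <- nm
  }
  out
}

#' Recover shared boundaries by relabeling
#'
#' After gap insertion, elements filling the artificial gap carry the
#' adjacent (outer) tissue's label.  This step retags elements against the
#' original (pre-gap) segmentation: first each connected region is
#' majority-voted as a whole (correcting wholesale mislabels), then elements
#' whose centroids fall inside the altered-voxel record form their own
#' connected sub-regions and are majority-voted separately, which restores
#' boundaries the segmentation shared before the gap was carved.  Ties
#' resolve to the innermost candidate tissue.
#'
#' @param mesh a labeled \linkS4class{TetMesh}.
#' @param stack the original \linkS4class{TissueStack}.
#' @param model the \linkS4class{LayeredModel} from
#'   \code{\link{buildLayeredModel}} (supplies the altered-voxel record);
#'   may be NULL, in which case only the whole-region vote runs.
#' @return the relabeled \linkS4class{TetMesh}.
#' @export
relabelSharedBoundaries <- function(mesh, stack, model = NULL) {
  cent <- (mesh@nodes[mesh@elements[, 1], ] + mesh@nodes[mesh@elements[, 2], ] +
           mesh@nodes[mesh@elements[, 3], ] + mesh@nodes[mesh@elements[, 4], ]) / 4
  orig <- .originalTissueAt(cent, stack)
  tissueRank <- c("air", names(stack@layers))   # innermost first, air first
  majority <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_character_)
    tb <- table(x)
    winners <- names(tb)[tb == max(tb)]
    winners[order(match(winners, tissueRank))][1]
  }
  labels <- mesh@labels
  regions <- mesh@regions
  if (length(regions) == 0)
    regions <- cpp_tet_regions(mesh@elements - 1L,
                               match(labels, unique(labels)))
  # 1) whole-region vote
  for (r in unique(regions)) {
    idx <- which(regions == r)
    m <- majority(orig[idx])
    if (!is.na(m)) labels[idx] <- m
  }
  # 2) altered-zone sub-regions
  if (!is.null(model) && length(model@altered)) {
    g <- stack@layers[[1]]
    dims <- dim(g@values)
    ijk <- round(sweep(sweep(cent, 2, g@origin), 2, g@spacing, "/"))
    ijk <- pmin(pmax(ijk, 0), matrix(rep(dims - 1L, each = nrow(cent)),
                                     ncol = 3))
    lin <- 1 + ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3])
    inAltered <- model@alteredMask[lin] & labels != "air"
    # inside the altered zone a gap is face-connected to genuine tissue of
    # the same preliminary label, so any region-level vote bleeds across the
    # recovered boundary; elements are retagged individually there
    sel <- inAltered & !is.na(orig) & orig != labels
    labels[sel] <- orig[sel]
  }
  out <- mesh
  out@labels <- labels
  out
}
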