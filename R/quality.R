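# Mesh quality metrics and the volume-conservation ratio.

#' Joe-Liu quality of a tetrahedron
#'
#' The scale-invariant shape metric
#' \deqn{q = 12 (3V)^{2/3} / \sum_{i<j} \ell_{ij}^2}
#' with \eqn{V} the (absolute) element volume and \eqn{\ell_{ij}} the six
#' edge lengths.  Equals 1 for the regular tetrahedron and tends to 0 as the
#' element degenerates; coincident points give 0.
#'
#' @param tet 4 x 3 numeric matrix of vertex coordinates.
#' @return quality in [0, 1].
#' @export
joeLiu <- function(tet) {
  stopifnot(nrow(tet) == 4, ncol(tet) == 3)
  v <- abs(det(cbind(tet[2, ] - tet[1, ], tet[3, ] - tet[1, ],
                     tet[4, ] - tet[1, ]))) / 6
  s2 <- sum(dist(tet)^2)
  if (s2 == 0) return(0)
  12 * (3 * v)^(2 / 3) / s2
}

#' Radius-edge ratio of a tetrahedron
#'
#' Circumsphere radius divided by the shortest edge length.  The regular
#' tetrahedron attains the minimum sqrt(6)/4; degenerate (coplanar)
#' elements return Inf.
#'
#' @param tet 4 x 3 numeric matrix of vertex coordinates.
#' @return the ratio (>= sqrt(6)/4), or Inf if degenerate.
#' @export
radiusEdge <- function(tet) {
  stopifnot(nrow(tet) == 4, ncol(tet) == 3)
  A <- 2 * rbind(tet[2, ] - tet[1, ], tet[3, ] - tet[1, ], tet[4, ] - tet[1, ])
  b <- c(sum(tet[2, ]^2) - sum(tet[1, ]^2),
         sum(tet[3, ]^2) - sum(tet[1, ]^2),
         sum(tet[4, ]^2) - sum(tet[1, ]^2))
  cc <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(cc)) return(Inf)
  R <- sqrt(sum((cc - tet[1, ])^2))
  R / min(dist(tet))
}

#' Per-element metrics of a tetrahedral mesh
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @return data.frame with columns \code{volume} (mm^3),
#'   \code{radiusEdge} and \code{joeLiu}.
#' @export
meshQuality <- function(mesh) {
  m <- cpp_tet_metrics(mesh@nodes, mesh@elements - 1L)
  data.frame(volume = abs(m$volume), radiusEdge = m$radius_edge,
             joeLiu = m$joe_liu)
}

#' Boundary surface of a tetrahedral mesh subset
#'
#' Outward-oriented faces used exactly once by the selected elements: for
#' the whole mesh this is its outer boundary; for a label subset it is that
#' tissue region's boundary.
#'
#' @param mesh a \linkS4class{TetMesh}.
#' @param labels optional character vector of labels to select (default:
#'   all elements).
#' @param tag tissue tag for the result.
#' @return A \linkS4class{TriSurface}.
#' @export
meshBoundary <- function(mesh, labels = NULL, tag = "") {
  keep <- if (is.null(labels)) rep(TRUE, nrow(mesh@elements))
          else mesh@labels %in% labels
  F <- cpp_subset_boundary(mesh@elements - 1L, keep) + 1L
  used <- sort(unique(as.vector(F)))
  remap <- integer(nrow(mesh@nodes))
  remap[used] <- seq_along(used)
  TriSurface(mesh@nodes[used, , drop = FALSE], matrix(remap[F], ncol = 3),
             tag = tag)
}

#' Per-tissue mesh volumes
#'
#' @param mesh a labeled \linkS4class{TetMesh}.
#' @return named numeric of summed element volumes (mm^3) per label.
#' @export
labelVolumes <- function(mesh) {
  v <- abs(.tetSignedVolumes(mesh@nodes, mesh@elements))
  vapply(split(v, mesh@labels), sum, 0)
}

#' Volume-conservation ratio Vrel
#'
#' Ratio of the mesh-side tissue volume to the segmentation-side voxel
#' volume.  A value close to 1 indicates that meshing preserved the tissue
#' shape.  For a \linkS4class{TetMesh} the numerator is the summed volume of
#' the tissue's elements (labels partition the shells exactly); for a
#' \linkS4class{TriSurface} it is the enclosed volume minus, if given, the
#' enclosed volume of the next-inner boundary.  The denominator counts
#' voxels of the original per-tissue map at or above \code{iso}.
#'
#' @param x a \linkS4class{TetMesh} or \linkS4class{TriSurface}.
#' @param tissue tissue name.
#' @param segmentation the original \linkS4class{TissueStack}.
#' @param innerSurface optional next-inner boundary (surface input only).
#' @param iso segmentation threshold (default 0.5).
#' @return the ratio (dimensionless).
#' @export
vRel <- function(x, tissue, segmentation, innerSurface = NULL, iso = 0.5) {
  if (tissue == "air") {
    if (!length(segmentation@airMasks)) stop("no air masks in segmentation")
    seg <- sum(vapply(segmentation@airMasks, thresholdVolume, 0, iso = iso))
  } else {
    if (!tissue %in% names(segmentation@layers))
      stop("tissue '", tissue, "' absent from the segmentation")
    seg <- thresholdVolume(segmentation@layers[[tissue]], iso = iso)
  }
  if (seg == 0) stop("zero-volume segmentation for tissue '", tissue, "'")
  num <- if (is(x, "TetMesh")) {
    if (!tissue %in% x@labels) stop("tissue '", tissue, "' absent from mesh")
    unname(labelVolumes(x)[tissue])
  } else {
    v <- enclosedVolume(x)
    if (!is.null(innerSurface)) v <- v - enclosedVolume(innerSurface)
    v
  }
  num / seg
}

#' Quality-control report for a mesh
#'
#' Aggregates the element metrics, per-tissue volume-conservation ratios and
#' node/element counts.
#'
#' @param mesh a labeled \linkS4class{TetMesh}.
#' @param segmentation optional \linkS4class{TissueStack} for Vrel.
#' @param histogramBins bins for the element-volume histogram.
#' @return A \linkS4class{QualityReport}.
#' @export
qcReport <- function(mesh, segmentation = NULL, histogramBins = 20L) {
  m <- meshQuality(mesh)
  vr <- numeric()
  if (!is.null(segmentation)) {
    tiss <- intersect(c(names(segmentation@layers),
                        if (length(segmentation@airMasks)) "air"),
                      unique(mesh@labels))
    vr <- vapply(tiss, function(tt) vRel(mesh, tt, segmentation), 0)
  }
  hist_breaks <- seq(0, max(m$volume), length.out = histogramBins + 1)
  hist_counts <- tabulate(pmin(findInterval(m$volume, hist_breaks,
                                            rightmost.closed = TRUE),
                               histogramBins), nbins = histogramBins)
  smry <- list(
    nNodes = nrow(mesh@nodes),
    nElements = nrow(mesh@elements),
    meanJoeLiu = mean(m$joeLiu),
    minJoeLiu = min(m$joeLiu),
    maxRadiusEdge = max(m$radiusEdge),
    maxVolume = max(m$volume),
    totalVolume = sum(m$volume),
    labelCounts = as.list(table(mesh@labels)),
    volumeHistogram = list(breaks = hist_breaks, counts = hist_counts))
  new("QualityReport", joeLiu = m$joeLiu, radiusEdge = m$radiusEdge,
      volume = m$volume, vRel = vr, summary = smry)
}

#' Serialize a QualityReport
#'
#' @param report a \linkS4class{QualityReport}.
#' @param path output file; extension picks JSON (\code{.json}) or
#'   markdown (anything else).
#' @return the path, invisibly.
#' @export
writeQcReport <- function(report, path) {
  if (grepl("\\.json$", path)) {
    payload <- c(report@summary, list(vRel = as.list(report@vRel)))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    s <- report@summary
    lines <- c("# Mesh quality report", "",
               sprintf("- nodes: %d", s$nNodes),
               sprintf("- elements: %d", s$nElements),
               sprintf("- mean Joe-Liu: %.4f", s$meanJoeLiu),
               sprintf("- min Joe-Liu: %.4f", s$minJoeLiu),
               sprintf("- max radius-edge: %.4f", s$maxRadiusEdge),
               sprintf("- max element volume: %.4g mm^3", s$maxVolume),
               sprintf("- total volume: %.6g mm^3", s$totalVolume), "")
    if (length(report@vRel))
      lines <- c(lines, "## Volume conservation (Vrel)", "",
                 sprintf("- %s: %.4f", names(report@vRel), report@vRel))
    writeLines(lines, path)
  }
  invisible(path)
}
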