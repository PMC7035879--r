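# Shared geometry helpers used across modules.

# signed volumes of tets given 1-based element matrix
.tetSignedVolumes <- function(nodes, elements) {
  a <- nodes[elements[, 1], , drop = FALSE]
  b <- nodes[elements[, 2], , drop = FALSE]
  c_ <- nodes[elements[, 3], , drop = FALSE]
  d <- nodes[elements[, 4], , drop = FALSE]
  u <- b - a; v <- c_ - a; w <- d - a
  (u[, 1] * (v[, 2] * w[, 3] - v[, 3] * w[, 2]) -
   u[, 2] * (v[, 1] * w[, 3] - v[, 3] * w[, 1]) +
   u[, 3] * (v[, 1] * w[, 2] - v[, 2] * w[, 1])) / 6
}

#' Enclosed volume of a closed oriented surface
#'
#' Signed volume by the divergence theorem; positive for outward-oriented
#' closed surfaces.
#'
#' @param surface a \linkS4class{TriSurface}.
#' @return volume in mm^3.
#' @export
enclosedVolume <- function(surface) {
  V <- surface@vertices
  F <- surface@faces
  if (nrow(F) == 0) return(0)
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# integer edge keys (vertex count < 2^26)
.edgeKeys <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  pmin(e[, 1], e[, 2]) * 2^26 + pmax(e[, 1], e[, 2])
}

#' Closedness check for a triangle surface
#'
#' A closed 2-manifold uses every edge in exactly two faces.
#'
#' @param surface a \linkS4class{TriSurface}.
#' @return logical.
#' @export
isClosedSurface <- function(surface) {
  if (nrow(surface@faces) == 0) return(FALSE)
  tb <- table(.edgeKeys(surface@faces))
  all(tb == 2L)
}

#' Number of unique edges of a surface
#' @param surface a \linkS4class{TriSurface}.
#' @return integer edge count.
#' @export
edgeCount <- function(surface) {
  length(unique(.edgeKeys(surface@faces)))
}

#' Euler characteristic V - E + F
#' @param surface a \linkS4class{TriSurface}.
#' @return integer; 2 for a genus-0 closed surface.
#' @export
eulerCharacteristic <- function(surface) {
  nrow(surface@vertices) - edgeCount(surface) + nrow(surface@faces)
}

#' Connected components of a surface
#'
#' @param surface a \linkS4class{TriSurface}.
#' @return integer vector of per-face component ids (1-based).
#' @export
surfaceComponents <- function(surface) {
  cpp_face_components(surface@faces - 1L, nrow(surface@vertices))
}

#' Self-intersection test
#'
#' Exact triangle-triangle intersection tests over candidate pairs from a
#' spatial hash, ignoring pairs that share a vertex.
#'
#' @param surface a \linkS4class{TriSurface}.
#' @param tol contact tolerance in mm.
#' @return number of intersecting triangle pairs found (0 = clean).
#' @export
countSelfIntersections <- function(surface, tol = 1e-9) {
  r <- cpp_tri_intersections(surface@vertices, surface@faces - 1L,
                             surface@vertices, surface@faces - 1L,
                             TRUE, tol)
  r$count
}

#' Surface-pair intersection test
#'
#' @param a,b \linkS4class{TriSurface} objects.
#' @param tol contact tolerance in mm.
#' @return TRUE if any triangle of \code{a} intersects a triangle of \code{b}.
#' @export
surfacesIntersect <- function(a, b, tol = 1e-9) {
  r <- cpp_tri_intersections(a@vertices, a@faces - 1L, b@vertices,
                             b@faces - 1L, FALSE, tol)
  r$count > 0
}

#' Circumradii of all surface triangles
#' @param surface a \linkS4class{TriSurface}.
#' @return numeric vector (mm).
#' @export
triangleCircumradii <- function(surface) {
  V <- surface@vertices
  F <- surface@faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  la <- sqrt(rowSums((b - c_)^2))
  lb <- sqrt(rowSums((a - c_)^2))
  lc <- sqrt(rowSums((a - b)^2))
  u <- b - a; v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  K <- sqrt(rowSums(cr^2)) / 2
  out <- la * lb * lc / (4 * K)
  out[K <= 0] <- Inf
  out
}

# congruence check used by voxelwise operators
.checkCongruent <- function(a, b) {
  if (!identical(dim(a@values), dim(b@values)))
    stop("volume grids have different dimensions")
  if (max(abs(a@spacing - b@spacing)) > 1e-9 ||
      max(abs(a@origin - b@origin)) > 1e-9)
    stop("volume grids are not aligned")
  invisible(TRUE)
}

#' Voxel volume of a grid
#' @param vol a \linkS4class{VolumeGrid}.
#' @return volume of one voxel in mm^3.
#' @export
voxelVolume <- function(vol) prod(vol@spacing)

#' Voxel-count volume of a thresholded map
#'
#' Number of voxels at or above \code{iso} times the voxel volume; the
#' segmentation-side volume entering the volume-conservation ratio.
#'
#' @param vol a \linkS4class{VolumeGrid}.
#' @param iso threshold (default 0.5).
#' @return volume in mm^3.
#' @export
thresholdVolume <- function(vol, iso = 0.5) {
  sum(vol@values >= iso) * voxelVolume(vol)
}
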