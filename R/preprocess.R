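# Gap insertion between adjacent tissue layers.  Adjacent tissues that share
# a boundary would yield intersecting iso-surfaces; a morphological
# thickening (T+) of the outer tissue or thinning (T-) of the inner tissue
# inserts a controlled one-or-more-voxel gap, only where the boundaries
# merge.  The altered voxels are recorded so the tetrahedral mesh can be
# relabeled afterwards to recover the original shared boundary.

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Cubic max filter (volumetric dilation)
#'
#' Replaces each voxel with the maximum over the cubic Chebyshev
#' neighborhood of half-edge \code{epsilon} voxels; the window shrinks at
#' the grid borders.
#'
#' @param vol a \linkS4class{VolumeGrid}.
#' @param epsilon neighborhood half-edge in voxels (integer >= 1).
#' @return filtered \linkS4class{VolumeGrid}.
#' @export
maxFilter <- function(vol, epsilon = 1L) {
  epsilon <- as.integer(epsilon)
  if (epsilon < 1L) stop("epsilon must be a positive integer")
  out <- vol
  out@values <- cpp_cube_filter(vol@values, dim(vol@values), epsilon, TRUE)
  out
}

#' Cubic min filter (volumetric erosion)
#'
#' Dual of \code{\link{maxFilter}}: minimum over the same neighborhood with
#' the same border rule.
#'
#' @inheritParams maxFilter
#' @return filtered \linkS4class{VolumeGrid}.
#' @export
minFilter <- function(vol, epsilon = 1L) {
  epsilon <- as.integer(epsilon)
  if (epsilon < 1L) stop("epsilon must be a positive integer")
  out <- vol
  out@values <- cpp_cube_filter(vol@values, dim(vol@values), epsilon, FALSE)
  out
}

#' Thickening operator T+
#'
#' Expands the outer tissue so that it strictly encloses the dilated inner
#' tissue: voxelwise \code{max(P_in + P_out, maxFilter(P_in, epsilon))},
#' clamped to [0,1].  Only voxels where the dilated inner map exceeds the
#' plain sum are changed, i.e. where the two boundaries merge.
#'
#' @param pout outer-tissue probability \linkS4class{VolumeGrid}.
#' @param pin inner-tissue probability \linkS4class{VolumeGrid}.
#' @param epsilon gap width in voxels.
#' @return thickened outer map (\linkS4class{VolumeGrid}).
#' @export
thicken <- function(pout, pin, epsilon = 1L) {
  .checkCongruent(pout, pin)
  d <- cpp_cube_filter(pin@values, dim(pin@values), as.integer(epsilon), TRUE)
  out <- pout
  out@values <- .clamp01(pmax(pin@values + pout@values, d))
  out
}

#' Thinning operator T-
#'
#' Shrinks the inner tissue away from the union boundary: voxelwise
#' \code{min(P_in, minFilter(clamp(P_in + P_out), epsilon))}.  Voxels deep
#' inside the union are unchanged.
#'
#' @param pin inner-tissue probability \linkS4class{VolumeGrid}.
#' @param pout outer-tissue probability \linkS4class{VolumeGrid}.
#' @param epsilon gap width in voxels.
#' @return thinned inner map (\linkS4class{VolumeGrid}).
#' @export
thin <- function(pin, pout, epsilon = 1L) {
  .checkCongruent(pin, pout)
  s <- .clamp01(pin@values + pout@values)
  e <- cpp_cube_filter(s, dim(s), as.integer(epsilon), FALSE)
  out <- pin
  out@values <- pmin(pin@values, e)
  out
}

# default strategies mirroring the two sample gap-insertion pathways:
# thin the white matter against gray matter, thicken elsewhere
.defaultStrategy <- function(innerName) {
  if (tolower(innerName) %in% c("wm", "white", "whitematter")) "thin_inner"
  else "thicken_outer"
}

#' Build the layered extraction model
#'
#' Processes adjacent tissue pairs from the innermost outward.  For each
#' pair the configured operator (\code{thicken_outer} or \code{thin_inner})
#' inserts an \code{epsilon}-voxel gap wherever the boundaries merge; the
#' extraction volume of layer i is the cumulative (clamped-sum) map of
#' layers innermost..i with interior holes filled, so successive 0.5-level
#' sets are strictly nested.  Air-cavity masks are subtracted from the
#' extraction volumes of their host layer outward and carried along for
#' separate surface extraction.  All altered voxels are recorded per pair
#' for the boundary-recovery relabeling.
#'
#' @param stack a \linkS4class{TissueStack}, innermost layer first.
#' @param gaps a \linkS4class{GapParams}.
#' @return A \linkS4class{LayeredModel}.
#' @export
buildLayeredModel <- function(stack, gaps = GapParams()) {
  layers <- stack@layers
  nm <- names(layers)
  eps <- gaps@epsilon
  keep <- vapply(layers, function(l) max(l@values) >= 0.5, TRUE)
  if (!all(keep)) {
    warning("layer(s) nowhere above threshold, skipped: ",
            paste(nm[!keep], collapse = ", "))
    layers <- layers[keep]
    nm <- nm[keep]
  }
  n <- length(layers)
  if (n == 0) stop("no usable layers")
  dims <- dim(layers[[1]]@values)
  proto <- layers[[1]]
  cums <- vector("list", n)
  altered <- list()
  alteredMask <- array(FALSE, dims)
  cums[[1]] <- .clamp01(layers[[1]]@values)
  for (i in seq_len(n)[-1]) {
    innerC <- cums[[i - 1]]
    P <- layers[[i]]@values
    raw <- .clamp01(innerC + P)
    strat <- gaps@strategies[nm[i - 1]]
    if (is.na(strat)) strat <- .defaultStrategy(nm[i - 1])
    if (strat == "thicken_outer") {
      dil <- cpp_cube_filter(innerC, dims, eps, TRUE)
      newC <- pmax(raw, dil)
      ch <- which(abs(newC - raw) > 1e-12)
      cums[[i]] <- newC
    } else {
      s <- .clamp01(innerC + P)
      ero <- cpp_cube_filter(s, dims, eps, FALSE)
      thinned <- pmin(innerC, ero)
      ch <- which(abs(thinned - innerC) > 1e-12)
      cums[[i - 1]] <- thinned
      cums[[i]] <- raw
    }
    key <- paste(nm[i - 1], nm[i], sep = "|")
    altered[[key]] <- ch
    alteredMask[ch] <- TRUE
  }
  # fill interior holes (background gaps between separated layers) so each
  # extraction volume is a filled, simply-enclosed region
  for (i in seq_len(n))
    cums[[i]] <- cpp_fill_holes(cums[[i]], dims, 0.5)
  # subtract air cavities from the host layer's extraction volume outward
  airOut <- list()
  for (an in names(stack@airMasks)) {
    am <- stack@airMasks[[an]]@values
    h <- match(an, nm)
    if (is.na(h)) next
    for (i in h:n) cums[[i]] <- pmin(cums[[i]], 1 - am)
    airOut[[an]] <- stack@airMasks[[an]]
  }
  # nesting check at threshold 0.5
  for (i in seq_len(n - 1)) {
    bad <- cums[[i]] >= 0.5 & cums[[i + 1]] < 0.5
    if (any(bad))
      stop(sprintf("nesting violated between %s and %s (%d voxels); ",
                   nm[i], nm[i + 1], sum(bad)),
           "inputs cannot be repaired with the given epsilon")
  }
  vols <- lapply(seq_len(n), function(i) {
    g <- proto
    g@values <- cums[[i]]
    g@kind <- "probability"
    g
  })
  names(vols) <- nm
  new("LayeredModel", extractionVolumes = vols, airMasks = airOut,
      altered = altered, alteredMask = alteredMask)
}
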