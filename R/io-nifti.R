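# NIfTI input/output for segmentations (via RNifti).

#' Read a tissue segmentation from NIfTI
#'
#' Reads a 3-D multi-label / binary volume or a probability map.  A 4-D file
#' is accepted for \code{kind = "probability"} only, one tissue per 4th-dim
#' index, and yields a list of grids.  Voxel spacing and the grid origin are
#' taken from the header transform; oblique acquisitions (rotational part in
#' the affine) are rejected because the gap-insertion operators are defined
#' on the grid axes.
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @param kind \code{"probability"}, \code{"label"} or \code{"binary"}.
#' @return A \linkS4class{VolumeGrid}, or a list of them for 4-D input.
#' @export
readSegmentation <- function(path, kind = c("probability", "label", "binary")) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  offdiag <- rot
  diag(offdiag) <- 0
  if (max(abs(offdiag)) > 1e-4 * max(abs(diag(rot))))
    stop("oblique NIfTI affine (rotation) is not supported; ",
         "resample the volume to the grid axes first")
  sp <- abs(diag(rot))
  if (any(sp <= 0)) sp <- RNifti::pixdim(img)[1:3]
  orig <- xf[1:3, 4]
  d <- dim(img)
  make_one <- function(values) {
    if (kind == "probability") {
      rng <- range(values)
      if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6)
        stop(sprintf("values in [%.4g, %.4g]: not a probability map",
                     rng[1], rng[2]))
      values[values > 1] <- 1
      values[values < 0] <- 0
    } else if (kind == "label") {
      if (any(values != round(values)) || any(values < 0))
        stop("not an integer label volume")
    } else {
      if (!all(values %in% c(0, 1))) stop("not a binary mask")
    }
    VolumeGrid(array(as.numeric(values), dim = dim(values)[1:3]),
               spacing = sp, origin = orig, kind = kind)
  }
  if (length(d) == 3L) {
    make_one(img[, , , drop = TRUE])
  } else if (length(d) == 4L) {
    if (kind != "probability")
      stop("4-D input is only accepted for probability maps")
    lapply(seq_len(d[4]), function(i) make_one(img[, , , i]))
  } else {
    stop("expected a 3-D (or 4-D probability) NIfTI volume")
  }
}

#' Write a VolumeGrid to NIfTI
#'
#' @param vol a \linkS4class{VolumeGrid}.
#' @param path output file (.nii or .nii.gz).
#' @return the path, invisibly.
#' @export
writeVolume <- function(vol, path) {
  img <- RNifti::asNifti(vol@values)
  RNifti::pixdim(img) <- vol@spacing
  mat <- diag(4)
  diag(mat)[1:3] <- vol@spacing
  mat[1:3, 4] <- vol@origin
  try(RNifti::`qform<-`(img, structure(mat, code = 2L)), silent = TRUE)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Convert a multi-label volume into per-tissue probability grids
#'
#' @param vol a label-kind \linkS4class{VolumeGrid}.
#' @param labelMap named integer vector mapping tissue name to label value,
#'   ordered innermost tissue first.
#' @return A \linkS4class{TissueStack} of binary-probability layers.
#' @export
splitLabels <- function(vol, labelMap) {
  if (vol@kind != "label") stop("expected a label volume")
  layers <- lapply(labelMap, function(lv) {
    VolumeGrid(array(as.numeric(vol@values == lv), dim = dim(vol@values)),
               spacing = vol@spacing, origin = vol@origin,
               kind = "probability")
  })
  names(layers) <- names(labelMap)
  TissueStack(layers)
}
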