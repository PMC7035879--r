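# Accessor generics and show methods.

#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @export
setGeneric("surfaceTag", function(x) standardGeneric("surfaceTag"))
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))
#' @export
setGeneric("elements", function(x) standardGeneric("elements"))
#' @export
setGeneric("elementLabels", function(x) standardGeneric("elementLabels"))
#' @export
setGeneric("layers", function(x) standardGeneric("layers"))
#' @export
setGeneric("airMasks", function(x) standardGeneric("airMasks"))
#' @export
setGeneric("analyticVolumes", function(x) standardGeneric("analyticVolumes"))
#' @export
setGeneric("extractionVolumes", function(x) standardGeneric("extractionVolumes"))
#' @export
setGeneric("alteredVoxels", function(x) standardGeneric("alteredVoxels"))

#' @describeIn VolumeGrid-class voxel spacing in mm
#' @param x object
#' @export
setMethod("spacing", "VolumeGrid", function(x) x@spacing)
#' @describeIn VolumeGrid-class mm coordinates of voxel (0,0,0)
#' @export
setMethod("origin", "VolumeGrid", function(x) x@origin)
#' @describeIn VolumeGrid-class the raw array
#' @export
setMethod("gridValues", "VolumeGrid", function(x) x@values)
#' @export
setMethod("dim", "VolumeGrid", function(x) dim(x@values))

#' @describeIn TriSurface-class vertex matrix (mm)
#' @param x object
#' @export
setMethod("vertices", "TriSurface", function(x) x@vertices)
#' @describeIn TriSurface-class 1-based face index matrix
#' @export
setMethod("faces", "TriSurface", function(x) x@faces)
#' @describeIn TriSurface-class tissue tag
#' @export
setMethod("surfaceTag", "TriSurface", function(x) x@tag)

#' @describeIn TetMesh-class node matrix (mm)
#' @param x object
#' @export
setMethod("nodes", "TetMesh", function(x) x@nodes)
#' @describeIn TetMesh-class 1-based element matrix
#' @export
setMethod("elements", "TetMesh", function(x) x@elements)
#' @describeIn TetMesh-class per-element tissue labels
#' @export
setMethod("elementLabels", "TetMesh", function(x) x@labels)

#' @describeIn TissueStack-class named list of tissue VolumeGrids
#' @param x object
#' @export
setMethod("layers", "TissueStack", function(x) x@layers)
#' @describeIn TissueStack-class named list of air masks
#' @export
setMethod("airMasks", "TissueStack", function(x) x@airMasks)
#' @describeIn TissueStack-class analytic tissue volumes (phantoms)
#' @export
setMethod("analyticVolumes", "TissueStack", function(x) x@analyticVolumes)

#' @describeIn LayeredModel-class cumulative extraction volumes
#' @param x object
#' @export
setMethod("extractionVolumes", "LayeredModel", function(x) x@extractionVolumes)
#' @describeIn LayeredModel-class linear indices altered by gap insertion
#' @export
setMethod("alteredVoxels", "LayeredModel", function(x) x@altered)
#' @describeIn LayeredModel-class air masks carried through preprocessing
#' @export
setMethod("airMasks", "LayeredModel", function(x) x@airMasks)

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("VolumeGrid [%s]: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              object@kind, d[1], d[2], d[3], object@spacing[1],
              object@spacing[2], object@spacing[3]))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(object@values),
              max(object@values)))
})

setMethod("show", "TissueStack", function(object) {
  cat(sprintf("TissueStack: %d layers (innermost first): %s\n",
              length(object@layers), paste(names(object@layers),
                                           collapse = " < ")))
  if (length(object@airMasks))
    cat(sprintf("  air cavities in: %s\n",
                paste(names(object@airMasks), collapse = ", ")))
})

setMethod("show", "TriSurface", function(object) {
  cat(sprintf("TriSurface '%s': %d vertices, %d faces\n", object@tag,
              nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "TetMesh", function(object) {
  cat(sprintf("TetMesh: %d nodes, %d elements\n", nrow(object@nodes),
              nrow(object@elements)))
  if (length(object@labels)) {
    tb <- table(object@labels)
    cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        "\n")
  }
})

setMethod("show", "LayeredModel", function(object) {
  cat(sprintf("LayeredModel: %d extraction volumes (%s)\n",
              length(object@extractionVolumes),
              paste(names(object@extractionVolumes), collapse = " < ")))
  n <- sum(lengths(object@altered))
  cat(sprintf("  %d voxels altered by gap insertion\n", n))
})

setMethod("show", "QualityReport", function(object) {
  cat("QualityReport\n")
  cat(sprintf("  elements: %d   mean Joe-Liu %.4f   min Joe-Liu %.4f\n",
              length(object@joeLiu), mean(object@joeLiu), min(object@joeLiu)))
  cat(sprintf("  max radius-edge %.4f   max volume %.4g mm^3\n",
              max(object@radiusEdge), max(object@volume)))
  if (length(object@vRel)) {
    cat("  Vrel:", paste(sprintf("%s=%.4f", names(object@vRel), object@vRel),
                         collapse = ", "), "\n")
  }
})
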