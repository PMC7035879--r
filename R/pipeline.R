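# End-to-end orchestration: segmentation stack -> layered model -> surfaces
# -> tetrahedral mesh -> QC.

#' Pipeline configuration
#'
#' Defaults follow the published full-head settings: per-layer surface
#' density bounds Rmax of 1.7 mm for white/gray matter, 2 mm for CSF, 2.5 mm
#' for skull and 3.5 mm for scalp; extraction threshold 0.5; element volume
#' bound 30 mm^3; radius-edge bound 1.414.
#'
#' @param tissueOrder character vector, innermost tissue first; NULL = take
#'   from the input stack.
#' @param rmax named per-layer triangle circumradius bounds (mm).
#' @param iso extraction threshold.
#' @param epsilon gap width in voxels.
#' @param strategies named per-pair gap strategies (see
#'   \linkS4class{GapParams}).
#' @param smoothMethod,smoothIterations surface smoothing settings.
#' @param q radius-edge bound.
#' @param vmax global element-volume bound (mm^3).
#' @param vmaxPerLabel named per-tissue volume bounds.
#' @param cellSize background lattice pitch (mm), NA = automatic.
#' @param relabel recover shared boundaries after meshing.
#' @param keepLargest drop noise-island surface components.
#' @param seed RNG seed recorded in the manifest.
#' @return a \code{pipelineConfig} list.
#' @export
pipelineConfig <- function(tissueOrder = NULL,
                           rmax = c(wm = 1.7, gm = 1.7, csf = 2,
                                    skull = 2.5, scalp = 3.5),
                           iso = 0.5, epsilon = 1L,
                           strategies = character(),
                           smoothMethod = "lowpass",
                           smoothIterations = 10L,
                           q = 1.414, vmax = 30,
                           vmaxPerLabel = numeric(),
                           cellSize = NA_real_,
                           relabel = TRUE, keepLargest = TRUE,
                           seed = 42L) {
  structure(list(tissueOrder = tissueOrder, rmax = rmax, iso = iso,
                 epsilon = as.integer(epsilon), strategies = strategies,
                 smoothMethod = smoothMethod,
                 smoothIterations = as.integer(smoothIterations),
                 q = q, vmax = vmax, vmaxPerLabel = vmaxPerLabel,
                 cellSize = cellSize, relabel = relabel,
                 keepLargest = keepLargest, seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from JSON
#'
#' Keys mirror the arguments of \code{\link{pipelineConfig}}; absent keys
#' keep their defaults.
#'
#' @param path JSON file.
#' @return a \code{pipelineConfig} list.
#' @export
readPipelineConfig <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- pipelineConfig()
  for (k in intersect(names(j), names(base))) base[[k]] <- j[[k]]
  if (!is.null(j$rmax)) base$rmax <- unlist(j$rmax)
  if (!is.null(j$strategies)) base$strategies <- unlist(j$strategies)
  if (!is.null(j$vmaxPerLabel)) base$vmaxPerLabel <- unlist(j$vmaxPerLabel)
  base
}

#' Run the surface-based meshing pipeline
#'
#' Stages: gap insertion (\code{\link{buildLayeredModel}}), per-layer
#' iso-surface extraction and smoothing, tetrahedralization under the
#' quality/volume bounds, region labeling, optional boundary-recovery
#' relabeling, and a QC report.  Identical inputs, configuration and seed
#' reproduce identical outputs.
#'
#' @param stack a \linkS4class{TissueStack} (or named character vector of
#'   per-tissue NIfTI files, innermost tissue first).
#' @param config a \code{\link{pipelineConfig}} list.
#' @param stopAfter \code{"mesh"} (default) runs everything;
#'   \code{"surfaces"} stops after surface extraction and smoothing.
#' @param verbose print stage progress and timings.
#' @return list with elements \code{mesh} (\linkS4class{TetMesh}),
#'   \code{surfaces} (named list of \linkS4class{TriSurface}),
#'   \code{airSurfaces}, \code{model} (\linkS4class{LayeredModel}),
#'   \code{report} (\linkS4class{QualityReport}; NULL if stopped early) and
#'   \code{manifest} (effective parameters and stage timings).
#' @export
runPipeline <- function(stack, config = pipelineConfig(),
                        stopAfter = c("mesh", "surfaces"), verbose = TRUE) {
  stopAfter <- match.arg(stopAfter)
  t_all <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  timings <- c()
  tic <- function() Sys.time()
  toc <- function(t0, stage) {
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    timings[stage] <<- round(dt, 2)
    dt
  }
  set.seed(config$seed)
  if (is.character(stack)) {
    if (is.null(names(stack))) stop("per-tissue files must be named")
    for (f in stack)
      if (!file.exists(f)) stop("missing tissue file: ", f)
    layers <- lapply(stack, readSegmentation, kind = "probability")
    stack <- TissueStack(layers)
  }
  if (!is.null(config$tissueOrder))
    stack@layers <- stack@layers[config$tissueOrder]

  t0 <- tic()
  gaps <- GapParams(config$epsilon, config$strategies)
  model <- buildLayeredModel(stack, gaps)
  say("preprocess: %d extraction volumes, %d altered voxels [%.1fs]",
      length(model@extractionVolumes), sum(lengths(model@altered)),
      toc(t0, "preprocess"))

  t0 <- tic()
  crit <- SurfaceCriteria(rmax = config$rmax, iso = config$iso,
                          smoothMethod = config$smoothMethod,
                          smoothIterations = config$smoothIterations,
                          keepLargest = config$keepLargest)
  # extract at grid density, smooth, then resample down to the per-layer
  # density bound: the mesher only needs triangles at the Rmax scale
  prepSurface <- function(vol, nm, rmaxHere) {
    s <- extractIsosurface(vol, crit, layer = nm)
    if (config$smoothMethod != "none" && config$smoothIterations > 0)
      s <- smoothSurface(s, config$smoothMethod, config$smoothIterations)
    ek <- .edgeKeys(s@faces)
    meanLen <- {
      e <- unique(ek)
      a <- e %/% 2^26; b <- e %% 2^26
      mean(sqrt(rowSums((s@vertices[a, , drop = FALSE] -
                         s@vertices[b, , drop = FALSE])^2)))
    }
    targetLen <- 1.2 * rmaxHere
    keep <- min(1, (meanLen / targetLen)^2)
    if (keep < 0.9) {
      # quadric decimation can fold the surface over itself in ways local
      # guards cannot see; verify the result and back off if it does
      for (k in unique(c(keep, sqrt(keep), keep^0.25, 1))) {
        cand <- if (k >= 1) s else decimateSurface(s, k)
        cand <- .enforceCircumradius(cand, rmaxHere, 0.15 * rmaxHere, nm)
        if (countSelfIntersections(cand) == 0) {
          s <- cand
          break
        }
      }
    }
    s
  }
  rmaxOf <- function(nm) {
    r <- config$rmax
    if (!is.null(names(r)) && nm %in% names(r)) r[[nm]] else r[[1]]
  }
  surfaces <- list()
  for (nm in names(model@extractionVolumes)) {
    s <- prepSurface(model@extractionVolumes[[nm]], nm, rmaxOf(nm))
    surfaces[[nm]] <- s
    say("surface %s: %d vertices, %d faces, volume %.0f mm^3", nm,
        nrow(s@vertices), nrow(s@faces), enclosedVolume(s))
  }
  airSurfaces <- list()
  for (an in names(model@airMasks)) {
    airSurfaces[[an]] <- prepSurface(model@airMasks[[an]], "air",
                                     min(unlist(config$rmax)))
  }
  toc(t0, "surfaces")
  if (stopAfter == "surfaces") {
    return(list(mesh = NULL, surfaces = surfaces, airSurfaces = airSurfaces,
                model = model, report = NULL,
                manifest = .manifest(config, timings, t_all)))
  }

  t0 <- tic()
  crit2 <- MeshingCriteria(q = config$q, vmax = config$vmax,
                           vmaxPerLabel = config$vmaxPerLabel,
                           cellSize = config$cellSize)
  mesh <- tetrahedralize(surfaces, crit2, airSurfaces = unname(airSurfaces),
                         verbose = verbose)
  say("tetrahedralize: %d nodes, %d elements [%.1fs]", nrow(mesh@nodes),
      nrow(mesh@elements), toc(t0, "tetrahedralize"))

  t0 <- tic()
  mesh <- assignRegionLabels(mesh, surfaces, unname(airSurfaces))
  toc(t0, "label")
  if (isTRUE(config$relabel)) {
    t0 <- tic()
    mesh <- relabelSharedBoundaries(mesh, stack, model)
    say("relabel: done [%.1fs]", toc(t0, "relabel"))
  }

  t0 <- tic()
  report <- qcReport(mesh, stack)
  toc(t0, "qc")
  say("total %.1fs", as.numeric(difftime(Sys.time(), t_all, units = "secs")))
  list(mesh = mesh, surfaces = surfaces, airSurfaces = airSurfaces,
       model = model, report = report,
       manifest = .manifest(config, timings, t_all))
}

.manifest <- function(config, timings, t_all) {
  list(parameters = unclass(config),
       timings_sec = as.list(timings),
       total_sec = round(as.numeric(difftime(Sys.time(), t_all,
                                             units = "secs")), 2),
       generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
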