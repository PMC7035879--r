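# Shared fixtures, built once per test run and memoized.  Heavy pipeline
# runs (96^3 phantoms) are reused across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, builder(), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# small sphere probability map (Gaussian-CDF profile, exact 0.5-level set)
sphereGrid <- function(n = 48L, r = 15, spacing = 1, sigma = 0.5,
                      center = NULL) {
  if (is.null(center)) center <- rep((n - 1) * spacing / 2, 3)
  x <- (0:(n - 1)) * spacing
  g <- expand.grid(x = x, y = x, z = x)
  rho <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2)
  p <- if (sigma > 0) pnorm((r - rho) / sigma) else as.numeric(rho <= r)
  VolumeGrid(array(p, dim = c(n, n, n)), spacing = rep(spacing, 3),
             kind = "probability")
}

# a clean closed sphere surface at a given density
sphereSurface <- function(n = 48L, r = 15, spacing = 1, smooth = 10L,
                          tag = "sphere") {
  s <- extractIsosurface(sphereGrid(n, r, spacing),
                         SurfaceCriteria(rmax = Inf), layer = tag)
  if (smooth > 0) s <- smoothSurface(s, "lowpass", smooth)
  s
}

# random probability volume for operator oracles
randomVolume <- function(n, seed) {
  set.seed(seed)
  VolumeGrid(array(runif(n^3), dim = c(n, n, n)), kind = "probability")
}

# shift-based brute-force cubic filter oracle: extremum over all (2e+1)^3
# offsets of the array, clipped at the borders (shrinking window)
bruteCubeFilter <- function(a, eps, op = max) {
  d <- dim(a)
  out <- array(if (identical(op, max)) -Inf else Inf, d)
  for (dx in -eps:eps) for (dy in -eps:eps) for (dz in -eps:eps) {
    # shrinking window at the borders: only in-range shifts contribute
    xr <- (1:d[1]) + dx; yr <- (1:d[2]) + dy; zr <- (1:d[3]) + dz
    vx <- xr >= 1 & xr <= d[1]; vy <- yr >= 1 & yr <= d[2]
    vz <- zr >= 1 & zr <= d[3]
    sub <- a[xr[vx], yr[vy], zr[vz], drop = FALSE]
    cur <- out[vx, vy, vz]
    out[vx, vy, vz] <- if (identical(op, max)) pmax(cur, sub) else pmin(cur, sub)
  }
  out
}

# full pipeline on the five-layer phantom (96^3, 1 mm), shared by the
# volume-conservation and quality-constraint checks
fiveLayerRun <- function() {
  memo("fiveLayer", function() {
    st <- makeLayeredPhantom(phantomPreset("five-layer"))
    res <- runPipeline(st, pipelineConfig(), verbose = FALSE)
    list(stack = st, res = res)
  })
}

# merged CSF/GM phantom meshed without relabeling (the relabeled variant is
# derived from the same mesh)
mergedRun <- function() {
  memo("merged", function() {
    st <- makeLayeredPhantom(phantomPreset("merged-csf-gm"))
    cfg <- pipelineConfig(strategies = c(gm = "thin_inner"), relabel = FALSE)
    res <- runPipeline(st, cfg, verbose = FALSE)
    list(stack = st, res = res,
         relabeled = relabelSharedBoundaries(res$mesh, st, res$model))
  })
}

# dense sphere for the decimation-error characterization
denseSphere <- function() {
  memo("denseSphere", function() sphereSurface(n = 64L, r = 20, spacing = 1))
}

# hand-built unit cube surface (8 vertices, 12 outward-oriented triangles)
unitCubeSurface <- function(lo = c(0, 0, 0), hi = c(1, 1, 1), tag = "cube") {
  v <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  # vertex order: x fastest; faces as quads split into triangles
  quads <- rbind(c(1, 3, 4, 2),   # z = lo
                 c(5, 6, 8, 7),   # z = hi
                 c(1, 2, 6, 5),   # y = lo
                 c(3, 7, 8, 4),   # y = hi
                 c(1, 5, 7, 3),   # x = lo
                 c(2, 4, 8, 6))   # x = hi
  f <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  s <- TriSurface(v, f, tag = tag)
  if (enclosedVolume(s) < 0) s@faces <- s@faces[, c(1, 3, 2)]
  s
}

expect_closed <- function(surface) {
  expect_true(isClosedSurface(surface))
  expect_gt(enclosedVolume(surface), 0)
}
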