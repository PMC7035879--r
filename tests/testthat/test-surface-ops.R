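# Surface extraction, smoothing, decimation, surface error, Booleans,
# rasterization.

test_that("iso-surface of a sphere is closed, genus 0 and volume-faithful", {
  vol <- sphereGrid(n = 48L, r = 15)
  s <- extractIsosurface(vol, SurfaceCriteria(rmax = 2), layer = "sph")
  expect_closed(s)
  expect_equal(eulerCharacteristic(s), 2L)
  expect_equal(countSelfIntersections(s), 0)
  expect_lt(abs(enclosedVolume(s) / (4 / 3 * pi * 15^3) - 1), 0.03)
  expect_lte(max(triangleCircumradii(s)), 2)
  # tighter rmax forces subdivision and keeps the bound
  s2 <- extractIsosurface(vol, SurfaceCriteria(rmax = 0.6), layer = "sph")
  expect_lte(max(triangleCircumradii(s2)), 0.6)
  expect_closed(s2)
  expect_error(extractIsosurface(VolumeGrid(array(0, c(8, 8, 8))),
                                 SurfaceCriteria()), "empty level set")
})

test_that("keep-largest-component removes injected noise islands", {
  st <- makeLayeredPhantom(PhantomSpec(c(outer = 16, mid = 11, inner = 7),
                                       gridSize = 44L))
  noisy <- addNoiseIslands(st, 3, size = 2L, seed = 3L)
  affected <- unique(vapply(attr(noisy, "islands"), function(i) i$tissue, ""))
  nm <- affected[1]
  sAll <- extractIsosurface(layers(noisy)[[nm]],
                            SurfaceCriteria(rmax = Inf, keepLargest = FALSE),
                            layer = nm)
  expect_gt(max(surfaceComponents(sAll)), 1)
  sOne <- extractIsosurface(layers(noisy)[[nm]],
                            SurfaceCriteria(rmax = Inf, keepLargest = TRUE),
                            layer = nm)
  expect_equal(max(surfaceComponents(sOne)), 1)
})

test_that("smoothing: identity at 0 iterations, shrink resistance, counts", {
  s <- sphereSurface(n = 40L, r = 12, smooth = 0L)
  expect_identical(smoothSurface(s, "laplacian", 0L)@vertices, s@vertices)
  # noisy sphere: radial noise of 0.5 mm
  set.seed(9)
  noisy <- s
  rad <- noisy@vertices - 19.5
  len <- sqrt(rowSums(rad^2))
  noisy@vertices <- 19.5 + rad * (1 + runif(nrow(rad), -0.5, 0.5) / len)
  v0 <- 4 / 3 * pi * 12^3
  lap <- smoothSurface(noisy, "laplacian", 10L)
  low <- smoothSurface(noisy, "lowpass", 10L)
  hc <- smoothSurface(noisy, "laplacian_hc", 10L)
  expect_lt(abs(enclosedVolume(low) / v0 - 1), 0.02)
  expect_gt(enclosedVolume(low), enclosedVolume(lap))  # Taubin resists shrink
  for (sm in list(lap, low, hc)) {
    expect_equal(nrow(sm@vertices), nrow(noisy@vertices))
    expect_identical(sm@faces, noisy@faces)
  }
  expect_error(smoothSurface(s, "frobnicate", 3L))
})

test_that("laplacian keeps the interior of a planar patch in-plane", {
  g <- expand.grid(x = 0:6, y = 0:6)
  v <- cbind(g$x, g$y, 0)
  idx <- function(i, j) i + 7 * (j - 1) + 1
  f <- do.call(rbind, lapply(1:6, function(j) do.call(rbind, lapply(1:6,
    function(i) rbind(c(idx(i - 1, j), idx(i, j), idx(i - 1, j + 1)),
                      c(idx(i, j), idx(i, j + 1), idx(i - 1, j + 1)))))))
  patch <- TriSurface(v, f, tag = "patch")
  sm <- smoothSurface(patch, "laplacian", 5L, alpha = 0.5)
  expect_lt(max(abs(sm@vertices[, 3])), 1e-9)
})

test_that("decimation hits the edge budget and preserves closedness", {
  s <- denseSphere()
  expect_identical(decimateSurface(s, 1), s)
  e0 <- edgeCount(s)
  d <- decimateSurface(s, 0.2)
  expect_lt(abs(edgeCount(d) / (0.2 * e0) - 1), 0.05)
  expect_closed(d)
  expect_equal(countSelfIntersections(d), 0)
  err <- surfaceError(d, s)
  expect_lt(mean(err), 0.2)
  expect_error(decimateSurface(s, 1e-6), "degenerate")
})

test_that("decimation error grows as the budget tightens", {
  s <- denseSphere()
  e50 <- mean(surfaceError(decimateSurface(s, 0.5), s))
  e05 <- mean(surfaceError(decimateSurface(s, 0.05), s))
  expect_lte(e50, e05)
})

test_that("surface error equals the brute-force nearest-node scan", {
  s <- sphereSurface(n = 24L, r = 7, smooth = 0L)
  expect_true(all(surfaceError(s, s) == 0))
  shifted <- s
  shifted@vertices <- s@vertices + rep(c(1, 0, 0), each = nrow(s@vertices))
  expect_lte(max(surfaceError(shifted, s)), 1 + max(dist(s@vertices[1:2, ])))
  set.seed(21)
  A <- matrix(runif(300, 0, 10), ncol = 3)
  B <- matrix(runif(300, 0, 10), ncol = 3)
  brute <- apply(A, 1, function(p) sqrt(min(colSums((t(B) - p)^2))))
  got <- surfaceError(TriSurface(A, matrix(c(1L, 2L, 3L), 1)),
                      TriSurface(B, matrix(c(1L, 2L, 3L), 1)))
  expect_equal(as.numeric(got), brute, tolerance = 1e-12)
})

test_that("boolean union obeys volume bounds in all three regimes", {
  a <- sphereSurface(n = 36L, r = 10, smooth = 5L, tag = "a")
  va <- enclosedVolume(a)
  # disjoint: translate a copy far away
  b <- a; b@vertices <- b@vertices + 25
  u <- booleanUnion(a, b, resolution = 0.4)
  expect_equal(max(surfaceComponents(u)), 2)
  expect_lt(abs(enclosedVolume(u) / (2 * va) - 1), 0.005)
  # contained: small sphere in the middle
  cSmall <- sphereSurface(n = 24L, r = 5, smooth = 5L)
  cSmall@vertices <- cSmall@vertices + (17.5 - 11.5)   # align centres
  u2 <- booleanUnion(a, cSmall, resolution = 0.4)
  expect_lt(abs(enclosedVolume(u2) / va - 1), 0.005)
  # overlapping spheres, centres 15 mm apart, radii 10: closed-form union
  b3 <- a; b3@vertices <- b3@vertices + rep(c(15, 0, 0), each = nrow(a@vertices))
  u3 <- booleanUnion(a, b3, resolution = 0.4)
  d <- 15; r <- 10
  lens <- pi * (2 * r - d)^2 * (d^2 + 4 * d * r) / (12 * d)
  expect_lt(abs(enclosedVolume(u3) / (2 * va - lens) - 1), 0.01)
  expect_error(booleanUnion(a, TriSurface(matrix(0, 3, 3),
                                          matrix(c(1L, 2L, 3L), 1))),
               "closed")
})

test_that("rasterization matches volumes and the containment oracle", {
  template <- VolumeGrid(array(0, c(48, 48, 48)))
  s <- sphereSurface(n = 48L, r = 15, smooth = 5L)
  m <- rasterizeSurface(s, template)
  expect_lt(abs(sum(gridValues(m)) / enclosedVolume(s) - 1), 0.03)
  # axis-aligned voxel cube: exactly the interior voxels
  cube <- unitCubeSurface(lo = c(9.5, 9.5, 9.5), hi = c(20.5, 20.5, 20.5))
  mc <- rasterizeSurface(cube, template)
  expect_equal(sum(gridValues(mc)), 11^3)
  idx <- which(gridValues(mc) == 1, arr.ind = TRUE) - 1
  expect_true(all(idx >= 10 & idx <= 20))
  # random containment cross-check
  set.seed(5)
  pts <- matrix(runif(3000, 4, 43), ncol = 3)
  inside <- pointInSurface(pts, s)
  vox <- gridValues(m)[cbind(round(pts[, 1]), round(pts[, 2]),
                             round(pts[, 3])) + 1]
  # exclude points within a voxel of the surface
  d <- abs(sqrt(rowSums((pts - 23.5)^2)) - 15)
  keep <- d > 1
  expect_equal(as.numeric(inside[keep]), as.numeric(vox[keep]))
  expect_error(rasterizeSurface(unitCubeSurface(lo = c(-5, 0, 0),
                                                hi = c(1, 1, 1)), template),
               "beyond")
})

test_that("probability subtraction is exact and guarded", {
  p <- randomVolume(10L, 31)
  zero <- VolumeGrid(array(0, c(10, 10, 10)), kind = "binary")
  expect_equal(gridValues(subtractProbability(p, zero)), gridValues(p))
  pb <- VolumeGrid(array(as.numeric(gridValues(p) > 0.5), c(10, 10, 10)),
                   kind = "binary")
  expect_true(all(gridValues(subtractProbability(pb, pb)) == 0))
  mask <- VolumeGrid(array(as.numeric(gridValues(randomVolume(10L, 32)) > 0.5),
                           c(10, 10, 10)), kind = "binary")
  expect_equal(gridValues(subtractProbability(p, mask)),
               pmax(gridValues(p) - gridValues(mask), 0))
  expect_error(subtractProbability(p, VolumeGrid(array(0, c(8, 8, 8)))),
               "dimensions")
})
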