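# Synthetic phantom generator: analytic volume oracle, merged boundaries,
# blur behavior, noise islands.

test_that("five-layer shell volumes match the analytic oracle within 3%", {
  st <- makeLayeredPhantom(phantomPreset("five-layer"))
  av <- analyticVolumes(st)
  for (nm in names(layers(st))) {
    rel <- thresholdVolume(layers(st)[[nm]]) / av[[nm]]
    expect_gt(rel, 0.97)
    expect_lt(rel, 1.03)
  }
  # maps are mutually exclusive at threshold and cover the head
  tot <- Reduce(`+`, lapply(layers(st), gridValues))
  expect_lte(max(tot), 1 + 1e-9)
})

test_that("merged boundaries: exclusive maps, zero-voxel gap at contact", {
  st <- makeLayeredPhantom(phantomPreset("merged-csf-gm"))
  csf <- gridValues(layers(st)$csf) >= 0.5
  gm <- gridValues(layers(st)$gm) >= 0.5
  expect_equal(sum(csf & gm), 0)          # both claiming a voxel is forbidden
  # face-adjacency across the merged boundary: gm voxels with csf neighbors
  d <- dim(csf)
  adj <- (gm[, , -d[3]] & csf[, , -1]) | (gm[, , -1] & csf[, , -d[3]])
  expect_gt(sum(adj), 0)
  # the clipped-cap construction has zero CSF thickness near the contact:
  # at the +z pole column the gm and csf level sets touch
  expect_gt(sum(lengths(alteredVoxels(
    buildLayeredModel(st, GapParams(1L, c(gm = "thin_inner")))))), 0)
})

test_that("blurred and binary phantoms agree on enclosed level-set volume", {
  radii <- c(outer = 16, inner = 10)
  b0 <- makeLayeredPhantom(PhantomSpec(radii, gridSize = 44L, blurSigma = 0))
  b1 <- makeLayeredPhantom(PhantomSpec(radii, gridSize = 44L, blurSigma = 1))
  expect_true(all(gridValues(layers(b0)$outer) %in% c(0, 1)))
  v1 <- gridValues(layers(b1)$inner)
  expect_true(min(v1) >= 0 && max(v1) <= 1 && any(v1 > 0 & v1 < 1))
  # cumulative (filled) volumes at 0.5 within 2%
  for (nm in names(radii)) {
    cum0 <- thresholdVolume(layers(b0)$inner) +
      (nm == "outer") * thresholdVolume(layers(b0)$outer)
    cum1 <- thresholdVolume(layers(b1)$inner) +
      (nm == "outer") * thresholdVolume(layers(b1)$outer)
    expect_lt(abs(cum1 / cum0 - 1), 0.02)
  }
})

test_that("cavity must sit inside its host layer", {
  expect_error(makeLayeredPhantom(
    PhantomSpec(c(outer = 16, inner = 10), gridSize = 44L,
                cavity = list(center = c(0, 0, 13), radius = 4,
                              host = "outer"))),
    "outside its host")
  expect_error(makeLayeredPhantom(
    PhantomSpec(c(outer = 16, inner = 10), gridSize = 44L,
                cavity = list(center = c(0, 0, 0), radius = 3,
                              host = "outer"))),
    "intersect")
})

test_that("noise islands are deterministic and countable", {
  st <- makeLayeredPhantom(PhantomSpec(c(outer = 16, mid = 11, inner = 7),
                                       gridSize = 44L))
  expect_identical(addNoiseIslands(st, 0), st)
  a <- addNoiseIslands(st, 5, size = 2L, seed = 7L)
  b <- addNoiseIslands(st, 5, size = 2L, seed = 7L)
  expect_identical(lapply(layers(a), gridValues), lapply(layers(b), gridValues))
  # component count of an affected tissue increases by its island count
  islands <- attr(a, "islands")
  expect_length(islands, 5)
  gained <- vapply(islands, function(i) i$tissue, "")     # foreign blob
  holed <- vapply(islands, function(i) i$host, "")        # hole in host
  for (nm in unique(c(gained, holed))) {
    s0 <- extractIsosurface(layers(st)[[nm]],
                            SurfaceCriteria(rmax = Inf, keepLargest = FALSE),
                            layer = nm)
    s1 <- extractIsosurface(layers(a)[[nm]],
                            SurfaceCriteria(rmax = Inf, keepLargest = FALSE),
                            layer = nm)
    # every foreign blob adds one closed component to its tissue; every
    # hole adds one closed component to its host's boundary
    expect_equal(max(surfaceComponents(s1)) - max(surfaceComponents(s0)),
                 sum(gained == nm) + sum(holed == nm))
  }
  expect_error(addNoiseIslands(st, 1, size = 50L), "larger than")
})
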