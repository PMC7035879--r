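# Element quality metrics and the volume-conservation ratio.

regular_tet <- function(a = 1) {
  rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0),
        c(a / 2, a * sqrt(3) / 6, a * sqrt(2 / 3)))
}

test_that("Joe-Liu metric: normalization, degeneracy, invariance", {
  for (a in c(1, 0.3, 17)) {
    expect_equal(joeLiu(regular_tet(a)), 1, tolerance = 1e-12)
  }
  coplanar <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_equal(joeLiu(coplanar), 0)
  expect_equal(joeLiu(matrix(0, 4, 3)), 0)   # coincident points
  set.seed(2)
  for (i in 1:20) {
    tet <- matrix(rnorm(12), 4, 3)
    q0 <- joeLiu(tet)
    # random rigid motion + uniform scaling
    ang <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
                c(0, sin(ang[1]), cos(ang[1])))
    Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
                c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
    s <- runif(1, 0.1, 10)
    tet2 <- s * tet %*% Rx %*% Rz + rep(runif(3, -5, 5), each = 4)
    expect_equal(joeLiu(tet2), q0, tolerance = 1e-10)
    # cross-check against the compiled implementation used for meshes
    m <- cpp_tet_metrics(tet, matrix(0:3, 1))
    expect_equal(m$joe_liu, q0, tolerance = 1e-12)
  }
})

test_that("radius-edge ratio: closed forms and circumsphere residual", {
  expect_equal(radiusEdge(regular_tet()), sqrt(6) / 4, tolerance = 1e-9)
  corner <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(radiusEdge(corner), sqrt(3) / 2, tolerance = 1e-9)
  expect_equal(radiusEdge(corner), 0.866025, tolerance = 1e-6)
  coplanar <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  expect_equal(radiusEdge(coplanar), Inf)
  set.seed(3)
  for (i in 1:20) {
    tet <- matrix(rnorm(12), 4, 3)
    re <- radiusEdge(tet)
    expect_gte(re, sqrt(6) / 4 - 1e-12)
    # verify the circumcentre is equidistant from all four vertices
    A <- 2 * rbind(tet[2, ] - tet[1, ], tet[3, ] - tet[1, ],
                   tet[4, ] - tet[1, ])
    b <- rowSums(rbind(tet[2, ], tet[3, ], tet[4, ])^2) - sum(tet[1, ]^2)
    cc <- solve(A, b)
    dists <- sqrt(rowSums((tet - rep(cc, each = 4))^2))
    expect_lt(diff(range(dists)), 1e-9 * mean(dists))
    expect_equal(re, dists[1] / min(dist(tet)), tolerance = 1e-9)
    m <- cpp_tet_metrics(tet, matrix(0:3, 1))
    expect_equal(m$radius_edge, re, tolerance = 1e-9)
  }
})

test_that("Vrel is exactly 1 for a grid-aligned cube", {
  # 11^3 voxels at 1 mm: surface through voxel-boundary planes
  cube <- unitCubeSurface(lo = c(9.5, 9.5, 9.5), hi = c(20.5, 20.5, 20.5),
                          tag = "cube")
  vol <- array(0, c(32, 32, 32))
  vol[11:21, 11:21, 11:21] <- 1
  seg <- TissueStack(list(cube = VolumeGrid(vol, kind = "probability")))
  expect_equal(vRel(cube, "cube", seg), 1, tolerance = 1e-9)
  expect_error(vRel(cube, "ghost", seg), "absent")
  empty <- TissueStack(list(cube = VolumeGrid(array(0.1, c(8, 8, 8)))))
  expect_error(vRel(cube, "cube", empty), "zero-volume")
})

test_that("qc report aggregates metrics and survives JSON round trip", {
  one <- TetMesh(regular_tet(2), matrix(1:4, 1), labels = "wm")
  rep1 <- qcReport(one)
  expect_equal(rep1@summary$meanJoeLiu, 1, tolerance = 1e-12)
  expect_equal(rep1@summary$minJoeLiu, 1, tolerance = 1e-12)
  expect_equal(rep1@summary$nElements, 1L)
  f <- tempfile(fileext = ".json")
  writeQcReport(rep1, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$meanJoeLiu, rep1@summary$meanJoeLiu, tolerance = 1e-12)
  expect_equal(back$nNodes, 4L)
  expect_equal(back$nElements, 1L)
  fm <- tempfile(fileext = ".md")
  writeQcReport(rep1, fm)
  expect_true(any(grepl("Joe-Liu", readLines(fm))))
})
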