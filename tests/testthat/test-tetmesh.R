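# Tetrahedralization, region labeling, point containment and boundary
# recovery on small inputs (the 96^3 phantom runs live in the acceptance
# tests).

test_that("a single sphere fills to its enclosed volume under the bounds", {
  s <- sphereSurface(n = 40L, r = 12, smooth = 10L)
  mesh <- tetrahedralize(list(ball = s),
                         MeshingCriteria(q = 1.414, vmax = 30))
  q <- meshQuality(mesh)
  expect_lte(max(q$radiusEdge), 1.414)
  expect_lte(max(q$volume), 30)
  expect_gt(min(q$joeLiu), 0)
  expect_lt(abs(sum(q$volume) / enclosedVolume(s) - 1), 0.005)
  expect_true(all(mesh@labels == "ball"))
  # exact partition: summed element volume = mesh outer boundary volume
  expect_lt(abs(sum(q$volume) / enclosedVolume(meshBoundary(mesh)) - 1),
            1e-9)
})

test_that("nested spheres produce two labeled regions with exact volumes", {
  inner <- sphereSurface(n = 40L, r = 7, smooth = 10L, tag = "core")
  outer <- sphereSurface(n = 40L, r = 13, smooth = 10L, tag = "shell")
  mesh <- tetrahedralize(list(core = inner, shell = outer),
                         MeshingCriteria(vmax = 30))
  mesh <- assignRegionLabels(mesh, list(core = inner, shell = outer))
  expect_setequal(unique(mesh@labels), c("core", "shell"))
  lv <- labelVolumes(mesh)
  expect_true(all(lv > 0))
  expect_lt(abs(lv[["core"]] / enclosedVolume(inner) - 1), 0.005)
  expect_lt(abs((lv[["core"]] + lv[["shell"]]) / enclosedVolume(outer) - 1),
            0.005)
  crossing <- inner
  crossing@vertices <- crossing@vertices + rep(c(8, 0, 0),
                                               each = nrow(inner@vertices))
  expect_error(tetrahedralize(list(a = inner, b = crossing),
                              MeshingCriteria()), "intersect")
})

test_that("vmax pigeonholes a unit-volume bound on a 10 mm cube", {
  cube <- unitCubeSurface(lo = c(0, 0, 0), hi = c(10, 10, 10))
  mesh <- tetrahedralize(list(cube = cube), MeshingCriteria(vmax = 1))
  q <- meshQuality(mesh)
  expect_lte(max(q$volume), 1)
  expect_gte(nrow(mesh@elements), 1000)
  expect_lt(abs(sum(q$volume) / 1000 - 1), 0.005)
})

test_that("sizing field and per-label caps tighten the element volume", {
  s <- sphereSurface(n = 32L, r = 9, smooth = 10L)
  m1 <- tetrahedralize(list(ball = s),
                       MeshingCriteria(vmax = 30,
                                       sizingField = function(p) rep(2, nrow(p))))
  expect_lte(max(meshQuality(m1)$volume), 2)
  m2 <- tetrahedralize(list(ball = s),
                       MeshingCriteria(vmax = 30,
                                       vmaxPerLabel = c(ball = 3)))
  expect_lte(max(meshQuality(m2)$volume), 3)
})

test_that("point containment is robust and agrees with rasterization", {
  s <- sphereSurface(n = 36L, r = 10, smooth = 5L)
  cen <- rep(17.5, 3)
  expect_true(pointInSurface(cen, s))
  expect_false(pointInSurface(cen + c(20, 0, 0), s))
  # points on lattice lines aligned with vertices still resolve
  expect_length(pointInSurface(rbind(cen, cen + 100), s), 2)
  template <- VolumeGrid(array(0, c(36, 36, 36)))
  vox <- gridValues(rasterizeSurface(s, template))
  set.seed(8)
  pts <- matrix(runif(3000, 2, 33), ncol = 3)
  d <- abs(sqrt(rowSums((pts - 17.5)^2)) - 10)
  keep <- d > 1
  got <- pointInSurface(pts[keep, ], s)
  ref <- vox[round(pts[keep, , drop = FALSE]) + 1] == 1
  expect_equal(as.numeric(got), as.numeric(ref))
})

test_that("relabeling is the identity when nothing was altered", {
  st <- makeLayeredPhantom(phantomPreset("three-layer", gridSize = 96L))
  model <- buildLayeredModel(st, GapParams(1L))
  expect_equal(sum(lengths(alteredVoxels(model))), 0)
  res <- runPipeline(st, pipelineConfig(relabel = FALSE, cellSize = 2.5),
                     verbose = FALSE)
  relab <- relabelSharedBoundaries(res$mesh, st, res$model)
  expect_identical(relab@labels, res$mesh@labels)
})

test_that("wholesale mislabeled regions are corrected by majority vote", {
  # two-region mesh with deliberately swapped labels against its own
  # two-layer segmentation: the whole-region vote must undo the swap
  st <- makeLayeredPhantom(PhantomSpec(c(top = 14, bottom = 8),
                                       gridSize = 36L, blurSigma = 0))
  res <- runPipeline(st, pipelineConfig(relabel = FALSE, smoothIterations = 5L),
                     verbose = FALSE)
  mesh <- res$mesh
  swapped <- mesh
  swapped@labels <- ifelse(mesh@labels == "top", "bottom", "top")
  fixed <- relabelSharedBoundaries(swapped, st, NULL)
  expect_identical(fixed@labels, mesh@labels)
})
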