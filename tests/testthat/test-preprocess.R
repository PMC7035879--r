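# Morphological operators and the layered extraction model.

test_that("cubic max/min filters match the brute-force oracle", {
  for (seed in 1:4) {
    for (eps in 1:3) {
      v <- randomVolume(8L + 2L * seed, seed * 10L + eps)
      expect_identical(gridValues(maxFilter(v, eps)),
                       bruteCubeFilter(gridValues(v), eps, max))
      expect_identical(gridValues(minFilter(v, eps)),
                       bruteCubeFilter(gridValues(v), eps, min))
    }
  }
})

test_that("filter edge cases: constants, single voxel, bad epsilon", {
  const <- VolumeGrid(array(0.7, c(6, 6, 6)))
  expect_identical(gridValues(maxFilter(const, 2L)), gridValues(const))
  expect_identical(gridValues(minFilter(const, 2L)), gridValues(const))
  spike <- array(0, c(7, 7, 7)); spike[4, 4, 4] <- 1
  d <- gridValues(maxFilter(VolumeGrid(spike), 1L))
  expect_equal(sum(d == 1), 27)           # 3x3x3 block
  expect_true(all(d[3:5, 3:5, 3:5] == 1))
  ones <- array(1, c(7, 7, 7)); ones[4, 4, 4] <- 0
  e <- gridValues(minFilter(VolumeGrid(ones), 1L))
  expect_equal(sum(e == 0), 27)
  expect_error(maxFilter(const, 0L), "positive")
})

test_that("thicken and thin follow their voxelwise definitions", {
  clamp <- function(x) pmin(pmax(x, 0), 1)
  for (seed in 1:3) {
    for (eps in c(1L, 2L)) {
      pin <- randomVolume(10L, seed)
      pout <- randomVolume(10L, seed + 100L)
      thick <- thicken(pout, pin, eps)
      oracle <- clamp(pmax(gridValues(pin) + gridValues(pout),
                           bruteCubeFilter(gridValues(pin), eps, max)))
      expect_equal(gridValues(thick), oracle, tolerance = 1e-12)
      thinned <- thin(pin, pout, eps)
      oracle2 <- pmin(gridValues(pin),
                      bruteCubeFilter(clamp(gridValues(pin) +
                                            gridValues(pout)), eps, min))
      expect_equal(gridValues(thinned), oracle2, tolerance = 1e-12)
    }
  }
  # no inner tissue -> thickening returns the outer map unchanged
  zero <- VolumeGrid(array(0, c(10, 10, 10)))
  pout <- randomVolume(10L, 5)
  expect_equal(gridValues(thicken(pout, zero, 1L)), gridValues(pout))
  # inner deep inside a full union is untouched by thinning
  onesv <- VolumeGrid(array(1, c(10, 10, 10)))
  pin <- randomVolume(10L, 6)
  expect_equal(gridValues(thin(pin, onesv, 1L)), gridValues(pin))
  expect_error(thicken(pout, randomVolume(8L, 1), 1L), "dimensions")
})

test_that("containment and composition properties of the filters", {
  for (seed in 1:3) {
    v <- randomVolume(12L, seed + 40L)
    d1 <- maxFilter(v, 1L)
    e1 <- minFilter(v, 1L)
    expect_true(all(gridValues(d1) >= gridValues(v)))
    expect_true(all(gridValues(v) >= gridValues(e1)))
    # D_1 o D_2 = D_3 away from the border (shrinking windows differ there)
    d12 <- maxFilter(maxFilter(v, 1L), 2L)
    d3 <- maxFilter(v, 3L)
    core <- 4:9
    expect_identical(gridValues(d12)[core, core, core],
                     gridValues(d3)[core, core, core])
  }
})

test_that("gap operators only act where boundaries merge (locality)", {
  # binary merged phantom: locality of T- is exact
  st <- makeLayeredPhantom(PhantomSpec(c(scalp = 40, skull = 36, csf = 33,
                                         gm = 31, wm = 27),
                                       gridSize = 96L, blurSigma = 0,
                                       offsets = c(gm = 3, wm = 3)))
  eps <- 1L
  model <- buildLayeredModel(st, GapParams(eps, c(gm = "thin_inner")))
  ch <- unlist(alteredVoxels(model))
  expect_gt(length(ch), 0)
  # contact set: gm voxels face-adjacent to the outside of the csf map
  gmv <- gridValues(layers(st)$gm) >= 0.5
  csfv <- gridValues(layers(st)$csf) >= 0.5
  outercum <- (gridValues(layers(st)$wm) + gridValues(layers(st)$gm) +
               gridValues(layers(st)$csf)) >= 0.5
  contact <- gmv & !bruteCubeFilter(outercum * 1, 1L, min)
  contactDil <- bruteCubeFilter(contact * 1, eps, max) > 0
  altered <- array(FALSE, dim(gmv))
  altered[ch] <- TRUE
  expect_true(all(altered[!contactDil] == FALSE))
})

test_that("layered model: nesting, gap insertion, skipping, air", {
  # well-separated layers need no alteration and keep their level sets
  st <- makeLayeredPhantom(phantomPreset("five-layer-separated"))
  m <- buildLayeredModel(st, GapParams(1L))
  expect_equal(sum(lengths(alteredVoxels(m))), 0)
  ev <- extractionVolumes(m)
  cum <- array(0, dim(gridValues(layers(st)[[1]])))
  for (i in seq_along(ev)) {
    cum <- pmin(cum + gridValues(layers(st)[[i]]), 1)
    inside_prev <- gridValues(ev[[i]]) >= 0.5
    # extraction volume = filled cumulative map: every cumulative-positive
    # voxel is inside, and nesting holds
    expect_true(all(inside_prev[cum >= 0.5]))
    if (i > 1)
      expect_true(all(inside_prev[gridValues(ev[[i - 1]]) >= 0.5]))
  }
  # merged boundary: the thinned layer's level set recedes only at contact
  stm <- makeLayeredPhantom(phantomPreset("merged-csf-gm"))
  mm <- buildLayeredModel(stm, GapParams(1L, c(gm = "thin_inner")))
  gm_before <- (gridValues(layers(stm)$wm) + gridValues(layers(stm)$gm)) >= 0.5
  gm_after <- gridValues(extractionVolumes(mm)$gm) >= 0.5
  expect_true(all(gm_before[gm_after]))       # receded, never grew
  expect_gt(sum(gm_before) - sum(gm_after), 0)
  # empty layer is skipped with a warning
  layers0 <- layers(st)
  layers0$ghost <- VolumeGrid(array(0.01, dim(gridValues(layers0[[1]]))))
  expect_warning(buildLayeredModel(TissueStack(layers0), GapParams(1L)),
                 "skipped")
  # cavity is absent from the host's extraction volume
  stc <- makeLayeredPhantom(phantomPreset("cavity"))
  mc <- buildLayeredModel(stc, GapParams(1L))
  cav <- gridValues(airMasks(stc)$skull) >= 0.5
  expect_true(all(gridValues(extractionVolumes(mc)$skull)[cav] < 0.5))
  expect_length(airMasks(mc), 1)
})
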