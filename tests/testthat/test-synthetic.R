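# Synthetic vasculature generator and its ground-truth oracles.

test_that("sinusoidal centerline matches its analytic/quadrature oracles", {
  straight <- makeSinusoidalCenterline(100, amplitude = 0)
  expect_equal(straight$tortuosity, 1, tolerance = 1e-9)
  expect_equal(straight$arcLength, straight$chordLength, tolerance = 1e-9)

  half <- makeSinusoidalCenterline(40, shape = "half_circle")
  expect_equal(half$tortuosity, pi / 2, tolerance = 1e-4)

  # independent quadrature oracle on the same analytic curve
  sine <- makeSinusoidalCenterline(200, amplitude = 5, wavelengthPx = 50)
  nHalf <- round(2 * 200 / 50)
  f <- function(x) sqrt(1 + (5 * nHalf * pi / 200)^2 *
                          cos(nHalf * pi * x / 200)^2)
  arc <- stats::integrate(f, 0, 200, subdivisions = 1000L)$value
  expect_equal(sine$tortuosity, arc / 200, tolerance = 1e-3)

  expect_error(makeSinusoidalCenterline(100, amplitude = -1), "amplitude")
  expect_error(makeSinusoidalCenterline(100, amplitude = 1,
                                        wavelengthPx = 150), "wavelength")
})

test_that("rasterizePolyline draws disk-union strokes with the expected area", {
  pts <- data.frame(row = rep(30, 2), col = c(20, 120))
  m <- rasterizePolyline(pts, 5, c(60L, 150L))
  expected <- 100 * 5 + pi * 2.5^2  # rectangle + endcaps
  expect_lt(abs(maskPixelCount(m) - expected) / expected, 0.05)

  thin <- rasterizePolyline(data.frame(row = c(10, 40), col = c(10, 45)),
                            1, c(60L, 60L))
  # a diameter-1 stroke traces as a single 8-connected 1-px path whose
  # endpoints span the drawn chord
  gthin <- buildVesselGraph(skeletonize(thin))
  expect_length(graphSegments(gthin), 1L)
  sthin <- graphSegments(gthin)[[1L]]
  chord <- sqrt(diff(sthin$row[c(1L, nrow(sthin))])^2 +
                diff(sthin$col[c(1L, nrow(sthin))])^2)
  expect_lt(abs(chord - sqrt(30^2 + 35^2)), 3)
  expect_lt(abs(segmentTortuosity(sthin) - 1), 0.02)

  a <- rasterizePolyline(data.frame(row = c(10, 10), col = c(5, 25)),
                         3, c(60L, 60L))
  b <- rasterizePolyline(data.frame(row = c(40, 40), col = c(5, 25)),
                         3, c(60L, 60L))
  both <- RasterMask(maskPixels(a) | maskPixels(b))
  expect_identical(maskPixelCount(both), maskPixelCount(a) + maskPixelCount(b))

  expect_error(rasterizePolyline(data.frame(row = 1, col = 1), 3,
                                 c(10L, 10L)), "2 points")
  expect_error(rasterizePolyline(pts, 0.5, c(60L, 150L)), "diameterPx")
})

test_that("generateTree truth matches combinatorial and caliber-law oracles", {
  trunk <- generateTree(treeParams(depth = 0L, tortuosityAmplitude = 0,
                                   seed = 5))
  expect_identical(unname(trunk$truth$nBifurcationsPerClass),
                   c(0L, 0L))
  expect_true(all(abs(trunk$truth$segments$true_tortuosity - 1) < 1e-9))

  sv <- generateTree(treeParams(depth = 3L, seed = 11))
  expect_identical(unname(sv$truth$nBifurcationsPerClass), c(7L, 7L))

  # Murray-type caliber law: symmetric split, parent^3 = 2 * child^3
  p16 <- treeParams(depth = 1L, rootDiameterPx = 16, caliberExponent = 3,
                    seed = 2)
  sv16 <- generateTree(p16)
  tr <- sv16$truth$segments
  child <- tr$true_diameter_px[tr$class == "artery" & tr$level == 1L][1L]
  expect_equal(child, 16 * 2^(-1 / 3), tolerance = 1e-9)  # ~12.70

  expect_true(all(sv$truth$segments$true_tortuosity >= 1))
})

test_that("same seed gives bit-identical rasters and truth", {
  a <- generateTree(treeParams(depth = 3L, seed = 99))
  b <- generateTree(treeParams(depth = 3L, seed = 99))
  expect_identical(maskPixels(a$artery), maskPixels(b$artery))
  expect_identical(maskPixels(a$vein), maskPixels(b$vein))
  expect_identical(a$truth$segments, b$truth$segments)
  c <- generateTree(treeParams(depth = 3L, seed = 100))
  expect_false(identical(maskPixels(a$artery), maskPixels(c$artery)))
})

test_that("trees exceeding the canvas fail loudly, naming the level", {
  expect_error(
    generateTree(treeParams(depth = 4L, segmentLengthPx = 90, seed = 1)),
    "level")
})

test_that("doubling all linear parameters scales vessel area ~4x", {
  p1 <- treeParams(depth = 2L, rootDiameterPx = 10, segmentLengthPx = 40,
                   tortuosityAmplitude = 1.5, tortuosityWavelengthPx = 40,
                   odRadiusPx = 20, seed = 21)
  p2 <- treeParams(depth = 2L, rootDiameterPx = 20, segmentLengthPx = 80,
                   tortuosityAmplitude = 3, tortuosityWavelengthPx = 80,
                   odRadiusPx = 40, seed = 21)
  n1 <- generateTree(p1, canvas = c(448L, 416L))$truth$trueVesselPixelCount
  n2 <- generateTree(p2, canvas = c(896L, 832L))$truth$trueVesselPixelCount
  expect_lt(abs(n2[["artery"]] / n1[["artery"]] - 4), 0.2)
  expect_lt(abs(n2[["vein"]] / n1[["vein"]] - 4), 0.2)
})
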