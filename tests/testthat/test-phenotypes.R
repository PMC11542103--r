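# The 17 image-derived phenotypes.

test_that("vascular density is the vessel fraction of the ROI", {
  roi <- RasterMask(matrix(TRUE, 20, 20))
  expect_identical(vascularDensity(RasterMask(matrix(FALSE, 20, 20)), roi), 0)
  expect_identical(vascularDensity(roi, roi), 1)
  half <- RasterMask(rbind(matrix(TRUE, 10, 20), matrix(FALSE, 10, 20)))
  expect_identical(vascularDensity(half, roi), 0.5)
  expect_error(vascularDensity(half, RasterMask(matrix(FALSE, 20, 20))),
               "empty")
  expect_error(vascularDensity(half, RasterMask(matrix(TRUE, 10, 20))),
               "shape")
})

test_that("diameter stats give median and population SD, or missing", {
  seg <- data.frame(row = 1:4, col = rep(1, 4), diameter = c(4, 4, 6, 6))
  g <- craftGraph(list(seg))
  expect_equal(unname(diameterStats(g, minPoints = 4L)), c(5, 1))
  g2 <- craftGraph(list(data.frame(row = 1:10, col = rep(1, 10),
                                   diameter = rep(5, 10))))
  expect_equal(unname(diameterStats(g2, minPoints = 10L)), c(5, 0))
  expect_true(all(is.na(diameterStats(g2, minPoints = 50L))))
})

test_that("tortuosity distance factor matches analytic fixtures", {
  straight <- data.frame(row = rep(5, 50), col = seq_len(50))
  expect_equal(segmentTortuosity(straight), 1, tolerance = 1e-9)

  # rasterized half-circle traced back through the pipeline (tips untouched:
  # the endcap disks are stroke, not analytic arc)
  half <- makeSinusoidalCenterline(80, shape = "half_circle")
  pts <- data.frame(row = half$points$row + 60, col = half$points$col + 20)
  m <- rasterizePolyline(pts, 5, c(120L, 120L))
  g <- pruneSpurs(buildVesselGraph(skeletonize(m)))
  i <- which.max(segmentInfo(g)$length)
  tort <- segmentTortuosity(graphSegments(g)[[i]])
  expect_lt(abs(tort - pi / 2) / (pi / 2), 0.02)

  # sinusoid: rasterize + trace against the quadrature oracle
  sine <- makeSinusoidalCenterline(150, amplitude = 4, wavelengthPx = 50)
  pts <- data.frame(row = sine$points$row + 40, col = sine$points$col + 10)
  g2 <- pruneSpurs(buildVesselGraph(skeletonize(
    rasterizePolyline(pts, 5, c(80L, 170L)))))
  i2 <- which.max(segmentInfo(g2)$length)
  expect_lt(abs(segmentTortuosity(graphSegments(g2)[[i2]]) - sine$tortuosity),
            1e-2 * sine$tortuosity + 1e-2)

  short <- data.frame(row = c(1, 2), col = c(1, 5))
  expect_true(is.na(segmentTortuosity(short, minChordPx = 10)))
})

test_that("median tortuosity pools eligible segments only", {
  mk <- function(tort, chord = 60) {
    # circular arc with the requested arc/chord ratio
    if (tort == 1) return(data.frame(row = rep(0, 100),
                                     col = seq(0, chord, length.out = 100)))
    f <- function(a) a / sin(a) - tort
    a <- stats::uniroot(f, c(1e-6, pi - 1e-6))$root
    r <- chord / (2 * sin(a))
    th <- seq(-a, a, length.out = 400)
    data.frame(row = r * cos(th), col = r * sin(th) + chord / 2)
  }
  g <- craftGraph(list(mk(1.0), mk(1.2), mk(1.4)))
  expect_equal(medianTortuosity(g, smoothWindow = 1L), 1.2, tolerance = 1e-3)
  # sub-threshold chord segments do not move the median
  g2 <- craftGraph(list(mk(1.0), mk(1.2), mk(1.4),
                        data.frame(row = c(0, 3), col = c(0, 4))))
  expect_equal(medianTortuosity(g2, smoothWindow = 1L),
               medianTortuosity(g, smoothWindow = 1L))
  expect_true(is.na(medianTortuosity(craftGraph(list(
    data.frame(row = c(0, 1), col = c(0, 2)))))))
})

test_that("Knudtson pairing matches its closed form and scales linearly", {
  expect_equal(knudtsonPair(100, 100, "artery"), 124.45, tolerance = 1e-2)
  expect_equal(knudtsonPair(100, 100, "vein"), 134.35, tolerance = 1e-2)
  expect_identical(knudtsonPair(80, 60, "artery"), knudtsonPair(60, 80, "artery"))
  expect_equal(knudtsonPair(3 * 80, 3 * 60, "vein"),
               3 * knudtsonPair(80, 60, "vein"), tolerance = 1e-12)
  expect_error(knudtsonPair(-1, 5, "artery"), "positive")
})

test_that("central retinal equivalents follow the iterative pairing scheme", {
  od <- OpticDisc(100, 100, 20)  # zone B = radii 40..60
  mkGraph <- function(widths, cls) {
    segs <- lapply(seq_along(widths), function(i)
      radialSegment(c(100, 100), 30 * i, 25, 75, widths[i]))
    craftGraph(segs, vesselClass = cls)
  }
  # hand-iterated oracle for six equal widths
  handIter <- function(w, k) {
    x <- rep(w, 6)
    while (length(x) > 1) {
      x <- sort(x, decreasing = TRUE)
      n <- length(x); h <- n %/% 2
      nx <- k * sqrt(x[1:h]^2 + x[n + 1 - (1:h)]^2)
      if (n %% 2) nx <- c(nx, x[h + 1])
      x <- nx
    }
    x
  }
  creA <- centralRetinalEquivalent(mkGraph(rep(10, 6), "artery"), od)
  expect_equal(creA$value, handIter(10, 0.88), tolerance = 1e-9)
  expect_equal(creA$value / 10, 1.74843, tolerance = 1e-4)
  creV <- centralRetinalEquivalent(mkGraph(rep(10, 6), "vein"), od)
  expect_equal(creV$value / 10, 2.13761, tolerance = 1e-4)

  # permutation invariance and homogeneity on unequal widths
  w <- c(11, 7, 9, 13, 8, 10)
  v1 <- centralRetinalEquivalent(mkGraph(w, "artery"), od)$value
  v2 <- centralRetinalEquivalent(mkGraph(sample(w), "artery"), od)$value
  expect_equal(v1, v2, tolerance = 1e-9)
  v3 <- centralRetinalEquivalent(mkGraph(2.5 * w, "artery"), od)$value
  expect_equal(v3, 2.5 * v1, tolerance = 1e-9)

  few <- centralRetinalEquivalent(mkGraph(c(10, 10), "artery"), od)
  expect_identical(few$flag, "few_segments")
  expect_identical(few$n, 2L)
  expect_true(is.na(centralRetinalEquivalent(mkGraph(rep(10, 6), "artery"),
                                             NULL)$value))
})

test_that("temporal angle recovers arcade elevations and their symmetry", {
  od <- OpticDisc(100, 60, 20)  # annulus 20..50, temporal = +col
  mkArc <- function(sup, inf) craftGraph(list(
    radialSegment(c(100, 60), -sup, 5, 60, 8),
    radialSegment(c(100, 60), +inf, 5, 60, 8)), dims = c(200L, 200L))
  expect_equal(temporalAngle(mkArc(60, 60), od), 120, tolerance = 1)
  # mirror about the OD horizontal leaves the angle unchanged
  expect_equal(temporalAngle(mkArc(40, 70), od),
               temporalAngle(mkArc(70, 40), od), tolerance = 1e-6)
  # single horizontal trunk: no hemifield separation -> missing
  trunk <- craftGraph(list(radialSegment(c(100, 60), 0, 5, 60, 8)))
  expect_true(is.na(temporalAngle(trunk, od)))
  # synthetic arcade oracle
  sv <- generateTree(treeParams(depth = 3L, arcadeSupDeg = 60,
                                arcadeInfDeg = 60, seed = 6))
  g <- traceMask(sv$artery)
  expect_lt(abs(temporalAngle(g, sv$od) - 120), 5)
})

test_that("bifurcations are counted per class, crossings excluded", {
  y <- pruneSpurs(buildVesselGraph(skeletonize(yMask())))
  expect_identical(countBifurcations(y, y), 2L)
  # an artery stroke crossing a vein stroke forms no node in either class
  a <- buildVesselGraph(skeletonize(barMask(width = 3L, len = 60L,
                                            vesselClass = "artery")))
  vm <- matrix(FALSE, 15L, 72L); vm[2:13, 36:38] <- TRUE
  v <- buildVesselGraph(skeletonize(RasterMask(vm, vesselClass = "vein")))
  expect_identical(countBifurcations(a, v), 0L)
  expect_identical(countBifurcations(NULL, NULL), 0L)
  sv <- generateTree(treeParams(depth = 3L, seed = 8))
  expect_identical(countBifurcations(traceMask(sv$artery),
                                     traceMask(sv$vein)), 14L)
})

test_that("computeIDPs assembles all 17 fields with explicit missingness", {
  sv <- generateTree(treeParams(depth = 3L, seed = 10))
  idp <- computeIDPs(sv$artery, sv$vein, sv$od)
  expect_true(all(idpNames() %in% names(idp)))
  vals <- unlist(idp[, idpNames()])
  expect_identical(sum(!is.na(vals)), 17L)
  # ratio consistency
  expect_lt(abs(idp$ratio_vascular_density * idp$v_vascular_density -
                  idp$a_vascular_density), 1e-12)
  expect_lt(abs(idp$ratio_tortuosity * idp$v_tortuosity - idp$a_tortuosity),
            1e-12)

  empty <- RasterMask(matrix(FALSE, nrow(maskPixels(sv$artery)),
                             ncol(maskPixels(sv$artery))),
                      vesselClass = "vein")
  idp2 <- computeIDPs(sv$artery, empty, sv$od)
  vcols <- grep("^v_|^ratio_", idpNames(), value = TRUE)
  expect_true(all(is.na(unlist(idp2[, vcols]))))
  acols <- grep("^a_", idpNames(), value = TRUE)
  expect_true(all(!is.na(unlist(idp2[, acols]))))

  expect_error(computeIDPs(sv$artery, RasterMask(matrix(FALSE, 5, 5))),
               "shape")
})

test_that("density and bifurcations are translation invariant", {
  sv <- generateTree(treeParams(depth = 2L, seed = 30))
  dims <- dim(maskPixels(sv$artery))
  big <- c(dims[1L] + 40L, dims[2L] + 40L)
  place <- function(mask, dr, dc) {
    m <- matrix(FALSE, big[1L], big[2L])
    m[dr + seq_len(dims[1L]), dc + seq_len(dims[2L])] <- maskPixels(mask)
    RasterMask(m, vesselClass = vesselClass(mask))
  }
  roi <- RasterMask(matrix(TRUE, big[1L], big[2L]))
  i1 <- computeIDPs(place(sv$artery, 5L, 5L), place(sv$vein, 5L, 5L),
                    OpticDisc(odCenter(sv$od)[1L] + 5, odCenter(sv$od)[2L] + 5,
                              odRadius(sv$od)), roi = roi)
  i2 <- computeIDPs(place(sv$artery, 25L, 30L), place(sv$vein, 25L, 30L),
                    OpticDisc(odCenter(sv$od)[1L] + 25,
                              odCenter(sv$od)[2L] + 30, odRadius(sv$od)),
                    roi = roi)
  expect_identical(i1$bifurcations, i2$bifurcations)
  expect_equal(i1$a_vascular_density, i2$a_vascular_density, tolerance = 1e-12)
  expect_equal(i1$v_vascular_density, i2$v_vascular_density, tolerance = 1e-12)
})

test_that("tortuosity and ratios are invariant under 2x upscaling", {
  sv <- generateTree(treeParams(depth = 2L, seed = 31,
                                tortuosityAmplitude = 2.5))
  g1 <- traceMask(sv$artery)
  g2 <- traceMask(upscaleMask(sv$artery))
  t1 <- medianTortuosity(g1); t2 <- medianTortuosity(g2)
  expect_lt(abs(t2 - t1) / t1, 0.02)
})
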