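# Synthetic retinal vasculature with exhaustive ground truth.
#
# Two vessel classes (artery, vein) are drawn as complete binary trees rooted
# at the optic disc. The first bifurcation sits at the OD margin and splits
# into the superior and inferior temporal arcades at the requested elevation
# angles; deeper levels fan out with a geometrically shrinking half-angle and
# are gently pulled back toward the horizontal, mimicking arcade curvature and
# keeping complete trees self-avoiding. Calibers follow a Murray-type law
# parent^k = sum(child^k) with symmetric splits. Centerlines get a sinusoidal
# perpendicular displacement vanishing at segment ends, so branch points are
# exact and the per-segment tortuosity oracle (arc/chord by dense quadrature)
# is self-consistent with the drawn raster.

#' Parameters of the synthetic vascular tree generator
#'
#' @param depth number of bifurcation levels (>= 0); 0 gives one unbranched
#'   trunk per class, a complete tree of depth d has 2^d - 1 bifurcations.
#' @param rootDiameterPx trunk diameter in pixels (> 0).
#' @param caliberExponent Murray-type caliber-decay exponent k (> 0); symmetric
#'   child diameter is parent * 2^(-1/k). Default 3 (Murray's law).
#' @param branchHalfAngleDeg half-angle of splits at levels >= 2, degrees in
#'   (0, 90).
#' @param segmentLengthPx length of level-1 segments in pixels (> 0); deeper
#'   levels shrink by a fixed factor 0.9.
#' @param tortuosityAmplitude sinusoidal centerline displacement amplitude in
#'   pixels (>= 0); 0 gives straight polylines.
#' @param tortuosityWavelengthPx sinusoid wavelength in pixels (> 0).
#' @param arcadeSupDeg,arcadeInfDeg elevation of the superior/inferior main
#'   arcade above/below the horizontal through the OD, degrees in (0, 90).
#' @param odRadiusPx optic disc radius in pixels.
#' @param seed integer RNG seed; fixes branch-angle jitter bit-for-bit.
#' @return A validated list of class \code{TreeParams}.
#' @examples
#' p <- treeParams(depth = 3, seed = 1)
#' @export
treeParams <- function(depth = 3L,
                       rootDiameterPx = 13,
                       caliberExponent = 3,
                       branchHalfAngleDeg = 28,
                       segmentLengthPx = 52,
                       tortuosityAmplitude = 2,
                       tortuosityWavelengthPx = 40,
                       arcadeSupDeg = 55,
                       arcadeInfDeg = 55,
                       odRadiusPx = 24,
                       seed = 1L) {
  stopifnot(
    depth >= 0, rootDiameterPx > 0, caliberExponent > 0,
    branchHalfAngleDeg > 0, branchHalfAngleDeg < 90,
    segmentLengthPx > 0, tortuosityAmplitude >= 0,
    tortuosityWavelengthPx > 0,
    arcadeSupDeg > 0, arcadeSupDeg < 90,
    arcadeInfDeg > 0, arcadeInfDeg < 90,
    odRadiusPx > 0
  )
  structure(list(
    depth = as.integer(depth), rootDiameterPx = rootDiameterPx,
    caliberExponent = caliberExponent,
    branchHalfAngleDeg = branchHalfAngleDeg,
    segmentLengthPx = segmentLengthPx,
    tortuosityAmplitude = tortuosityAmplitude,
    tortuosityWavelengthPx = tortuosityWavelengthPx,
    arcadeSupDeg = arcadeSupDeg, arcadeInfDeg = arcadeInfDeg,
    odRadiusPx = odRadiusPx, seed = as.integer(seed)
  ), class = "TreeParams")
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Unit direction (row, col) of an angle in degrees: 0 = temporal (+col),
# positive = inferior (+row, i.e. down in the image).
dirVec <- function(thetaDeg) {
  t <- thetaDeg * pi / 180
  c(sin(t), cos(t))
}

# Dense polyline from `start` along direction thetaDeg over `len` px with a
# sinusoidal perpendicular displacement vanishing at both ends (an integer
# number of half-periods closest to the requested wavelength).
segmentPolyline <- function(start, thetaDeg, len, amplitude, wavelength,
                            step = 0.25) {
  s <- seq(0, len, by = step)
  if (s[length(s)] < len) s <- c(s, len)
  u <- dirVec(thetaDeg)
  perp <- c(u[2L], -u[1L])
  disp <- if (amplitude > 0) {
    nHalf <- max(1L, round(2 * len / wavelength))
    amplitude * sin(nHalf * pi * s / len)
  } else rep(0, length(s))
  data.frame(row = start[1L] + s * u[1L] + disp * perp[1L],
             col = start[2L] + s * u[2L] + disp * perp[2L])
}

#' Sinusoidal (or half-circle) centerline with analytic arc length
#'
#' Builds a dense planar centerline of known arc length, the ground-truth
#' oracle for the tortuosity distance factor (arc length / chord length). The
#' sinusoid uses the integer number of half-periods closest to the requested
#' wavelength so the displacement vanishes at both endpoints; arc length is
#' computed by dense numerical quadrature (0.05 px steps).
#'
#' @param chordPx chord (endpoint-to-endpoint) length in pixels.
#' @param amplitude perpendicular displacement amplitude in pixels (>= 0).
#' @param wavelengthPx requested wavelength (must be <= chord).
#' @param shape \code{"sine"} or \code{"half_circle"} (a semicircle of
#'   diameter \code{chordPx}, whose distance factor is pi/2).
#' @return list with \code{points} (data.frame row, col), \code{arcLength},
#'   \code{chordLength}, \code{tortuosity}.
#' @examples
#' cl <- makeSinusoidalCenterline(200, 5, 50)
#' cl$tortuosity
#' makeSinusoidalCenterline(40, shape = "half_circle")$tortuosity  # ~ pi/2
#' @export
makeSinusoidalCenterline <- function(chordPx, amplitude = 0,
                                     wavelengthPx = chordPx,
                                     shape = c("sine", "half_circle")) {
  shape <- match.arg(shape)
  if (chordPx <= 0) stop("chordPx must be positive")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (shape == "half_circle") {
    r <- chordPx / 2
    theta <- seq(0, pi, length.out = max(200L, ceiling(pi * r / 0.05)))
    pts <- data.frame(row = -r * sin(theta), col = r - r * cos(theta))
  } else {
    if (wavelengthPx > chordPx)
      stop("wavelengthPx must not exceed chordPx")
    pts <- segmentPolyline(c(0, 0), 0, chordPx, amplitude, wavelengthPx,
                           step = 0.05)
  }
  arc <- polylineLength(pts)
  chord <- sqrt((pts$row[nrow(pts)] - pts$row[1L])^2 +
                (pts$col[nrow(pts)] - pts$col[1L])^2)
  list(points = pts, arcLength = arc, chordLength = chord,
       tortuosity = arc / chord)
}

#' Rasterize a polyline at a given stroke diameter
#'
#' The stroke is the union of disks of radius \code{diameterPx/2} centered on
#' the densified polyline, computed via the Euclidean distance transform.
#'
#' @param points data.frame/matrix of ordered (row, col) centerline points
#'   (>= 2 points).
#' @param diameterPx stroke diameter in pixels (>= 1).
#' @param dims canvas dims c(rows, cols).
#' @param vesselClass,imageId metadata for the returned mask.
#' @return A \linkS4class{RasterMask}.
#' @examples
#' pts <- data.frame(row = rep(10, 2), col = c(5, 25))
#' m <- rasterizePolyline(pts, 3, c(20L, 30L))
#' @export
rasterizePolyline <- function(points, diameterPx, dims,
                              vesselClass = "none", imageId = "image") {
  points <- as.data.frame(points)
  if (nrow(points) < 2L)
    stop("polyline needs at least 2 points")
  if (diameterPx < 1)
    stop("diameterPx must be >= 1")
  px <- strokePixels(points, diameterPx, as.integer(dims))
  RasterMask(px, vesselClass = vesselClass, imageId = imageId)
}

# Recursively lay out the segments of one vessel class as a space-filling
# dyadic fan: every terminal branch of a hemifield gets an evenly spaced
# target direction (spacing 2 * branchHalfAngleDeg for shallow trees, half
# that for depth >= 4), and every internal branch heads along the mean of its
# leaves' directions. Spatial ordering of branches then matches angular
# ordering by construction, so complete trees are self-avoiding. Per-leaf
# angular jitter is demeaned per hemifield, keeping the level-1 arcade
# directions exactly at the requested elevations.
# Returns a list of records: level, theta, polyline, diameter, chord.
layoutTree <- function(params, odCenter, lenFactor = 1, canvas,
                       lengthDecay = 1.15, jitterSd = 1) {
  p <- params
  segs <- list()
  # trunk enters from the nasal side and ends at the disc center, so the
  # level-1 arcades radiate from the OD center at exactly the arcade angles
  rootLen <- if (p$depth == 0L) p$segmentLengthPx * lenFactor else p$odRadiusPx
  rootStart <- c(odCenter[1L], odCenter[2L] - rootLen)
  root <- segmentPolyline(rootStart, 0, rootLen,
                          p$tortuosityAmplitude, p$tortuosityWavelengthPx)
  segs[[1L]] <- list(level = 0L, theta = 0, polyline = root,
                     diameter = p$rootDiameterPx, chord = rootLen)
  if (p$depth >= 1L) {
    m <- 2L^(p$depth - 1L)  # leaves per hemifield
    delta <- if (p$depth >= 4L) 2 * p$branchHalfAngleDeg / 3
      else 4 * p$branchHalfAngleDeg / 3
    spread <- (seq_len(m) - (m + 1) / 2) * delta
    emit <- function(center) {  # center = signed arcade elevation
      jit <- stats::rnorm(m, 0, jitterSd)
      jit <- jit - mean(jit)
      leafAngles <- center + spread + jit
      rec <- function(pos, lo, hi, lev) {
        theta <- mean(leafAngles[lo:hi])
        len <- p$segmentLengthPx * lenFactor * lengthDecay^(lev - 1L)
        diam <- max(1, p$rootDiameterPx * 2^(-lev / p$caliberExponent))
        pl <- segmentPolyline(pos, theta, len,
                              p$tortuosityAmplitude, p$tortuosityWavelengthPx)
        segs[[length(segs) + 1L]] <<-
          list(level = lev, theta = theta, polyline = pl,
               diameter = diam, chord = len)
        if (lev < p$depth) {
          end <- c(pl$row[nrow(pl)], pl$col[nrow(pl)])
          mid <- lo + (hi - lo + 1L) %/% 2L
          rec(end, lo, mid - 1L, lev + 1L)
          rec(end, mid, hi, lev + 1L)
        }
      }
      rec(odCenter, 1L, m, 1L)
    }
    emit(-p$arcadeSupDeg)
    emit(+p$arcadeInfDeg)
  }
  # canvas containment check, margin = stroke radius + 1
  for (s in segs) {
    m <- s$diameter / 2 + 1
    r <- range(s$polyline$row); cc <- range(s$polyline$col)
    if (r[1L] < m || r[2L] > canvas[1L] - m + 1 ||
        cc[1L] < m || cc[2L] > canvas[2L] - m + 1)
      stop(sprintf(
        "tree exceeds canvas at level %d (segment length %.1f px); %s",
        s$level, s$chord,
        "increase the canvas or reduce depth/segmentLengthPx"))
  }
  segs
}

#' Generate a synthetic artery/vein image pair with ground truth
#'
#' Draws one complete binary vessel tree per class rooted at the optic disc
#' (veins 15 percent wider and 8 percent longer, with independently jittered
#' sub-arcade branching so crossings between the class rasters arise
#' naturally), and records exhaustive ground truth: per-segment diameters,
#' quadrature tortuosities, arc lengths and midpoints, bifurcation counts
#' (2^depth - 1 per class), arcade angle sum, and per-class vessel pixel
#' counts.
#'
#' @param params a \code{\link{treeParams}} object.
#' @param canvas integer c(rows, cols) canvas size.
#' @param imageId image identifier stamped on the masks.
#' @return list with elements \code{artery}, \code{vein}
#'   (\linkS4class{RasterMask}), \code{od} (\linkS4class{OpticDisc}) and
#'   \code{truth} (class \code{SyntheticTruth}: list with
#'   \code{nBifurcationsPerClass}, \code{segments} data.frame,
#'   \code{trueTemporalAngleDeg}, \code{trueVesselPixelCount},
#'   \code{odCenter}, \code{odRadius}, \code{params}).
#' @examples
#' sv <- generateTree(treeParams(depth = 2, seed = 7))
#' sv$truth$nBifurcationsPerClass
#' @export
generateTree <- function(params, canvas = c(448L, 416L), imageId = "synthetic") {
  stopifnot(inherits(params, "TreeParams"))
  canvas <- as.integer(canvas)
  odCenter <- c(canvas[1L] / 2, round(canvas[2L] * 0.19))
  withSeed(params$seed, {
    layouts <- list(
      artery = layoutTree(params, odCenter, lenFactor = 1, canvas = canvas),
      vein = {
        vp <- params
        vp$rootDiameterPx <- params$rootDiameterPx * 1.15
        layoutTree(vp, odCenter, lenFactor = 1.08, canvas = canvas)
      }
    )
  })
  masks <- list(); truthRows <- list(); pxCount <- c(artery = 0L, vein = 0L)
  for (cls in c("artery", "vein")) {
    segs <- layouts[[cls]]
    grid <- matrix(FALSE, canvas[1L], canvas[2L])
    for (s in segs)
      grid <- grid | strokePixels(s$polyline, s$diameter, canvas)
    masks[[cls]] <- RasterMask(grid, vesselClass = cls, imageId = imageId,
                               scale = 2 * params$odRadiusPx)
    pxCount[cls] <- sum(grid)
    for (i in seq_along(segs)) {
      s <- segs[[i]]
      arc <- polylineLength(s$polyline)
      n <- nrow(s$polyline)
      chord <- sqrt((s$polyline$row[n] - s$polyline$row[1L])^2 +
                    (s$polyline$col[n] - s$polyline$col[1L])^2)
      mid <- s$polyline[ceiling(n / 2), ]
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        class = cls, segment = i, level = s$level,
        true_diameter_px = s$diameter, true_arc_length_px = arc,
        chord_px = chord, true_tortuosity = arc / chord,
        mid_row = mid$row, mid_col = mid$col
      )
    }
  }
  nb <- as.integer(2^params$depth - 1)
  truth <- structure(list(
    nBifurcationsPerClass = c(artery = nb, vein = nb),
    segments = do.call(rbind, truthRows),
    trueTemporalAngleDeg = c(artery = params$arcadeSupDeg + params$arcadeInfDeg,
                             vein = params$arcadeSupDeg + params$arcadeInfDeg),
    trueVesselPixelCount = pxCount,
    odCenter = odCenter, odRadius = params$odRadiusPx,
    params = params
  ), class = "SyntheticTruth")
  list(artery = masks$artery, vein = masks$vein,
       od = OpticDisc(odCenter[1L], odCenter[2L], params$odRadiusPx),
       truth = truth)
}
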