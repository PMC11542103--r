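# Ground-truth validation utilities for the synthetic generator.

#' Match measured graph segments to generator ground truth
#'
#' For each true segment of the graph's class, finds the measured centerline
#' point nearest to the true segment midpoint and reports the owning measured
#' segment's median diameter and tortuosity next to the true values.
#'
#' @param graph pruned, caliber-annotated \linkS4class{VesselGraph}.
#' @param truth \code{SyntheticTruth} from \code{\link{generateTree}}.
#' @param maxDist matches farther than this (px) are dropped.
#' @param minChordPx tortuosity eligibility passed through to
#'   \code{\link{segmentTortuosity}}.
#' @return data.frame: level, true_diameter_px, measured_diameter_px,
#'   true_tortuosity, measured_tortuosity, match_dist_px.
#' @export
matchTruthSegments <- function(graph, truth, maxDist = 4, minChordPx = 10) {
  stopifnot(is(graph, "VesselGraph"), inherits(truth, "SyntheticTruth"))
  segs <- graph@segments
  if (!length(segs)) return(NULL)
  ptSeg <- rep(seq_along(segs), vapply(segs, nrow, integer(1)))
  ptR <- unlist(lapply(segs, `[[`, "row"), use.names = FALSE)
  ptC <- unlist(lapply(segs, `[[`, "col"), use.names = FALSE)
  medDiam <- vapply(segs, function(s)
    if (is.null(s$diameter)) NA_real_ else stats::median(s$diameter),
    numeric(1))
  tort <- vapply(segs, segmentTortuosity, numeric(1), minChordPx = minChordPx)
  tr <- truth$segments[truth$segments$class == graph@vesselClass, ,
                       drop = FALSE]
  out <- lapply(seq_len(nrow(tr)), function(i) {
    d2 <- (ptR - tr$mid_row[i])^2 + (ptC - tr$mid_col[i])^2
    j <- which.min(d2)
    data.frame(level = tr$level[i],
               true_diameter_px = tr$true_diameter_px[i],
               measured_diameter_px = medDiam[ptSeg[j]],
               true_tortuosity = tr$true_tortuosity[i],
               measured_tortuosity = tort[ptSeg[j]],
               match_dist_px = sqrt(d2[j]))
  })
  out <- do.call(rbind, out)
  out[out$match_dist_px <= maxDist, , drop = FALSE]
}

# Draw randomized but canvas-safe generator parameters.
randomTreeParams <- function(seed) {
  withSeed(seed, {
    depth <- sample(2:4, 1L)
    deep <- depth == 4L
    treeParams(
      depth = depth,
      rootDiameterPx = if (deep) stats::runif(1, 11, 14)
        else stats::runif(1, 10, 16),
      branchHalfAngleDeg = stats::runif(1, 25, 30),
      segmentLengthPx = if (deep) stats::runif(1, 44, 48)
        else stats::runif(1, 46, 56),
      tortuosityAmplitude = if (deep) stats::runif(1, 0, 2)
        else stats::runif(1, 0, 3),
      tortuosityWavelengthPx = stats::runif(1, 35, 60),
      arcadeSupDeg = stats::runif(1, 45, 62),
      arcadeInfDeg = stats::runif(1, 45, 62),
      seed = seed
    )
  })
}

# Canvas large enough for a tree of the given depth at batch parameter ranges.
canvasFor <- function(depth) {
  if (depth >= 4L) c(576L, 512L) else c(448L, 416L)
}

#' Measured-vs-true recovery over a batch of synthetic images
#'
#' Generates \code{nImages} randomized synthetic images (depth 2-4, varying
#' calibers, tortuosity amplitudes and arcade angles), runs the image-domain
#' pipeline on each, and collects measured against true bifurcation counts,
#' median tortuosities, temporal angles and matched per-segment diameters.
#'
#' @param nImages number of images.
#' @param seed integer master seed (per-image seeds derive from it).
#' @param canvas canvas size; NULL (default) picks a canvas fitting each
#'   image's tree depth.
#' @return list with \code{perImage} (one row per image: true/measured
#'   bifurcations, tortuosity medians, temporal angle and truth angle) and
#'   \code{perSegment} (matched diameter table across all images).
#' @export
syntheticRecovery <- function(nImages = 200L, seed = 1L, canvas = NULL) {
  perImage <- vector("list", nImages)
  perSegment <- vector("list", nImages)
  for (i in seq_len(nImages)) {
    p <- randomTreeParams(seed = (seed * 1000L + i) %% 2147483647L)
    cv <- if (is.null(canvas)) canvasFor(p$depth) else canvas
    sv <- generateTree(p, canvas = cv, imageId = sprintf("img%03d", i))
    gA <- traceClassGraph(sv$artery)
    gV <- traceClassGraph(sv$vein)
    trA <- sv$truth$segments[sv$truth$segments$class == "artery", ]
    trueTortA <- stats::median(trA$true_tortuosity[trA$chord_px >= 10])
    perImage[[i]] <- data.frame(
      image = i, depth = p$depth,
      true_bifurcations = sum(sv$truth$nBifurcationsPerClass),
      measured_bifurcations = countBifurcations(gA, gV),
      true_tortuosity = trueTortA,
      measured_tortuosity = medianTortuosity(gA),
      true_angle = sv$truth$trueTemporalAngleDeg[["artery"]],
      measured_angle = temporalAngle(gA, sv$od),
      a_density = vascularDensity(sv$artery,
                                  defaultDensityROI(cv, sv$od))
    )
    m <- matchTruthSegments(gA, sv$truth)
    if (!is.null(m) && nrow(m)) perSegment[[i]] <- cbind(image = i, m)
  }
  list(perImage = do.call(rbind, perImage),
       perSegment = do.call(rbind, perSegment))
}
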