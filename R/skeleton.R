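# Topology-preserving thinning of binary vessel masks.

#' Skeletonize a binary mask
#'
#' Zhang-Suen iterative thinning: two subiterations per pass delete border
#' pixels that have 2..6 foreground 8-neighbours, exactly one 0-to-1
#' transition around the neighbourhood, and pass the directional conditions;
#' iteration stops when no pixel is deleted. The result is a 1-px-wide,
#' 8-connected, topology-preserving skeleton. Empty masks pass through.
#'
#' @param mask a \linkS4class{RasterMask}.
#' @return A \linkS4class{RasterMask} holding the skeleton (same class and
#'   image id).
#' @examples
#' m <- matrix(FALSE, 9, 40); m[4:6, 3:38] <- TRUE
#' sk <- skeletonize(RasterMask(m))
#' maskPixelCount(sk)
#' @export
skeletonize <- function(mask) {
  stopifnot(is(mask, "RasterMask"))
  px <- mask@pixels
  if (!any(px))
    return(RasterMask(px, vesselClass = mask@vesselClass,
                      imageId = mask@imageId, scale = mask@scale))
  # pad with a 1-px background border so neighbour index arithmetic is safe;
  # per pass only foreground pixels are examined (index-based, not full-grid)
  nr <- nrow(px) + 2L
  M <- matrix(FALSE, nr, ncol(px) + 2L)
  M[2:(nr - 1L), 2:(ncol(px) + 1L)] <- px
  # ring order P2..P9 = N, NE, E, SE, S, SW, W, NW (column-major offsets)
  off <- c(-1L, nr - 1L, nr, nr + 1L, 1L, 1L - nr, -nr, -nr - 1L)
  repeat {
    deleted <- FALSE
    for (step in 1:2) {
      cand <- which(M)
      nb <- matrix(FALSE, length(cand), 8L)
      for (j in 1:8) nb[, j] <- M[cand + off[j]]
      B <- rowSums(nb)
      A <- rowSums(!nb & nb[, c(2:8, 1L)])
      del <- B >= 2 & B <= 6 & A == 1
      if (step == 1L)
        del <- del & !(nb[, 1L] & nb[, 3L] & nb[, 5L]) &
                     !(nb[, 3L] & nb[, 5L] & nb[, 7L])
      else
        del <- del & !(nb[, 1L] & nb[, 3L] & nb[, 7L]) &
                     !(nb[, 1L] & nb[, 5L] & nb[, 7L])
      if (any(del)) {
        M[cand[del]] <- FALSE
        deleted <- TRUE
      }
    }
    if (!deleted) break
  }
  RasterMask(M[2:(nr - 1L), 2:(ncol(px) + 1L)],
             vesselClass = mask@vesselClass,
             imageId = mask@imageId, scale = mask@scale)
}
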