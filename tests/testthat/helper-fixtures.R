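# Small raster fixtures built in code.

# horizontal bar of given width (rows) and length (cols)
barMask <- function(width = 3L, len = 50L, pad = 6L, vesselClass = "none") {
  m <- matrix(FALSE, width + 2L * pad, len + 2L * pad)
  m[pad + seq_len(width), pad + seq_len(len)] <- TRUE
  RasterMask(m, vesselClass = vesselClass)
}

# "Y": vertical stem meeting two diagonal arms
yMask <- function() {
  m <- matrix(FALSE, 80L, 80L)
  m[40:75, 39:41] <- TRUE                       # stem
  for (i in 0:30) {
    m[40 - i, (39:41) - i] <- TRUE              # left arm
    m[40 - i, (39:41) + i] <- TRUE              # right arm
  }
  RasterMask(m)
}

# "+": two crossing strokes in one class
plusMask <- function() {
  m <- matrix(FALSE, 81L, 81L)
  m[39:41, 6:76] <- TRUE
  m[6:76, 39:41] <- TRUE
  RasterMask(m)
}

# filled disk
diskMask <- function(radius = 10L, pad = 5L) {
  n <- 2L * (radius + pad) + 1L
  ctr <- radius + pad + 1L
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  RasterMask((rows - ctr)^2 + (cols - ctr)^2 <= radius^2)
}

# trace one class mask end to end (exported-surface composition)
traceMask <- function(mask, minSpurPx = 10) {
  g <- pruneSpurs(buildVesselGraph(skeletonize(mask)), minSpurPx)
  measureDiameters(g, mask)
}

# hand-built VesselGraph from a list of point data.frames (diameters optional)
craftGraph <- function(segments, vesselClass = "artery", dims = c(200L, 200L)) {
  nodes <- do.call(rbind, lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    data.frame(id = c(2L * i - 1L, 2L * i),
               row = c(s$row[1L], s$row[nrow(s)]),
               col = c(s$col[1L], s$col[nrow(s)]),
               kind = "endpoint", degree = 1L)
  }))
  info <- data.frame(id = seq_along(segments),
                     node1 = 2L * seq_along(segments) - 1L,
                     node2 = 2L * seq_along(segments),
                     length = vapply(segments, function(s)
                       sum(sqrt(diff(s$row)^2 + diff(s$col)^2)), numeric(1)))
  new("VesselGraph", nodes = nodes, segments = segments, segmentInfo = info,
      vesselClass = vesselClass, imageId = "crafted", dims = as.integer(dims),
      junctionPixels = matrix(integer(), 0L, 2L,
                              dimnames = list(NULL, c("row", "col"))))
}

# straight radial segment from a center, with constant diameter
radialSegment <- function(center, angleDeg, from, to, diameter, n = 60L) {
  t <- seq(from, to, length.out = n)
  a <- angleDeg * pi / 180
  data.frame(row = center[1L] + t * sin(a), col = center[2L] + t * cos(a),
             diameter = rep(diameter, n))
}

# nearest-neighbour 2x upscaling
upscaleMask <- function(mask) {
  m <- maskPixels(mask)
  RasterMask(m[rep(seq_len(nrow(m)), each = 2L),
               rep(seq_len(ncol(m)), each = 2L)],
             vesselClass = vesselClass(mask), imageId = imageId(mask))
}
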