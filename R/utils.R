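# Internal geometry / raster helpers.

# Shift a matrix by (dr, dc), zero-filling exposed cells.
shiftMatrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Euclidean length of an ordered polyline given as matrix/data.frame (row, col).
polylineLength <- function(pts) {
  r <- pts[[1L]]; c <- pts[[2L]]
  n <- length(r)
  if (n < 2L) return(0)
  sum(sqrt(diff(r)^2 + diff(c)^2))
}

# Moving-average smoothing of a centerline (window must be odd); endpoints kept.
smoothPolyline <- function(pts, window = 3L) {
  n <- nrow(pts)
  if (window <= 1L || n <= window) return(pts)
  half <- (window - 1L) %/% 2L
  sm <- function(v) {
    out <- stats::filter(v, rep(1 / window, window), sides = 2)
    out <- as.numeric(out)
    out[seq_len(half)] <- v[seq_len(half)]
    out[(n - half + 1L):n] <- v[(n - half + 1L):n]
    out
  }
  data.frame(row = sm(pts$row), col = sm(pts$col))
}

# Densify a polyline so consecutive points are at most `step` apart.
densifyPolyline <- function(pts, step = 0.25) {
  r <- pts[[1L]]; c <- pts[[2L]]
  n <- length(r)
  if (n < 2L) return(cbind(row = r, col = c))
  outR <- list(); outC <- list()
  for (i in seq_len(n - 1L)) {
    d <- sqrt((r[i + 1L] - r[i])^2 + (c[i + 1L] - c[i])^2)
    k <- max(1L, ceiling(d / step))
    t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    outR[[i]] <- r[i] + t * (r[i + 1L] - r[i])
    outC[[i]] <- c[i] + t * (c[i + 1L] - c[i])
  }
  cbind(row = c(unlist(outR), r[n]), col = c(unlist(outC), c[n]))
}

# Set of raster pixels within `radius` of the densified polyline: the union of
# disks of that radius centered on the polyline, computed with the Euclidean
# distance transform of the marked centerline pixels.
strokePixels <- function(pts, diameter, dims) {
  stopifnot(diameter >= 1)
  dense <- densifyPolyline(pts, step = 0.25)
  rr <- round(dense[, "row"]); cc <- round(dense[, "col"])
  keep <- rr >= 1 & rr <= dims[1L] & cc <= dims[2L] & cc >= 1
  rr <- rr[keep]; cc <- cc[keep]
  out <- matrix(FALSE, dims[1L], dims[2L])
  if (!length(rr)) return(out)
  if (diameter < 1.5) {
    # near-1-px strokes reduce to the digital centerline: 1-px arc steps
    # give an 8-connected, 1-px-wide path
    d1 <- densifyPolyline(pts, step = 1)
    r1 <- round(d1[, "row"]); c1 <- round(d1[, "col"])
    ok <- r1 >= 1 & r1 <= dims[1L] & c1 >= 1 & c1 <= dims[2L]
    out[cbind(r1[ok], c1[ok])] <- TRUE
    return(out)
  }
  # distance transform only on the stroke's bounding box
  pad <- ceiling(diameter / 2) + 2L
  r0 <- max(1L, min(rr) - pad); r1 <- min(dims[1L], max(rr) + pad)
  c0 <- max(1L, min(cc) - pad); c1 <- min(dims[2L], max(cc) + pad)
  center <- matrix(TRUE, r1 - r0 + 1L, c1 - c0 + 1L)
  center[cbind(rr - r0 + 1L, cc - c0 + 1L)] <- FALSE
  # distmap gives, for each TRUE pixel, the distance to the nearest FALSE pixel
  d <- EBImage::distmap(EBImage::Image(center * 1), metric = "euclidean")
  out[r0:r1, c0:c1] <- as.matrix(d) <= diameter / 2
  out
}

# Polynomial rolling hash of a character scalar (hex string); used only as a
# config fingerprint in logs.
configHash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

firstNonMissing <- function(...) {
  for (v in list(...)) if (!is.null(v) && !all(is.na(v))) return(v)
  NA
}
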