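# Vessel graph extraction from 1-px skeletons: node detection, segment
# tracing, junction-cluster merging, spur pruning and caliber measurement.

# 8-neighbour offsets (row, col)
NB8 <- cbind(
  dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
  dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
)

# Reduced-adjacency neighbour count: 8-connectivity minus redundant diagonal
# links. A diagonal link p-q is redundant when one of the two orthogonal
# stepping stones between them is itself a skeleton pixel; thinning staircases
# otherwise masquerade as junctions on raw 8-neighbour counts.
neighbourCount <- function(M) {
  deg <- shiftMatrix(M, 1, 0) + shiftMatrix(M, -1, 0) +
    shiftMatrix(M, 0, 1) + shiftMatrix(M, 0, -1)
  for (d in list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
    q <- shiftMatrix(M, d[1L], d[2L])
    stone <- shiftMatrix(M, d[1L], 0) + shiftMatrix(M, 0, d[2L])
    deg <- deg + q * (stone == 0)
  }
  deg
}

# Reduced-adjacency test for a single pixel pair (assumes both foreground).
reducedAdjacent <- function(M, r1, c1, r2, c2) {
  dr <- r2 - r1; dc <- c2 - c1
  if (abs(dr) > 1L || abs(dc) > 1L) return(FALSE)
  if (dr == 0L || dc == 0L) return(TRUE)
  !(M[r1 + dr, c1] || M[r1, c1 + dc])
}

emptyVesselGraph <- function(vesselClass, imageId, dims) {
  new("VesselGraph",
      nodes = data.frame(id = integer(), row = numeric(), col = numeric(),
                         kind = character(), degree = integer()),
      segments = list(),
      segmentInfo = data.frame(id = integer(), node1 = integer(),
                               node2 = integer(), length = numeric()),
      vesselClass = vesselClass, imageId = imageId, dims = dims,
      junctionPixels = matrix(integer(), 0L, 2L,
                              dimnames = list(NULL, c("row", "col"))))
}

#' Build a vessel graph from a skeleton
#'
#' Skeleton pixels with a number of 8-neighbours different from 2 become node
#' pixels; node pixels within Chebyshev distance 2 of each other are merged
#' into one node at their centroid (thinning leaves small branch-point
#' clusters). Segments are the maximal node-to-node 8-connected paths, kept as
#' ordered pixel lists. Cycles without any node pixel get a synthetic degree-2
#' node. Node kinds follow the merged degree: 1 = \code{endpoint},
#' 3 = \code{bifurcation}, >= 4 = \code{crossing_candidate} (within-class
#' crossings are not bifurcations), 2 = \code{internal}.
#'
#' @param skeleton a \linkS4class{RasterMask} holding a 1-px skeleton
#'   (see \code{\link{skeletonize}}).
#' @param mergeChebyshev cluster radius for junction merging (px).
#' @return A \linkS4class{VesselGraph}.
#' @examples
#' m <- matrix(FALSE, 9, 40); m[5, 3:38] <- TRUE
#' g <- buildVesselGraph(RasterMask(m))
#' nrow(graphNodes(g))  # two endpoints
#' @export
buildVesselGraph <- function(skeleton, mergeChebyshev = 2L) {
  stopifnot(is(skeleton, "RasterMask"))
  M <- skeleton@pixels
  dims <- dim(M)
  if (!any(M))
    return(emptyVesselGraph(skeleton@vesselClass, skeleton@imageId, dims))
  deg <- neighbourCount(M * 1)
  isNode <- M & deg != 2
  isEdge <- M & deg == 2
  nbrsOf <- function(r, c) {
    rr <- r + NB8[, "dr"]; cc <- c + NB8[, "dc"]
    ok <- rr >= 1L & rr <= dims[1L] & cc >= 1L & cc <= dims[2L]
    rr <- rr[ok]; cc <- cc[ok]
    keep <- M[cbind(rr, cc)]
    rr <- rr[keep]; cc <- cc[keep]
    if (length(rr)) {
      red <- vapply(seq_along(rr), function(i)
        reducedAdjacent(M, r, c, rr[i], cc[i]), logical(1))
      rr <- rr[red]; cc <- cc[red]
    }
    cbind(rr, cc)
  }
  visited <- matrix(FALSE, dims[1L], dims[2L])
  paths <- list()
  nodePix <- which(isNode, arr.ind = TRUE)
  lin <- function(r, c) (c - 1L) * dims[1L] + r
  # walk from a node pixel into an edge pixel until the next node pixel
  walk <- function(r0, c0, r1, c1) {
    pr <- c(r0, r1); pc <- c(c0, c1)
    visited[r1, c1] <<- TRUE
    prevR <- r0; prevC <- c0; curR <- r1; curC <- c1
    repeat {
      nb <- nbrsOf(curR, curC)
      sel <- !(nb[, 1L] == prevR & nb[, 2L] == prevC)
      nb <- nb[sel, , drop = FALSE]
      if (nrow(nb) == 0L) break  # dangling (shouldn't happen on deg-2 paths)
      nr <- nb[1L, 1L]; nc <- nb[1L, 2L]
      pr <- c(pr, nr); pc <- c(pc, nc)
      if (isNode[nr, nc]) break
      visited[nr, nc] <<- TRUE
      prevR <- curR; prevC <- curC; curR <- nr; curC <- nc
    }
    cbind(row = pr, col = pc)
  }
  if (nrow(nodePix)) {
    for (i in seq_len(nrow(nodePix))) {
      r0 <- nodePix[i, 1L]; c0 <- nodePix[i, 2L]
      nb <- nbrsOf(r0, c0)
      for (j in seq_len(nrow(nb))) {
        r1 <- nb[j, 1L]; c1 <- nb[j, 2L]
        if (isNode[r1, c1]) {
          if (lin(r0, c0) < lin(r1, c1))
            paths[[length(paths) + 1L]] <-
              cbind(row = c(r0, r1), col = c(c0, c1))
        } else if (!visited[r1, c1]) {
          paths[[length(paths) + 1L]] <- walk(r0, c0, r1, c1)
        }
      }
    }
  }
  # pure cycles: unvisited degree-2 pixels with no node pixel on the loop
  cyc <- which(isEdge & !visited, arr.ind = TRUE)
  while (nrow(cyc)) {
    r0 <- cyc[1L, 1L]; c0 <- cyc[1L, 2L]
    isNode[r0, c0] <- TRUE  # synthetic loop anchor
    nb <- nbrsOf(r0, c0)
    paths[[length(paths) + 1L]] <- walk(r0, c0, nb[1L, 1L], nb[1L, 2L])
    nodePix <- rbind(nodePix, cbind(row = r0, col = c0))
    cyc <- which(isEdge & !visited & !isNode, arr.ind = TRUE)
  }
  # ---- merge node pixels within Chebyshev distance <= mergeChebyshev ----
  nn <- nrow(nodePix)
  parent <- seq_len(max(nn, 1L))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nodeAt <- matrix(0L, dims[1L], dims[2L])
  if (nn) nodeAt[nodePix] <- seq_len(nn)
  if (nn > 1L) {
    for (i in seq_len(nn)) {
      r <- nodePix[i, 1L]; c <- nodePix[i, 2L]
      rs <- max(1L, r - mergeChebyshev):min(dims[1L], r + mergeChebyshev)
      cs <- max(1L, c - mergeChebyshev):min(dims[2L], c + mergeChebyshev)
      js <- nodeAt[rs, cs]
      for (j in js[js > 0L & js < i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  clusterOf <- if (nn) vapply(seq_len(nn), find, integer(1)) else integer()
  clusterIds <- unique(clusterOf)
  clusterMap <- match(clusterOf, clusterIds)  # node pixel -> cluster index
  nClust <- length(clusterIds)
  cRow <- vapply(seq_len(nClust), function(k)
    mean(nodePix[clusterMap == k, 1L]), numeric(1))
  cCol <- vapply(seq_len(nClust), function(k)
    mean(nodePix[clusterMap == k, 2L]), numeric(1))
  # ---- classify paths: real segments vs junction-internal connections ----
  segs <- list(); info <- list(); junction <- list()
  for (p in paths) {
    n <- nrow(p)
    e1 <- nodeAt[p[1L, 1L], p[1L, 2L]]
    e2 <- nodeAt[p[n, 1L], p[n, 2L]]
    k1 <- if (e1 > 0L) clusterMap[e1] else NA_integer_
    k2 <- if (e2 > 0L) clusterMap[e2] else NA_integer_
    if (!is.na(k1) && !is.na(k2) && k1 == k2 &&
        n <= 2L * mergeChebyshev + 1L && !identical(p[1L, ], p[n, ])) {
      junction[[length(junction) + 1L]] <- p  # short intra-cluster path
    } else {
      segs[[length(segs) + 1L]] <- data.frame(row = as.numeric(p[, 1L]),
                                              col = as.numeric(p[, 2L]))
      info[[length(info) + 1L]] <- data.frame(
        id = length(segs), node1 = k1, node2 = k2,
        length = polylineLength(data.frame(p[, 1L], p[, 2L])))
    }
  }
  info <- if (length(info)) do.call(rbind, info) else
    data.frame(id = integer(), node1 = integer(), node2 = integer(),
               length = numeric())
  degree <- integer(nClust)
  if (nrow(info))
    for (k in seq_len(nClust))
      degree[k] <- sum(info$node1 == k) + sum(info$node2 == k)
  kind <- ifelse(degree == 1L, "endpoint",
          ifelse(degree == 3L, "bifurcation",
          ifelse(degree >= 4L, "crossing_candidate", "internal")))
  nodes <- data.frame(id = seq_len(nClust), row = cRow, col = cCol,
                      kind = kind, degree = degree)
  # unused isolated single-pixel nodes (degree 0) are dropped; their pixels go
  # to the junction ledger so the skeleton stays reconstructible
  drop <- nodes$degree == 0L & nodes$kind == "internal"
  if (any(drop)) {
    for (k in nodes$id[drop]) {
      mem <- nodePix[clusterMap == k, , drop = FALSE]
      junction[[length(junction) + 1L]] <- mem
    }
    keepIds <- nodes$id[!drop]
    remap <- match(seq_len(nClust), keepIds)
    nodes <- nodes[!drop, , drop = FALSE]
    nodes$id <- seq_len(nrow(nodes))
    info$node1 <- remap[info$node1]
    info$node2 <- remap[info$node2]
  }
  jm <- if (length(junction)) {
    jj <- do.call(rbind, junction)
    colnames(jj) <- c("row", "col")
    storage.mode(jj) <- "integer"
    jj
  } else matrix(integer(), 0L, 2L, dimnames = list(NULL, c("row", "col")))
  g <- new("VesselGraph", nodes = nodes, segments = segs, segmentInfo = info,
           vesselClass = skeleton@vesselClass, imageId = skeleton@imageId,
           dims = dims, junctionPixels = jm)
  g <- absorbSmallLoops(g, minLoopPx = 15)
  g <- contractShortBars(g, maxBarPx = 15)
  dissolveInternalNodes(g)
}

# Wide junctions can thin into two or three nearby branch pixels connected by
# short "bars" (or triangles) instead of a single branch point. Contract any
# segment shorter than maxBarPx joining two distinct nodes of degree >= 3:
# the pair collapses to one node at their midpoint and all parallel bars
# between them are absorbed as junction pixels. Iterates shortest-first.
contractShortBars <- function(g, maxBarPx = 15) {
  repeat {
    info <- g@segmentInfo
    if (!nrow(info)) return(g)
    deg <- vapply(g@nodes$id, function(k)
      sum(info$node1 == k) + sum(info$node2 == k), integer(1))
    names(deg) <- g@nodes$id
    cand <- which(info$node1 != info$node2 & info$length < maxBarPx &
                    deg[as.character(info$node1)] >= 3L &
                    deg[as.character(info$node2)] >= 3L)
    if (!length(cand)) return(g)
    i <- cand[which.min(info$length[cand])]
    u <- info$node1[i]; v <- info$node2[i]
    bars <- which((info$node1 == u & info$node2 == v) |
                    (info$node1 == v & info$node2 == u))
    add <- do.call(rbind, lapply(g@segments[bars], function(s)
      cbind(row = as.integer(round(s$row)), col = as.integer(round(s$col)))))
    g@junctionPixels <- rbind(g@junctionPixels, add)
    g@segments <- g@segments[-bars]
    info <- info[-bars, , drop = FALSE]
    iu <- g@nodes$id == u; iv <- g@nodes$id == v
    g@nodes$row[iu] <- (g@nodes$row[iu] + g@nodes$row[iv]) / 2
    g@nodes$col[iu] <- (g@nodes$col[iu] + g@nodes$col[iv]) / 2
    info$node1[info$node1 == v] <- u
    info$node2[info$node2 == v] <- u
    keep <- !iv
    remap <- match(g@nodes$id, g@nodes$id[keep])
    g@nodes <- g@nodes[keep, , drop = FALSE]
    info$node1 <- remap[info$node1]
    info$node2 <- remap[info$node2]
    g@nodes$id <- seq_len(nrow(g@nodes))
    info$id <- seq_len(nrow(info))
    g@segmentInfo <- info
  }
}

# Self-loops shorter than minLoopPx are holes left by thinning inside wide
# junctions, not vessel loops: drop them into the junction pixel ledger so
# the junction's kind reflects its true branch count.
absorbSmallLoops <- function(g, minLoopPx = 15) {
  info <- g@segmentInfo
  small <- which(info$node1 == info$node2 & info$length < minLoopPx)
  if (!length(small)) return(g)
  add <- do.call(rbind, lapply(g@segments[small], function(s)
    cbind(row = as.integer(round(s$row)), col = as.integer(round(s$col)))))
  g@junctionPixels <- rbind(g@junctionPixels, add)
  g@segments <- g@segments[-small]
  info <- info[-small, , drop = FALSE]
  info$id <- seq_len(nrow(info))
  g@segmentInfo <- info
  g
}

# Merge the two segments meeting at every degree-2 "internal" node (thinning
# artifacts absorbed into clusters fragment otherwise-maximal paths); loop
# anchors (node1 == node2) are kept.
dissolveInternalNodes <- function(g) {
  repeat {
    info <- g@segmentInfo
    nd <- g@nodes
    cand <- nd$id[nd$degree == 2L & nd$kind == "internal"]
    done <- TRUE
    for (nid in cand) {
      at <- which(info$node1 == nid | info$node2 == nid)
      if (length(at) != 2L) next  # loop anchor (one segment twice)
      i1 <- at[1L]; i2 <- at[2L]
      s1 <- g@segments[[i1]]; s2 <- g@segments[[i2]]
      if (info$node2[i1] != nid) { s1 <- s1[rev(seq_len(nrow(s1))), ]
        info$node1[i1] <- info$node2[i1] }
      if (info$node1[i2] != nid) s2 <- s2[rev(seq_len(nrow(s2))), ]
      other2 <- if (info$node1[i2] == nid) info$node2[i2] else info$node1[i2]
      if (s1$row[nrow(s1)] == s2$row[1L] && s1$col[nrow(s1)] == s2$col[1L])
        s2 <- s2[-1L, , drop = FALSE]
      merged <- rbind(s1, s2)
      rownames(merged) <- NULL
      g@segments[[i1]] <- merged
      info$node2[i1] <- other2
      info$length[i1] <- polylineLength(merged[, c("row", "col")])
      g@segments[[i2]] <- NULL
      info <- info[-i2, , drop = FALSE]
      info$id <- seq_len(nrow(info))
      g@segmentInfo <- info
      done <- FALSE
      break
    }
    if (done) break
  }
  # recompute degrees/kinds and drop orphaned nodes
  info <- g@segmentInfo
  nd <- g@nodes
  deg <- vapply(nd$id, function(k)
    sum(info$node1 == k) + sum(info$node2 == k), integer(1))
  nd$degree <- deg
  nd$kind <- ifelse(deg == 1L, "endpoint",
             ifelse(deg == 3L, "bifurcation",
             ifelse(deg >= 4L, "crossing_candidate", "internal")))
  keep <- deg > 0L
  if (!all(keep)) {
    remap <- match(nd$id, nd$id[keep])
    nd <- nd[keep, , drop = FALSE]
    info$node1 <- remap[info$node1]
    info$node2 <- remap[info$node2]
    nd$id <- seq_len(nrow(nd))
  }
  g@nodes <- nd
  g@segmentInfo <- info
  g
}

# Rebuild the skeleton raster a graph was traced from.
reconstructSkeleton <- function(graph) {
  M <- matrix(FALSE, graph@dims[1L], graph@dims[2L])
  for (s in graph@segments) M[cbind(s$row, s$col)] <- TRUE
  if (nrow(graph@junctionPixels)) M[graph@junctionPixels] <- TRUE
  M
}

#' Remove short terminal spurs from a vessel graph
#'
#' Terminal segments (exactly one end is a degree-1 node) shorter than
#' \code{minSpurPx} are removed at the pixel level and the graph is retraced,
#' so junctions that lose their third branch dissolve and their two remaining
#' segments merge. Iterates to a fixed point, hence idempotent. Isolated
#' segments (both ends free) are never removed.
#'
#' @param graph a \linkS4class{VesselGraph}.
#' @param minSpurPx spur length threshold in pixels (default 10, suppressing
#'   thinning artifacts at typical fundus resolutions).
#' @return A pruned \linkS4class{VesselGraph}.
#' @export
pruneSpurs <- function(graph, minSpurPx = 10) {
  stopifnot(is(graph, "VesselGraph"))
  repeat {
    info <- graph@segmentInfo
    if (!nrow(info)) return(graph)
    deg <- graph@nodes$degree[match(c(info$node1, info$node2),
                                    graph@nodes$id)]
    d1 <- deg[seq_len(nrow(info))]
    d2 <- deg[nrow(info) + seq_len(nrow(info))]
    isSpur <- ((d1 == 1L) + (d2 == 1L)) == 1L & info$length < minSpurPx
    if (!any(isSpur)) return(graph)
    keepPix <- matrix(FALSE, graph@dims[1L], graph@dims[2L])
    for (i in which(!isSpur)) {
      s <- graph@segments[[i]]
      keepPix[cbind(s$row, s$col)] <- TRUE
    }
    if (nrow(graph@junctionPixels)) keepPix[graph@junctionPixels] <- TRUE
    M <- reconstructSkeleton(graph)
    for (i in which(isSpur)) {
      s <- graph@segments[[i]]
      rm <- !keepPix[cbind(s$row, s$col)]
      M[cbind(s$row[rm], s$col[rm])] <- FALSE
    }
    graph <- buildVesselGraph(
      RasterMask(M, vesselClass = graph@vesselClass,
                 imageId = graph@imageId))
  }
}

#' Measure per-point vessel calibers along a graph's centerlines
#'
#' Samples the Euclidean distance transform of the class mask at every
#' centerline pixel; the per-point diameter is twice the distance to the mask
#' boundary, 2 * (EDT - 0.5), where EDT is the distance to the nearest
#' background pixel center. Before sampling, terminal segments are extended
#' along their end direction while they remain inside the mask foreground,
#' compensating the tip erosion of iterative thinning (about half the vessel
#' width per end).
#'
#' @param graph a \linkS4class{VesselGraph} traced from \code{mask}'s
#'   skeleton.
#' @param mask the originating \linkS4class{RasterMask}.
#' @param extendTips logical; extend free segment ends into the mask
#'   (default TRUE).
#' @return The graph with a \code{diameter} column added to every segment.
#' @export
measureDiameters <- function(graph, mask, extendTips = TRUE) {
  stopifnot(is(graph, "VesselGraph"), is(mask, "RasterMask"))
  if (!length(graph@segments)) return(graph)
  if (!identical(graph@dims, dim(mask@pixels)))
    stop("centerline point outside mask foreground: graph/mask mismatch")
  edt <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask@pixels * 1),
                                             metric = "euclidean"))
  if (extendTips) graph <- extendTerminalSegments(graph, mask@pixels, edt)
  segs <- graph@segments
  for (i in seq_along(segs)) {
    d <- edt[cbind(segs[[i]]$row, segs[[i]]$col)]
    if (any(d == 0))
      stop("centerline point outside mask foreground: graph/mask mismatch")
    segs[[i]]$diameter <- 2 * d - 1
  }
  graph@segments <- segs
  graph
}

# Extend every segment end attached to a degree-1 node along the local end
# direction, one pixel step at a time, while the stepped pixel stays in the
# mask foreground; capped at the local vessel radius + 2 px.
extendTerminalSegments <- function(graph, px, edt) {
  deg1 <- graph@nodes$id[graph@nodes$degree == 1L]
  info <- graph@segmentInfo
  dims <- dim(px)
  for (i in seq_len(nrow(info))) {
    for (end in c(1L, 2L)) {
      nid <- if (end == 1L) info$node1[i] else info$node2[i]
      if (!(nid %in% deg1)) next
      s <- graph@segments[[i]]
      n <- nrow(s)
      if (n < 3L) next
      if (end == 1L) s <- s[rev(seq_len(n)), ]  # work on the tail
      k <- min(5L, n - 1L)
      dir <- c(s$row[n] - s$row[n - k], s$col[n] - s$col[n - k])
      len <- sqrt(sum(dir^2))
      if (len == 0) next
      dir <- dir / len
      cap <- ceiling(edt[round(s$row[n]), round(s$col[n])]) + 2L
      addR <- numeric(); addC <- numeric()
      for (t in seq_len(cap)) {
        r <- s$row[n] + t * dir[1L]; c <- s$col[n] + t * dir[2L]
        ri <- round(r); ci <- round(c)
        if (ri < 1L || ri > dims[1L] || ci < 1L || ci > dims[2L] ||
            !px[ri, ci]) break
        addR <- c(addR, ri); addC <- c(addC, ci)
      }
      if (!length(addR)) next
      keep <- !duplicated(cbind(addR, addC)) &
        !(addR == s$row[n] & addC == s$col[n])
      ext <- data.frame(row = addR[keep], col = addC[keep])
      if (!nrow(ext)) next
      s <- rbind(s, ext)
      if (end == 1L) s <- s[rev(seq_len(nrow(s))), ]
      rownames(s) <- NULL
      graph@segments[[i]] <- s
      info$length[i] <- polylineLength(s[, c("row", "col")])
      # move the endpoint node to the new tip
      tip <- if (end == 1L) s[1L, ] else s[nrow(s), ]
      at <- graph@nodes$id == nid
      graph@nodes$row[at] <- tip$row
      graph@nodes$col[at] <- tip$col
    }
  }
  graph@segmentInfo <- info
  graph
}
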