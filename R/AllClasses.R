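#' @import methods
NULL

#' Binary vessel raster for one vessel class
#'
#' A per-class binary segmentation raster on a pixel grid. The grid is 0-based
#' conceptually (row, col), origin top-left, y increasing downward; internally
#' pixels are stored as an R logical matrix (1-based indexing) and all
#' serialized coordinates are 0-based.
#'
#' @slot pixels logical matrix, \code{TRUE} = vessel.
#' @slot imageId character scalar identifying the source image.
#' @slot vesselClass one of \code{"artery"}, \code{"vein"}, \code{"none"}
#'   (class-agnostic rasters such as ROIs or skeletons).
#' @slot scale optional pixels-per-disc-diameter scale (\code{NA} if unknown).
#'
#' @exportClass RasterMask
setClass("RasterMask",
  representation(
    pixels = "matrix",
    imageId = "character",
    vesselClass = "character",
    scale = "numeric"
  ),
  prototype(imageId = "image", vesselClass = "none", scale = NA_real_)
)

setValidity("RasterMask", function(object) {
  msgs <- character()
  if (!is.logical(object@pixels))
    msgs <- c(msgs, "pixels must be a logical matrix")
  if (length(object@vesselClass) != 1L ||
      !object@vesselClass %in% c("artery", "vein", "none"))
    msgs <- c(msgs, "vesselClass must be one of 'artery', 'vein', 'none'")
  if (length(object@imageId) != 1L)
    msgs <- c(msgs, "imageId must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Construct a RasterMask
#'
#' @param pixels logical or 0/1 numeric matrix.
#' @param vesselClass vessel class label.
#' @param imageId image identifier.
#' @param scale optional pixels-per-disc-diameter scale.
#' @return A \linkS4class{RasterMask}.
#' @examples
#' m <- RasterMask(matrix(0, 5, 5))
#' maskPixelCount(m)
#' @export
RasterMask <- function(pixels, vesselClass = "none", imageId = "image",
                       scale = NA_real_) {
  if (!is.logical(pixels)) {
    storage.mode(pixels) <- "double"
    pixels <- pixels != 0
  }
  new("RasterMask", pixels = pixels, vesselClass = vesselClass,
      imageId = imageId, scale = as.numeric(scale))
}

#' Optic disc location
#'
#' @slot center numeric length-2 (row, col) in pixels, 0-based convention.
#' @slot radius positive radius in pixels.
#' @exportClass OpticDisc
setClass("OpticDisc",
  representation(center = "numeric", radius = "numeric"))

setValidity("OpticDisc", function(object) {
  if (length(object@center) != 2L) return("center must be (row, col)")
  if (length(object@radius) != 1L || !is.finite(object@radius) ||
      object@radius <= 0) return("radius must be a positive number")
  TRUE
})

#' Construct an OpticDisc
#' @param row,col disc center in pixels.
#' @param radius disc radius in pixels (> 0).
#' @return An \linkS4class{OpticDisc}.
#' @examples
#' OpticDisc(160, 60, 24)
#' @export
OpticDisc <- function(row, col, radius) {
  new("OpticDisc", center = c(row = as.numeric(row), col = as.numeric(col)),
      radius = as.numeric(radius))
}

#' Vessel graph: nodes, and segments with centerlines and diameters
#'
#' Nodes are skeleton junction/terminal clusters; segments are maximal
#' node-to-node centerline paths with optional per-point diameters.
#'
#' @slot nodes data.frame with columns id, row, col, kind
#'   (\code{endpoint}/\code{bifurcation}/\code{crossing_candidate}/\code{internal}),
#'   degree.
#' @slot segments list of data.frames, each with columns row, col and
#'   (after \code{\link{measureDiameters}}) diameter.
#' @slot segmentInfo data.frame with columns id, node1, node2 (node ids of the
#'   segment ends; equal for loops).
#' @slot vesselClass vessel class the graph was traced from.
#' @slot imageId source image id.
#' @slot dims integer dims of the source raster.
#' @slot junctionPixels integer matrix (row, col) of skeleton pixels swallowed
#'   by node clusters; retained so the skeleton can be reconstructed.
#' @exportClass VesselGraph
setClass("VesselGraph",
  representation(
    nodes = "data.frame",
    segments = "list",
    segmentInfo = "data.frame",
    vesselClass = "character",
    imageId = "character",
    dims = "integer",
    junctionPixels = "matrix"
  )
)

setValidity("VesselGraph", function(object) {
  msgs <- character()
  if (length(object@segments) != nrow(object@segmentInfo))
    msgs <- c(msgs, "segments and segmentInfo must have equal length")
  if (nrow(object@nodes)) {
    bad <- !object@nodes$kind %in%
      c("endpoint", "bifurcation", "crossing_candidate", "internal")
    if (any(bad)) msgs <- c(msgs, "invalid node kind")
    ep <- object@nodes$kind == "endpoint"
    if (any(object@nodes$degree[ep] != 1L))
      msgs <- c(msgs, "endpoint nodes must have degree 1")
    bf <- object@nodes$kind == "bifurcation"
    if (any(object@nodes$degree[bf] < 3L))
      msgs <- c(msgs, "bifurcation nodes must have degree >= 3")
  }
  for (s in object@segments) {
    if (nrow(s) < 2L) { msgs <- c(msgs, "segments need >= 2 points"); break }
  }
  if (nrow(object@segmentInfo)) {
    known <- object@segmentInfo$node1 %in% object@nodes$id &
      object@segmentInfo$node2 %in% object@nodes$id
    if (!all(known)) msgs <- c(msgs, "segment ends must reference nodes")
  }
  if (length(msgs)) msgs else TRUE
})

#' Correlation-structure comparison result
#'
#' Paired statistics between a genetic and a phenotypic correlation matrix over
#' their off-diagonal (upper-triangle) entries.
#'
#' @slot nPairs number of unordered phenotype pairs compared.
#' @slot d standardized mean difference (Cohen's d).
#' @slot t paired t statistic.
#' @slot df degrees of freedom (nPairs - 1).
#' @slot p two-sided p value of the paired t test.
#' @slot corrOfCorr Pearson correlation between the two pair vectors.
#' @slot permutationP permutation p value for corrOfCorr.
#' @slot nPermutations number of permutations used.
#' @slot seed RNG seed used for the permutations.
#' @exportClass CorrelationComparison
setClass("CorrelationComparison",
  representation(
    nPairs = "integer", d = "numeric", t = "numeric", df = "integer",
    p = "numeric", corrOfCorr = "numeric", permutationP = "numeric",
    nPermutations = "integer", seed = "integer"
  )
)

setMethod("show", "RasterMask", function(object) {
  cat(sprintf("RasterMask '%s' [%s]: %d x %d px, %d vessel px\n",
              object@imageId, object@vesselClass,
              nrow(object@pixels), ncol(object@pixels),
              sum(object@pixels)))
})

setMethod("show", "OpticDisc", function(object) {
  cat(sprintf("OpticDisc: center (row %.1f, col %.1f), radius %.1f px\n",
              object@center[1L], object@center[2L], object@radius))
})

setMethod("show", "VesselGraph", function(object) {
  k <- table(factor(object@nodes$kind,
                    c("endpoint", "bifurcation", "crossing_candidate",
                      "internal")))
  cat(sprintf(paste0(
    "VesselGraph '%s' [%s]: %d segments, %d nodes ",
    "(%d endpoints, %d bifurcations, %d crossing candidates)\n"),
    object@imageId, object@vesselClass, length(object@segments),
    nrow(object@nodes), k[["endpoint"]], k[["bifurcation"]],
    k[["crossing_candidate"]]))
})

setMethod("show", "CorrelationComparison", function(object) {
  cat(sprintf(
    "CorrelationComparison: %d pairs; d = %.3f, t(%d) = %.2f, p = %.3g\n",
    object@nPairs, object@d, object@df, object@t, object@p))
  cat(sprintf("  corr of correlations = %.3f (permutation p = %.3g, %d perms)\n",
              object@corrOfCorr, object@permutationP, object@nPermutations))
})

# ---- accessors ----

#' Accessors for RasterMask, OpticDisc and VesselGraph
#'
#' @param x object.
#' @return \code{maskPixels}: logical matrix; \code{maskPixelCount}: integer;
#'   \code{vesselClass}/\code{imageId}: character; \code{odCenter}: numeric
#'   (row, col); \code{odRadius}: numeric; \code{graphNodes}/\code{segmentInfo}:
#'   data.frame; \code{graphSegments}: list of data.frames.
#' @name accessors
NULL

#' @rdname accessors
#' @export
maskPixels <- function(x) x@pixels

#' @rdname accessors
#' @export
maskPixelCount <- function(x) sum(x@pixels)

#' @rdname accessors
#' @export
vesselClass <- function(x) x@vesselClass

#' @rdname accessors
#' @export
imageId <- function(x) x@imageId

#' @rdname accessors
#' @export
odCenter <- function(x) x@center

#' @rdname accessors
#' @export
odRadius <- function(x) x@radius

#' @rdname accessors
#' @export
graphNodes <- function(x) x@nodes

#' @rdname accessors
#' @export
graphSegments <- function(x) x@segments

#' @rdname accessors
#' @export
segmentInfo <- function(x) x@segmentInfo
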