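# Readers and writers for masks, optic-disc records, graphs and truth.
# All serialized coordinates are 0-based (row, col), origin top-left.

#' Read a binary vessel mask from PNG or TIFF
#'
#' Accepts single-channel or paletted/RGB-with-equal-channels images whose
#' values are essentially binary (0/255 or 0/1); more than
#' \code{tolerance} fraction of intermediate-valued pixels is an error.
#'
#' @param path PNG or TIFF file.
#' @param vesselClass,imageId metadata for the mask.
#' @param tolerance maximum fraction of non-binary pixels (default 0.01).
#' @return A \linkS4class{RasterMask}.
#' @export
readMask <- function(path, vesselClass = "none",
                     imageId = sub("\\.[^.]+$", "", basename(path)),
                     tolerance = 0.01) {
  ext <- tolower(sub(".*\\.", "", path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' is required to read TIFF masks")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(img)) == 3L) {
    for (ch in seq_len(dim(img)[3L])[-1L])
      if (max(abs(img[, , ch] - img[, , 1L])) > 1e-6)
        stop("multi-channel mask with differing channels: not a binary mask")
    img <- img[, , 1L]
  }
  frac <- mean(img > tolerance & img < 1 - tolerance)
  if (frac > tolerance)
    stop(sprintf("mask is not binary: %.1f%% intermediate pixels", 100 * frac))
  RasterMask(img >= 0.5, vesselClass = vesselClass, imageId = imageId)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask a \linkS4class{RasterMask}.
#' @param path output PNG path.
#' @return invisibly, \code{path}.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "RasterMask"))
  png::writePNG(mask@pixels * 1, path)
  invisible(path)
}

#' Read optic-disc records from CSV or JSON
#'
#' CSV columns (0-based pixel coordinates): image_id, row, col, radius.
#' JSON: an array of objects with the same fields.
#'
#' @param path file path.
#' @return named list of \linkS4class{OpticDisc} keyed by image_id.
#' @export
readOpticDiscs <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("image_id", "row", "col", "radius") %in% names(df)))
  out <- lapply(seq_len(nrow(df)), function(i)
    OpticDisc(df$row[i] + 1, df$col[i] + 1, df$radius[i]))
  names(out) <- df$image_id
  out
}

#' Write optic-disc records to CSV
#'
#' @param discs named list of \linkS4class{OpticDisc} (names = image ids).
#' @param path output CSV (0-based coordinates).
#' @return invisibly, \code{path}.
#' @export
writeOpticDiscs <- function(discs, path) {
  df <- do.call(rbind, lapply(names(discs), function(id)
    data.frame(image_id = id, row = discs[[id]]@center[1L] - 1,
               col = discs[[id]]@center[2L] - 1,
               radius = discs[[id]]@radius)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a vessel graph to the two-file CSV dialect
#'
#' nodes.csv: id, row, col, kind (0-based coordinates). segments.csv:
#' segment_id, class, point_index, row, col, diameter_px.
#'
#' @param graph \linkS4class{VesselGraph}.
#' @param nodesPath,segmentsPath output CSV paths.
#' @return invisibly, the two paths.
#' @export
writeVesselGraph <- function(graph, nodesPath, segmentsPath) {
  stopifnot(is(graph, "VesselGraph"))
  nd <- graph@nodes
  nd$row <- nd$row - 1; nd$col <- nd$col - 1
  utils::write.csv(nd[, c("id", "row", "col", "kind")], nodesPath,
                   row.names = FALSE)
  segRows <- lapply(seq_along(graph@segments), function(i) {
    s <- graph@segments[[i]]
    data.frame(segment_id = i, class = graph@vesselClass,
               point_index = seq_len(nrow(s)) - 1L,
               row = s$row - 1, col = s$col - 1,
               diameter_px = if (is.null(s$diameter)) NA_real_ else s$diameter)
  })
  seg <- if (length(segRows)) do.call(rbind, segRows) else
    data.frame(segment_id = integer(), class = character(),
               point_index = integer(), row = numeric(), col = numeric(),
               diameter_px = numeric())
  utils::write.csv(seg, segmentsPath, row.names = FALSE)
  invisible(c(nodesPath, segmentsPath))
}

#' Write generator ground truth: per-segment CSV plus a JSON sidecar
#'
#' @param truth \code{SyntheticTruth} from \code{\link{generateTree}}.
#' @param csvPath per-segment truth table.
#' @param jsonPath sidecar with parameters, seed, bifurcation counts, angles,
#'   pixel counts and OD record.
#' @return invisibly, the two paths.
#' @export
writeTruth <- function(truth, csvPath, jsonPath) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  utils::write.csv(truth$segments, csvPath, row.names = FALSE)
  side <- list(
    params = unclass(truth$params),
    n_bifurcations_per_class = as.list(truth$nBifurcationsPerClass),
    true_temporal_angle_deg = as.list(truth$trueTemporalAngleDeg),
    true_vessel_pixel_count = as.list(truth$trueVesselPixelCount),
    od_center = as.numeric(truth$odCenter) - 1,
    od_radius_px = truth$odRadius
  )
  jsonlite::write_json(side, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(c(csvPath, jsonPath))
}
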