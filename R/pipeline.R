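# End-to-end pipeline: simulate / extract / aggregate / correlate / associate.
# Every stage reads and writes plain files, so chaining the stages by hand
# (or via the CLI subcommands) reproduces runPipeline() exactly.

#' Default pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its default. The
#' configuration round-trips losslessly through YAML
#' (\code{\link{writePipelineConfig}} / \code{\link{readPipelineConfig}}).
#'
#' @param outDir output directory.
#' @param masksDir directory of \code{<id>_artery.png} / \code{<id>_vein.png}
#'   mask pairs (ignored when \code{nSimulate > 0}).
#' @param odFile optic-disc CSV (see \code{\link{readOpticDiscs}}).
#' @param qcScoresFile optional CSV image_id,score; when absent a vascular
#'   density proxy score is used (synthetic runs).
#' @param mappingFile optional CSV image_id,subject_id,eye,visit; when absent
#'   every image is its own subject (eye R, visit 0).
#' @param traitsFile optional CSV of per-subject traits (subject_id + trait
#'   columns) for the association battery.
#' @param nSimulate number of synthetic images to generate (0 = read masks
#'   from \code{masksDir}).
#' @param canvas synthetic canvas c(rows, cols); NULL (default) sizes the
#'   canvas to each simulated tree.
#' @param minSpurPx,minChordPx,minPoints,smoothWindow image-domain thresholds
#'   (see \code{\link{computeIDPs}}).
#' @param creAnnulus,angleAnnulus measurement annuli in OD-radius units.
#' @param rbintOffset rb-INT rank offset (Blom 3/8).
#' @param qcQuantile QC removal quantile (lowest quartile, 0.25).
#' @param seed integer master seed.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(outDir = "retiphen_out", masksDir = NULL,
                           odFile = NULL, qcScoresFile = NULL,
                           mappingFile = NULL, traitsFile = NULL,
                           nSimulate = 0L, canvas = NULL,
                           minSpurPx = 10, minChordPx = 10, minPoints = 50L,
                           smoothWindow = 3L, creAnnulus = c(2, 3),
                           angleAnnulus = c(1, 2.5), rbintOffset = 3 / 8,
                           qcQuantile = 0.25, seed = 1L) {
  structure(list(
    outDir = outDir, masksDir = masksDir, odFile = odFile,
    qcScoresFile = qcScoresFile, mappingFile = mappingFile,
    traitsFile = traitsFile, nSimulate = as.integer(nSimulate),
    canvas = if (is.null(canvas)) NULL else as.integer(canvas),
    minSpurPx = minSpurPx,
    minChordPx = minChordPx, minPoints = as.integer(minPoints),
    smoothWindow = as.integer(smoothWindow), creAnnulus = creAnnulus,
    angleAnnulus = angleAnnulus, rbintOffset = rbintOffset,
    qcQuantile = qcQuantile, seed = as.integer(seed)
  ), class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param config a \code{PipelineConfig}.
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipelineConfig()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg$nSimulate <- as.integer(cfg$nSimulate)
  if (!is.null(cfg$canvas)) cfg$canvas <- as.integer(cfg$canvas)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Simulate a directory of synthetic images
#'
#' Writes \code{<id>_artery.png}/\code{<id>_vein.png} mask pairs, an
#' optic-disc CSV, and per-image ground truth (CSV + JSON sidecar).
#'
#' @param n number of images.
#' @param dir output directory.
#' @param seed master seed; image i uses a seed derived from it.
#' @param canvas canvas dims; NULL (default) picks a canvas fitting each
#'   image's tree depth.
#' @return invisibly, the image ids.
#' @export
stageSimulate <- function(n, dir, seed = 1L, canvas = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("img%03d", seq_len(n))
  discs <- list()
  for (i in seq_len(n)) {
    p <- randomTreeParams(seed = (seed * 1000L + i) %% 2147483647L)
    sv <- generateTree(p, canvas = if (is.null(canvas)) canvasFor(p$depth)
                       else canvas, imageId = ids[i])
    writeMask(sv$artery, file.path(dir, paste0(ids[i], "_artery.png")))
    writeMask(sv$vein, file.path(dir, paste0(ids[i], "_vein.png")))
    writeTruth(sv$truth, file.path(dir, paste0(ids[i], "_truth.csv")),
               file.path(dir, paste0(ids[i], "_truth.json")))
    discs[[ids[i]]] <- sv$od
  }
  writeOpticDiscs(discs, file.path(dir, "optic_discs.csv"))
  invisible(ids)
}

#' Extract per-image phenotypes for a directory of masks
#'
#' Runs \code{\link{computeIDPs}} on every \code{<id>_artery.png} /
#' \code{<id>_vein.png} pair. Per-image failures are logged and isolated; the
#' stage errors only when more than half the images fail.
#'
#' @param masksDir mask directory.
#' @param odFile optic-disc CSV.
#' @param outCsv output per-image IDP table.
#' @param config \code{PipelineConfig} supplying thresholds.
#' @param logLines environment collecting log lines (optional).
#' @return invisibly, the per-image data.frame.
#' @export
stageExtract <- function(masksDir, odFile, outCsv,
                         config = pipelineConfig(), logLines = NULL) {
  arteries <- sort(list.files(masksDir, "_artery\\.png$", full.names = TRUE))
  if (!length(arteries)) stop("no *_artery.png masks found in ", masksDir)
  ids <- sub("_artery\\.png$", "", basename(arteries))
  discs <- if (!is.null(odFile) && file.exists(odFile))
    readOpticDiscs(odFile) else list()
  rows <- list(); failures <- 0L
  for (id in ids) {
    res <- tryCatch({
      a <- readMask(file.path(masksDir, paste0(id, "_artery.png")),
                    "artery", id)
      v <- readMask(file.path(masksDir, paste0(id, "_vein.png")), "vein", id)
      computeIDPs(a, v, od = discs[[id]],
                  minSpurPx = config$minSpurPx,
                  minChordPx = config$minChordPx,
                  minPoints = config$minPoints,
                  smoothWindow = config$smoothWindow)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      msg <- sprintf("image %s failed: %s", id, conditionMessage(res))
      if (!is.null(logLines)) logLines$lines <- c(logLines$lines, msg)
      warning(msg)
    } else rows[[id]] <- res
  }
  if (failures > length(ids) / 2)
    stop(sprintf("%d of %d images failed phenotype extraction",
                 failures, length(ids)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, outCsv, row.names = FALSE)
  invisible(out)
}

#' QC-gate and aggregate per-image phenotypes to subjects
#'
#' Applies the lowest-quartile QC filter (external scores when provided, a
#' vascular-density proxy score otherwise), joins the image-subject mapping,
#' and aggregates to one row per subject
#' (\code{\link{aggregateSubjects}}).
#'
#' @param idpCsv per-image IDP table from \code{\link{stageExtract}}.
#' @param outCsv per-subject output CSV.
#' @param qcScoresFile optional CSV image_id,score.
#' @param mappingFile optional CSV image_id,subject_id,eye,visit.
#' @param logLines environment collecting log lines (optional).
#' @return invisibly, the per-subject data.frame.
#' @export
stageAggregate <- function(idpCsv, outCsv, qcScoresFile = NULL,
                           mappingFile = NULL, logLines = NULL) {
  idp <- utils::read.csv(idpCsv, stringsAsFactors = FALSE)
  scores <- if (!is.null(qcScoresFile) && file.exists(qcScoresFile)) {
    utils::read.csv(qcScoresFile, stringsAsFactors = FALSE)
  } else {
    # fallback proxy for synthetic runs: vascular density tracks image quality
    data.frame(image_id = idp$image_id,
               score = rowSums(cbind(idp$a_vascular_density,
                                     idp$v_vascular_density), na.rm = TRUE))
  }
  qc <- quartileFilter(scores)
  idp <- merge(idp, qc[, c("image_id", "score", "pass")], by = "image_id",
               sort = TRUE)
  if (!is.null(logLines))
    logLines$lines <- c(logLines$lines, sprintf(
      "QC: image %s score %.4f %s", idp$image_id, idp$score,
      ifelse(idp$pass, "pass", "fail")))
  map <- if (!is.null(mappingFile) && file.exists(mappingFile)) {
    utils::read.csv(mappingFile, stringsAsFactors = FALSE)
  } else {
    data.frame(image_id = idp$image_id, subject_id = idp$image_id,
               eye = "R", visit = 0L)
  }
  idp <- merge(idp, map, by = "image_id", sort = TRUE)
  subj <- aggregateSubjects(idp)
  utils::write.csv(subj, outCsv, row.names = FALSE)
  invisible(subj)
}

#' Phenotype correlation matrix of a subject table
#'
#' rb-INT-transforms each phenotype column, then writes the pairwise Pearson
#' correlation matrix as labeled CSV.
#'
#' @param subjectsCsv per-subject table from \code{\link{stageAggregate}}.
#' @param outCsv labeled correlation-matrix CSV.
#' @param rbintOffset rank offset for \code{\link{rankInverseNormal}}.
#' @return invisibly, the correlation matrix.
#' @export
stageCorrelate <- function(subjectsCsv, outCsv, rbintOffset = 3 / 8) {
  subj <- utils::read.csv(subjectsCsv, stringsAsFactors = FALSE)
  cols <- intersect(idpNames(), names(subj))
  X <- subj[, cols, drop = FALSE]
  keep <- vapply(X, function(x)
    sum(!is.na(x)) >= 2L && length(unique(x[!is.na(x)])) > 1L, logical(1))
  X <- X[, keep, drop = FALSE]
  Xt <- as.data.frame(lapply(X, rankInverseNormal, offset = rbintOffset))
  R <- correlationMatrix(Xt)
  utils::write.csv(cbind(idp = rownames(R), as.data.frame(R)), outCsv,
                   row.names = FALSE)
  invisible(R)
}

#' Association battery between a subject table and traits
#'
#' z-scores the phenotypes and runs \code{\link{associationBattery}} against
#' the trait columns, writing the tidy result CSV.
#'
#' @param subjectsCsv per-subject table.
#' @param traitsFile CSV subject_id + trait columns.
#' @param outCsv tidy results CSV (idp, trait, model, effect, se, p, tier).
#' @return invisibly, the results data.frame.
#' @export
stageAssociate <- function(subjectsCsv, traitsFile, outCsv) {
  subj <- utils::read.csv(subjectsCsv, stringsAsFactors = FALSE)
  traits <- utils::read.csv(traitsFile, stringsAsFactors = FALSE)
  merged <- merge(subj, traits, by = "subject_id", sort = TRUE)
  idpCols <- intersect(idpNames(), names(subj))
  res <- associationBattery(merged[, idpCols, drop = FALSE],
                            merged[, setdiff(names(traits), "subject_id"),
                                   drop = FALSE])
  utils::write.csv(res, outCsv, row.names = FALSE)
  invisible(res)
}

#' Run the full pipeline
#'
#' simulate (or read masks) -> extract -> QC + aggregate -> correlate
#' [-> associate]. Deterministic for a fixed seed: rerunning with the same
#' configuration reproduces byte-identical CSVs. The log records the config
#' hash, seed, versions and every per-image QC decision.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return invisibly, the output directory.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$outDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logEnv <- new.env(); logEnv$lines <- character()
  cfgPath <- file.path(out, "config.yaml")
  writePipelineConfig(config, cfgPath)
  logEnv$lines <- c(logEnv$lines,
    sprintf("config_hash %s", configHash(paste(readLines(cfgPath),
                                               collapse = "\n"))),
    sprintf("seed %d", config$seed),
    sprintf("r_version %s", R.version.string),
    sprintf("package_version RetiPhen %s",
            as.character(utils::packageVersion("RetiPhen"))))
  if (config$nSimulate > 0L) {
    masksDir <- file.path(out, "masks")
    stageSimulate(config$nSimulate, masksDir, seed = config$seed,
                  canvas = config$canvas)
    odFile <- file.path(masksDir, "optic_discs.csv")
  } else {
    if (is.null(config$masksDir) || !dir.exists(config$masksDir))
      stop("masksDir does not exist and nSimulate is 0")
    masksDir <- config$masksDir
    odFile <- config$odFile
  }
  idpCsv <- file.path(out, "idps_per_image.csv")
  stageExtract(masksDir, odFile, idpCsv, config, logEnv)
  subjCsv <- file.path(out, "idps_per_subject.csv")
  stageAggregate(idpCsv, subjCsv, config$qcScoresFile, config$mappingFile,
                 logEnv)
  stageCorrelate(subjCsv, file.path(out, "phenotypic_correlations.csv"),
                 config$rbintOffset)
  if (!is.null(config$traitsFile) && file.exists(config$traitsFile))
    stageAssociate(subjCsv, config$traitsFile,
                   file.path(out, "associations.csv"))
  writeLines(logEnv$lines, file.path(out, "pipeline.log"))
  invisible(out)
}
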