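# Image-level quality control and subject-level phenotype assembly.

#' Lowest-quartile quality-control filter
#'
#' Flags images whose quality score is at or above the 25th percentile; the
#' lowest quartile is removed, retaining the 75 percent highest-quality
#' images. The percentile interpolates linearly between order statistics at
#' the Weibull plotting position h = (n + 1) p (R quantile type 6), which
#' retains at least 75 percent for every n of distinct scores and exactly
#' 75 of 100. Ties at the threshold pass. With fewer than 4 scores all pass,
#' with a warning.
#'
#' @param scores data.frame with columns \code{image_id} and \code{score},
#'   or a numeric vector of scores.
#' @return data.frame with columns image_id, score, pass.
#' @examples
#' quartileFilter(c(1, 2, 3, 4))$pass
#' @export
quartileFilter <- function(scores) {
  if (is.numeric(scores))
    scores <- data.frame(image_id = as.character(seq_along(scores)),
                         score = scores)
  stopifnot(all(c("image_id", "score") %in% names(scores)))
  if (!is.numeric(scores$score)) stop("scores must be numeric")
  if (any(is.na(scores$score))) stop("scores must not be missing")
  if (nrow(scores) < 4L) {
    warning("fewer than 4 scores: no meaningful quartile, all images pass")
    scores$pass <- TRUE
    return(scores)
  }
  thr <- stats::quantile(scores$score, 0.25, type = 6, names = FALSE)
  scores$pass <- scores$score >= thr
  scores
}

#' Spherical equivalent of a refraction
#'
#' spherical power + cylindrical power / 2, in diopters; missing inputs give
#' missing output.
#'
#' @param spherical,cylindrical diopters.
#' @return diopters.
#' @examples
#' sphericalEquivalent(-2, -1)  # -2.5
#' @export
sphericalEquivalent <- function(spherical, cylindrical) {
  spherical + cylindrical / 2
}

#' Aggregate per-image phenotypes to one row per subject
#'
#' Restricts each subject to the earliest visit having at least one
#' QC-passing eye; when both eyes pass, phenotype fields are averaged
#' (field-wise over non-missing values), otherwise the single passing eye is
#' used. Subjects with no passing image are absent from the output.
#'
#' @param rows data.frame with columns \code{subject_id}, \code{eye}
#'   (\code{"L"}/\code{"R"}), \code{visit} (integer), \code{pass} (logical)
#'   and the phenotype columns named in \code{idpCols}.
#' @param idpCols phenotype column names (default \code{\link{idpNames}}).
#' @return data.frame, one row per retained subject.
#' @export
aggregateSubjects <- function(rows, idpCols = idpNames()) {
  stopifnot(all(c("subject_id", "eye", "visit", "pass") %in% names(rows)))
  idpCols <- intersect(idpCols, names(rows))
  rows <- rows[rows$pass, , drop = FALSE]
  if (!nrow(rows))
    return(cbind(data.frame(subject_id = character(), visit = integer()),
                 stats::setNames(as.data.frame(
                   matrix(numeric(), 0L, length(idpCols))), idpCols)))
  out <- lapply(split(rows, rows$subject_id), function(sub) {
    v0 <- min(sub$visit)
    sub <- sub[sub$visit == v0, , drop = FALSE]
    vals <- vapply(idpCols, function(cn) {
      x <- sub[[cn]]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, numeric(1))
    cbind(data.frame(subject_id = sub$subject_id[1L], visit = v0),
          as.data.frame(as.list(vals)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank-based inverse normal transformation (rb-INT)
#'
#' Maps values to normal quantiles of their Blom-offset ranks:
#' qnorm((rank - 3/8) / (n + 1/4)), with average ranks for ties and missing
#' values preserved. Strictly monotone on distinct inputs. If all values are
#' identical, everything maps to 0 with a warning.
#'
#' @param values numeric vector (NA allowed).
#' @param offset rank offset constant (Blom 3/8, the GWAS convention).
#' @return transformed numeric vector, same length and NA pattern.
#' @examples
#' rankInverseNormal(c(10, 20, 30))
#' @export
rankInverseNormal <- function(values, offset = 3 / 8) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2L) stop("need at least 2 non-missing values")
  out <- rep(NA_real_, length(values))
  if (length(unique(values[ok])) == 1L) {
    warning("all values identical: rb-INT maps everything to 0")
    out[ok] <- 0
    return(out)
  }
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Expand the standard covariate set
#'
#' Builds the derived covariate columns used before association testing from
#' base columns: age squared, sex-by-age, sex-by-age-squared, spherical and
#' cylindrical power squares, and indicator expansion of categorical batch /
#' centre labels. Columns absent from the input are skipped.
#'
#' @param df data.frame of base covariates.
#' @param age,sex,spherical,cylindrical column names (NULL to skip).
#' @param categorical character vector of categorical column names.
#' @param pcs character vector of numeric passthrough columns (genomic PCs
#'   etc.).
#' @return numeric data.frame of expanded covariates.
#' @export
expandCovariates <- function(df, age = "age", sex = "sex",
                             spherical = "spherical", cylindrical = "cylindrical",
                             categorical = character(),
                             pcs = grep("^pc", names(df), value = TRUE)) {
  out <- list()
  has <- function(cn) !is.null(cn) && cn %in% names(df)
  if (has(age)) { out$age <- df[[age]]; out$age2 <- df[[age]]^2 }
  if (has(sex)) {
    sx <- if (is.numeric(df[[sex]])) df[[sex]] else
      as.numeric(factor(df[[sex]])) - 1
    out$sex <- sx
    if (has(age)) {
      out$sex_age <- sx * df[[age]]
      out$sex_age2 <- sx * df[[age]]^2
    }
  }
  if (has(spherical)) {
    out$spherical <- df[[spherical]]; out$spherical2 <- df[[spherical]]^2
  }
  if (has(cylindrical)) {
    out$cylindrical <- df[[cylindrical]]
    out$cylindrical2 <- df[[cylindrical]]^2
  }
  for (cn in intersect(categorical, names(df))) {
    f <- factor(df[[cn]])
    if (nlevels(f) > 1L) {
      mm <- stats::model.matrix(~ f)[, -1L, drop = FALSE]
      colnames(mm) <- paste0(cn, "_", levels(f)[-1L])
      for (j in seq_len(ncol(mm))) out[[colnames(mm)[j]]] <- mm[, j]
    }
  }
  for (cn in intersect(pcs, names(df))) out[[cn]] <- df[[cn]]
  as.data.frame(out)
}

#' Residualize a phenotype on covariates
#'
#' Ordinary-least-squares residuals of \code{y} on the covariate columns
#' (categorical columns are expanded to drop-one indicators); collinear
#' columns are dropped with a warning. Residuals are orthogonal to every
#' retained covariate column. Rows with missing y or covariates stay NA.
#'
#' @param y numeric response.
#' @param covariates data.frame of covariates.
#' @param zScore if TRUE (default) scale residuals to mean 0, sd 1.
#' @return numeric vector of (optionally z-scored) residuals.
#' @export
residualize <- function(y, covariates, zScore = TRUE) {
  covariates <- as.data.frame(covariates)
  stopifnot(length(y) == nrow(covariates))
  if (length(y) <= ncol(covariates))
    stop("need more observations than covariate columns")
  cc <- stats::complete.cases(covariates) & !is.na(y)
  Xcc <- stats::model.matrix(~ ., data = covariates[cc, , drop = FALSE])
  fit <- stats::lm.fit(Xcc, y[cc])
  if (any(is.na(fit$coefficients)))
    warning("rank-deficient covariate design: collinear columns dropped")
  out <- rep(NA_real_, length(y))
  out[cc] <- fit$residuals
  if (zScore) {
    s <- stats::sd(out, na.rm = TRUE)
    if (is.na(s) || s == 0) stop("residuals have zero variance")
    out <- (out - mean(out, na.rm = TRUE)) / s
  }
  out
}
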