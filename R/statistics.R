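# Correlation-structure comparison and the disease-association battery.

#' Pairwise Pearson correlation matrix of phenotypes
#'
#' Pairwise-complete Pearson correlations; cells backed by fewer than
#' \code{minPairs} complete observation pairs are set missing. Symmetric with
#' unit diagonal.
#'
#' @param idpTable data.frame/matrix, one column per phenotype.
#' @param minPairs minimum complete pairs per cell (default 3).
#' @return correlation matrix with dimnames.
#' @export
correlationMatrix <- function(idpTable, minPairs = 3L) {
  X <- as.matrix(idpTable)
  if (ncol(X) < 2L) stop("need at least 2 phenotype columns")
  R <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  counts <- crossprod(!is.na(X))
  R[counts < minPairs] <- NA_real_
  diag(R) <- 1
  R
}

#' Compare genetic and phenotypic correlation structures
#'
#' Over the k(k-1)/2 upper-triangle phenotype pairs: Cohen's d for the mean
#' difference between the two correlation sets, a paired two-sided t test
#' with df = nPairs - 1, the correlation of correlations, and a permutation
#' p value for the latter obtained by randomly re-pairing the entries of the
#' two vectors.
#'
#' The d denominator is the pooled form sqrt((SDg^2 + SDp^2) / 2) by default;
#' \code{dDenominator = "printed"} uses the difference form
#' sqrt((SDg^2 - SDp^2) / 2), which is undefined when SDp > SDg and is kept
#' only for auditability.
#'
#' @param Rg,Rp correlation matrices with identical dimnames (genetic and
#'   phenotypic).
#' @param nPerm number of permutations (>= 1000).
#' @param seed integer RNG seed for the permutations.
#' @param dDenominator \code{"pooled"} (default) or \code{"printed"}.
#' @return A \linkS4class{CorrelationComparison}.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' R1 <- cor(X); R2 <- cor(X + rnorm(300, sd = 0.5))
#' compareCorrelationSets(R1, R2, nPerm = 1000, seed = 1)
#' @export
compareCorrelationSets <- function(Rg, Rp, nPerm = 10000L, seed = 1L,
                                   dDenominator = c("pooled", "printed")) {
  dDenominator <- match.arg(dDenominator)
  Rg <- as.matrix(Rg); Rp <- as.matrix(Rp)
  if (!identical(dim(Rg), dim(Rp)) ||
      !identical(dimnames(Rg)[[1L]], dimnames(Rp)[[1L]]))
    stop("correlation matrices must share labels and order")
  if (nPerm < 1000L) stop("nPerm must be at least 1000")
  ut <- upper.tri(Rg)
  g <- Rg[ut]; p <- Rp[ut]
  ok <- !is.na(g) & !is.na(p)
  g <- g[ok]; p <- p[ok]
  nPairs <- length(g)
  sdg <- stats::sd(g); sdp <- stats::sd(p)
  denom <- if (dDenominator == "pooled") sqrt((sdg^2 + sdp^2) / 2)
    else sqrt((sdg^2 - sdp^2) / 2)
  d <- (mean(g) - mean(p)) / denom
  diffs <- g - p
  tStat <- mean(diffs) / (stats::sd(diffs) / sqrt(nPairs))
  df <- nPairs - 1L
  pVal <- 2 * stats::pt(-abs(tStat), df)
  cc <- stats::cor(g, p)
  perm <- withSeed(seed, {
    vapply(seq_len(nPerm), function(i) stats::cor(g, sample(p)), numeric(1))
  })
  permP <- (1 + sum(abs(perm) >= abs(cc))) / (nPerm + 1)
  new("CorrelationComparison",
      nPairs = as.integer(nPairs), d = d, t = tStat, df = as.integer(df),
      p = pVal, corrOfCorr = cc, permutationP = permP,
      nPermutations = as.integer(nPerm), seed = as.integer(seed))
}

#' Phenotype-trait association battery
#'
#' For every (phenotype, trait) pair, fits a linear regression (continuous
#' trait; both sides z-scored, so the slope is a standardized effect) or a
#' logistic regression (binary trait; phenotype z-scored, effect reported as
#' an odds ratio per 1 SD of phenotype). Significance tiers follow Bonferroni
#' thresholds 0.05 / Ntests (\code{*}) and 0.001 / Ntests (\code{**}) with
#' Ntests = Nphenotypes x Ntraits.
#'
#' Phenotypes are expected to be residualized/z-scored beforehand (see
#' \code{\link{residualize}}); they are re-centered and scaled defensively.
#'
#' @param idpTable data.frame of phenotype columns.
#' @param traitTable data.frame of trait columns (numeric continuous, or
#'   binary coded 0/1 / logical / two-level factor).
#' @return data.frame: idp, trait, model, effect, se, p, tier
#'   (\code{ns}/\code{*}/\code{**}). Binary traits with a single observed
#'   class give NA with a warning.
#' @export
associationBattery <- function(idpTable, traitTable) {
  idpTable <- as.data.frame(idpTable)
  traitTable <- as.data.frame(traitTable)
  stopifnot(nrow(idpTable) == nrow(traitTable))
  nTests <- ncol(idpTable) * ncol(traitTable)
  thr1 <- 0.05 / nTests; thr2 <- 0.001 / nTests
  res <- vector("list", nTests)
  k <- 0L
  for (tn in names(traitTable)) {
    trait <- traitTable[[tn]]
    if (is.logical(trait)) trait <- as.numeric(trait)
    if (is.factor(trait)) trait <- as.numeric(trait) - 1
    uu <- unique(trait[!is.na(trait)])
    binary <- length(uu) >= 1L && length(uu) <= 2L && all(uu %in% c(0, 1))
    for (pn in names(idpTable)) {
      k <- k + 1L
      x <- idpTable[[pn]]
      cc <- !is.na(x) & !is.na(trait)
      row <- data.frame(idp = pn, trait = tn,
                        model = if (binary) "logistic" else "linear",
                        effect = NA_real_, se = NA_real_, p = NA_real_,
                        tier = NA_character_)
      if (sum(cc) >= 3L && stats::sd(x[cc]) > 0) {
        xz <- (x[cc] - mean(x[cc])) / stats::sd(x[cc])
        if (binary) {
          if (length(unique(trait[cc])) < 2L) {
            warning(sprintf("trait '%s' has a single class: skipped", tn))
          } else {
            fit <- stats::glm(trait[cc] ~ xz, family = stats::binomial())
            sm <- summary(fit)$coefficients
            row$effect <- exp(sm["xz", "Estimate"])
            row$se <- sm["xz", "Std. Error"]
            row$p <- sm["xz", "Pr(>|z|)"]
          }
        } else if (stats::sd(trait[cc]) > 0) {
          tz <- (trait[cc] - mean(trait[cc])) / stats::sd(trait[cc])
          fit <- stats::lm(tz ~ xz)
          sm <- summary(fit)$coefficients
          row$effect <- sm["xz", "Estimate"]
          row$se <- sm["xz", "Std. Error"]
          row$p <- sm["xz", "Pr(>|t|)"]
        }
      }
      if (!is.na(row$p))
        row$tier <- if (row$p < thr2) "**" else if (row$p < thr1) "*" else "ns"
      res[[k]] <- row
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "nTests") <- nTests
  attr(out, "thresholds") <- c(tier1 = thr1, tier2 = thr2)
  out
}
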