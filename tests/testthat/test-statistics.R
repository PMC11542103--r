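# Correlation structure comparison and the association battery.

test_that("correlation matrix is symmetric, unit-diagonal, NA-aware", {
  set.seed(3)
  x <- rnorm(50)
  df <- data.frame(a = x, b = x, c = -x + rnorm(50, sd = 1e-9))
  R <- correlationMatrix(df)
  expect_identical(unname(diag(R)), rep(1, 3))
  expect_equal(R["a", "b"], 1, tolerance = 1e-12)
  expect_equal(R["a", "c"], -1, tolerance = 1e-6)
  expect_equal(R, t(R), tolerance = 1e-15)

  set.seed(4)
  noise <- as.data.frame(matrix(rnorm(5e4), 1e4, 5))
  Rn <- correlationMatrix(noise)
  expect_lt(max(abs(Rn[upper.tri(Rn)])), 0.05)

  df$na_col <- c(1, 2, rep(NA, 48))
  Rna <- correlationMatrix(df)
  expect_true(is.na(Rna["a", "na_col"]))
  expect_error(correlationMatrix(df["a"]), "2 phenotype")
})

test_that("correlation-set comparison reproduces the pair arithmetic", {
  set.seed(5)
  X <- matrix(rnorm(1700), 100, 17,
              dimnames = list(NULL, paste0("idp", 1:17)))
  Rp <- cor(X)
  Rg <- cor(X + matrix(rnorm(1700, sd = 1), 100, 17))
  cmp <- compareCorrelationSets(Rg, Rp, nPerm = 1000L, seed = 1L)
  expect_identical(cmp@nPairs, 136L)
  expect_identical(cmp@df, 135L)
})

test_that("identical correlation sets give d = 0 and perfect agreement", {
  set.seed(6)
  X <- matrix(rnorm(500), 100, 5, dimnames = list(NULL, letters[1:5]))
  R <- cor(X)
  cmp <- compareCorrelationSets(R, R, nPerm = 1000L, seed = 2L)
  expect_equal(cmp@d, 0)
  expect_equal(cmp@corrOfCorr, 1)
})

test_that("a constant shift yields the closed-form pooled d", {
  k <- 17L
  labs <- paste0("p", seq_len(k))
  set.seed(8)
  # off-diagonal entries with sample SD exactly 0.2, then a +0.1 shift
  vals <- as.numeric(scale(rnorm(k * (k - 1) / 2))) * 0.2
  asMat <- function(v) {
    m <- matrix(0, k, k, dimnames = list(labs, labs))
    m[upper.tri(m)] <- v
    m <- m + t(m); diag(m) <- 1
    m
  }
  Rp <- asMat(vals)
  Rg <- asMat(vals + 0.1)
  cmp <- compareCorrelationSets(Rg, Rp, nPerm = 1000L, seed = 3L)
  # oracle: direct evaluation of (mean_g - mean_p) / sqrt((sd_g^2+sd_p^2)/2)
  expect_equal(cmp@d, 0.1 / sqrt((sd(vals + 0.1)^2 + sd(vals)^2) / 2),
               tolerance = 1e-12)
  expect_equal(cmp@d, 0.5, tolerance = 1e-9)  # SD fixed at 0.2

  # antisymmetry: swapping the matrices negates d and t
  rev <- compareCorrelationSets(Rp, Rg, nPerm = 1000L, seed = 3L)
  expect_equal(rev@d, -cmp@d, tolerance = 1e-12)
  expect_equal(rev@t, -cmp@t, tolerance = 1e-12)
  expect_equal(rev@corrOfCorr, cmp@corrOfCorr, tolerance = 1e-12)

  # the printed difference-form denominator stays available for audit
  Rg2 <- asMat(1.5 * vals + 0.1)  # SD 0.3 vs 0.2
  printed <- compareCorrelationSets(Rg2, Rp, nPerm = 1000L, seed = 3L,
                                    dDenominator = "printed")
  expect_equal(printed@d, 0.1 / sqrt((0.3^2 - 0.2^2) / 2), tolerance = 1e-9)
})

test_that("permutation p-values are bounded and seed-reproducible", {
  set.seed(9)
  X <- matrix(rnorm(800), 100, 8, dimnames = list(NULL, letters[1:8]))
  Rp <- cor(X); Rg <- cor(X[sample(100), ])
  a <- compareCorrelationSets(Rg, Rp, nPerm = 2000L, seed = 7L)
  b <- compareCorrelationSets(Rg, Rp, nPerm = 2000L, seed = 7L)
  expect_identical(a@permutationP, b@permutationP)
  expect_gte(a@permutationP, 1 / 2001)
  expect_lte(a@permutationP, 1)
  expect_error(compareCorrelationSets(Rg, Rp, nPerm = 10L, seed = 1L),
               "1000")
  bad <- Rp; dimnames(bad) <- list(LETTERS[1:8], LETTERS[1:8])
  expect_error(compareCorrelationSets(Rg, bad, seed = 1L), "labels")
})

test_that("the battery recovers a known standardized effect", {
  set.seed(10)
  n <- 2000L
  idp <- data.frame(x = rnorm(n, sd = 2))
  trait <- data.frame(y = 0.5 * idp$x + rnorm(n, sd = 1))
  res <- associationBattery(idp, trait)
  expect_identical(res$model, "linear")
  expected <- 0.5 * sd(idp$x) / sd(trait$y)
  expect_lt(abs(res$effect - expected), 0.05)

  # logistic: odds ratio per SD in the simulated direction
  lp <- 0.8 * scale(idp$x)[, 1L]
  trait2 <- data.frame(z = rbinom(n, 1, plogis(lp)))
  res2 <- associationBattery(idp, trait2)
  expect_identical(res2$model, "logistic")
  expect_lt(abs(log(res2$effect) - 0.8), 0.15)

  # single-class binary trait: missing with warning
  expect_warning(res3 <- associationBattery(idp,
                                            data.frame(w = rep(0L, n))),
                 "single class")
  expect_true(is.na(res3$effect))
})

test_that("Bonferroni tiers follow the printed thresholds", {
  set.seed(13)
  n <- 400L
  idps <- as.data.frame(matrix(rnorm(n * 17), n, 17))
  names(idps) <- paste0("idp", 1:17)
  traits <- as.data.frame(matrix(rnorm(n * 20), n, 20))
  names(traits) <- paste0("t", 1:20)
  res <- associationBattery(idps, traits)
  thr <- attr(res, "thresholds")
  expect_equal(unname(thr["tier1"]), 0.05 / 340, tolerance = 1e-15)
  expect_equal(unname(thr["tier2"]), 0.001 / 340, tolerance = 1e-15)
  expect_identical(attr(res, "nTests"), 340L)
  agree <- ifelse(res$p < 0.001 / 340, "**",
                  ifelse(res$p < 0.05 / 340, "*", "ns"))
  expect_identical(res$tier, agree)
})

test_that("null p-values are uniform and the star rate is Bonferroni-controlled", {
  set.seed(14)
  n <- 250L
  pvals <- c(); anyStar <- logical()
  for (rep in 1:30) {
    idps <- as.data.frame(matrix(rnorm(n * 17), n, 17))
    traits <- as.data.frame(matrix(rnorm(n * 20), n, 20))
    res <- associationBattery(idps, traits)
    pvals <- c(pvals, res$p)
    anyStar <- c(anyStar, any(res$tier != "ns"))
  }
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
  # family-wise "*" rate at most the Bonferroni level + Monte-Carlo margin
  expect_lte(mean(anyStar), 0.05 + 3 * sqrt(0.05 * 0.95 / 30))
})
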