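test_that("methylation fractions use strict thresholds and exclude empty probes", {
  x <- makeToyBeta(5, 2, beta = matrix(0, 5, 4))
  fr <- methylationFractions(x)
  expect_equal(c(fr$fractionLow, fr$fractionHigh), c(1, 0))
  # values exactly at the threshold fall in neither tail
  xT <- makeToyBeta(3, 2, beta = matrix(c(0.25, 0.75, 0.5), 3, 4))
  frT <- methylationFractions(xT)
  expect_equal(frT$fractionLow, 0)
  expect_equal(frT$fractionHigh, 0)
  expect_equal(frT$fractionMid, 1)
  b <- matrix(c(rep(0.1, 4), rep(NA, 4), rep(0.9, 4)), 3, 4, byrow = TRUE)
  xN <- makeToyBeta(3, 2, beta = b)
  frN <- methylationFractions(xN)
  expect_equal(frN$nExcluded, 1L)
  expect_equal(frN$fractionLow + frN$fractionMid + frN$fractionHigh, 1)
})

test_that("sample correlation matches a from-scratch Pearson computation", {
  a <- c(0.1, 0.4, 0.35, 0.8, 0.55)
  b <- c(0.15, 0.5, 0.3, 0.7, 0.6)
  x <- makeToyBeta(5, 2, beta = cbind(a, b, a, b))
  rOracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  res <- sampleCorrelation(x, "P01_T2D", "P01_non")
  expect_equal(res$r, rOracle, tolerance = 1e-12)
  expect_equal(sampleCorrelation(x, "P01_T2D", "P01_T2D")$r, 1)
  # exact negation around 0.5
  xNeg <- makeToyBeta(5, 2, beta = cbind(a, 1 - a, a, 1 - a))
  expect_equal(sampleCorrelation(xNeg, "P01_T2D", "P01_non")$r, -1)
  xConst <- makeToyBeta(5, 2, beta = cbind(rep(0.5, 5), b, a, b))
  expect_error(sampleCorrelation(xConst, "P01_T2D", "P01_non"), "constant")
})

test_that("overall ANOVA separates pair structure from status", {
  # co-twins identical, pairs far apart: all variance on the pair factor
  pairLevels <- c(0.2, 0.5, 0.8)
  b <- matrix(rep(rep(pairLevels, each = 2), each = 4), 4, 6) +
    matrix(rnorm(24, 0, 0.01), 4, 6)
  b[b < 0] <- 0; b[b > 1] <- 1
  x <- makeToyBeta(4, 3, beta = b)
  an <- overallAnova(x)
  fPair <- an$F[an$term == "pair"]
  fStatus <- an$F[an$term == "status"]
  expect_gt(fPair, 100)
  expect_lt(fStatus, 5)
  expect_true(all(an$df[an$term != "Residuals"] >= 1))
  expect_error(overallAnova(makeToyBeta(4, 1)), "2 pairs")
})

test_that("ANOVA pair-effect P is calibrated on exchangeable data", {
  # with no pair structure in the values (iid noise around 0.5) the pair
  # factor's P is uniform; probe-level baselines would instead make the
  # pooled test conservative, which the degenerate-input test above covers
  set.seed(77)
  ps <- replicate(100, {
    b <- matrix(pmin(1, pmax(0, rnorm(60 * 12, 0.5, 0.1))), 60, 12)
    overallAnova(makeToyBeta(60, 6, beta = b))$p[1]
  })
  expect_lt(abs(mean(ps) - 0.5), 0.1)
  expect_lt(abs(mean(ps < 0.2) - 0.2), 0.12)
})

test_that("pair-specific status effects surface in the interaction term", {
  set.seed(88)
  hits <- replicate(20, {
    b <- matrix(pmin(1, pmax(0, rnorm(40 * 12, 0.5, 0.05))), 40, 12)
    # opposite-direction disease effects in different pairs: no status main
    # effect, strong pair x status interaction
    shift <- rep(c(0.08, -0.08), 3)
    for (p in 1:6) b[, 2 * p - 1] <- b[, 2 * p - 1] + shift[p]
    b[b < 0] <- 0; b[b > 1] <- 1
    an <- overallAnova(makeToyBeta(40, 6, beta = b))
    an$p[an$term == "pair:status"] < an$p[an$term == "status"]
  })
  expect_gt(mean(hits), 0.8)
})

test_that("intra-pair variation is the SD of absolute differences", {
  # co-twins identical -> zero variation
  b <- matrix(rep(c(0.2, 0.4, 0.6), each = 8), 3, 8, byrow = TRUE)
  x0 <- makeToyBeta(3, 4, beta = b)
  expect_equal(intrapairVariationSd(x0, scope = "pooled")$sd, 0)
  # constant |differences| of 10 points -> per-pair SD 0 (SD, not mean)
  bC <- b; bC[, 1] <- b[, 1] + 0.1  # pair 1 T2D shifted at all probes
  xC <- makeToyBeta(3, 4, beta = bC)
  pp <- intrapairVariationSd(xC, scope = "per_pair")
  expect_equal(pp$sd[pp$pair_id == "P01"], 0)
  # 3 pairs x 4 probes toy table against a direct formula oracle
  set.seed(5)
  bT <- matrix(runif(24, 0.2, 0.8), 4, 6)
  xT <- makeToyBeta(4, 3, beta = bT)
  diffs <- abs(bT[, c(1, 3, 5)] - bT[, c(2, 4, 6)]) * 100
  expect_equal(intrapairVariationSd(xT, scope = "pooled")$sd,
               sd(as.vector(diffs)), tolerance = 1e-12)
  # invariance to which twin is labelled first (status swap)
  d <- studyDesign(xT)
  dSwap <- d
  dSwap$status <- ifelse(d$status == "T2D", "nonT2D", "T2D")
  xSwap <- TwinBetaSet(bT |> `dimnames<-`(dimnames(betaValues(xT))), dSwap)
  expect_equal(intrapairVariationSd(xSwap, scope = "pooled")$sd,
               intrapairVariationSd(xT, scope = "pooled")$sd)
  expect_error(intrapairVariationSd(x0, probeSet = character(0)), "empty")
})

test_that("variation-phenotype correlation behaves at the extremes", {
  v <- c(P01 = 3, P02 = 7, P03 = 5, P04 = 9)
  expect_equal(correlateVariationPhenotype(v, v)$r, 1)
  expect_error(correlateVariationPhenotype(v, v * 0 + 2), "constant")
  expect_error(correlateVariationPhenotype(v[1:2], v[1:2]), "3 pairs")
})
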