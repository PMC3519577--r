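test_that("paired differences follow the T2D-minus-nonT2D convention", {
  b <- matrix(c(0.139, 0.090, 0.25, 0.25), 2, 2, byrow = FALSE)
  # one probe per row; pair P01: T2D 0.139, non 0.090
  bm <- rbind(c(0.139, 0.090, 0.30, 0.20, 0.45, 0.40),
              c(0.50, 0.50, 0.60, 0.60, 0.70, 0.70))
  x <- makeToyBeta(2, 3, beta = bm)
  D <- pairedDifferences(x)
  expect_equal(D["cg0000001", "P01"], 4.9, tolerance = 1e-9)
  expect_equal(unname(D["cg0000002", ]), c(0, 0, 0))
  # masking one twin at one probe removes the pair from that probe only
  bm[1, 3] <- NA
  xM <- makeToyBeta(2, 3, beta = bm)
  DM <- pairedDifferences(xM)
  expect_true(is.na(DM["cg0000001", "P02"]))
  expect_false(is.na(DM["cg0000001", "P03"]))
  expect_false(anyNA(DM["cg0000002", ]))
  # probes with < 2 complete pairs are dropped with a message
  bm[1, 1] <- NA
  xD <- makeToyBeta(2, 3, beta = bm)
  expect_message(DD <- pairedDifferences(xD), "dropped")
  expect_identical(rownames(DD), "cg0000002")
})

test_that("pairedT matches the arithmetic oracle and handles degeneracy", {
  res <- pairedT(c(1, 2, 3, 4, 5))
  expect_equal(res$t, 3 / (sd(1:5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-res$t, 4), tolerance = 1e-12)
  anti <- pairedT(c(-2, 2, -7, 7))
  expect_equal(anti$t, 0)
  expect_equal(anti$p, 1)
  expect_error(pairedT(c(5, 5, 5, 5, 5)), "zero variance")
  zero <- pairedT(rep(0, 6))
  expect_equal(c(zero$t, zero$p), c(0, 1))
})

test_that("the Shapiro-Wilk screen is calibrated and has power", {
  set.seed(13)
  Dnorm <- matrix(rnorm(2000 * 11), 2000, 11)
  frac <- shapiroFraction(Dnorm)$fraction
  expect_lt(abs(frac - 0.05), 0.02)
  Dskew <- matrix(rexp(500 * 11)^2, 500, 11)
  expect_gt(shapiroFraction(Dskew)$fraction, 0.3)
  short <- matrix(1:2, 1, 2)
  expect_equal(shapiroFraction(short)$nExcluded, 1L)
})

test_that("permutation plans pick exhaustive mode when feasible", {
  expect_equal(permutationPlan(11)$mode, "exhaustive")
  expect_equal(permutationPlan(11)$B, 2048L)
  expect_equal(permutationPlan(20)$mode, "sampled")
  expect_equal(permutationPlan(20, B = 500)$B, 500L)
  expect_error(permutationPlan(20, mode = "exhaustive"), "infeasible")
})

test_that("step-down maxT agrees with brute-force enumeration", {
  set.seed(19)
  D <- matrix(rnorm(4 * 5, mean = c(2, 0, 0, 0.5)), 4, 5)
  res <- westfallYoungMaxT(D, plan = permutationPlan(5, mode = "exhaustive"))
  expect_equal(res$p_adj, bruteForceMaxT(D), tolerance = 1e-12)
})

test_that("maxT adjusted P-values satisfy the step-down properties", {
  set.seed(23)
  D <- matrix(rnorm(30 * 8, mean = rep(c(1.5, 0), c(5, 25))), 30, 8)
  res <- westfallYoungMaxT(D, plan = permutationPlan(8, mode = "exhaustive"))
  expect_true(all(res$p_adj >= res$p_perm - 1e-12))
  expect_true(all(res$p_adj >= res$p - 1e-12))
  ord <- order(abs(res$t), decreasing = TRUE)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-12))
  expect_true(all(res$p_adj >= 2^-8))  # exhaustive floor
  # sign symmetry: negating every difference changes nothing but the sign
  resNeg <- westfallYoungMaxT(-D, plan = permutationPlan(8,
                                                         mode = "exhaustive"))
  expect_equal(abs(resNeg$t), abs(res$t))
  expect_equal(resNeg$p, res$p)
  expect_equal(resNeg$p_adj, res$p_adj)
  # single probe: adjusted equals its own sign-flip permutation P
  one <- westfallYoungMaxT(D[1, , drop = FALSE],
                           plan = permutationPlan(8, mode = "exhaustive"))
  expect_equal(one$p_adj, one$p_perm)
})

test_that("sampled maxT converges to the exhaustive values", {
  set.seed(29)
  D <- matrix(rnorm(20 * 10, mean = rep(c(1, 0), c(4, 16))), 20, 10)
  exh <- westfallYoungMaxT(D, plan = permutationPlan(10, mode = "exhaustive"))
  B <- 4000L
  smp <- westfallYoungMaxT(D, plan = permutationPlan(10, B = B,
                                                     mode = "sampled",
                                                     seed = 101))
  tol <- 3 * sqrt(exh$p_adj * (1 - exh$p_adj) / B) + 2 / (B + 1)
  expect_true(all(abs(smp$p_adj - exh$p_adj) <= tol))
})

test_that("probes with missing pairs are handled per the chosen policy", {
  set.seed(31)
  D <- matrix(rnorm(10 * 6), 10, 6)
  D[3, 2] <- NA
  keep <- westfallYoungMaxT(D, plan = permutationPlan(6, mode = "exhaustive"))
  expect_equal(nrow(keep), 10L)
  expect_equal(keep$n[3], 5)
  expect_message(
    drop <- westfallYoungMaxT(D, plan = permutationPlan(6,
                                                        mode = "exhaustive"),
                              incomplete = "drop"),
    "dropped")
  expect_equal(nrow(drop), 9L)
})

test_that("candidate analysis is scoped to candidate probes", {
  g <- generateProbeManifest(300, nCandidate = 40, seed = 41)
  mf <- g$manifest
  candProbe <- mf$probe_id[mf$candidate][1]
  otherProbe <- mf$probe_id[!mf$candidate][1]
  cfgNull <- simulationConfig(nPairs = 11, nProbes = 300, sigmaInd = 0.0354)
  cfgOther <- simulationConfig(nPairs = 11, nProbes = 300, sigmaInd = 0.0354,
                               effectSites = stats::setNames(15, otherProbe))
  plan <- permutationPlan(11, mode = "exhaustive")
  xNull <- generateTwinBeta(cfgNull, manifest = mf, seed = 43)$object
  xOther <- generateTwinBeta(cfgOther, manifest = mf, seed = 43)$object
  resNull <- runCandidateAnalysis(xNull, plan = plan)
  resOther <- runCandidateAnalysis(xOther, plan = plan)
  expect_equal(nrow(resNull), 40L)
  # injecting an effect outside the candidate family leaves it untouched
  expect_equal(resNull[order(resNull$probe_id), c("t", "p", "p_adj")],
               resOther[order(resOther$probe_id), c("t", "p", "p_adj")])
  expect_true(all(resNull$scope == "candidate"))
  expect_error(runCandidateAnalysis(makeToyBeta(5, 3)), "manifest")
})

test_that("genome-wide nulls reject at the nominal raw rate", {
  g <- generateProbeManifest(2000, seed = 47)
  x <- generateTwinBeta(simulationConfig(nPairs = 11, nProbes = 2000),
                        manifest = g$manifest, seed = 47)$object
  res <- runGenomeWide(x, plan = permutationPlan(11, mode = "exhaustive"))
  nRaw <- attr(res, "nRawSignificant")
  expect_gt(nRaw, 50)   # ~100 expected of 2000 at alpha 0.05
  expect_lt(nRaw, 160)
  expect_true(all(res$p_adj >= res$p - 1e-12))
})
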