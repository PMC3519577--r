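test_that("manifest generation honours counts, determinism and feasibility", {
  g <- generateProbeManifest(10, 0, 0, 0, seed = 5)
  expect_equal(sum(!g$manifest$multi_aligned & !g$manifest$snp_in_cpg), 10)
  g2 <- generateProbeManifest(10, 0, 0, 0, seed = 5)
  expect_identical(g, g2)
  g3 <- generateProbeManifest(200, 12, 7, 30, seed = 9)
  expect_equal(sum(g3$manifest$multi_aligned), 12)
  expect_equal(sum(g3$manifest$snp_in_cpg), 7)
  expect_equal(sum(g3$manifest$multi_aligned & g3$manifest$snp_in_cpg), 0)
  expect_equal(sum(g3$manifest$candidate), 30)
  expect_true(all(g3$manifest$gene_symbol[g3$manifest$candidate] %in%
                    t2dCandidateGenes))
  # candidate probes are QC-clean
  expect_false(any(g3$manifest$candidate &
                     (g3$manifest$multi_aligned | g3$manifest$snp_in_cpg)))
  expect_error(generateProbeManifest(10, 8, 5), "exceeds")
  expect_error(generateProbeManifest(10, 5, 4, 5), "exceeds")
})

test_that("probe sequences are embedded once (twice when multi-flagged)", {
  g <- generateProbeManifest(30, nMulti = 3, seed = 11)
  conv <- bisulfiteConvert(g$reference)
  mf <- g$manifest
  for (i in c(which(mf$multi_aligned)[1:2], which(!mf$multi_aligned)[1:3])) {
    expected <- if (mf$multi_aligned[i]) 2L else 1L
    expect_equal(countAlignments(mf$probe_sequence[i], conv), expected)
  }
})

test_that("generated beta respects range, determinism and the noise model", {
  cfg <- simulationConfig(nPairs = 4, nProbes = 100)
  sim <- generateTwinBeta(cfg, seed = 2)
  b <- betaValues(sim$object)
  expect_true(all(b >= 0 & b <= 1))
  expect_identical(b, betaValues(generateTwinBeta(cfg, seed = 2)$object))
  # no individual noise, no effects: co-twins identical
  cfg0 <- simulationConfig(nPairs = 3, nProbes = 50, sigmaInd = 0)
  b0 <- betaValues(generateTwinBeta(cfg0, seed = 4)$object)
  d0 <- studyDesign(generateTwinBeta(cfg0, seed = 4)$object)
  for (p in unique(d0$pair_id)) {
    s <- d0$sample_id[d0$pair_id == p]
    expect_identical(b0[, s[1]], unname(b0[, s[2]]) |>
                       stats::setNames(rownames(b0)))
  }
  expect_error(generateTwinBeta(
    simulationConfig(nPairs = 2, nProbes = 10,
                     effectSites = c(nope = 5)), seed = 1), "absent")
})

test_that("injected effects are recoverable without bias", {
  cfg <- simulationConfig(nPairs = 200, nProbes = 50, sigmaInd = 0.03,
                          effectSites = c(cg0000007 = 8))
  sim <- generateTwinBeta(cfg, seed = 6)
  d <- pairedDifferences(sim$object, "cg0000007")
  # SE of the mean difference: 0.03*sqrt(2)*100/sqrt(200) = 0.3 points
  expect_lt(abs(mean(d) - 8), 1)
  expect_equal(unname(sim$truth$effect["cg0000007"]), 8)
})

test_that("under the null the paired t-test rejects at the nominal rate", {
  rates <- vapply(1:5, function(s) {
    sim <- generateTwinBeta(simulationConfig(nPairs = 11, nProbes = 1000),
                            seed = 100 + s)
    D <- pairedDifferences(sim$object)
    p <- apply(D, 1, function(d) pairedT(d)$p)
    mean(p < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.02)
})

test_that("phenotype generation matches the configured group means", {
  ph <- generatePhenotypes(2000, seed = 8)
  expect_lt(abs(mean(ph$BMI[ph$status == "nonT2D"]) - 30.2), 0.5)
  expect_lt(abs(mean(ph$BMI[ph$status == "T2D"]) - 32.3), 0.5)
  expect_lt(abs(mean(ph$HbA1c[ph$status == "T2D"]) - 7.7), 0.2)
  expect_true(mean(ph$GIR[ph$status == "T2D"]) <
                mean(ph$GIR[ph$status == "nonT2D"]))
  # all SDs zero: every pair sits exactly on the means
  p0 <- lapply(twindiff:::.phenotypeDefaults, function(p)
    c(p[1:2], 0, 0, 0))
  ph0 <- generatePhenotypes(5, seed = 1, params = p0)
  expect_true(all(ph0$BMI[ph0$status == "nonT2D"] == 30.2))
  expect_true(all(ph0$BMI[ph0$status == "T2D"] == 32.3))
  expect_identical(generatePhenotypes(7, seed = 3),
                   generatePhenotypes(7, seed = 3))
})

test_that("repeat panel couples LINE1 variation to BMI discordance only", {
  d <- studyDesign(makeToyBeta(2, 12))
  ph <- generatePhenotypes(12, seed = 2)
  cfg0 <- simulationConfig(nPairs = 12, repeatCoupling = 0)
  rs <- vapply(1:40, function(s) {
    rp <- generateRepeatPanel(d, ph, cfg0, seed = s)
    line1 <- intrapairVariationSd(rp$panel, design = d, probeSet = "LINE1",
                                  scope = "per_pair")
    correlateVariationPhenotype(line1, phenotypeDeltas(ph, "BMI"))$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)  # no coupling, no correlation
  rp <- generateRepeatPanel(d, ph, simulationConfig(nPairs = 12), seed = 1)
  for (el in c("LINE1", "D4Z4", "NBL2")) {
    m <- repeatElement(rp$panel, el)
    expect_true(all(m >= 0 & m <= 100))
  }
  expect_equal(dim(repeatElement(rp$panel, "D4Z4"))[1], 9)
})

test_that("coupled repeat-panel correlation matches a Monte-Carlo oracle", {
  # Oracle: direct simulation of the latent model at the same configuration,
  # bypassing the panel machinery (per-pair scale + SD-of-|N(0, scale)| over
  # 8 sites), averaged over many replicates.
  nP <- 200
  cfg <- simulationConfig(nPairs = nP)
  ph <- generatePhenotypes(nP, seed = 30)
  dBMI <- phenotypeDeltas(ph, "BMI")
  set.seed(99)
  oracle <- mean(vapply(1:500, function(i) {
    sc <- pmax(0.5, cfg@repeatBase[["LINE1"]] + cfg@repeatCoupling * dBMI +
                 rnorm(nP, 0, cfg@repeatNoiseSd))
    sds <- vapply(sc, function(s) sd(abs(rnorm(8, 0, s))), numeric(1))
    cor(sds, dBMI)
  }, numeric(1)))
  d <- studyDesign(makeToyBeta(2, nP))
  obs <- mean(vapply(1:20, function(s) {
    rp <- generateRepeatPanel(d, ph, cfg, seed = 400 + s)
    line1 <- intrapairVariationSd(rp$panel, design = d, probeSet = "LINE1",
                                  scope = "per_pair")
    correlateVariationPhenotype(line1, dBMI)$r
  }, numeric(1)))
  expect_lt(abs(obs - oracle), 0.05)
})

test_that("pooled repeat variation exceeds pooled promoter variation", {
  cfg <- simulationConfig(nPairs = 11, nProbes = 500)
  sim <- generateTwinBeta(cfg, seed = 12)
  d <- studyDesign(sim$object)
  ph <- generatePhenotypes(11, seed = 12)
  rp <- generateRepeatPanel(d, ph, cfg, seed = 12)
  promoterSd <- intrapairVariationSd(sim$object, scope = "pooled")$sd
  repeatSd <- intrapairVariationSd(rp$panel, design = d,
                                   probeSet = "repeats_all",
                                   scope = "pooled")$sd
  expect_gt(repeatSd, promoterSd)
})

test_that("clone counts follow the binomial sampling model", {
  expect_true(all(generateCloneTable(rep(100, 5))$n_methylated == 12))
  expect_true(all(generateCloneTable(rep(0, 5))$n_methylated == 0))
  ct <- generateCloneTable(rep(50, 1e4), nClones = 12, seed = 21)
  expect_true(all(ct$n_methylated + ct$n_unmethylated == 12))
  # mean ~ Binomial(12, .5)/site: SE of the mean count = sqrt(3/1e4)
  expect_lt(abs(mean(ct$n_methylated) - 6), 3 * sqrt(12 * 0.25 / 1e4))
})
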