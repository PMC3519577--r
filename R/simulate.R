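#' Type 2 diabetes susceptibility gene panel
#'
#' The 49 monogenic and confirmed common-variety T2D susceptibility genes
#' used for the candidate analysis; on the 27K array they are represented by
#' 136 probes. Synthetic manifests draw candidate-probe gene symbols from
#' this panel.
#'
#' @format character vector of 49 gene symbols.
#' @export
t2dCandidateGenes <- c(
  "ABCC8", "ADAMTS9", "ADCY5", "AGPAT2", "AKT2", "BSCL2", "CAMK1D", "CAV1",
  "CDC123", "CDKAL1", "CDKN2A", "CDKN2B", "CEL", "CIDEC", "DUSP9", "HHEX",
  "HMGA2", "HNF1A", "HNF1B", "HNF4A", "GCK", "GCKR", "IDE", "IGF2BP2", "INS",
  "INSR", "IRS1", "JAZF1", "KCNJ11", "KCNQ1", "KIF11", "KLF11", "KLF14",
  "LGR5", "LMNA", "MTNR1B", "NEUROD1", "NOTCH2", "PDX1", "PPARG", "PPARGC1A",
  "PROX1", "RBMS1", "SLC30A8", "TBC1D4", "TCF7L2", "TP53INP1", "TSPAN8",
  "WFS1")

# draw from a Beta(a, b) truncated to [lo, hi] by inverse-CDF
.rtruncbeta <- function(n, a, b, lo, hi) {
  stats::qbeta(stats::runif(n, stats::pbeta(lo, a, b),
                            stats::pbeta(hi, a, b)), a, b)
}

#' Build a SimulationConfig with shipped tissue defaults
#'
#' Defaults emulate the study's skeletal-muscle (or subcutaneous adipose)
#' beta-value structure: a low/mid/high truncated-Beta mixture whose weights
#' reproduce the printed tail fractions (64%/13% of probes below 0.25 / above
#' 0.75 in muscle, 65%/15% in adipose), a shared pair baseline perturbation
#' (`sigmaPair = 0.02`) and individual noise calibrated once so that the mean
#' within-pair Pearson correlation of co-twin profiles is ~0.95 in muscle
#' (`sigmaInd = 0.078`) and ~0.97 in adipose (`sigmaInd = 0.060`).
#'
#' @param tissue `"muscle"` or `"adipose"`.
#' @param nPairs,nProbes design size (defaults 11 pairs, 2,000 probes).
#' @param effectSites named numeric of true T2D minus nonT2D differences in
#'   percentage points, keyed by probe id.
#' @param sigmaPair,sigmaInd override the noise SDs (beta scale).
#' @param repeatBase,repeatCoupling,repeatNoiseSd repeat-panel scale
#'   parameters (percentage points; coupling is points per kg/m2 of |delta
#'   BMI|).
#' @param nClones clones per site for simulated bisulfite validation.
#' @return a [SimulationConfig][SimulationConfig-class].
#' @export
simulationConfig <- function(tissue = c("muscle", "adipose"),
                             nPairs = 11L, nProbes = 2000L,
                             effectSites = numeric(0),
                             sigmaPair = 0.02, sigmaInd = NULL,
                             repeatBase = c(LINE1 = 10, D4Z4 = 12, NBL2 = 12),
                             repeatCoupling = 2, repeatNoiseSd = 3,
                             nClones = 12L) {
  tissue <- match.arg(tissue)
  weights <- if (tissue == "muscle") c(0.64, 0.23, 0.13) else
    c(0.65, 0.20, 0.15)
  if (is.null(sigmaInd)) sigmaInd <- if (tissue == "muscle") 0.078 else 0.060
  methods::new("SimulationConfig",
    nPairs = as.integer(nPairs), nProbes = as.integer(nProbes),
    tissue = tissue, mixtureWeights = weights,
    mixtureShapes = list(c(1.5, 15), c(5, 5), c(15, 1.5)),
    mixtureBounds = list(c(0, 0.22), c(0.28, 0.72), c(0.78, 1)),
    sigmaPair = sigmaPair, sigmaInd = sigmaInd,
    effectSites = effectSites, repeatBase = repeatBase,
    repeatCoupling = repeatCoupling, repeatNoiseSd = repeatNoiseSd,
    nClones = as.integer(nClones))
}

#' Generate a synthetic probe manifest with an embedded reference
#'
#' Creates `nTotal` probes with random 50-mer sequences, flags `nMulti` of
#' them as multi-aligning and a disjoint `nSnp` as having a SNP on the
#' interrogated CpG, and marks `nCandidate` of the clean remainder as
#' candidate probes carrying gene symbols from [t2dCandidateGenes]. A
#' reference sequence is generated in which every probe sequence is embedded
#' exactly once -- twice for multi-flagged probes -- so that the alignment
#' filter in [countAlignments()]/[qcFilter()] can be exercised end to end.
#' Probe sequences are drawn C-free (as bisulfite-converted forward-strand
#' probes are), so forward conversion of the reference leaves the embedded
#' copies intact.
#'
#' @param nTotal total probes.
#' @param nMulti probes embedded twice and flagged `multi_aligned`.
#' @param nSnp probes flagged `snp_in_cpg` (disjoint from `nMulti`).
#' @param nCandidate candidate probes among the clean remainder.
#' @param seed integer RNG seed; identical arguments and seed give an
#'   identical manifest.
#' @return list with `manifest` (data.frame, see [readProbeManifest()]),
#'   `reference` (unconverted reference sequence, character scalar) and
#'   `snpPositions` (data.frame of 0-based SNP coordinates).
#' @export
generateProbeManifest <- function(nTotal, nMulti = 0L, nSnp = 0L,
                                  nCandidate = 0L, seed = 1L) {
  nTotal <- as.integer(nTotal); nMulti <- as.integer(nMulti)
  nSnp <- as.integer(nSnp); nCandidate <- as.integer(nCandidate)
  if (nMulti + nSnp > nTotal)
    stop("nMulti + nSnp exceeds nTotal")
  if (nCandidate > nTotal - nMulti - nSnp)
    stop("nCandidate exceeds the number of QC-clean probes")
  set.seed(seed)
  ids <- sprintf("cg%07d", seq_len(nTotal))
  # C-free 50-mers: bisulfite-converted forward-strand probe sequences
  seqs <- vapply(seq_len(nTotal), function(i)
    paste(sample(c("A", "G", "T"), 50, replace = TRUE), collapse = ""),
    character(1))
  flagged <- sample.int(nTotal, nMulti + nSnp)
  multi <- rep(FALSE, nTotal); multi[flagged[seq_len(nMulti)]] <- TRUE
  snp <- rep(FALSE, nTotal)
  if (nSnp) snp[flagged[nMulti + seq_len(nSnp)]] <- TRUE
  clean <- which(!multi & !snp)
  cand <- rep(FALSE, nTotal)
  if (nCandidate) cand[sample(clean, nCandidate)] <- TRUE

  gene <- paste0("GENE", sprintf("%05d", ceiling(seq_len(nTotal) / 2)))
  if (nCandidate)
    gene[cand] <- rep_len(t2dCandidateGenes, nCandidate)
  tss <- sample(-1500:1500, nTotal, replace = TRUE)
  tss[sample.int(nTotal, round(nTotal * 0.1))] <- NA

  # reference: random ACGT filler between embedded probes
  filler <- function(n) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""),
    character(1))
  pieces <- as.vector(rbind(filler(nTotal), seqs))
  extra <- seqs[multi]
  if (length(extra))
    pieces <- c(pieces, as.vector(rbind(filler(length(extra)), extra)))
  reference <- paste(pieces, collapse = "")
  # 0-based start of each probe's first embedding
  starts <- cumsum(c(0L, nchar(pieces)))[seq(2, by = 2,
                                             length.out = nTotal)]
  cpgPos <- as.integer(starts + 24L)  # interrogated CpG offset in reference

  snpIdx <- which(snp)
  snpPositions <- data.frame(
    seqname = rep("synthetic_ref", length(snpIdx)),
    position = if (length(snpIdx))
      cpgPos[snpIdx] + sample(0:1, length(snpIdx), replace = TRUE)
    else integer(0))

  list(manifest = data.frame(
         probe_id = ids, gene_symbol = gene, distance_to_tss = tss,
         probe_sequence = seqs, cpg_position = cpgPos,
         multi_aligned = multi, snp_in_cpg = snp, candidate = cand,
         stringsAsFactors = FALSE),
       reference = reference,
       snpPositions = snpPositions)
}

.defaultManifest <- function(nProbes) {
  data.frame(probe_id = sprintf("cg%07d", seq_len(nProbes)),
             gene_symbol = paste0("GENE", sprintf("%05d",
                                                  ceiling(seq_len(nProbes) / 2))),
             distance_to_tss = NA_integer_,
             probe_sequence = strrep("A", 50), cpg_position = NA_integer_,
             multi_aligned = FALSE, snp_in_cpg = FALSE, candidate = FALSE,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic twin-pair beta matrix
#'
#' Per probe, a mixture component and a baseline methylation level are drawn;
#' per pair, the baseline is perturbed by a shared `sigmaPair` deviation; per
#' individual, `sigmaInd` noise is added and the value truncated to \[0, 1\].
#' At effect sites the configured difference (percentage points / 100) is
#' added to the T2D twin before truncation. Co-twins thus share a pair-level
#' profile, which is what produces the strong within-pair correlation seen
#' in discordant-twin methylome data.
#'
#' @param config a [SimulationConfig][SimulationConfig-class].
#' @param manifest optional probe manifest; its `probe_id` order defines the
#'   rows (and must contain all `effectSites`). When `NULL` a minimal
#'   manifest of `config@nProbes` probes is used.
#' @param seed integer RNG seed.
#' @return list with `object` (a [TwinBetaSet][TwinBetaSet-class]) and
#'   `truth` (list: `baseline`, `component`, `effect` per probe;
#'   `pairShift`, the probes-by-pairs latent pair perturbations).
#' @export
generateTwinBeta <- function(config, manifest = NULL, seed = 1L) {
  stopifnot(methods::is(config, "SimulationConfig"))
  methods::validObject(config)
  if (is.null(manifest)) manifest <- .defaultManifest(config@nProbes)
  probes <- manifest$probe_id
  nProbes <- length(probes)
  np <- config@nPairs
  eff <- config@effectSites
  if (length(eff) && !all(names(eff) %in% probes))
    stop("effectSites refer to probes absent from the manifest")
  set.seed(seed)
  comp <- sample.int(3L, nProbes, replace = TRUE,
                     prob = config@mixtureWeights)
  base <- numeric(nProbes)
  for (k in 1:3) {
    idx <- comp == k
    sh <- config@mixtureShapes[[k]]; bd <- config@mixtureBounds[[k]]
    base[idx] <- .rtruncbeta(sum(idx), sh[1], sh[2], bd[1], bd[2])
  }
  effect <- numeric(nProbes); names(effect) <- probes
  effect[names(eff)] <- eff

  pid <- sprintf("P%02d", seq_len(np))
  samples <- as.vector(rbind(paste0(pid, "_T2D"), paste0(pid, "_non")))
  beta <- matrix(NA_real_, nProbes, 2L * np,
                 dimnames = list(probes, samples))
  pairShift <- matrix(0, nProbes, np, dimnames = list(probes, pid))
  for (p in seq_len(np)) {
    shift <- stats::rnorm(nProbes, 0, config@sigmaPair)
    pairShift[, p] <- shift
    pb <- base + shift
    t2d <- pb + effect / 100 + stats::rnorm(nProbes, 0, config@sigmaInd)
    non <- pb + stats::rnorm(nProbes, 0, config@sigmaInd)
    beta[, 2L * p - 1L] <- pmin(1, pmax(0, t2d))
    beta[, 2L * p] <- pmin(1, pmax(0, non))
  }
  design <- data.frame(
    sample_id = samples,
    pair_id = rep(pid, each = 2L),
    status = rep(c("T2D", "nonT2D"), np),
    tissue = config@tissue,
    sex = rep(rep_len(c("F", "M"), np), each = 2L),
    stringsAsFactors = FALSE)
  list(object = TwinBetaSet(beta, design, manifest = manifest),
       truth = list(baseline = stats::setNames(base, probes),
                    component = stats::setNames(comp, probes),
                    effect = effect, pairShift = pairShift))
}

.phenotypeDefaults <- list(
  #             meanNon meanT2D sdShared sdNon  sdT2D
  BMI        = c(30.2,   32.3,   6.0,    1.93,  2.24),
  glucose_2h = c(9.3,    15.0,   1.0,    1.62,  3.35),
  GIR        = c(6.0,    3.5,    1.0,    1.73,  1.12),
  HbA1c      = c(6.0,    7.7,    0.3,    0.40,  1.37))

#' Generate per-pair twin phenotypes
#'
#' Draws BMI (kg/m2), 2-hour OGTT plasma glucose (mmol/l), glucose infusion
#' rate (GIR, mg/kg/min) and HbA1c (%) for each twin. Each trait has a shared
#' pair-level component plus independent twin deviations, so co-twins are
#' correlated and the intra-pair difference distribution is realistic for a
#' discordant-pair design. Group means/SDs for BMI and HbA1c follow the
#' study's subject characteristics (30.2+-6.3 vs 32.3+-6.4 kg/m2;
#' 6.0+-0.5 vs 7.7+-1.4 %); the glycemic traits use defaults typical of
#' impaired-glucose-tolerant versus overtly diabetic elderly twins.
#'
#' @param nPairs number of pairs.
#' @param seed integer RNG seed.
#' @param params optional override list with the structure of the shipped
#'   defaults (per trait: meanNon, meanT2D, sdShared, sdNon, sdT2D).
#' @return `data.frame` with two rows per pair (`pair_id`, `status`, one
#'   column per trait).
#' @export
generatePhenotypes <- function(nPairs, seed = 1L, params = NULL) {
  stopifnot(nPairs >= 1)
  if (is.null(params)) params <- .phenotypeDefaults
  set.seed(seed)
  pid <- sprintf("P%02d", seq_len(nPairs))
  out <- data.frame(pair_id = rep(pid, each = 2L),
                    status = rep(c("T2D", "nonT2D"), nPairs),
                    stringsAsFactors = FALSE)
  for (tr in names(params)) {
    p <- params[[tr]]
    shared <- rep(stats::rnorm(nPairs, 0, p[3]), each = 2L)
    mu <- rep(c(p[2], p[1]), nPairs)
    dev <- stats::rnorm(2L * nPairs, 0, rep(c(p[5], p[4]), nPairs))
    out[[tr]] <- pmax(0.1, mu + shared + dev)
  }
  out
}

#' Generate a synthetic repetitive-element methylation panel
#'
#' Per pair, the latent intra-pair difference scale for LINE1 is
#' `base + repeatCoupling * |delta BMI| + noise`; D4Z4 and NBL2 scales are
#' uncoupled from phenotype. Per CpG site, co-twin values are the site mean
#' plus independent deviations of SD `scale / sqrt(2)`, so the intra-pair
#' difference has SD `scale` (percentage points); values are truncated to
#' \[0, 100\].
#'
#' @param design study-design `data.frame` (`sample_id`, `pair_id`,
#'   `status`), e.g. `studyDesign(x)`.
#' @param phenotypes output of [generatePhenotypes()] for the same pairs.
#' @param config a [SimulationConfig][SimulationConfig-class] supplying
#'   `repeatBase`, `repeatCoupling`, `repeatNoiseSd`.
#' @param seed integer RNG seed.
#' @return list with `panel` (a [RepeatPanel][RepeatPanel-class]) and
#'   `truth` (per-element matrix of latent per-pair scales).
#' @export
generateRepeatPanel <- function(design, phenotypes, config, seed = 1L) {
  stopifnot(methods::is(config, "SimulationConfig"))
  pid <- sort(unique(design$pair_id))
  bmi <- merge(phenotypes[phenotypes$status == "T2D", c("pair_id", "BMI")],
               phenotypes[phenotypes$status == "nonT2D", c("pair_id", "BMI")],
               by = "pair_id", suffixes = c("_t2d", "_non"))
  dBMI <- abs(bmi$BMI_t2d - bmi$BMI_non)[match(pid, bmi$pair_id)]
  if (anyNA(dBMI)) stop("phenotypes do not cover every design pair")
  set.seed(seed)
  siteCounts <- c(LINE1 = 8L, D4Z4 = 9L, NBL2 = 8L)
  siteMeans <- list(LINE1 = stats::runif(8, 60, 80),
                    D4Z4 = stats::runif(9, 45, 65),
                    NBL2 = stats::runif(8, 70, 90))
  ord <- design$sample_id[order(match(design$pair_id, pid),
                                design$status != "T2D")]
  mats <- list(); scales <- list()
  for (el in names(siteCounts)) {
    ns <- siteCounts[[el]]
    sc <- config@repeatBase[[el]] +
      (if (el == "LINE1") config@repeatCoupling * dBMI else 0) +
      stats::rnorm(length(pid), 0, config@repeatNoiseSd)
    sc <- pmax(0.5, sc)
    m <- matrix(NA_real_, ns, 2L * length(pid),
                dimnames = list(paste0(el, "_cpg", seq_len(ns)), ord))
    for (p in seq_along(pid)) {
      a <- siteMeans[[el]] + stats::rnorm(ns, 0, sc[p] / sqrt(2))
      b <- siteMeans[[el]] + stats::rnorm(ns, 0, sc[p] / sqrt(2))
      m[, 2L * p - 1L] <- pmin(100, pmax(0, a))
      m[, 2L * p] <- pmin(100, pmax(0, b))
    }
    mats[[el]] <- m
    scales[[el]] <- stats::setNames(sc, pid)
  }
  list(panel = methods::new("RepeatPanel", LINE1 = mats$LINE1,
                            D4Z4 = mats$D4Z4, NBL2 = mats$NBL2),
       truth = scales)
}

#' Simulate a bisulfite-sequencing clone-count table
#'
#' Per site, the methylated clone count is binomial(`nClones`,
#' `truePct / 100`), mirroring how colonies are scored after cloning an
#' amplicon.
#'
#' @param truePct numeric vector of true per-site methylation percentages in
#'   \[0, 100\]; names become site ids.
#' @param nClones clones sequenced per site (the study collected 12).
#' @param seed integer RNG seed.
#' @param ampliconId optional amplicon label stored in the `amplicon_id`
#'   column.
#' @return clone-table `data.frame` (`site`, `n_methylated`,
#'   `n_unmethylated`, `amplicon_id`).
#' @export
generateCloneTable <- function(truePct, nClones = 12L, seed = 1L,
                               ampliconId = "amplicon1") {
  stopifnot(all(truePct >= 0 & truePct <= 100), nClones >= 1)
  set.seed(seed)
  nm <- stats::rbinom(length(truePct), nClones, truePct / 100)
  data.frame(site = if (is.null(names(truePct)))
               paste0("cpg", seq_along(truePct)) else names(truePct),
             n_methylated = nm, n_unmethylated = nClones - nm,
             amplicon_id = ampliconId, stringsAsFactors = FALSE)
}
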