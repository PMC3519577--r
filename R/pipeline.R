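#' Default pipeline configuration
#'
#' Builds the configuration list for [runPipeline()]: stage toggles,
#' simulation settings, permutation plan parameters and thresholds. The
#' demo-scale defaults (2,000 probes, 11 muscle pairs, exhaustive sign
#' flips) run the whole pipeline in well under a minute.
#'
#' @param nProbes,nPairs simulated design size.
#' @param tissue `"muscle"` or `"adipose"`.
#' @param effectSites named numeric of injected differences (percentage
#'   points by probe id).
#' @param permutations `B` for sampled mode.
#' @param permutationMode `"auto"`, `"exhaustive"` or `"sampled"`.
#' @param detectionThreshold detection-P masking threshold.
#' @param significance raw significance level.
#' @param lowThreshold,highThreshold methylation-category cut points.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "qc", "global", "differential", "power", "validate",
#'   "enrich")`.
#' @param seed integer master seed; stage seeds are derived from it.
#' @return configuration list (class `"PipelineConfig"`).
#' @export
pipelineConfig <- function(nProbes = 2000L, nPairs = 11L,
                           tissue = "muscle", effectSites = numeric(0),
                           permutations = 10000L,
                           permutationMode = "auto",
                           detectionThreshold = 0.05, significance = 0.05,
                           lowThreshold = 0.25, highThreshold = 0.75,
                           stages = c("simulate", "qc", "global",
                                      "differential", "power", "validate",
                                      "enrich"),
                           seed = 1L) {
  stopifnot(detectionThreshold > 0, detectionThreshold < 1,
            significance > 0, significance < 1,
            lowThreshold > 0, highThreshold < 1,
            lowThreshold < highThreshold)
  structure(list(nProbes = as.integer(nProbes), nPairs = as.integer(nPairs),
                 tissue = tissue, effectSites = effectSites,
                 permutations = as.integer(permutations),
                 permutationMode = permutationMode,
                 detectionThreshold = detectionThreshold,
                 significance = significance,
                 lowThreshold = lowThreshold,
                 highThreshold = highThreshold,
                 stages = stages, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipelineConfig()] arguments.
#' @return configuration list (class `"PipelineConfig"`).
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$effectSites)) y$effectSites <- unlist(y$effectSites)
  do.call(pipelineConfig, y)
}

.stageSeed <- function(config, offset) config$seed + 1000L * offset

#' Run the twin-discordance methylation pipeline end to end
#'
#' Orchestrates simulate -> qc -> global -> differential -> power ->
#' validate -> enrich on synthetic data, writing per-stage TSV outputs, a
#' JSON summary of headline numbers and the resolved configuration (YAML)
#' into `outDir`. Runs are deterministic given the configuration seed;
#' stage failures abort with a stage-named error, retaining partial outputs.
#'
#' @param config a [pipelineConfig()] (or path handled by
#'   [readPipelineConfig()]).
#' @param outDir output directory, created if needed.
#' @return invisibly, the summary list (also written as `summary.json`).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config)[names(config) != "effectSites" |
                                     lengths(config) > 0],
                   file.path(outDir, "config_resolved.yaml"))
  summary <- list(seed = config$seed)
  produced <- character(0)
  emit <- function(name) produced <<- c(produced, name)
  runStage <- function(name, expr) {
    if (!name %in% config$stages) return(NULL)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # simulate ----------------------------------------------------------------
  sim <- NULL; mf <- NULL; phen <- NULL
  runStage("simulate", {
    mfGen <- generateProbeManifest(config$nProbes,
                                   nMulti = max(0L, round(config$nProbes * 0.018)),
                                   nSnp = max(0L, round(config$nProbes * 0.0085)),
                                   nCandidate = min(136L, config$nProbes %/% 4L),
                                   seed = .stageSeed(config, 1L))
    mf <- mfGen$manifest
    cfg <- simulationConfig(tissue = config$tissue, nPairs = config$nPairs,
                            nProbes = config$nProbes,
                            effectSites = config$effectSites)
    sim <- generateTwinBeta(cfg, manifest = mf,
                             seed = .stageSeed(config, 2L))
    phen <- generatePhenotypes(config$nPairs,
                                seed = .stageSeed(config, 3L))
    writeBetaMatrix(sim$object, file.path(outDir, "beta.tsv"),
                    file.path(outDir, "design.tsv"))
    writeProbeManifest(mf, file.path(outDir, "manifest.tsv"))
    utils::write.table(phen, file.path(outDir, "phenotypes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("beta.tsv"); emit("design.tsv"); emit("manifest.tsv")
    emit("phenotypes.tsv")
    summary$simulate <- list(nProbes = nrow(sim$object),
                              nSamples = ncol(sim$object),
                              nPairs = config$nPairs)
  })
  if (is.null(sim)) stop("the pipeline requires the simulate stage")

  # qc ----------------------------------------------------------------------
  x <- sim$object
  runStage("qc", {
    q <- qcFilter(mf)
    writeQcReport(q$report, file.path(outDir, "qc_report.tsv"))
    emit("qc_report.tsv")
    summary$qc <- list(nInput = q$report@nInput,
                        nExcludedMulti = q$report@nExcludedMulti,
                        nExcludedSnp = q$report@nExcludedSnp,
                        nRetained = q$report@nRetained)
    keep <- rownames(betaValues(x)) %in% q$manifest$probe_id
    x <- TwinBetaSet(betaValues(x)[keep, , drop = FALSE], studyDesign(x),
                      manifest = q$manifest)
  })

  # global ------------------------------------------------------------------
  runStage("global", {
    fr <- methylationFractions(x, config$lowThreshold, config$highThreshold)
    d <- studyDesign(x)
    rs <- vapply(sort(unique(d$pair_id)), function(p) {
      s <- d$sample_id[d$pair_id == p]
      sampleCorrelation(x, s[1], s[2])$r
    }, numeric(1))
    an <- overallAnova(x)
    pooledProm <- intrapairVariationSd(x, scope = "pooled")
    rp <- generateRepeatPanel(d, phen,
                              simulationConfig(tissue = config$tissue,
                                               nPairs = config$nPairs),
                              seed = .stageSeed(config, 4L))
    pooledRep <- intrapairVariationSd(rp$panel, design = d,
                                      probeSet = "repeats_all",
                                      scope = "pooled")
    line1 <- intrapairVariationSd(rp$panel, design = d, probeSet = "LINE1",
                                  scope = "per_pair")
    cv <- correlateVariationPhenotype(line1, phenotypeDeltas(phen, "BMI"))
    utils::write.table(an, file.path(outDir, "anova.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(rbind(pooledProm, pooledRep, line1),
                       file.path(outDir, "variation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("anova.tsv"); emit("variation.tsv")
    summary$global <- list(
      fractionLow = fr$fractionLow, fractionHigh = fr$fractionHigh,
      meanWithinPairR = mean(rs),
      anovaPairP = an$p[an$term == "pair"],
      pooledPromoterSd = pooledProm$sd, pooledRepeatSd = pooledRep$sd,
      line1BmiR = cv$r, line1BmiP = cv$p)
  })

  # differential ------------------------------------------------------------
  runStage("differential", {
    plan <- permutationPlan(config$nPairs, B = config$permutations,
                            mode = config$permutationMode,
                            seed = .stageSeed(config, 5L))
    cand <- runCandidateAnalysis(x, plan = plan)
    gw <- runGenomeWide(x, plan = plan)
    writeDifferentialResults(cand, file.path(outDir, "candidate.tsv"))
    writeDifferentialResults(gw, file.path(outDir, "genome_wide.tsv"))
    emit("candidate.tsv"); emit("genome_wide.tsv")
    summary$differential <- list(
      permutationMode = attr(cand, "mode"),
      nPermutations = attr(cand, "nPermutations"),
      candidateRawSignificant = attr(cand, "nRawSignificant"),
      candidateAdjSignificant = attr(cand, "nAdjSignificant"),
      genomeWideRawSignificant = attr(gw, "nRawSignificant"),
      genomeWideAdjSignificant = attr(gw, "nAdjSignificant"))
  })

  # power -------------------------------------------------------------------
  runStage("power", {
    pt <- powerTable()
    utils::write.table(pt, file.path(outDir, "power_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("power_table.tsv")
    summary$power <- stats::setNames(
      as.list(pt$rounded),
      paste0(pt$tissue, "_m", pt$m_tests))
  })

  # validate ----------------------------------------------------------------
  runStage("validate", {
    top <- rownames(betaValues(x))[1]
    truePct <- pmin(100, pmax(0, betaValues(x)[top, 1:5] * 100))
    ct <- generateCloneTable(stats::setNames(truePct, paste0("cpg", 1:5)),
                             seed = .stageSeed(config, 6L))
    cs <- cloneMethylationSummary(ct)
    utils::write.table(ct, file.path(outDir, "clone_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("clone_table.tsv")
    summary$validate <- list(ampliconMean = cs$ampliconMean,
                              nSites = length(cs$perSite))
  })

  # enrich ------------------------------------------------------------------
  runStage("enrich", {
    gw <- utils::read.delim(file.path(outDir, "genome_wide.tsv"))
    bg <- unique(probeManifest(x)$gene_symbol)
    hits <- unique(gw$gene_symbol[gw$p < config$significance])
    set.seed(.stageSeed(config, 7L))
    sets <- list(
      demo_set_hitlike = unique(c(sample(hits, min(20, length(hits))),
                                  sample(bg, 30))),
      demo_set_random = sample(bg, 50))
    et <- enrichmentTable(hits, sets, bg)
    utils::write.table(et, file.path(outDir, "enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("enrichment.tsv")
    summary$enrich <- list(nHitGenes = length(hits),
                            topSet = et$set[1], topSetP = et$p[1])
  })

  summary$files <- c("config_resolved.yaml", produced, "summary.json")
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
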