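#' Container for twin-pair methylation beta values
#'
#' `TwinBetaSet` extends
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' and holds a probes-by-samples matrix of methylation beta values (fraction
#' methylated, 0 to 1, `NA` for masked cells) in the `"beta"` assay, the twin
#' study design in `colData` (columns `sample_id`, `pair_id`, `status`,
#' `tissue`, `sex`), and optionally a probe manifest in `rowData`.
#'
#' Validity requires: all non-missing beta values in \[0, 1\]; unique probe and
#' sample identifiers; each (pair, tissue) combination carrying exactly one
#' `"T2D"` and one `"nonT2D"` sample; co-twins of identical sex.
#'
#' @param beta numeric matrix of beta values with probe rownames and sample
#'   colnames. Missing measurements are `NA`.
#' @param design `data.frame` keyed by `sample_id` with columns `pair_id`,
#'   `status` (`"T2D"`/`"nonT2D"`), `tissue`, `sex`. Every matrix column must
#'   be present; extra design rows are an error.
#' @param manifest optional probe manifest `data.frame` (see
#'   [generateProbeManifest()]) whose `probe_id` column covers all matrix rows.
#' @param x a `TwinBetaSet`.
#' @param ... unused.
#'
#' @return `TwinBetaSet()` returns a validated object. `betaValues()` the beta
#'   matrix, `studyDesign()` the design `data.frame`, `probeManifest()` the
#'   manifest `data.frame` (or `NULL`), `pairIds()` the sorted pair
#'   identifiers, `nPairs()` their number.
#'
#' @examples
#' beta <- matrix(runif(8), 2, 4,
#'                dimnames = list(c("cg01", "cg02"), paste0("S", 1:4)))
#' design <- data.frame(sample_id = paste0("S", 1:4),
#'                      pair_id = rep(c("P1", "P2"), each = 2),
#'                      status = rep(c("T2D", "nonT2D"), 2),
#'                      tissue = "muscle", sex = rep(c("F", "M"), each = 2))
#' tbs <- TwinBetaSet(beta, design)
#' nPairs(tbs)
#'
#' @aliases betaValues studyDesign probeManifest pairIds nPairs
#' @export
setClass("TwinBetaSet", contains = "SummarizedExperiment")

.validTwinBetaSet <- function(object) {
  msg <- character()
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    return("assay 'beta' is missing")
  b <- SummarizedExperiment::assay(object, "beta")
  if (anyDuplicated(rownames(b)))
    msg <- c(msg, "probe identifiers are not unique")
  if (anyDuplicated(colnames(b)))
    msg <- c(msg, "sample identifiers are not unique")
  v <- b[!is.na(b)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    msg <- c(msg, "beta values outside [0, 1]")
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "pair_id", "status", "tissue", "sex")
  if (!all(need %in% colnames(cd))) {
    msg <- c(msg, paste("design columns missing:",
                        paste(setdiff(need, colnames(cd)), collapse = ", ")))
  } else {
    if (!all(cd$status %in% c("T2D", "nonT2D")))
      msg <- c(msg, "status must be 'T2D' or 'nonT2D'")
    key <- paste(cd$pair_id, cd$tissue)
    for (k in unique(key)) {
      st <- cd$status[key == k]
      if (length(st) != 2L || !setequal(st, c("T2D", "nonT2D")))
        msg <- c(msg, paste0("pair/tissue '", k,
                             "' does not have exactly one T2D and one nonT2D sample"))
      sx <- cd$sex[key == k]
      if (length(unique(sx)) > 1L)
        msg <- c(msg, paste0("co-twins of pair/tissue '", k, "' differ in sex"))
    }
  }
  if (length(msg)) msg else TRUE
}

setValidity("TwinBetaSet", .validTwinBetaSet)

#' Probe quality-control report
#'
#' Summarises the probe-validity filter: how many input probes were excluded
#' for aligning to more than one location in the bisulfite-converted
#' reference, how many of the remainder for a SNP on the interrogated CpG,
#' and how many were retained. Dispositions are mutually exclusive
#' (multi-alignment takes precedence) and partition the input exactly.
#'
#' @slot nInput number of probes examined.
#' @slot nExcludedMulti probes excluded for multiple alignments.
#' @slot nExcludedSnp probes excluded for a SNP in the CpG site.
#' @slot nRetained probes surviving both filters.
#' @slot disposition character vector named by probe id, one of
#'   `"retained"`, `"multi_aligned"`, `"snp_in_cpg"`.
#'
#' @seealso [qcFilter()]
#' @export
setClass("QcReport",
  representation(nInput = "integer", nExcludedMulti = "integer",
                 nExcludedSnp = "integer", nRetained = "integer",
                 disposition = "character"))

setValidity("QcReport", function(object) {
  msg <- character()
  if (object@nInput != object@nExcludedMulti + object@nExcludedSnp +
        object@nRetained)
    msg <- c(msg, "dispositions do not partition the input")
  tab <- table(factor(object@disposition,
                      levels = c("retained", "multi_aligned", "snp_in_cpg")))
  if (tab[["retained"]] != object@nRetained ||
      tab[["multi_aligned"]] != object@nExcludedMulti ||
      tab[["snp_in_cpg"]] != object@nExcludedSnp)
    msg <- c(msg, "per-probe dispositions disagree with the totals")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic twin-methylome generator
#'
#' Holds the free parameters of the generator: the three-component mixture of
#' truncated Beta distributions that produces the bimodal per-probe baseline
#' methylation, the between-pair (`sigmaPair`) and within-pair individual
#' (`sigmaInd`) noise standard deviations on the beta scale, disease effects
#' to inject at chosen probes, and the coupling of LINE1 intra-pair
#' variability to the pair's BMI discordance.
#'
#' Shipped defaults (see [simulationConfig()]) reproduce the calibration
#' targets of the skeletal-muscle study data: ~64% of probes with mean beta
#' below 0.25, ~13% above 0.75, and mean within-pair Pearson r ~0.95.
#'
#' @slot nPairs number of twin pairs.
#' @slot nProbes number of probes.
#' @slot tissue tissue label attached to generated samples.
#' @slot mixtureWeights numeric(3), low/mid/high component weights (sum 1).
#' @slot mixtureShapes list of 3 `c(shape1, shape2)` Beta parameters.
#' @slot mixtureBounds list of 3 `c(lo, hi)` truncation intervals on \[0, 1\].
#' @slot sigmaPair SD of the shared pair-level baseline perturbation.
#' @slot sigmaInd SD of the individual noise added to each twin.
#' @slot effectSites named numeric, true T2D minus nonT2D difference in
#'   percentage points per probe id.
#' @slot repeatBase named numeric(3), baseline intra-pair difference scale
#'   (percentage points) for LINE1, D4Z4, NBL2.
#' @slot repeatCoupling slope linking the per-pair LINE1 scale to |delta BMI|.
#' @slot repeatNoiseSd SD of the per-pair scale noise (percentage points).
#' @slot nClones clones sequenced per site in simulated validation data.
#'
#' @seealso [simulationConfig()], [generateTwinBeta()], [generateRepeatPanel()]
#' @export
setClass("SimulationConfig",
  representation(nPairs = "integer", nProbes = "integer", tissue = "character",
                 mixtureWeights = "numeric", mixtureShapes = "list",
                 mixtureBounds = "list", sigmaPair = "numeric",
                 sigmaInd = "numeric", effectSites = "numeric",
                 repeatBase = "numeric", repeatCoupling = "numeric",
                 repeatNoiseSd = "numeric", nClones = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nPairs < 1L) msg <- c(msg, "nPairs must be >= 1")
  if (object@nProbes < 1L) msg <- c(msg, "nProbes must be >= 1")
  if (length(object@mixtureWeights) != 3L ||
      abs(sum(object@mixtureWeights) - 1) > 1e-8 ||
      any(object@mixtureWeights < 0))
    msg <- c(msg, "mixtureWeights must be 3 non-negative weights summing to 1")
  if (object@sigmaPair < 0 || object@sigmaInd < 0)
    msg <- c(msg, "noise SDs must be >= 0")
  if (object@nClones < 1L) msg <- c(msg, "nClones must be >= 1")
  if (length(object@effectSites) &&
      is.null(names(object@effectSites)))
    msg <- c(msg, "effectSites must be named by probe id")
  if (!setequal(names(object@repeatBase), c("LINE1", "D4Z4", "NBL2")))
    msg <- c(msg, "repeatBase must be named LINE1, D4Z4, NBL2")
  if (length(msg)) msg else TRUE
})

#' Repetitive-element methylation panel
#'
#' Per-sample, per-CpG methylation percentages for the three repetitive DNA
#' families assayed by bisulfite pyrosequencing: LINE1 (interspersed repeat,
#' 8 CpG sites), D4Z4 (tandem repeat, 9 sites) and NBL2 (tandem repeat,
#' 8 sites). Values are percentages in \[0, 100\]; columns are samples and
#' must agree across elements.
#'
#' @slot LINE1 8 x n matrix of percentages.
#' @slot D4Z4 9 x n matrix of percentages.
#' @slot NBL2 8 x n matrix of percentages.
#'
#' @seealso [generateRepeatPanel()], [intrapairVariationSd()]
#' @export
setClass("RepeatPanel",
  representation(LINE1 = "matrix", D4Z4 = "matrix", NBL2 = "matrix"))

setValidity("RepeatPanel", function(object) {
  msg <- character()
  dims <- c(LINE1 = 8L, D4Z4 = 9L, NBL2 = 8L)
  for (el in names(dims)) {
    m <- slot(object, el)
    if (nrow(m) != dims[[el]])
      msg <- c(msg, paste0(el, " must have ", dims[[el]], " CpG sites"))
    if (length(m) && (min(m) < 0 || max(m) > 100))
      msg <- c(msg, paste0(el, " percentages outside [0, 100]"))
  }
  if (!identical(colnames(object@LINE1), colnames(object@D4Z4)) ||
      !identical(colnames(object@LINE1), colnames(object@NBL2)))
    msg <- c(msg, "sample columns differ between elements")
  if (length(msg)) msg else TRUE
})
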