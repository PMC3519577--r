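#' @include AllClasses.R AllGenerics.R
NULL

.checkDesignFrame <- function(design) {
  need <- c("sample_id", "pair_id", "status", "tissue", "sex")
  miss <- setdiff(need, colnames(design))
  if (length(miss))
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  bad <- design$sample_id[is.na(design$pair_id) | design$pair_id == ""]
  if (length(bad))
    stop("design lacks a pair_id for sample(s): ", paste(bad, collapse = ", "))
  invisible(design)
}

#' @rdname TwinBetaSet-class
#' @export
TwinBetaSet <- function(beta, design, manifest = NULL) {
  if (!is.matrix(beta) || !is.numeric(beta))
    stop("beta must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("beta must have probe rownames and sample colnames")
  design <- as.data.frame(design)
  .checkDesignFrame(design)
  absent <- setdiff(colnames(beta), design$sample_id)
  if (length(absent))
    stop("sample(s) in matrix absent from design: ",
         paste(absent, collapse = ", "))
  design <- design[match(colnames(beta), design$sample_id), , drop = FALSE]
  rownames(design) <- design$sample_id
  rd <- S4Vectors::DataFrame(row.names = rownames(beta))
  if (!is.null(manifest)) {
    manifest <- as.data.frame(manifest)
    if (anyDuplicated(manifest$probe_id))
      stop("manifest probe ids are not unique")
    hit <- match(rownames(beta), manifest$probe_id)
    if (anyNA(hit))
      stop("manifest does not cover probe(s): ",
           paste(utils::head(rownames(beta)[is.na(hit)], 5), collapse = ", "))
    rd <- S4Vectors::DataFrame(manifest[hit, , drop = FALSE],
                               row.names = rownames(beta))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = beta),
    colData = S4Vectors::DataFrame(design, row.names = design$sample_id),
    rowData = rd)
  methods::new("TwinBetaSet", se)
}

#' @rdname TwinBetaSet-class
#' @export
setMethod("betaValues", "TwinBetaSet", function(x, ...)
  SummarizedExperiment::assay(x, "beta"))

#' @rdname TwinBetaSet-class
#' @export
setMethod("studyDesign", "TwinBetaSet", function(x, ...)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname TwinBetaSet-class
#' @export
setMethod("probeManifest", "TwinBetaSet", function(x, ...) {
  rd <- SummarizedExperiment::rowData(x)
  if (!ncol(rd)) return(NULL)
  as.data.frame(rd)
})

#' @rdname TwinBetaSet-class
#' @export
setMethod("pairIds", "TwinBetaSet", function(x, ...)
  sort(unique(studyDesign(x)$pair_id)))

#' @rdname TwinBetaSet-class
#' @export
setMethod("nPairs", "TwinBetaSet", function(x, ...)
  length(pairIds(x)))

setMethod("show", "TwinBetaSet", function(object) {
  d <- studyDesign(object)
  cat("TwinBetaSet:", nrow(object), "probes x", ncol(object), "samples\n")
  cat("  pairs:", length(unique(d$pair_id)),
      " tissue(s):", paste(unique(d$tissue), collapse = ", "), "\n")
  nm <- sum(is.na(betaValues(object)))
  cat("  missing beta values:", nm, "\n")
})

setMethod("show", "QcReport", function(object) {
  cat("QcReport:", object@nInput, "probes in\n")
  cat("  excluded, multiple alignments:", object@nExcludedMulti, "\n")
  cat("  excluded, SNP in CpG site:   ", object@nExcludedSnp, "\n")
  cat("  retained:                    ", object@nRetained, "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nProbes, "probes,", object@nPairs,
      "pairs,", object@tissue, "\n")
  cat("  mixture weights:", paste(object@mixtureWeights, collapse = "/"),
      " sigmaPair:", object@sigmaPair, " sigmaInd:", object@sigmaInd, "\n")
  cat("  effect sites:", length(object@effectSites), "\n")
})

setMethod("show", "RepeatPanel", function(object) {
  cat("RepeatPanel: LINE1 (8), D4Z4 (9), NBL2 (8) sites x",
      ncol(object@LINE1), "samples\n")
})

#' Repeat-panel element accessor
#'
#' @param x a [RepeatPanel][RepeatPanel-class].
#' @param element one of `"LINE1"`, `"D4Z4"`, `"NBL2"`.
#' @return the sites-by-samples percentage matrix for that element.
#' @export
repeatElement <- function(x, element = c("LINE1", "D4Z4", "NBL2")) {
  stopifnot(methods::is(x, "RepeatPanel"))
  slot(x, match.arg(element))
}

#' Twin pairs with complete data at a probe
#'
#' Lists the pair identifiers for which both co-twins have a non-missing beta
#' value at the given probe, in ascending pair order. Paired tests use exactly
#' these pairs (complete-pair analysis per probe).
#'
#' @param x a [TwinBetaSet][TwinBetaSet-class].
#' @param probe a probe identifier present in `x`.
#' @param ... unused.
#' @return character vector of pair ids (possibly empty).
#' @export
setMethod("completePairs", "TwinBetaSet", function(x, probe, ...) {
  b <- betaValues(x)
  if (!probe %in% rownames(b)) stop("unknown probe: ", probe)
  d <- studyDesign(x)
  ok <- !is.na(b[probe, d$sample_id])
  keep <- vapply(split(ok, d$pair_id), all, logical(1))
  sort(names(keep)[keep])
})
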