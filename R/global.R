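#' Fractions of low- and high-methylated probes
#'
#' Classifies probes by their mean beta over samples: low when strictly below
#' `low` (the study's "<25%"), high when strictly above `high` (">75%"),
#' intermediate otherwise. Probes with all values missing are excluded and
#' counted.
#'
#' @param x a [TwinBetaSet][TwinBetaSet-class] or numeric beta matrix.
#' @param low,high classification thresholds on the beta scale.
#' @return list with `fractionLow`, `fractionMid`, `fractionHigh` (fractions
#'   of classified probes, summing to 1), `nProbes` classified and
#'   `nExcluded` all-missing probes.
#' @export
methylationFractions <- function(x, low = 0.25, high = 0.75) {
  b <- if (methods::is(x, "TwinBetaSet")) betaValues(x) else x
  if (!nrow(b)) stop("empty beta matrix")
  m <- rowMeans(b, na.rm = TRUE)
  excluded <- !is.finite(m)
  m <- m[!excluded]
  if (!length(m)) stop("all probes are fully missing")
  list(fractionLow = mean(m < low),
       fractionMid = mean(m >= low & m <= high),
       fractionHigh = mean(m > high),
       nProbes = length(m), nExcluded = sum(excluded))
}

#' Pearson correlation between two samples' beta profiles
#'
#' Correlates two columns of the beta matrix over probes where both are
#' non-missing, as in co-twin or cross-tissue similarity scatter plots.
#'
#' @param x a [TwinBetaSet][TwinBetaSet-class] or beta matrix.
#' @param sampleA,sampleB sample identifiers (column names).
#' @param method `"pearson"` (default, as reported) or `"spearman"`.
#' @return list with `r`, `p` (two-sided), `n` complete probes.
#' @export
sampleCorrelation <- function(x, sampleA, sampleB,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  b <- if (methods::is(x, "TwinBetaSet")) betaValues(x) else x
  if (!all(c(sampleA, sampleB) %in% colnames(b)))
    stop("unknown sample id")
  a <- b[, sampleA]; bb <- b[, sampleB]
  ok <- !is.na(a) & !is.na(bb)
  if (sum(ok) < 3L) stop("fewer than 3 complete probes")
  if (stats::sd(a[ok]) == 0 || stats::sd(bb[ok]) == 0)
    stop("constant profile: correlation undefined")
  ct <- stats::cor.test(a[ok], bb[ok], method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Two-factor ANOVA of overall methylation
#'
#' Fits, on the long-format non-missing beta values, an ANOVA with twin pair,
#' disease status and their interaction as explanatory factors, using
#' sequential (type I) sums of squares in that order. A significant pair
#' effect reflects co-twin similarity of the overall methylation pattern; a
#' significant interaction indicates pair-specific disease effects.
#'
#' @param x a [TwinBetaSet][TwinBetaSet-class] with at least 2 pairs.
#' @return `data.frame` with one row per term (`pair`, `status`,
#'   `pair:status`, `Residuals`): `df`, `F`, `p`.
#' @export
overallAnova <- function(x) {
  if (nPairs(x) < 2L)
    stop("at least 2 pairs are required (interaction unidentifiable)")
  b <- betaValues(x)
  d <- studyDesign(x)
  long <- data.frame(
    value = as.vector(b),
    pair = factor(rep(d$pair_id[match(colnames(b), d$sample_id)],
                      each = nrow(b))),
    status = factor(rep(d$status[match(colnames(b), d$sample_id)],
                        each = nrow(b))))
  long <- long[!is.na(long$value), ]
  fit <- stats::aov(value ~ pair + status + pair:status, data = long)
  s <- summary(fit)[[1]]
  data.frame(term = trimws(rownames(s)), df = s$Df, F = s$`F value`,
             p = s$`Pr(>F)`, row.names = NULL)
}

.pairDiffMatrix <- function(values, design, pairs = NULL) {
  # values: sites x samples, percentage scale; returns |T2D - nonT2D| signed
  if (is.null(pairs)) pairs <- sort(unique(design$pair_id))
  t2d <- design$sample_id[match(paste(pairs, "T2D"),
                                paste(design$pair_id, design$status))]
  non <- design$sample_id[match(paste(pairs, "nonT2D"),
                                paste(design$pair_id, design$status))]
  if (anyNA(t2d) || anyNA(non))
    stop("design does not provide both co-twins for every pair")
  d <- values[, t2d, drop = FALSE] - values[, non, drop = FALSE]
  colnames(d) <- pairs
  d
}

#' Intra-pair methylation variation (SD of absolute differences)
#'
#' The variation statistic: the standard deviation of the absolute intra-pair
#' methylation differences (percentage points). With `scope = "per_pair"` the
#' SD is taken across the probe set separately for each pair (the per-pair
#' points of a variation-versus-phenotype plot); with `scope = "pooled"` it
#' is taken over all pairs and probes jointly (the headline
#' repeats-versus-promoters comparison). The absolute value is applied before
#' the SD, so the statistic is invariant to which twin is labelled first.
#'
#' Probes with a missing value in either co-twin of a pair contribute no
#' difference for that pair (complete-pair rule); an attribute `nDropped`
#' counts them.
#'
#' @param x a [TwinBetaSet][TwinBetaSet-class] (beta rescaled to
#'   percentages), a [RepeatPanel][RepeatPanel-class] element label via
#'   `probeSet`, or a sites-by-samples percentage matrix.
#' @param design study design `data.frame`; taken from `x` when it is a
#'   `TwinBetaSet`.
#' @param probeSet for a `TwinBetaSet`/matrix: optional row subset (probe
#'   ids); for a `RepeatPanel`: one of `"LINE1"`, `"D4Z4"`, `"NBL2"`,
#'   `"repeats_all"`.
#' @param scope `"pooled"` or `"per_pair"`.
#' @param label probe-set label stored in the output (defaults to a sensible
#'   name).
#' @return `data.frame` (scope, probe_set, pair_id, sd); one row for pooled
#'   scope, one per pair otherwise. Attribute `nDropped`: incomplete
#'   (probe, pair) differences excluded.
#' @export
intrapairVariationSd <- function(x, design = NULL, probeSet = NULL,
                                 scope = c("pooled", "per_pair"),
                                 label = NULL) {
  scope <- match.arg(scope)
  if (methods::is(x, "TwinBetaSet")) {
    design <- studyDesign(x)
    values <- betaValues(x) * 100
    if (!is.null(probeSet)) values <- values[probeSet, , drop = FALSE]
    if (is.null(label)) label <- "promoters"
  } else if (methods::is(x, "RepeatPanel")) {
    if (is.null(probeSet)) probeSet <- "repeats_all"
    values <- if (probeSet == "repeats_all")
      rbind(x@LINE1, x@D4Z4, x@NBL2) else repeatElement(x, probeSet)
    if (is.null(label)) label <- probeSet
  } else {
    values <- x
    if (!is.null(probeSet)) values <- values[probeSet, , drop = FALSE]
    if (is.null(label)) label <- "custom"
  }
  if (!nrow(values)) stop("empty probe set")
  if (is.null(design)) stop("a study design is required")
  d <- abs(.pairDiffMatrix(values, design))
  nDropped <- sum(is.na(d))
  if (scope == "pooled") {
    v <- d[!is.na(d)]
    if (length(v) < 2L) stop("fewer than 2 usable differences")
    out <- data.frame(scope = "pooled", probe_set = label,
                      pair_id = NA_character_, sd = stats::sd(v))
  } else {
    sds <- apply(d, 2, function(col) {
      v <- col[!is.na(col)]
      if (length(v) < 2L) NA_real_ else stats::sd(v)
    })
    out <- data.frame(scope = "per_pair", probe_set = label,
                      pair_id = colnames(d), sd = unname(sds))
  }
  attr(out, "nDropped") <- nDropped
  out
}

#' Correlate intra-pair variation with phenotype discordance
#'
#' Pearson correlation of the per-pair variation SD against the absolute
#' intra-pair phenotype difference (e.g. LINE1 variation versus |delta BMI|).
#'
#' @param perPair per-pair output of [intrapairVariationSd()] (or a numeric
#'   vector named by pair id).
#' @param phenotypeDelta numeric vector of absolute phenotype differences
#'   named by pair id.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `r`, `p`, `n`.
#' @export
correlateVariationPhenotype <- function(perPair, phenotypeDelta,
                                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.data.frame(perPair))
    perPair <- stats::setNames(perPair$sd, perPair$pair_id)
  common <- intersect(names(perPair), names(phenotypeDelta))
  if (length(common) < 3L) stop("fewer than 3 pairs in common")
  a <- perPair[common]; b <- phenotypeDelta[common]
  ok <- !is.na(a) & !is.na(b)
  if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(a[ok], b[ok], method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Absolute intra-pair phenotype differences
#'
#' @param phenotypes output of [generatePhenotypes()] (or any long
#'   per-pair/per-status phenotype table).
#' @param trait column name, e.g. `"BMI"`.
#' @return numeric |T2D - nonT2D| per pair, named by pair id.
#' @export
phenotypeDeltas <- function(phenotypes, trait) {
  t2d <- phenotypes[phenotypes$status == "T2D", ]
  non <- phenotypes[phenotypes$status == "nonT2D", ]
  i <- match(t2d$pair_id, non$pair_id)
  stats::setNames(abs(t2d[[trait]] - non[[trait]][i]), t2d$pair_id)
}
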