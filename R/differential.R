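#' Per-probe intra-pair methylation differences
#'
#' Computes, for each probe, the vector of paired differences
#' `100 * (beta_T2D - beta_nonT2D)` in percentage points, one entry per
#' complete pair, ordered by ascending pair id. Pairs with a missing value in
#' either twin contribute `NA` for that probe; probes with fewer than 2
#' complete pairs are dropped with a message.
#'
#' @param x a [TwinBetaSet][TwinBetaSet-class].
#' @param probes optional subset of probe ids (default: all).
#' @return probes-by-pairs numeric matrix (percentage points) with `NA` for
#'   incomplete pairs; attribute `dropped` lists probes removed for having
#'   fewer than 2 complete pairs.
#' @export
pairedDifferences <- function(x, probes = NULL) {
  b <- betaValues(x)
  if (!is.null(probes)) {
    unknown <- setdiff(probes, rownames(b))
    if (length(unknown))
      stop("unknown probe(s): ", paste(utils::head(unknown, 5), collapse = ", "))
    b <- b[probes, , drop = FALSE]
  }
  d <- .pairDiffMatrix(b * 100, studyDesign(x))
  nComplete <- rowSums(!is.na(d))
  dropped <- rownames(d)[nComplete < 2L]
  if (length(dropped)) {
    message(length(dropped), " probe(s) dropped with < 2 complete pairs")
    d <- d[nComplete >= 2L, , drop = FALSE]
  }
  attr(d, "dropped") <- dropped
  d
}

#' Paired t-test on a difference vector
#'
#' One-sample t-test of the intra-pair differences against zero, two-sided P
#' from the t distribution with n - 1 degrees of freedom.
#'
#' @param d numeric vector of paired differences (percentage points); `NA`s
#'   removed.
#' @return list with `mean`, `t`, `p` (two-sided), `n`, `df`. An all-zero
#'   vector gives `t = 0`, `p = 1`; zero variance with nonzero mean is a
#'   degenerate case and errors.
#' @examples
#' pairedT(c(1, 2, 3, 4, 5))  # t = 3 / (sd/sqrt(5)) = 4.2426
#' @export
pairedT <- function(d) {
  d <- d[!is.na(d)]
  if (length(d) < 2L) stop("fewer than 2 paired differences")
  m <- mean(d); s <- stats::sd(d); n <- length(d)
  if (s == 0) {
    if (m == 0) return(list(mean = 0, t = 0, p = 1, n = n, df = n - 1L))
    stop("zero variance with nonzero mean: t statistic undefined")
  }
  tval <- m / (s / sqrt(n))
  list(mean = m, t = tval, p = 2 * stats::pt(-abs(tval), n - 1L),
       n = n, df = n - 1L)
}

#' Shapiro-Wilk normality screen of difference vectors
#'
#' Applies the Shapiro-Wilk test to each probe's paired-difference vector and
#' reports the fraction with P < `alpha`, the screen used to justify
#' parametric paired tests.
#'
#' @param diffs probes-by-pairs difference matrix (see
#'   [pairedDifferences()]).
#' @param alpha screening level (default 0.05).
#' @return list with `p` (named per-probe SW P-values), `fraction` below
#'   `alpha`, and `nExcluded` probes too short (n < 3) or degenerate for the
#'   test.
#' @export
shapiroFraction <- function(diffs, alpha = 0.05) {
  p <- apply(diffs, 1, function(d) {
    d <- d[!is.na(d)]
    if (length(d) < 3L || length(d) > 5000L) return(NA_real_)
    if (stats::sd(d) == 0) return(NA_real_)
    stats::shapiro.test(d)$p.value
  })
  list(p = p, fraction = mean(p < alpha, na.rm = TRUE),
       nExcluded = sum(is.na(p)))
}

#' Plan the sign-flip permutation scheme
#'
#' In a paired design the exchangeable operation under the null is swapping
#' the co-twin labels within a pair, i.e. flipping the sign of that pair's
#' difference -- applied jointly across probes so inter-probe correlation is
#' preserved. With `mode = "auto"` the full set of `2^nPairs` sign
#' assignments is enumerated when it does not exceed `cap` (default 4,096,
#' i.e. up to 12 pairs); otherwise `B` random assignments are sampled.
#'
#' @param nPairs number of complete pairs.
#' @param B permutations in sampled mode (the study used 10,000).
#' @param mode `"auto"`, `"exhaustive"` or `"sampled"`.
#' @param cap largest admissible `2^nPairs` for exhaustive mode.
#' @param seed RNG seed for sampled mode.
#' @return list of class `"PermutationPlan"`: `mode`, `nPairs`, `B` (number
#'   of sign assignments actually used), `seed`.
#' @export
permutationPlan <- function(nPairs, B = 10000L,
                            mode = c("auto", "exhaustive", "sampled"),
                            cap = 4096L, seed = NULL) {
  mode <- match.arg(mode)
  nPairs <- as.integer(nPairs)
  exhaustiveSize <- 2^nPairs
  if (mode == "auto")
    mode <- if (exhaustiveSize <= cap) "exhaustive" else "sampled"
  if (mode == "exhaustive" && exhaustiveSize > cap)
    stop("exhaustive enumeration infeasible: 2^", nPairs, " exceeds cap ", cap)
  if (mode == "sampled" && B < 1L) stop("B must be >= 1")
  structure(list(mode = mode, nPairs = nPairs,
                 B = if (mode == "exhaustive") as.integer(exhaustiveSize)
                     else as.integer(B),
                 seed = seed),
            class = "PermutationPlan")
}

# |t| statistics for every sign assignment in S (pairs x B matrix of +-1).
# NAs in D are treated as absent pairs: they contribute nothing to any flip,
# and each probe's statistic uses its own complete-pair count.
.flipT <- function(A, present, nj, ssq, S) {
  m <- (A %*% S) / nj
  v <- (ssq - nj * m^2) / (nj - 1)
  v[v < 0] <- 0  # guard against negative rounding residue
  tt <- abs(m) / sqrt(v / nj)
  tt[abs(m) < 1e-12] <- 0     # covers 0/0 for all-zero probes
  tt
}

#' Westfall-Young step-down maxT adjusted P-values
#'
#' Family-wise error control by the step-down maxT resampling procedure:
#' probes are ordered by decreasing |t|; for every sign-flip assignment the
#' statistics are recomputed and successive maxima taken from the least
#' significant probe upward; each probe's adjusted P is the fraction of
#' assignments whose successive maximum reaches its observed |t|, with
#' monotonicity enforced along the ordering. Because all probes are flipped
#' jointly, the inter-probe correlation structure enters the null
#' distribution, which is what distinguishes the procedure from Bonferroni.
#'
#' In sampled mode the estimator is `(b + 1) / (B + 1)` so no adjusted P is
#' exactly zero; in exhaustive mode the exact proportion over all `2^n`
#' assignments (identity included) is returned, whose smallest possible
#' value is `2^-n`.
#'
#' @param diffs probes-by-pairs difference matrix (percentage points, `NA`
#'   for incomplete pairs, each probe with >= 2 complete pairs).
#' @param plan a [permutationPlan()]; default: auto for `ncol(diffs)` pairs.
#' @param incomplete `"keep"` (default) retains probes with missing pairs,
#'   computing their statistics on their complete pairs within the same
#'   family; `"drop"` removes them from the family first.
#' @param blockSize permutations processed per block (memory control).
#' @return `data.frame` with `probe_id`, `n`, `mean`, `t`, `p` (raw
#'   two-sided, t distribution), `p_perm` (marginal sign-flip P), `p_adj`
#'   (step-down maxT); attributes `mode` and `nPermutations`.
#' @export
westfallYoungMaxT <- function(diffs, plan = NULL,
                              incomplete = c("keep", "drop"),
                              blockSize = 1024L) {
  incomplete <- match.arg(incomplete)
  if (is.null(dim(diffs))) diffs <- matrix(diffs, nrow = 1)
  if (is.null(rownames(diffs)))
    rownames(diffs) <- paste0("probe", seq_len(nrow(diffs)))
  if (incomplete == "drop") {
    keep <- rowSums(is.na(diffs)) == 0L
    if (!all(keep)) {
      message(sum(!keep), " probe(s) with incomplete pairs dropped from the family")
      diffs <- diffs[keep, , drop = FALSE]
    }
  }
  n <- ncol(diffs); m <- nrow(diffs)
  if (is.null(plan)) plan <- permutationPlan(n)
  if (plan$nPairs != n) stop("plan was built for a different number of pairs")
  nj <- rowSums(!is.na(diffs))
  if (any(nj < 2L)) stop("every probe needs >= 2 complete pairs")
  A <- diffs; A[is.na(A)] <- 0
  ssq <- rowSums(A^2)

  tobs <- as.vector(.flipT(A, NULL, nj, ssq, matrix(1, n, 1)))
  rawP <- 2 * stats::pt(-tobs, nj - 1L)

  if (plan$mode == "exhaustive") {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    S <- t(unname(signs))
  } else {
    if (!is.null(plan$seed)) set.seed(plan$seed)
    S <- matrix(sample(c(1, -1), n * plan$B, replace = TRUE), n, plan$B)
  }
  B <- ncol(S)
  ord <- order(tobs, decreasing = TRUE)
  tSorted <- tobs[ord]
  countStep <- numeric(m)   # successive-max exceedances (step-down)
  countMarg <- numeric(m)   # marginal exceedances per probe (sorted order)
  for (start in seq(1, B, by = blockSize)) {
    cols <- start:min(start + blockSize - 1L, B)
    Tb <- .flipT(A, NULL, nj, ssq, S[, cols, drop = FALSE])
    Tb <- Tb[ord, , drop = FALSE]
    countMarg <- countMarg + rowSums(Tb >= tSorted)
    if (m > 1L)
      for (r in seq(m - 1L, 1L)) Tb[r, ] <- pmax(Tb[r, ], Tb[r + 1L, ])
    countStep <- countStep + rowSums(Tb >= tSorted)
  }
  est <- if (plan$mode == "exhaustive") function(cnt) cnt / B
         else function(cnt) (cnt + 1) / (B + 1)
  adjSorted <- cummax(est(countStep))
  adj <- numeric(m); adj[ord] <- adjSorted
  marg <- numeric(m); marg[ord] <- est(countMarg)

  out <- data.frame(probe_id = rownames(diffs), n = nj,
                    mean = rowSums(A) / nj, t = tobs * sign(rowSums(A)),
                    p = rawP, p_perm = marg, p_adj = adj,
                    row.names = NULL)
  attr(out, "mode") <- plan$mode
  attr(out, "nPermutations") <- B
  out
}

.differentialTable <- function(x, probes, plan, scope, incomplete) {
  diffs <- pairedDifferences(x, probes)
  res <- westfallYoungMaxT(diffs, plan = plan, incomplete = incomplete)
  b <- betaValues(x) * 100
  d <- studyDesign(x)
  t2d <- d$sample_id[d$status == "T2D"]
  non <- d$sample_id[d$status == "nonT2D"]
  i <- match(res$probe_id, rownames(b))
  res$mean_t2d <- rowMeans(b[i, t2d, drop = FALSE], na.rm = TRUE)
  res$sd_t2d <- apply(b[i, t2d, drop = FALSE], 1, stats::sd, na.rm = TRUE)
  res$mean_nont2d <- rowMeans(b[i, non, drop = FALSE], na.rm = TRUE)
  res$sd_nont2d <- apply(b[i, non, drop = FALSE], 1, stats::sd, na.rm = TRUE)
  mf <- probeManifest(x)
  if (!is.null(mf)) {
    j <- match(res$probe_id, mf$probe_id)
    res$gene_symbol <- mf$gene_symbol[j]
    res$distance_to_tss <- mf$distance_to_tss[j]
  }
  res$scope <- scope
  cols <- intersect(c("probe_id", "gene_symbol", "distance_to_tss", "n",
                      "mean_t2d", "sd_t2d", "mean_nont2d", "sd_nont2d",
                      "mean", "t", "p", "p_perm", "p_adj", "scope"),
                    colnames(res))
  out <- res[order(res$p), cols]
  rownames(out) <- NULL
  attr(out, "mode") <- attr(res, "mode")
  attr(out, "nPermutations") <- attr(res, "nPermutations")
  attr(out, "nRawSignificant") <- sum(res$p < 0.05)
  attr(out, "nAdjSignificant") <- sum(res$p_adj < 0.05)
  out
}

#' Candidate-gene differential methylation analysis
#'
#' Paired t-tests at the candidate probes (those flagged `candidate` in the
#' manifest, the 136 probes of the 49 susceptibility genes in the study's
#' design) with Westfall-Young maxT adjustment over that family alone.
#'
#' @param x a [TwinBetaSet][TwinBetaSet-class] whose manifest marks the
#'   candidate probes.
#' @param plan a [permutationPlan()] (default auto: exhaustive up to 12
#'   pairs, else 10,000 sampled flips).
#' @param incomplete see [westfallYoungMaxT()].
#' @return `data.frame` ordered by raw P with group means +- SD (percent),
#'   difference (percentage points, T2D minus nonT2D), `t`, `p`, `p_adj`;
#'   attributes `nRawSignificant`, `nAdjSignificant`, `mode`,
#'   `nPermutations`.
#' @export
runCandidateAnalysis <- function(x, plan = NULL,
                                 incomplete = c("keep", "drop")) {
  mf <- probeManifest(x)
  if (is.null(mf) || !"candidate" %in% colnames(mf))
    stop("the manifest must flag candidate probes")
  probes <- mf$probe_id[mf$candidate]
  if (!length(probes)) stop("no candidate probes in the manifest")
  .differentialTable(x, probes, plan, "candidate", match.arg(incomplete))
}

#' Genome-wide (explorative) differential methylation analysis
#'
#' Paired t-tests at every QC-retained probe with maxT adjustment over the
#' full family.
#'
#' @inheritParams runCandidateAnalysis
#' @return as [runCandidateAnalysis()], scope `"genome_wide"`.
#' @export
runGenomeWide <- function(x, plan = NULL, incomplete = c("keep", "drop")) {
  mf <- probeManifest(x)
  probes <- if (!is.null(mf) &&
                all(c("multi_aligned", "snp_in_cpg") %in% colnames(mf)))
    mf$probe_id[!mf$multi_aligned & !mf$snp_in_cpg]
  else rownames(betaValues(x))
  .differentialTable(x, probes, plan, "genome_wide", match.arg(incomplete))
}

#' Write a differential result table as TSV
#'
#' Columns mirror the published result tables: probe target id, gene,
#' distance to TSS, group means +- SD, difference, P and adjusted P.
#'
#' @param result output of [runCandidateAnalysis()] or [runGenomeWide()].
#' @param path output TSV.
#' @return invisibly, `path`.
#' @export
writeDifferentialResults <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
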