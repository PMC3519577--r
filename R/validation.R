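#' Summarise clone-count methylation for an amplicon
#'
#' Per site, the methylation percentage is
#' `methylated / (methylated + unmethylated) * 100`; the amplicon value is
#' the unweighted mean over sites ("average methylation of all CpG sites in
#' the amplicon"). Sites with zero clones are excluded and flagged.
#'
#' @param cloneTable `data.frame` with columns `site`, `n_methylated`,
#'   `n_unmethylated` (see [readCloneTable()], [generateCloneTable()]).
#' @return list with `perSite` (named percentages), `ampliconMean`, and
#'   `excludedSites` (zero-clone sites).
#' @examples
#' tab <- data.frame(site = c("s1", "s2"), n_methylated = c(6, 3),
#'                   n_unmethylated = c(6, 9))
#' cloneMethylationSummary(tab)  # sites 50 and 25, amplicon mean 37.5
#' @export
cloneMethylationSummary <- function(cloneTable) {
  tot <- cloneTable$n_methylated + cloneTable$n_unmethylated
  if (any(cloneTable$n_methylated < 0 | cloneTable$n_unmethylated < 0))
    stop("negative clone counts")
  empty <- tot == 0
  if (all(empty)) stop("no site has any clones")
  if (any(empty))
    warning(sum(empty), " site(s) with zero clones excluded")
  pct <- 100 * cloneTable$n_methylated[!empty] / tot[!empty]
  names(pct) <- cloneTable$site[!empty]
  list(perSite = pct, ampliconMean = mean(pct),
       excludedSites = cloneTable$site[empty])
}

#' One-sided paired validation test
#'
#' Paired t-test of the validation measurements (e.g. bisulfite-sequencing
#' percentages in three twin pairs) with a one-sided alternative in the
#' direction the array reported -- the a-priori replication hypothesis.
#'
#' @param t2d,nonT2d equal-length paired vectors of methylation percentages.
#' @param direction `"greater"` if the array found higher methylation in the
#'   T2D twin, `"less"` otherwise.
#' @return list with `p` (one-sided), `t`, `df`, `meanDifference`.
#' @export
oneSidedPairedValidation <- function(t2d, nonT2d,
                                     direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(length(t2d) == length(nonT2d), length(t2d) >= 2)
  d <- t2d - nonT2d
  if (stats::sd(d) == 0)
    stop("zero variance of paired differences: test degenerate")
  ht <- stats::t.test(t2d, nonT2d, paired = TRUE, alternative = direction)
  list(p = ht$p.value, t = unname(ht$statistic),
       df = unname(ht$parameter), meanDifference = mean(d))
}

#' Fisher exact gene-set enrichment
#'
#' One-sided (over-representation) Fisher exact test of the 2x2 table
#' cross-classifying background genes by set membership and differential-
#' methylation status. Only genes in the background (those represented on
#' the array) are counted: set genes outside it are dropped with a warning,
#' and duplicate entries are removed. P-values are reported without
#' multiple-testing adjustment, as is conventional for exploratory pathway
#' scans.
#'
#' @param hitGenes differentially methylated genes (conventionally: >= 1
#'   probe with raw P < 0.05); must be a subset of `backgroundGenes`.
#' @param geneSet gene symbols of the pathway.
#' @param backgroundGenes all array-represented genes.
#' @param directions optional named numeric of per-gene mean differences,
#'   used to report the fractions of hit genes in the set with increased /
#'   decreased methylation.
#' @return list with `setName`-free fields: `counts` (hitsInSet, hitsOut,
#'   nonHitsInSet, nonHitsOut), `oddsRatio`, `p`, and `direction`
#'   (`fracUp`, `fracDown`) when `directions` is given.
#' @export
fisherEnrichment <- function(hitGenes, geneSet, backgroundGenes,
                             directions = NULL) {
  backgroundGenes <- unique(backgroundGenes)
  if (!length(backgroundGenes)) stop("empty background")
  hitGenes <- unique(hitGenes)
  geneSet <- unique(geneSet)
  outside <- setdiff(geneSet, backgroundGenes)
  if (length(outside)) {
    warning(length(outside),
            " gene-set gene(s) absent from the background dropped")
    geneSet <- intersect(geneSet, backgroundGenes)
  }
  bad <- setdiff(hitGenes, backgroundGenes)
  if (length(bad))
    stop("hit gene(s) absent from the background: ",
         paste(utils::head(bad, 5), collapse = ", "))
  a <- length(intersect(hitGenes, geneSet))
  b <- length(hitGenes) - a
  cc <- length(geneSet) - a
  d <- length(backgroundGenes) - a - b - cc
  ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                           alternative = "greater")
  out <- list(counts = c(hitsInSet = a, hitsOut = b, nonHitsInSet = cc,
                         nonHitsOut = d),
              oddsRatio = unname(ft$estimate), p = ft$p.value)
  if (!is.null(directions)) {
    dd <- directions[intersect(hitGenes, geneSet)]
    dd <- dd[!is.na(dd)]
    out$direction <- c(fracUp = if (length(dd)) mean(dd > 0) else NA_real_,
                       fracDown = if (length(dd)) mean(dd < 0) else NA_real_)
  }
  out
}

#' Enrichment over a collection of gene sets
#'
#' Applies [fisherEnrichment()] to every set of a GMT collection and returns
#' a table sorted by P.
#'
#' @inheritParams fisherEnrichment
#' @param geneSets named list of gene vectors (see [readGmt()]).
#' @return `data.frame` with one row per set: `set`, the four contingency
#'   counts, `odds_ratio`, `p`, and direction fractions when `directions`
#'   is supplied.
#' @export
enrichmentTable <- function(hitGenes, geneSets, backgroundGenes,
                            directions = NULL) {
  rows <- lapply(names(geneSets), function(nm) {
    e <- fisherEnrichment(hitGenes, geneSets[[nm]], backgroundGenes,
                          directions)
    data.frame(set = nm, hits_in_set = e$counts[["hitsInSet"]],
               hits_out = e$counts[["hitsOut"]],
               nonhits_in_set = e$counts[["nonHitsInSet"]],
               nonhits_out = e$counts[["nonHitsOut"]],
               odds_ratio = e$oddsRatio, p = e$p,
               frac_up = if (is.null(directions)) NA_real_
                         else e$direction[["fracUp"]],
               frac_down = if (is.null(directions)) NA_real_
                           else e$direction[["fracDown"]])
  })
  out <- do.call(rbind, rows)
  out[order(out$p), , drop = FALSE]
}
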