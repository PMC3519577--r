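# Fixture builders and independent oracles shared across the suite.

# Small valid TwinBetaSet: deterministic values unless beta is supplied.
makeToyBeta <- function(nProbes = 10, nPairs = 4, beta = NULL,
                        tissue = "muscle") {
  pid <- sprintf("P%02d", seq_len(nPairs))
  samples <- as.vector(rbind(paste0(pid, "_T2D"), paste0(pid, "_non")))
  if (is.null(beta)) {
    beta <- matrix(seq(0.05, 0.95, length.out = nProbes * 2 * nPairs),
                   nProbes, 2 * nPairs)
  }
  dimnames(beta) <- list(sprintf("cg%07d", seq_len(nProbes)), samples)
  design <- data.frame(sample_id = samples,
                       pair_id = rep(pid, each = 2),
                       status = rep(c("T2D", "nonT2D"), nPairs),
                       tissue = tissue,
                       sex = rep(rep_len(c("F", "M"), nPairs), each = 2),
                       stringsAsFactors = FALSE)
  TwinBetaSet(beta, design)
}

# Quadratic position-by-position scan: reference alignment oracle.
bruteForceScan <- function(probe, refStrand, maxMismatches = 0) {
  pChars <- strsplit(probe, "")[[1]]
  rChars <- strsplit(refStrand, "")[[1]]
  k <- length(pChars); n <- length(rChars)
  if (k > n) return(0L)
  hits <- 0L
  for (start in seq_len(n - k + 1L)) {
    mm <- sum(rChars[start:(start + k - 1L)] != pChars)
    if (mm <= maxMismatches) hits <- hits + 1L
  }
  hits
}

# Step-down maxT by direct enumeration of all sign flips, computing each
# permuted t with stats::t.test -- independent of the package's vectorised
# engine.
bruteForceMaxT <- function(D) {
  m <- nrow(D); n <- ncol(D)
  tAbs <- function(mat) apply(mat, 1, function(d)
    abs(unname(stats::t.test(d)$statistic)))
  tobs <- tAbs(D)
  ord <- order(tobs, decreasing = TRUE)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  counts <- numeric(m)
  for (b in seq_len(nrow(signs))) {
    tStar <- tAbs(sweep(D, 2, signs[b, ], `*`))[ord]
    v <- rev(cummax(rev(tStar)))           # successive maxima, bottom-up
    counts <- counts + (v >= tobs[ord])
  }
  adj <- cummax(counts / nrow(signs))
  out <- numeric(m); out[ord] <- adj
  out
}

# One-sided upper hypergeometric tail by explicit enumeration with choose().
hyperTail <- function(a, b, cc, d) {
  # P(X >= a) for X ~ Hypergeometric drawing (a+b) hits from a background
  # with (a+cc) set genes out of (a+b+cc+d)
  nSet <- a + cc; nHits <- a + b; N <- a + b + cc + d
  ks <- a:min(nSet, nHits)
  sum(choose(nSet, ks) * choose(N - nSet, nHits - ks) / choose(N, nHits))
}
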