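#' Construct bisulfite-converted reference strands
#'
#' Full bisulfite conversion of an unmethylated genome reads every cytosine
#' as thymine. For alignment of converted probe sequences, two in-silico
#' references are built: the forward strand with every C replaced by T, and
#' the reverse strand with every G replaced by A (the reverse-strand
#' conversion as seen in forward coordinates). `N` is preserved.
#'
#' The conversion is idempotent per strand: re-converting the forward output
#' leaves it unchanged.
#'
#' @param reference character scalar or
#'   [DNAString][Biostrings::DNAString-class]; alphabet A/C/G/T/N.
#' @return object of class `"ConvertedReference"`: list with `forward`,
#'   `reverse` (character) and `sourceLength`.
#' @examples
#' bisulfiteConvert("ACGT")  # forward "ATGT", reverse "ACAT"
#' @export
bisulfiteConvert <- function(reference) {
  if (methods::is(reference, "DNAString") ||
      methods::is(reference, "XString"))
    reference <- as.character(reference)
  stopifnot(is.character(reference), length(reference) == 1L)
  if (grepl("[^ACGTN]", reference))
    stop("reference contains characters outside A/C/G/T/N")
  structure(list(forward = chartr("C", "T", reference),
                 reverse = chartr("G", "A", reference),
                 sourceLength = nchar(reference)),
            class = "ConvertedReference")
}

#' Count probe alignments against a converted reference
#'
#' Scans both bisulfite-converted strands for occurrences of the probe
#' sequence with at most `maxMismatches` mismatches (no gaps) and returns the
#' total number of distinct start positions. A probe is uniquely aligned iff
#' the count is 1. This is a deliberate seed-free replacement for a full
#' BLAT-style aligner: at synthetic-reference scale the uniqueness criterion,
#' not alignment score, is what matters.
#'
#' @param probeSequence character scalar, alphabet A/C/G/T.
#' @param converted a `"ConvertedReference"` from [bisulfiteConvert()].
#' @param maxMismatches allowed mismatches per hit (default 0, exact match).
#' @return integer hit count (forward plus reverse strand).
#' @export
countAlignments <- function(probeSequence, converted, maxMismatches = 0L) {
  stopifnot(inherits(converted, "ConvertedReference"))
  if (!nzchar(probeSequence)) stop("empty probe sequence")
  if (nchar(probeSequence) > converted$sourceLength)
    stop("probe longer than reference")
  pat <- Biostrings::BString(probeSequence)
  sum(vapply(c(converted$forward, converted$reverse), function(s)
    Biostrings::countPattern(pat, Biostrings::BString(s),
                             max.mismatch = maxMismatches),
    integer(1)))
}

#' Flag probes whose interrogated CpG carries a SNP
#'
#' A probe is flagged when a SNP coordinate falls on either base of the
#' interrogated CpG dinucleotide, i.e. on `cpg_position` (the C) or
#' `cpg_position + 1` (the G). SNPs elsewhere in the probe body do not
#' trigger exclusion.
#'
#' @param manifest probe manifest `data.frame` with a `cpg_position` column
#'   (0-based reference offsets).
#' @param snpPositions integer vector of 0-based SNP coordinates, or a
#'   `data.frame` with a `position` column (see [readSnpPositions()]).
#' @return the manifest with `snp_in_cpg` recomputed.
#' @export
flagSnpCpg <- function(manifest, snpPositions) {
  if (is.data.frame(snpPositions)) snpPositions <- snpPositions$position
  snpPositions <- as.integer(snpPositions)
  manifest$snp_in_cpg <- manifest$cpg_position %in% snpPositions |
    (manifest$cpg_position + 1L) %in% snpPositions
  manifest$snp_in_cpg[is.na(manifest$cpg_position)] <- FALSE
  manifest
}

#' Mask beta values that fail the detection filter
#'
#' Cells whose detection P-value is at or above the threshold (intensity not
#' distinguishable from background at `P >= 0.05` by default; the boundary is
#' inclusive) are set to missing.
#'
#' @param x a [TwinBetaSet][TwinBetaSet-class].
#' @param detectionP numeric matrix of detection P-values, same dimnames as
#'   the beta matrix.
#' @param threshold masking threshold (default 0.05).
#' @return list with `object` (masked `TwinBetaSet`) and `maskedPerSample`
#'   (named integer, newly masked cells per sample).
#' @export
applyDetectionFilter <- function(x, detectionP, threshold = 0.05) {
  b <- betaValues(x)
  if (!identical(dim(b), dim(detectionP)))
    stop("detectionP shape differs from the beta matrix")
  if (!is.null(rownames(detectionP)) &&
      !identical(rownames(detectionP), rownames(b)))
    stop("detectionP probe order differs from the beta matrix")
  mask <- !is.na(detectionP) & detectionP >= threshold
  newlyMasked <- mask & !is.na(b)
  b[mask] <- NA_real_
  counts <- stats::setNames(as.integer(colSums(newlyMasked)), colnames(b))
  obj <- TwinBetaSet(b, studyDesign(x), manifest = probeManifest(x))
  list(object = obj, maskedPerSample = counts)
}

#' Apply the probe-validity filter
#'
#' Excludes probes flagged as multi-aligned first, then, among the
#' remainder, probes with a SNP in the CpG site; the dispositions are
#' mutually exclusive and partition the input exactly (asserted through the
#' report's validity).
#'
#' @param manifest probe manifest `data.frame` with populated
#'   `multi_aligned` and `snp_in_cpg` flags.
#' @return list with `manifest` (retained probes) and `report` (a
#'   [QcReport][QcReport-class]).
#' @examples
#' mf <- generateProbeManifest(100, nMulti = 5, nSnp = 3)$manifest
#' qcFilter(mf)$report
#' @export
qcFilter <- function(manifest) {
  stopifnot(all(c("multi_aligned", "snp_in_cpg") %in% colnames(manifest)))
  disp <- ifelse(manifest$multi_aligned, "multi_aligned",
                 ifelse(manifest$snp_in_cpg, "snp_in_cpg", "retained"))
  names(disp) <- manifest$probe_id
  report <- methods::new("QcReport",
    nInput = nrow(manifest),
    nExcludedMulti = sum(disp == "multi_aligned"),
    nExcludedSnp = sum(disp == "snp_in_cpg"),
    nRetained = sum(disp == "retained"),
    disposition = disp)
  methods::validObject(report)
  list(manifest = manifest[disp == "retained", , drop = FALSE],
       report = report)
}

#' Write a QcReport as TSV
#'
#' @param report a [QcReport][QcReport-class].
#' @param path output TSV (probe id, disposition).
#' @return invisibly, `path`.
#' @export
writeQcReport <- function(report, path) {
  utils::write.table(
    data.frame(probe_id = names(report@disposition),
               disposition = unname(report@disposition)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
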