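#' Read a beta matrix and its study design from TSV files
#'
#' The matrix file has a header row `probe_id<TAB>sample1<TAB>...`; each
#' further row is a probe. Missing measurements are the literal `NA`. The
#' design file has columns `sample_id`, `pair_id`, `status`, `tissue`, `sex`
#' and is authoritative for pairing: matrix columns may appear in any order
#' but every one must be keyed by the design.
#'
#' @param path beta matrix TSV.
#' @param designPath study design TSV.
#' @param manifest optional probe manifest `data.frame` attached as rowData.
#' @return a [TwinBetaSet][TwinBetaSet-class].
#' @seealso [writeBetaMatrix()]
#' @export
readBetaMatrix <- function(path, designPath, manifest = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (colnames(tab)[1] != "probe_id")
    stop("first column of ", path, " must be 'probe_id'")
  probes <- tab[[1]]
  if (anyDuplicated(probes))
    stop("duplicate probe ids in ", path)
  if (anyDuplicated(colnames(tab)[-1]))
    stop("duplicate sample ids in ", path)
  beta <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(beta) <- "double"
  rownames(beta) <- probes
  v <- beta[!is.na(beta)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stop("beta value outside [0, 1] in ", path)
  design <- utils::read.delim(designPath, colClasses = "character")
  TwinBetaSet(beta, design, manifest = manifest)
}

#' Write a beta matrix and study design to TSV files
#'
#' Values are written at full precision (`format(..., digits = 17)`), so a
#' write/read round trip preserves them exactly.
#'
#' @param x a [TwinBetaSet][TwinBetaSet-class].
#' @param path output TSV for the matrix.
#' @param designPath output TSV for the design (omitted if `NULL`).
#' @return invisibly, `path`.
#' @export
writeBetaMatrix <- function(x, path, designPath = NULL) {
  b <- betaValues(x)
  chr <- format(b, digits = 17, trim = TRUE, scientific = FALSE)
  chr[is.na(b)] <- "NA"  # format() pads; keep a clean literal
  out <- data.frame(probe_id = rownames(b), chr, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(designPath))
    utils::write.table(studyDesign(x), designPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Read or write a probe manifest TSV
#'
#' Columns: `probe_id`, `gene_symbol`, `distance_to_tss` (signed base pairs,
#' negative upstream of the TSS, may be `NA`), `probe_sequence` (50-mer),
#' `cpg_position` (0-based reference offset of the interrogated CpG),
#' `multi_aligned`, `snp_in_cpg`, `candidate` (logicals).
#'
#' @param path TSV file.
#' @return `readProbeManifest()`: a `data.frame`.
#' @export
readProbeManifest <- function(path) {
  m <- utils::read.delim(path, colClasses = c(
    probe_id = "character", gene_symbol = "character",
    distance_to_tss = "integer", probe_sequence = "character",
    cpg_position = "integer", multi_aligned = "logical",
    snp_in_cpg = "logical", candidate = "logical"))
  if (anyDuplicated(m$probe_id)) stop("duplicate probe ids in ", path)
  bad <- grepl("[^ACGT]", m$probe_sequence)
  if (any(bad))
    stop("probe sequence with characters outside A/C/G/T: ",
         paste(utils::head(m$probe_id[bad], 5), collapse = ", "))
  m
}

#' @rdname readProbeManifest
#' @param manifest a manifest `data.frame`.
#' @export
writeProbeManifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file.
#' @return named list of character vectors of gene symbols.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L)
      stop("malformed GMT line (need name, description, >=1 gene)")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
  sets
}

#' Read SNP positions for CpG masking
#'
#' Two-column TSV: sequence name and 0-based position.
#'
#' @param path TSV file.
#' @return `data.frame` with columns `seqname`, `position`.
#' @export
readSnpPositions <- function(path) {
  tab <- utils::read.delim(path, header = TRUE)
  colnames(tab)[1:2] <- c("seqname", "position")
  tab$position <- as.integer(tab$position)
  tab
}

#' Read a bisulfite-sequencing clone-count table
#'
#' TSV with columns `site`, `n_methylated`, `n_unmethylated` and optionally
#' `amplicon_id`, `pair_id`, `group`. Counts must be non-negative.
#'
#' @param path TSV file.
#' @return a clone-table `data.frame`.
#' @export
readCloneTable <- function(path) {
  tab <- utils::read.delim(path)
  need <- c("site", "n_methylated", "n_unmethylated")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("clone table missing column(s): ", paste(miss, collapse = ", "))
  if (any(tab$n_methylated < 0 | tab$n_unmethylated < 0))
    stop("negative clone counts")
  tab
}
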