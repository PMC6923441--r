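#' @importFrom data.table fread fwrite as.data.table setDF
NULL

#' Recognized probe exclusion flags
#'
#' Vocabulary of QC flags that [filter_probes()] understands: array internal
#' controls, probes failing detection, low bead counts, sex-chromosome probes,
#' cross-reactive probes, probes with common SNPs at or near the single-base
#' extension site, and probes known to be age-sensitive in buccal epithelium.
#' @export
PROBE_FLAGS <- c("control", "high_detection_fail", "low_bead", "sex_chrom",
                 "cross_reactive", "snp_at_sbe", "snp_near_sbe",
                 "age_sensitive")

#' Recognized gene-context categories
#'
#' 450K-style relation of a probe to its linked gene: within 1500 bp or
#' 200 bp of the transcription start site, 5' UTR, first exon, gene body,
#' 3' UTR, or intergenic (IGR, no linked gene).
#' @export
GENE_CONTEXTS <- c("TSS1500", "TSS200", "5'UTR", "1stExon", "Body", "3'UTR",
                   "IGR")

#' Construct a methylation study object
#'
#' The central container joining the beta-value matrix, its M-value
#' counterpart, the sample sheet and the probe annotation. Probes are rows of
#' the matrices (sorted by chromosome then position), samples are columns.
#'
#' @param beta Numeric matrix of methylation fractions in (0, 1), probes x
#'   samples, with rownames matching `probes$probe_id` and colnames matching
#'   `samples$sample_id`.
#' @param samples Data frame with at least `sample_id`, `group`
#'   ("ESAM"/"NESAM"), `timepoint` ("DC"/"DL"), `age`, `sex` ("M"/"F");
#'   further numeric covariate columns (cohort label, PCs/MDS axes) are
#'   carried along.
#' @param probes Data frame with `probe_id`, `chromosome`, `position`
#'   (1-based bp), optional `gene`, `context` and `flags` (semicolon-separated
#'   subset of [PROBE_FLAGS]).
#' @return An object of class `methylation_study` with elements `beta`, `m`,
#'   `samples`, `probes`.
#' @export
methylation_study <- function(beta, samples, probes) {
  stopifnot(is.matrix(beta), is.data.frame(samples), is.data.frame(probes))
  samples <- as.data.frame(samples)
  probes <- as.data.frame(probes)
  req_s <- c("sample_id", "group", "timepoint", "age", "sex")
  if (!all(req_s %in% names(samples)))
    stop("sample sheet must contain columns: ",
         paste(setdiff(req_s, names(samples)), collapse = ", "))
  req_p <- c("probe_id", "chromosome", "position")
  if (!all(req_p %in% names(probes)))
    stop("probe annotation must contain columns: ",
         paste(setdiff(req_p, names(probes)), collapse = ", "))
  if (anyNA(samples$group) || anyNA(samples$timepoint))
    stop("group and timepoint must be non-missing for every sample")
  if (!all(samples$group %in% c("ESAM", "NESAM")))
    stop("group must be 'ESAM' or 'NESAM'")
  if (!all(samples$timepoint %in% c("DC", "DL")))
    stop("timepoint must be 'DC' or 'DL'")
  if (any(probes$position <= 0)) stop("probe positions must be positive")
  if (!is.null(probes$flags)) .check_flags(probes$flags)
  if (!is.null(probes$context) &&
      !all(stats::na.omit(unique(probes$context)) %in% GENE_CONTEXTS))
    stop("unknown gene-context label in probe annotation")
  if (nrow(beta) != nrow(probes) || ncol(beta) != nrow(samples))
    stop("beta matrix dimensions do not match annotation tables")
  if (is.null(rownames(beta))) rownames(beta) <- probes$probe_id
  if (is.null(colnames(beta))) colnames(beta) <- samples$sample_id
  if (!identical(rownames(beta), as.character(probes$probe_id)) ||
      !identical(colnames(beta), as.character(samples$sample_id)))
    stop("beta dimnames must match probe_id / sample_id")
  if (any(beta <= 0 | beta >= 1))
    stop("beta values must lie strictly in (0, 1)")
  ord <- order(probes$chromosome, probes$position)
  probes <- probes[ord, , drop = FALSE]
  beta <- beta[ord, , drop = FALSE]
  rownames(probes) <- NULL
  structure(list(beta = beta, m = beta_to_m(beta),
                 samples = samples, probes = probes),
            class = "methylation_study")
}

.check_flags <- function(flags) {
  toks <- unique(unlist(strsplit(flags[!is.na(flags) & nzchar(flags)], ";",
                                 fixed = TRUE)))
  bad <- setdiff(toks, PROBE_FLAGS)
  if (length(bad))
    stop("unknown probe flag(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.methylation_study <- function(x, ...) {
  cat("methylation_study:", nrow(x$beta), "probes x", ncol(x$beta),
      "samples\n")
  cat("  groups:    ", paste(names(table(x$samples$group)),
                             table(x$samples$group),
                             sep = "=", collapse = ", "), "\n")
  cat("  timepoints:", paste(names(table(x$samples$timepoint)),
                             table(x$samples$timepoint),
                             sep = "=", collapse = ", "), "\n")
  cat("  chromosomes:", length(unique(x$probes$chromosome)), "\n")
  invisible(x)
}

#' Number of probes / samples in a study
#' @param study A `methylation_study`.
#' @return Integer count.
#' @export
n_probes <- function(study) nrow(study$beta)

#' @rdname n_probes
#' @export
n_samples <- function(study) ncol(study$beta)

#' Remove probes carrying QC exclusion flags
#'
#' Restricts a study to probes carrying none of the given flags, mirroring
#' standard 450K pre-analysis exclusions (internal controls, failed
#' detection, low bead counts, sex chromosomes, cross-reactive probes, and
#' probes with SNPs at or near the single-base extension site).
#'
#' @param study A `methylation_study` whose probe annotation has a `flags`
#'   column (semicolon-separated; empty string or NA = unflagged).
#' @param exclude_flags Character vector, subset of [PROBE_FLAGS]. Empty
#'   vector returns the study unchanged.
#' @return Filtered `methylation_study`; attribute `"filter_report"` holds a
#'   named list with per-flag removal counts (probes carrying each flag,
#'   overlaps possible), `n_removed` and `n_kept`.
#' @export
filter_probes <- function(study, exclude_flags) {
  stopifnot(inherits(study, "methylation_study"))
  exclude_flags <- as.character(exclude_flags)
  bad <- setdiff(exclude_flags, PROBE_FLAGS)
  if (length(bad))
    stop("unknown probe flag(s): ", paste(bad, collapse = ", "))
  flags <- study$probes$flags
  if (is.null(flags)) flags <- rep("", n_probes(study))
  flags[is.na(flags)] <- ""
  toks <- strsplit(flags, ";", fixed = TRUE)
  per_flag <- vapply(exclude_flags,
                     function(f) sum(vapply(toks, function(t) f %in% t,
                                            logical(1L))),
                     integer(1L))
  drop <- vapply(toks, function(t) any(t %in% exclude_flags), logical(1L))
  keep <- !drop
  out <- study
  out$beta <- study$beta[keep, , drop = FALSE]
  out$m <- study$m[keep, , drop = FALSE]
  out$probes <- study$probes[keep, , drop = FALSE]
  rownames(out$probes) <- NULL
  attr(out, "filter_report") <- list(per_flag = as.list(per_flag),
                                     n_removed = sum(drop),
                                     n_kept = sum(keep))
  out
}

# ---- plain-text I/O ---------------------------------------------------------

# Full-precision TSV writer: numeric columns serialized with %.17g so that
# read(write(x)) round-trips doubles bit-exactly.
write_tsv_full <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- formatC(df[[j]], format = "g",
                                               digits = 17)
  }
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  data.table::setDF(data.table::fread(path, sep = "\t", na.strings = "NA"))
}

#' Write / read a methylation study as TSV tables
#'
#' Serializes the beta matrix (probes as rows, first column `probe_id`,
#' remaining columns samples), the sample sheet, and the probe annotation to
#' `beta.tsv`, `samples.tsv` and `probes.tsv` in `dir`, at full double
#' precision (bit-exact round trip). M values are recomputed on read.
#'
#' @param study A `methylation_study`.
#' @param dir Directory (created if needed).
#' @return `write_study` returns `dir` invisibly; `read_study` returns the
#'   reconstructed `methylation_study`.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "methylation_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bm <- data.frame(probe_id = rownames(study$beta), study$beta,
                   check.names = FALSE)
  write_tsv_full(bm, file.path(dir, "beta.tsv"))
  write_tsv_full(study$samples, file.path(dir, "samples.tsv"))
  write_tsv_full(study$probes, file.path(dir, "probes.tsv"))
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  bm <- read_tsv(file.path(dir, "beta.tsv"))
  beta <- as.matrix(bm[, -1L, drop = FALSE])
  rownames(beta) <- bm[[1L]]
  samples <- read_tsv(file.path(dir, "samples.tsv"))
  probes <- read_tsv(file.path(dir, "probes.tsv"))
  if ("flags" %in% names(probes)) {
    probes$flags <- as.character(probes$flags)
    probes$flags[is.na(probes$flags)] <- ""
  }
  methylation_study(beta, samples, probes)
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Reading uses `fgsea::gmtPathways()` when fgsea is installed, otherwise a
#' plain parser with identical semantics.
#'
#' @param path File path.
#' @param sets Named list of character vectors (names must be unique).
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(toks, function(t) t[-(1:2)])
  names(sets) <- vapply(toks, `[[`, character(1L), 1L)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names")
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}
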