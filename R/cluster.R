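#' Bin CpGs into direction-consistent differentially methylated clusters
#'
#' Probes with beta-scale effect sizes strictly inside the open interval
#' `effect_window` are removed (marginal effects whose direction is
#' ambiguous), then the retained probes are scanned left-to-right per
#' chromosome and chained into maximal non-overlapping clusters in which the
#' distance between adjacent retained probes is at most `max_gap` and all
#' members share the effect sign. Boundary convention: an effect of exactly
#' +/-0.05 is retained. Dropped probes neither bridge nor break chains.
#' Singletons are allowed.
#'
#' @param results `single_site_result` table (needs `probe_id`,
#'   `chromosome`, `position`, `beta_slope`).
#' @param effect_window Open interval of beta-slopes to drop
#'   (default `c(-0.05, 0.05)`).
#' @param max_gap Maximum adjacent-probe distance in bp within a cluster
#'   (`<= max_gap` chains; default 10 kb).
#' @return List of class `cluster_set`: `clusters` (cluster_id, chromosome,
#'   start, end, n_probes, direction, marginal_probes_in_span,
#'   flag_marginal), `members` (cluster_id, probe_id, position),
#'   `dropped_probes` (ids removed by the effect filter), and the parameters
#'   used.
#' @export
build_clusters <- function(results, effect_window = c(-0.05, 0.05),
                           max_gap = 10000) {
  stopifnot(all(c("probe_id", "chromosome", "position", "beta_slope") %in%
                  names(results)))
  stopifnot(length(effect_window) == 2L, effect_window[1] < effect_window[2])
  res <- as.data.frame(results)
  ord <- order(res$chromosome, res$position)
  if (is.unsorted(ord)) message("input not position-sorted; sorting")
  res <- res[ord, , drop = FALSE]
  marginal <- res$beta_slope > effect_window[1] &
              res$beta_slope < effect_window[2]
  dropped <- res[marginal, , drop = FALSE]
  kept <- res[!marginal, , drop = FALSE]
  if (nrow(kept) == 0L) {
    cl <- data.frame(cluster_id = character(), chromosome = character(),
                     start = integer(), end = integer(),
                     n_probes = integer(), direction = integer(),
                     marginal_probes_in_span = integer(),
                     flag_marginal = logical())
    return(structure(list(clusters = cl,
                          members = data.frame(cluster_id = character(),
                                               probe_id = character(),
                                               position = integer()),
                          dropped_probes = dropped$probe_id,
                          effect_window = effect_window, max_gap = max_gap),
                     class = "cluster_set"))
  }
  dir <- sign(kept$beta_slope)
  new_chrom <- c(TRUE, kept$chromosome[-1L] != kept$chromosome[-nrow(kept)])
  gap <- c(Inf, diff(kept$position))
  flip <- c(TRUE, dir[-1L] != dir[-length(dir)])
  breaks <- new_chrom | gap > max_gap | flip
  cid <- cumsum(breaks)
  clusters <- data.frame(
    cluster_id = paste0("dmc", seq_len(max(cid))),
    chromosome = tapply(kept$chromosome, cid, `[`, 1L),
    start = as.integer(tapply(kept$position, cid, min)),
    end = as.integer(tapply(kept$position, cid, max)),
    n_probes = as.integer(tabulate(cid)),
    direction = as.integer(tapply(dir, cid, `[`, 1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  members <- data.frame(cluster_id = clusters$cluster_id[cid],
                        probe_id = kept$probe_id,
                        position = kept$position,
                        stringsAsFactors = FALSE)
  # retrospective annotation: marginal (filtered) probes falling inside a
  # final cluster span; clusters with >2 are flagged
  nmarg <- integer(nrow(clusters))
  if (nrow(dropped)) {
    for (i in seq_len(nrow(clusters))) {
      nmarg[i] <- sum(dropped$chromosome == clusters$chromosome[i] &
                        dropped$position >= clusters$start[i] &
                        dropped$position <= clusters$end[i])
    }
  }
  clusters$marginal_probes_in_span <- nmarg
  clusters$flag_marginal <- nmarg > 2L
  structure(list(clusters = clusters, members = members,
                 dropped_probes = dropped$probe_id,
                 effect_window = effect_window, max_gap = max_gap),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", nrow(x$clusters), "clusters over",
      nrow(x$members), "probes (", length(x$dropped_probes),
      "dropped by effect filter )\n")
  if (nrow(x$clusters))
    cat("  sizes:", paste(range(x$clusters$n_probes), collapse = ".."),
        "probes; spans up to",
        max(x$clusters$end - x$clusters$start), "bp\n")
  invisible(x)
}

#' Cluster-level differential methylation regression
#'
#' Repeats the single-site regression with the per-sample mean of the member
#' probes' transformed M values as the dependent variable; the design matrix
#' (covariates + group) is identical to the single-site analysis. The
#' Bonferroni threshold is `alpha / n_clusters`.
#'
#' @inheritParams fit_single_sites
#' @param cluster_set A `cluster_set` built on the same probe universe.
#' @return Data frame of class `cluster_result`: `cluster_id`, `chromosome`,
#'   `start`, `end`, `n_probes`, `span_bp`, `direction`, `mean_m_slope`,
#'   `t_stat`, `p`, `fdr_q`, `bonferroni_sig`; Bonferroni threshold in
#'   attribute `"bonferroni_threshold"`.
#' @export
fit_clusters <- function(study, cluster_set, covariates = c("age", "sex"),
                         group_col = "group", transform = TRUE,
                         alpha = 0.05) {
  stopifnot(inherits(study, "methylation_study"),
            inherits(cluster_set, "cluster_set"))
  missing <- setdiff(cluster_set$members$probe_id, rownames(study$m))
  if (length(missing))
    stop("cluster members missing from study: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  X <- build_design(study$samples, covariates, group_col)
  Ym <- if (transform) rank_inverse_normal(study$m) else study$m
  cl <- cluster_set$clusters
  Ycl <- matrix(NA_real_, nrow(cl), ncol(Ym),
                dimnames = list(cl$cluster_id, colnames(Ym)))
  idx <- split(match(cluster_set$members$probe_id, rownames(Ym)),
               cluster_set$members$cluster_id)
  for (i in seq_len(nrow(cl))) {
    rows <- idx[[cl$cluster_id[i]]]
    Ycl[i, ] <- if (length(rows) == 1L) Ym[rows, ] else colMeans(Ym[rows, ])
  }
  fit <- ols_by_row(Ycl, X, "group")
  thr <- alpha / nrow(cl)
  out <- data.frame(cluster_id = cl$cluster_id,
                    chromosome = cl$chromosome,
                    start = cl$start, end = cl$end,
                    n_probes = cl$n_probes,
                    span_bp = cl$end - cl$start,
                    direction = cl$direction,
                    mean_m_slope = fit$estimate,
                    t_stat = fit$t_stat,
                    p = fit$p,
                    fdr_q = stats::p.adjust(fit$p, method = "BH"),
                    bonferroni_sig = fit$p < thr,
                    stringsAsFactors = FALSE)
  attr(out, "bonferroni_threshold") <- thr
  class(out) <- c("cluster_result", "data.frame")
  out
}

#' Overlap between significant single sites and significant clusters
#'
#' Summarizes how Bonferroni-significant single CpGs distribute over
#' Bonferroni- and FDR-significant clusters, and how many significant
#' clusters contain no individually significant CpG.
#'
#' @param cluster_results `cluster_result` table.
#' @param cluster_set The `cluster_set` the results were fitted on.
#' @param single_results `single_site_result` table.
#' @param fdr_alpha FDR level for the cluster FDR tier.
#' @return List with counts: `n_single_bonf`, `n_single_in_bonf_clusters`,
#'   `n_single_in_fdr_clusters`, `n_bonf_clusters`,
#'   `n_bonf_clusters_no_sig_single`, `frac_single_in_bonf_clusters`.
#' @export
cluster_overlap_report <- function(cluster_results, cluster_set,
                                   single_results, fdr_alpha = 0.01) {
  sig_single <- single_results$probe_id[single_results$bonferroni_sig]
  bonf_cl <- cluster_results$cluster_id[cluster_results$bonferroni_sig]
  fdr_cl <- cluster_results$cluster_id[cluster_results$fdr_q < fdr_alpha]
  mem <- cluster_set$members
  in_bonf <- sig_single %in% mem$probe_id[mem$cluster_id %in% bonf_cl]
  in_fdr <- sig_single %in% mem$probe_id[mem$cluster_id %in% fdr_cl]
  cl_has_sig <- unique(mem$cluster_id[mem$probe_id %in% sig_single])
  list(n_single_bonf = length(sig_single),
       n_single_in_bonf_clusters = sum(in_bonf),
       n_single_in_fdr_clusters = sum(in_fdr),
       n_bonf_clusters = length(bonf_cl),
       n_bonf_clusters_no_sig_single = sum(!bonf_cl %in% cl_has_sig),
       frac_single_in_bonf_clusters =
         if (length(sig_single)) mean(in_bonf) else NA_real_)
}

#' Write a cluster set as BED-like TSV tables
#'
#' `clusters.bed.tsv` holds chrom, 0-based start, end, cluster_id, direction
#' and n_probes (BED convention: start = min position - 1); `members.tsv`
#' maps cluster ids to member probes.
#'
#' @param cluster_set A `cluster_set`.
#' @param dir Output directory.
#' @export
write_cluster_set <- function(cluster_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cl <- cluster_set$clusters
  bed <- data.frame(chrom = cl$chromosome, start = cl$start - 1L,
                    end = cl$end, name = cl$cluster_id,
                    direction = cl$direction, n_probes = cl$n_probes)
  write_tsv_full(bed, file.path(dir, "clusters.bed.tsv"))
  write_tsv_full(cluster_set$members, file.path(dir, "members.tsv"))
  invisible(dir)
}
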