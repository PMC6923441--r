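#' Run the full analysis pipeline on simulated data
#'
#' Orchestrates the stages end to end: simulate a study (plus genotypes,
#' expression and gene-set universes), QC-filter probes, fit the per-probe
#' differential methylation model at the acute timepoint, bin probes into
#' direction-consistent clusters and fit cluster-level models, map cluster
#' genes and compute enrichment statistics, classify nutrition-sensitive
#' cis-meQTLs from the acute vs recovered interaction fits, and correlate
#' methylation with expression. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param covariates Covariates for the methylation regressions; `"pc1"`
#'   refers to the first principal component recomputed from the analyzed
#'   methylation matrix (see [add_methylation_pcs()]).
#' @param alpha Family-wise alpha for Bonferroni thresholds.
#' @param fdr_alpha FDR level used for cluster and recovery summaries.
#' @param n_perms Permutations for the enrichment stages.
#' @param out_dir Optional directory; when given, stage tables and the JSON
#'   report are written there.
#' @return List of class `methsam_report` with per-stage summaries and
#'   provenance (config hash, seed, package version).
#' @export
run_pipeline <- function(config = simulation_config(),
                         covariates = c("age", "sex", "pc1"),
                         alpha = 0.05, fdr_alpha = 0.01, n_perms = 1000L,
                         out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  sim <- simulate_study(config)
  geno_sim <- simulate_genotypes(config, sim)
  study <- geno_sim$study
  study <- filter_probes(study, c("control", "high_detection_fail",
                                  "low_bead", "sex_chrom",
                                  "cross_reactive", "snp_at_sbe",
                                  "snp_near_sbe"))
  filter_report <- attr(study, "filter_report")

  dc <- study
  keep_dc <- study$samples$timepoint == "DC"
  dc$beta <- dc$beta[, keep_dc, drop = FALSE]
  dc$m <- dc$m[, keep_dc, drop = FALSE]
  dc$samples <- dc$samples[keep_dc, , drop = FALSE]
  if ("pc1" %in% covariates) dc <- add_methylation_pcs(dc, 1L)

  single <- fit_single_sites(dc, covariates = covariates, alpha = alpha)
  lambda <- genomic_inflation(single$p)
  cluster_set <- build_clusters(single)
  cluster_res <- fit_clusters(dc, cluster_set, covariates = covariates,
                              alpha = alpha)
  overlap <- cluster_overlap_report(cluster_res, cluster_set, single,
                                    fdr_alpha = fdr_alpha)

  sig_clusters <- cluster_set
  sig_ids <- cluster_res$cluster_id[cluster_res$fdr_q < fdr_alpha]
  sig_clusters$clusters <-
    cluster_set$clusters[cluster_set$clusters$cluster_id %in% sig_ids, ,
                         drop = FALSE]
  sig_clusters$members <-
    cluster_set$members[cluster_set$members$cluster_id %in% sig_ids, ,
                        drop = FALSE]

  gmap <- map_genes(sig_clusters, sim$genes)
  bg_map <- map_genes(cluster_set, sim$genes)
  candidate_genes <- unique(gmap$gene)
  universe <- unique(bg_map$gene)
  gs <- simulate_genesets(config, universe = universe,
                          hit_genes = candidate_genes)
  efo_tab <- efo_score(candidate_genes, gs$efo_catalog)
  efo_perm <- if (length(candidate_genes))
    efo_permutation(candidate_genes, gs$universe, gs$efo_catalog,
                    n_perms = n_perms,
                    seed = derive_seed(config$seed, "efo_perm")) else NULL
  hpo <- if (length(candidate_genes))
    hpo_overlap_z(candidate_genes, gs$hpo_map[[1L]], gs$universe,
                  n_perms = n_perms,
                  seed = derive_seed(config$seed, "hpo_perm")) else NULL
  ctx_enrich <- context_enrichment(
    dc$probes$context[dc$probes$probe_id %in% sig_clusters$members$probe_id],
    dc$probes$context)

  # --- meQTLs -----------------------------------------------------------
  meqtl_summary <- NULL
  if (config$n_samples_per_group_dl > 0 && config$n_snps > 0) {
    geno <- genotype_qc(geno_sim$geno)
    pairs <- cis_pairs(geno, study$probes)
    s <- study$samples
    dc_sel <- s$timepoint == "DC"
    dl_sel <- s$timepoint == "DL"
    dc_add <- fit_meqtl(study, geno, pairs, covariates = c("age", "sex"),
                        subset = dc_sel)
    dc_int <- fit_interaction(study, geno, pairs,
                              covariates = c("age", "sex"),
                              subset = dc_sel)
    dl_add <- fit_meqtl(study, geno, pairs, covariates = c("age", "sex"),
                        subset = dl_sel)
    dl_int <- fit_interaction(study, geno, pairs,
                              covariates = c("age", "sex"),
                              subset = dl_sel)
    cls <- classify_nutrition_sensitive(meqtl_records(dc_add, dc_int),
                                        meqtl_records(dl_add, dl_int))
    meqtl_summary <- list(
      n_pairs = nrow(pairs),
      qc = attr(geno, "qc_report"),
      n_sensitive = sum(cls$classification == "nutrition_sensitive"),
      n_insensitive = sum(cls$classification == "insensitive"),
      n_untested = sum(cls$classification == "untested"),
      n_stringent = sum(cls$stringent),
      classified = cls)
  }

  # --- expression correlation ------------------------------------------
  expr_summary <- NULL
  if (config$n_expr_samples >= 3L) {
    ex <- simulate_expression(config, sim)
    expressed <- expressed_filter(ex$expr, ex$antigenomic)
    contexts <- stats::setNames(dc$probes$context, dc$probes$probe_id)
    recs <- correlate_expression(study, ex$expr, sig_clusters, gmap,
                                 expressed, contexts = contexts)
    expr_summary <- list(n_expressed = length(expressed),
                         n_records = nrow(recs),
                         records = recs)
  }

  report <- structure(list(
    provenance = list(config_hash = config_hash(config),
                      seed = config$seed,
                      version = as.character(utils::packageVersion(
                        "methsam"))),
    filter = filter_report,
    single_site = list(
      n_probes = n_probes(dc),
      bonferroni_threshold =
        bonferroni_threshold(alpha, n_probes(dc))$threshold_2sf,
      n_fdr_sig = sum(single$fdr_q < fdr_alpha),
      n_bonferroni_sig = sum(single$bonferroni_sig),
      lambda = lambda,
      mean_abs_beta_slope_sig =
        if (any(single$bonferroni_sig))
          mean(abs(single$beta_slope[single$bonferroni_sig])) else NA_real_,
      frac_hypo = if (any(single$bonferroni_sig))
        mean(single$direction[single$bonferroni_sig] < 0) else NA_real_),
    clusters = list(
      n_clusters = nrow(cluster_res),
      bonferroni_threshold =
        bonferroni_threshold(alpha, nrow(cluster_res))$threshold_2sf,
      n_fdr_sig = length(sig_ids),
      n_bonferroni_sig = sum(cluster_res$bonferroni_sig),
      overlap = overlap),
    enrichment = list(n_candidate_genes = length(candidate_genes),
                      efo_terms = length(unique(efo_tab$efo_id)),
                      efo_joint_p = if (!is.null(efo_perm))
                        efo_perm$empirical_p_raw else NA_real_,
                      hpo_z = if (!is.null(hpo)) hpo$z else NA_real_,
                      context = ctx_enrich),
    meqtl = meqtl_summary,
    expression = expr_summary,
    tables = list(single = single, cluster = cluster_res,
                  cluster_set = cluster_set)),
    class = "methsam_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(unclass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Write a pipeline report to disk
#'
#' JSON summary (`report.json`) plus the single-site and cluster result
#' tables as TSV.
#'
#' @param report A `methsam_report`.
#' @param dir Output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- report
  summ$tables <- NULL
  if (!is.null(summ$meqtl)) summ$meqtl$classified <- NULL
  if (!is.null(summ$expression)) summ$expression$records <- NULL
  jsonlite::write_json(summ, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  write_tsv_full(report$tables$single, file.path(dir, "single_site.tsv"))
  write_tsv_full(report$tables$cluster, file.path(dir, "clusters.tsv"))
  write_cluster_set(report$tables$cluster_set, dir)
  if (!is.null(report$meqtl))
    write_tsv_full(report$meqtl$classified, file.path(dir, "meqtl.tsv"))
  if (!is.null(report$expression))
    write_tsv_full(report$expression$records,
                   file.path(dir, "expr_corr.tsv"))
  invisible(dir)
}

#' @export
print.methsam_report <- function(x, ...) {
  ss <- x$single_site
  cat("methsam pipeline report (seed", x$provenance$seed, ")\n")
  cat("  single-site:", ss$n_probes, "probes;",
      ss$n_fdr_sig, "FDR-significant,", ss$n_bonferroni_sig,
      "Bonferroni-significant (threshold", ss$bonferroni_threshold,
      "); lambda =", round(ss$lambda, 2), "\n")
  cat("  clusters:", x$clusters$n_clusters, "built;",
      x$clusters$n_bonferroni_sig, "Bonferroni-significant\n")
  if (!is.null(x$meqtl))
    cat("  meQTLs:", x$meqtl$n_sensitive, "nutrition-sensitive /",
        x$meqtl$n_insensitive, "insensitive\n")
  if (!is.null(x$expression))
    cat("  expression:", x$expression$n_records,
        "CpG-gene correlation records\n")
  invisible(x)
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Validates keys against [simulation_config()]; unknown keys are rejected
#' before any computation.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON file of configuration fields.
#' @return A `simulation_config`.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(simulation_config, cfg)
}
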