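#' Map clusters (or probes) to nearby genes
#'
#' A gene is linked to a cluster when its annotated interval overlaps the
#' cluster span or lies within `window` bp of it (the same +/-10 kb cis rule
#' used throughout the analysis). Distances are `|pos_a - pos_b|` on 1-based
#' coordinates; "within 10 kb" means `<= 10000`.
#'
#' @param x A `cluster_set`, or a data frame with `chromosome`, `start`,
#'   `end` (probes can be passed with `start = end = position`).
#' @param genes Data frame with `gene`, `chromosome`, `start`, `end`. If
#'   gene coordinates are absent but `x` carries probe-level `gene` links,
#'   those links are returned with a warning.
#' @param window Maximum separation in bp (default 10 kb).
#' @return Data frame of class `gene_map`: `cluster_id`, `gene`, `distance`
#'   (0 when overlapping), deduplicated.
#' @export
map_genes <- function(x, genes, window = 10000) {
  spans <- if (inherits(x, "cluster_set")) x$clusters else as.data.frame(x)
  if (!all(c("chromosome", "start", "end") %in% names(spans)))
    stop("x must provide chromosome/start/end spans")
  if (is.null(spans$cluster_id))
    spans$cluster_id <- spans$probe_id %||% paste0("span", seq_len(nrow(spans)))
  if (is.null(genes) || !all(c("gene", "chromosome", "start", "end") %in%
                               names(genes))) {
    if (!is.null(spans$gene)) {
      warning("gene coordinates unavailable; falling back to probe-level ",
              "gene links")
      out <- unique(data.frame(cluster_id = spans$cluster_id,
                               gene = spans$gene, distance = NA_real_))
      out <- out[!is.na(out$gene) & nzchar(out$gene), , drop = FALSE]
      class(out) <- c("gene_map", "data.frame")
      return(out)
    }
    stop("gene annotation must have gene/chromosome/start/end")
  }
  res <- vector("list", nrow(spans))
  for (i in seq_len(nrow(spans))) {
    g <- genes[genes$chromosome == spans$chromosome[i], , drop = FALSE]
    if (!nrow(g)) next
    d <- pmax(0, pmax(g$start - spans$end[i], spans$start[i] - g$end))
    hit <- d <= window
    if (any(hit))
      res[[i]] <- data.frame(cluster_id = spans$cluster_id[i],
                             gene = g$gene[hit], distance = d[hit],
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(cluster_id = character(), gene = character(),
                      distance = numeric())
  out <- unique(out)
  rownames(out) <- NULL
  class(out) <- c("gene_map", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gene-context enrichment of a probe subset
#'
#' Two-tailed hypergeometric tests, per gene-context category, comparing the
#' composition of a probe subset (e.g. CpGs inside significant DMCs) with the
#' full tested background: `p_enrich = P(X >= k)` and `p_deplete = P(X <= k)`
#' for `X ~ Hypergeometric(K, N - K, n)`.
#'
#' @param subset_contexts Character vector of context labels for the subset
#'   (one entry per probe-gene link).
#' @param background_contexts Same for the background; must contain the
#'   subset's categories.
#' @return Data frame: `context`, `k_hits`, `K_set`, `n_drawn`,
#'   `N_universe`, `p_enrich`, `p_deplete`.
#' @export
context_enrichment <- function(subset_contexts, background_contexts) {
  n <- length(subset_contexts)
  N <- length(background_contexts)
  if (N == 0L) stop("empty background")
  cats <- sort(unique(background_contexts))
  out <- lapply(cats, function(cc) {
    k <- sum(subset_contexts == cc)
    K <- sum(background_contexts == cc)
    data.frame(context = cc, k_hits = k, K_set = K, n_drawn = n,
               N_universe = N,
               p_enrich = stats::phyper(k - 1, K, N - K, n,
                                        lower.tail = FALSE),
               p_deplete = stats::phyper(k, K, N - K, n))
  })
  do.call(rbind, out)
}

#' Score candidate genes against a GWAS-catalog EFO table
#'
#' Restricts the catalog to candidate genes, aggregates genome-wide
#' significant SNP counts per (EFO, gene), and keeps EFO terms represented by
#' at least `min_genes` candidate genes.
#'
#' @param candidate_genes Character vector of genes (e.g. genes within 10 kb
#'   of significant DMCs).
#' @param efo_catalog Data frame: `efo_id`, optional `efo_label`, `gene`,
#'   `snp_count` (genome-wide-significant SNPs mapped to the gene under that
#'   EFO term).
#' @param min_genes Minimum distinct candidate genes per retained EFO.
#' @return Data frame `efo_id` (+ label), `gene`, `snp_count`, sorted by EFO.
#' @export
efo_score <- function(candidate_genes, efo_catalog, min_genes = 2L) {
  stopifnot(all(c("efo_id", "gene", "snp_count") %in% names(efo_catalog)))
  hit <- efo_catalog[efo_catalog$gene %in% candidate_genes, , drop = FALSE]
  if (!nrow(hit)) return(hit[0, , drop = FALSE])
  agg <- stats::aggregate(snp_count ~ efo_id + gene, data = hit, FUN = sum)
  ngene <- table(agg$efo_id)
  keep <- names(ngene)[ngene >= min_genes]
  out <- agg[agg$efo_id %in% keep, , drop = FALSE]
  if ("efo_label" %in% names(efo_catalog)) {
    lab <- unique(efo_catalog[, c("efo_id", "efo_label")])
    out$efo_label <- lab$efo_label[match(out$efo_id, lab$efo_id)]
  }
  out <- out[order(out$efo_id, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Permutation null for the joint GWAS-gene / EFO-count statistic
#'
#' Repeatedly draws `length(candidate_genes)` genes without replacement from
#' the universe and records, per draw, `G` = number of drawn genes with any
#' catalog entry and `E` = number of EFO terms represented by at least
#' `min_genes` drawn genes. The joint-tail empirical probability is the
#' fraction of draws with `G >= G_obs` and `E >= E_obs`. Per-EFO recurrence
#' frequencies (fraction of draws in which the EFO reaches `min_genes`) are
#' also reported. Both the raw fraction and the bias-corrected
#' `(b + 1)/(n + 1)` estimate are returned.
#'
#' @inheritParams efo_score
#' @param universe Character vector of genes to draw from (must contain at
#'   least `length(candidate_genes)` genes).
#' @param n_perms Number of random draws.
#' @param seed Optional integer seed for reproducibility.
#' @return List of class `efo_permutation`: `g_obs`, `e_obs`,
#'   `empirical_p_raw`, `empirical_p`, `n_perms`, `null_g`/`null_e`
#'   summaries, `efo_recurrence` (named vector), `seed`.
#' @export
efo_permutation <- function(candidate_genes, universe, efo_catalog,
                            n_perms = 10000L, seed = NULL, min_genes = 2L) {
  k <- length(candidate_genes)
  if (k > length(universe))
    stop("candidate set larger than universe")
  if (!is.null(seed)) set.seed(seed)
  pairs <- unique(efo_catalog[, c("efo_id", "gene")])
  catalog_genes <- unique(pairs$gene)
  efos <- sort(unique(pairs$efo_id))
  gene2efo <- split(match(pairs$efo_id, efos), pairs$gene)
  efo_tab <- function(genes) {
    idx <- unlist(gene2efo[genes[genes %in% catalog_genes]],
                  use.names = FALSE)
    tabulate(if (is.null(idx)) integer(0) else idx,
             nbins = length(efos))
  }
  g_obs <- sum(candidate_genes %in% catalog_genes)
  e_obs <- sum(efo_tab(candidate_genes) >= min_genes)
  null_g <- integer(n_perms)
  null_e <- integer(n_perms)
  recur <- numeric(length(efos))
  for (b in seq_len(n_perms)) {
    draw <- sample(universe, k)
    tab <- efo_tab(draw)
    null_g[b] <- sum(draw %in% catalog_genes)
    null_e[b] <- sum(tab >= min_genes)
    recur <- recur + (tab >= min_genes)
  }
  hits <- sum(null_g >= g_obs & null_e >= e_obs)
  structure(list(g_obs = g_obs, e_obs = e_obs,
                 empirical_p_raw = hits / n_perms,
                 empirical_p = (hits + 1) / (n_perms + 1),
                 n_perms = n_perms,
                 null_g_mean = mean(null_g), null_e_mean = mean(null_e),
                 efo_recurrence = stats::setNames(recur / n_perms, efos),
                 seed = seed),
            class = "efo_permutation")
}

#' Resampling Z-score for overlap with a phenotype gene set
#'
#' Compares the observed overlap between a candidate gene set and an
#' HPO-derived gene set against size-matched random draws from the universe:
#' `Z = (obs - mean_null) / sd_null`, plus upper-tail empirical p (both the
#' raw fraction and `(b + 1)/(n + 1)`). A degenerate null (sd = 0) yields
#' `Z = NA` with `degenerate = TRUE`.
#'
#' @param candidate_genes Character vector.
#' @param hpo_genes Character vector (genes linked to the phenotype terms).
#' @param universe Character vector of genes to draw from.
#' @param n_perms Number of random draws.
#' @param seed Optional integer seed.
#' @return List of class `enrichment_score`: `observed`, `null_mean`,
#'   `null_sd`, `z`, `empirical_p_raw`, `empirical_p`, `n_perms`, `seed`,
#'   `degenerate`.
#' @export
hpo_overlap_z <- function(candidate_genes, hpo_genes, universe,
                          n_perms = 10000L, seed = NULL) {
  k <- length(candidate_genes)
  if (k > length(universe)) stop("candidate set larger than universe")
  if (!is.null(seed)) set.seed(seed)
  obs <- sum(candidate_genes %in% hpo_genes)
  in_hpo <- universe %in% hpo_genes
  null <- vapply(seq_len(n_perms),
                 function(b) sum(in_hpo[sample.int(length(universe), k)]),
                 numeric(1L))
  m <- mean(null)
  s <- stats::sd(null)
  hits <- sum(null >= obs)
  structure(list(observed = obs, null_mean = m, null_sd = s,
                 z = if (s > 0) (obs - m) / s else NA_real_,
                 empirical_p_raw = hits / n_perms,
                 empirical_p = (hits + 1) / (n_perms + 1),
                 n_perms = n_perms, seed = seed, degenerate = s == 0),
            class = "enrichment_score")
}

#' @export
print.enrichment_score <- function(x, ...) {
  cat("overlap", x$observed, "vs null", round(x$null_mean, 2), "+/-",
      round(x$null_sd, 2), "-> Z =",
      if (is.na(x$z)) "NA (degenerate null)" else round(x$z, 2),
      ", empirical p =", format(x$empirical_p, digits = 3), "\n")
  invisible(x)
}

# quartile value by ascending p-value rank: best (smallest-p) quartile -> 1,
# then 0.75, 0.5, 0.25; ties get the average rank before quartile assignment
quartile_value <- function(p) {
  n <- length(p)
  r <- rank(p, ties.method = "average")
  idx <- ceiling(4 * r / n)
  (5 - idx) / 4
}

#' Quartile-weighted overlap score between study and phenotype ontologies
#'
#' Combines, for every (study gene ontology, phenotype) pair, (i) a quartile
#' score: the product of the SGO's p-value quartile value (1, 0.75, 0.5,
#' 0.25 from most to least significant) in the study list and in the
#' kwashiorkor-phenotype (KGO) list — 0 when the SGO is absent from the KGO
#' list; and (ii) a proportion score: the fraction of the phenotype's genes
#' that map to the SGO. The final score is the arithmetic mean of the two
#' and lies in [0, 1].
#'
#' @param sgo_pvals Named numeric vector: enrichment p per study gene
#'   ontology.
#' @param kgo_pvals Named numeric vector: enrichment p per
#'   phenotype-derived gene ontology.
#' @param phenotype_gene_map Named list: phenotype -> character gene vector.
#' @param sgo_gene_map Named list: SGO -> character gene vector.
#' @return Data frame of class `sgo_kgo_score`: `sgo_id`, `phenotype_id`,
#'   `quartile_score`, `proportion_score`, `final`, `flag_empty_phenotype`.
#' @export
sgo_kgo_score <- function(sgo_pvals, kgo_pvals, phenotype_gene_map,
                          sgo_gene_map) {
  stopifnot(!is.null(names(sgo_pvals)), !is.null(names(kgo_pvals)))
  q_sgo <- stats::setNames(quartile_value(sgo_pvals), names(sgo_pvals))
  q_kgo <- stats::setNames(quartile_value(kgo_pvals), names(kgo_pvals))
  rows <- list()
  for (sgo in names(sgo_pvals)) {
    qs <- if (sgo %in% names(kgo_pvals))
      q_sgo[[sgo]] * q_kgo[[sgo]] else 0
    sg <- sgo_gene_map[[sgo]] %||% character()
    for (ph in names(phenotype_gene_map)) {
      pg <- phenotype_gene_map[[ph]]
      empty <- length(pg) == 0L
      prop <- if (empty) NA_real_ else sum(pg %in% sg) / length(pg)
      rows[[length(rows) + 1L]] <-
        data.frame(sgo_id = sgo, phenotype_id = ph,
                   quartile_score = qs, proportion_score = prop,
                   final = if (empty) NA_real_ else (qs + prop) / 2,
                   flag_empty_phenotype = empty,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sgo_kgo_score", "data.frame")
  out
}

# Dunn's post-hoc z-tests on rank sums after a Kruskal-Wallis omnibus.
# z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))
# with tie correction T = sum(t^3 - t). Unadjusted two-sided p by default.
dunn_test <- function(values, groups, p_adjust = "none") {
  g <- factor(groups)
  N <- length(values)
  r <- rank(values, ties.method = "average")
  rbar <- tapply(r, g, mean)
  ng <- table(g)
  ties <- table(values)
  Tcorr <- sum(ties^3 - ties)
  s2 <- N * (N + 1) / 12 - Tcorr / (12 * (N - 1))
  combs <- utils::combn(levels(g), 2L)
  out <- apply(combs, 2L, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    z <- (rbar[[i]] - rbar[[j]]) /
      sqrt(s2 * (1 / ng[[i]] + 1 / ng[[j]]))
    c(z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  })
  data.frame(group1 = combs[1L, ], group2 = combs[2L, ],
             z = out["z", ],
             p = stats::p.adjust(out["p", ], method = p_adjust),
             row.names = NULL)
}

#' Effect-size differences across gene contexts
#'
#' Kruskal-Wallis omnibus test of per-probe effect sizes grouped by
#' gene-context category, followed by Dunn's pairwise z-tests (unadjusted p
#' by default, matching common reporting of bare Dunn p values; an adjustment
#' method can be requested).
#'
#' @param results `single_site_result` table (or any data frame with
#'   `beta_slope`).
#' @param contexts Character vector of context labels, parallel to
#'   `results` rows.
#' @param value `"absolute"` (default, |beta_slope|) or `"signed"`.
#' @param p_adjust Method passed to [stats::p.adjust()] for the Dunn p
#'   values (`"none"` default).
#' @return List: `kw_stat`, `kw_df`, `kw_p`, `dunn` (pairwise table),
#'   `n_per_group`.
#' @export
effect_by_context <- function(results, contexts,
                              value = c("absolute", "signed"),
                              p_adjust = "none") {
  value <- match.arg(value)
  v <- results$beta_slope
  if (value == "absolute") v <- abs(v)
  ok <- !is.na(v) & !is.na(contexts)
  v <- v[ok]
  g <- factor(contexts[ok])
  if (nlevels(g) < 2L) stop("need at least two context groups")
  kw <- stats::kruskal.test(v, g)
  list(kw_stat = unname(kw$statistic), kw_df = unname(kw$parameter),
       kw_p = kw$p.value,
       dunn = dunn_test(v, g, p_adjust = p_adjust),
       n_per_group = table(g))
}
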