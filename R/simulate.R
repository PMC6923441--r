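#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults emulate the
#' statistical structure of a two-cohort buccal methylation study of severe
#' acute malnutrition: logit-normal per-probe methylation with bimodal
#' baseline levels, group effects concentrated in spatial probe clusters and
#' present only at the acute (DC) timepoint, covariate effects on the M
#' scale, and additive plus interaction-only cis-meQTLs.
#'
#' @param n_samples_per_group Acute (DC) samples per group (ESAM/NESAM).
#' @param n_samples_per_group_dl Recovered (DL) samples per group (0 = no DL
#'   arm).
#' @param n_probes Total probe count.
#' @param n_chromosomes Number of chromosomes probes are spread over.
#' @param cluster_size Integer range of probes per spatial block.
#' @param intra_gap Range (bp) of gaps between adjacent probes in a block.
#' @param inter_gap_mean Mean (bp) of the exponential excess gap between
#'   blocks (added to 10001 bp so blocks are never chainable by a 10 kb
#'   rule).
#' @param n_true_dmcs Number of blocks given a true group effect (the
#'   probes of each such block form one true differentially methylated
#'   cluster with a shared sign).
#' @param true_effect_beta Beta-scale shift applied to ESAM-DC samples at
#'   true DMC probes (0 < value < 0.5).
#' @param covariate_effects Named M-scale slopes for `age` (per year),
#'   `sex` (M vs F) and `pc1`.
#' @param noise_sd_m Residual SD on the M scale.
#' @param n_snps Total simulated SNPs.
#' @param maf_range Minor-allele-frequency range, within (0, 0.5].
#' @param n_additive_meqtls,n_interaction_meqtls Numbers of planted
#'   SNP-CpG pairs with an additive effect in all samples vs an effect only
#'   in ESAM-DC samples.
#' @param meqtl_slope_m M-value change per minor allele for planted pairs.
#' @param n_expr_samples Samples with paired expression data.
#' @param expr_coupling M-scale-to-expression slope magnitude for coupled
#'   genes.
#' @param geneset_universe_size Gene-universe size for ontology/GWAS
#'   catalogs.
#' @param seed Integer RNG seed; all components derive their own stream
#'   from it deterministically.
#' @return Validated list of class `simulation_config`. Unknown arguments
#'   are rejected.
#' @export
simulation_config <- function(n_samples_per_group = 150L,
                              n_samples_per_group_dl = 50L,
                              n_probes = 10000L,
                              n_chromosomes = 5L,
                              cluster_size = c(2L, 10L),
                              intra_gap = c(50, 2000),
                              inter_gap_mean = 30000,
                              n_true_dmcs = 8L,
                              true_effect_beta = 0.05,
                              covariate_effects = c(age = 0.02, sex = 0.05,
                                                    pc1 = 0.1),
                              noise_sd_m = 0.5,
                              n_snps = 200L,
                              maf_range = c(0.1, 0.5),
                              n_additive_meqtls = 5L,
                              n_interaction_meqtls = 5L,
                              meqtl_slope_m = 0.4,
                              n_expr_samples = 20L,
                              expr_coupling = 0.8,
                              geneset_universe_size = 5000L,
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_samples_per_group > 0, cfg$n_probes > 0,
            cfg$n_chromosomes > 0, cfg$n_snps > 0,
            cfg$n_samples_per_group_dl >= 0, cfg$n_true_dmcs >= 0,
            cfg$n_additive_meqtls >= 0, cfg$n_interaction_meqtls >= 0)
  if (!(cfg$true_effect_beta > 0 && cfg$true_effect_beta < 0.5))
    stop("true_effect_beta must lie in (0, 0.5)")
  if (!(cfg$maf_range[1] > 0 && cfg$maf_range[2] <= 0.5 &&
          cfg$maf_range[1] <= cfg$maf_range[2]))
    stop("maf_range must lie within (0, 0.5]")
  stopifnot(length(cfg$cluster_size) == 2L,
            cfg$cluster_size[1] >= 1L,
            cfg$cluster_size[1] <= cfg$cluster_size[2])
  structure(cfg, class = "simulation_config")
}

# deterministic per-component sub-seed from the master seed
derive_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((as.numeric(seed) * 7919 + h * 1009) %% 2147483647)
}

#' Simulate a methylation study with a ground-truth ledger
#'
#' Generates probe positions cluster-first (blocks of `cluster_size` probes
#' with intra-block gaps of `intra_gap` bp; gaps above 10 kb between
#' blocks, so true DMCs are chainable by the 10 kb rule while distinct
#' blocks are not), draws bimodal per-probe baseline beta levels, and builds
#' per-sample M values as
#' `logit2(mu_beta) + covariate effects + N(0, noise_sd_m)`. The group
#' effect is injected on the beta scale (shifting `mu_beta` by
#' `true_effect_beta` with a per-block shared sign) at all probes of each
#' true DMC, for ESAM samples at the acute (DC) timepoint only — recovered
#' (DL) samples carry no group effect.
#'
#' @param config A `simulation_config`.
#' @return List of class `sim_study`: `study` (a [methylation_study()]),
#'   `truth` (probe ledger: `probe_id`, `block`, `is_differential`,
#'   `true_direction`, `cluster_id`), `genes` (synthetic gene annotation:
#'   one gene near each probe block plus distant decoys).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, "study"))
  # --- probe layout, cluster-first --------------------------------------
  per_chrom <- ceiling(config$n_probes / config$n_chromosomes)
  chrom <- integer(0); pos <- integer(0); block <- integer(0)
  bid <- 0L
  for (cc in seq_len(config$n_chromosomes)) {
    p <- 1e6
    np <- 0L
    while (np < per_chrom) {
      bid <- bid + 1L
      s <- sample(seq(config$cluster_size[1], config$cluster_size[2]), 1L)
      gaps <- if (s > 1L) round(stats::runif(s - 1L, config$intra_gap[1],
                                             config$intra_gap[2])) else
        numeric(0)
      bp <- p + cumsum(c(0, gaps))
      chrom <- c(chrom, rep(cc, s))
      pos <- c(pos, bp)
      block <- c(block, rep(bid, s))
      np <- np + s
      # 10002 base keeps the inter-block gap above 10 kb after rounding
      p <- bp[length(bp)] + 10002 + stats::rexp(1L, 1 / config$inter_gap_mean)
    }
  }
  keep <- seq_len(config$n_probes)
  chrom <- chrom[keep]; pos <- as.integer(round(pos[keep]))
  block <- block[keep]
  probe_id <- sprintf("cg%06d", seq_along(pos))
  # --- baseline methylation: bimodal mixture, block-correlated ----------
  blocks <- unique(block)
  comp <- sample(1:3, length(blocks), replace = TRUE,
                 prob = c(0.4, 0.4, 0.2))
  b0_block <- ifelse(comp == 1L, stats::rbeta(length(blocks), 2, 8),
                     ifelse(comp == 2L, stats::rbeta(length(blocks), 8, 2),
                            stats::rbeta(length(blocks), 5, 5)))
  beta0 <- pmin(pmax(b0_block[match(block, blocks)] +
                       stats::rnorm(length(pos), 0, 0.03), 0.02), 0.98)
  # --- true DMCs: whole blocks with a shared sign -----------------------
  if (config$n_true_dmcs > length(blocks))
    stop("n_true_dmcs exceeds the number of probe blocks")
  true_blocks <- if (config$n_true_dmcs > 0)
    sample(blocks, config$n_true_dmcs) else integer(0)
  # shift direction points away from a boundary the designed effect would
  # cross, so the injected beta shift is fully realizable
  b0_true <- b0_block[match(true_blocks, blocks)]
  dir_block <- stats::setNames(
    ifelse(b0_true > 1 - config$true_effect_beta - 0.05, -1L,
           ifelse(b0_true < config$true_effect_beta + 0.05, 1L,
                  sample(c(-1L, 1L), length(true_blocks), replace = TRUE))),
    true_blocks)
  is_diff <- block %in% true_blocks
  true_dir <- integer(length(pos))
  true_dir[is_diff] <- dir_block[as.character(block[is_diff])]
  # --- samples ----------------------------------------------------------
  n_dc <- config$n_samples_per_group
  n_dl <- config$n_samples_per_group_dl
  grp <- c(rep(c("ESAM", "NESAM"), each = n_dc),
           rep(c("ESAM", "NESAM"), each = n_dl))
  tp <- c(rep("DC", 2L * n_dc), rep("DL", 2L * n_dl))
  ns <- length(grp)
  samples <- data.frame(
    sample_id = sprintf("S%04d", seq_len(ns)),
    group = grp, timepoint = tp,
    age = ifelse(tp == "DC", stats::runif(ns, 0.5, 4),
                 stats::runif(ns, 18, 45)),
    sex = sample(c("M", "F"), ns, replace = TRUE),
    cohort = ifelse(tp == "DC",
                    sample(c("Jamaica", "Malawi"), ns, replace = TRUE),
                    "Jamaica"),
    pc1 = stats::rnorm(ns), stringsAsFactors = FALSE)
  # --- methylation matrix ----------------------------------------------
  eff <- config$covariate_effects
  cov_shift <- eff[["age"]] * samples$age +
    eff[["sex"]] * (samples$sex == "M") + eff[["pc1"]] * samples$pc1
  mu <- matrix(beta0, nrow = length(pos), ncol = ns)
  affected <- samples$group == "ESAM" & samples$timepoint == "DC"
  if (any(is_diff) && any(affected)) {
    shift <- true_dir[is_diff] * config$true_effect_beta
    mu[is_diff, affected] <- mu[is_diff, affected] + shift
  }
  n_clamped <- sum(mu < 0.001 | mu > 0.999)
  if (n_clamped > 0) {
    warning(n_clamped, " mean beta value(s) outside (0.001, 0.999) clamped")
    mu <- pmin(pmax(mu, 0.001), 0.999)
  }
  M <- log2(mu / (1 - mu)) +
    matrix(cov_shift, length(pos), ns, byrow = TRUE) +
    matrix(stats::rnorm(length(pos) * ns, 0, config$noise_sd_m),
           length(pos), ns)
  beta <- m_to_beta(M)
  dimnames(beta) <- list(probe_id, samples$sample_id)
  # --- probe annotation -------------------------------------------------
  context <- sample(GENE_CONTEXTS, length(pos), replace = TRUE,
                    prob = c(0.12, 0.08, 0.08, 0.05, 0.35, 0.05, 0.27))
  gene_of_block <- stats::setNames(sprintf("GENE%05d", seq_along(blocks)),
                                   blocks)
  gene <- ifelse(context == "IGR", "",
                 gene_of_block[as.character(block)])
  flags <- character(length(pos))
  flagged <- sample(length(pos), round(0.02 * length(pos)))
  flags[flagged] <- sample(c("cross_reactive", "sex_chrom", "low_bead"),
                           length(flagged), replace = TRUE)
  probes <- data.frame(probe_id = probe_id, chromosome = chrom,
                       position = pos, gene = gene, context = context,
                       flags = flags, block = block,
                       stringsAsFactors = FALSE)
  study <- methylation_study(beta, samples, probes)
  # study construction re-sorts probes; align truth to the sorted order
  ord <- match(study$probes$probe_id, probe_id)
  truth <- data.frame(probe_id = probe_id[ord], block = block[ord],
                      is_differential = is_diff[ord],
                      true_direction = true_dir[ord],
                      cluster_id = ifelse(is_diff[ord],
                                          paste0("true_dmc", block[ord]),
                                          NA_character_),
                      stringsAsFactors = FALSE)
  # --- synthetic gene annotation: one gene per block + distant decoys ---
  bl_start <- tapply(pos, block, min)
  bl_end <- tapply(pos, block, max)
  bl_chrom <- tapply(chrom, block, `[`, 1L)
  genes <- data.frame(
    gene = unname(gene_of_block[as.character(blocks)]),
    chromosome = as.integer(bl_chrom[as.character(blocks)]),
    start = as.integer(bl_start[as.character(blocks)] -
                         round(stats::runif(length(blocks), 0, 8000))),
    end = as.integer(bl_end[as.character(blocks)] +
                       round(stats::runif(length(blocks), 0, 8000))),
    stringsAsFactors = FALSE)
  decoys <- data.frame(
    gene = sprintf("DECOY%04d", seq_len(200)),
    chromosome = sample(config$n_chromosomes, 200, replace = TRUE),
    start = as.integer(round(stats::runif(200, 1, 5e5))),
    end = NA_integer_, stringsAsFactors = FALSE)
  decoys$end <- decoys$start + 2000L
  genes <- rbind(genes, decoys)
  structure(list(study = study, truth = truth, genes = genes,
                 config = config),
            class = "sim_study")
}

#' Simulate genotypes and inject cis-meQTL effects
#'
#' Draws 0/1/2 minor-allele dosages as Binomial(2, MAF) per SNP, places
#' planted meQTL SNPs within 10 kb of their target CpG, and injects their
#' effects into the study's M values: additive pairs add
#' `slope x dosage` in all samples; interaction-only pairs add it in
#' ESAM-DC samples only (zero additive slope in the NESAM reference group
#' and at recovery).
#'
#' @param config The `simulation_config` used for the study.
#' @param sim Output of [simulate_study()].
#' @return List of class `sim_genotypes`: `geno` (a [genotype_matrix()]),
#'   `study` (effect-modified copy), `truth_pairs` (`snp_id`, `cpg_id`,
#'   `type`, `slope`), and the probe-level `truth` carried through.
#' @export
simulate_genotypes <- function(config, sim) {
  stopifnot(inherits(sim, "sim_study"))
  set.seed(derive_seed(config$seed, "genotypes"))
  study <- sim$study
  probes <- study$probes
  n_int <- config$n_interaction_meqtls
  n_add <- config$n_additive_meqtls
  diff_probes <- sim$truth$probe_id[sim$truth$is_differential]
  null_probes <- sim$truth$probe_id[!sim$truth$is_differential]
  if (n_int > length(diff_probes) || n_add > length(null_probes) ||
        n_int + n_add > config$n_snps)
    stop("requesting more meQTL pairs than available cis pairs")
  int_cpg <- if (n_int) sample(diff_probes, n_int) else character(0)
  add_cpg <- if (n_add) sample(null_probes, n_add) else character(0)
  target_cpg <- c(add_cpg, int_cpg)
  type <- c(rep("additive", n_add), rep("interaction", n_int))
  n_bg <- config$n_snps - length(target_cpg)
  tpos <- probes$position[match(target_cpg, probes$probe_id)]
  tchrom <- probes$chromosome[match(target_cpg, probes$probe_id)]
  # background SNPs scattered near random probes so that cis pairs exist
  bg_idx <- sample(nrow(probes), n_bg, replace = TRUE)
  snp_pos <- c(pmax(1L, tpos + sample(-10000:10000, length(tpos),
                                      replace = TRUE)),
               pmax(1L, probes$position[bg_idx] +
                      sample(-50000:50000, n_bg, replace = TRUE)))
  snp_chrom <- c(tchrom, probes$chromosome[bg_idx])
  snps <- data.frame(snp_id = sprintf("rs%06d", seq_along(snp_pos)),
                     chromosome = snp_chrom,
                     position = as.integer(snp_pos),
                     stringsAsFactors = FALSE)
  maf <- stats::runif(nrow(snps), config$maf_range[1], config$maf_range[2])
  ns <- n_samples(study)
  dosage <- matrix(stats::rbinom(nrow(snps) * ns, 2L, rep(maf, ns)),
                   nrow = nrow(snps), ncol = ns,
                   dimnames = list(snps$snp_id, study$samples$sample_id))
  # inject effects
  esam_dc <- study$samples$group == "ESAM" & study$samples$timepoint == "DC"
  M <- study$m
  for (i in seq_along(target_cpg)) {
    cpg <- target_cpg[i]
    snp <- snps$snp_id[i]
    if (type[i] == "additive") {
      M[cpg, ] <- M[cpg, ] + config$meqtl_slope_m * dosage[snp, ]
    } else {
      M[cpg, esam_dc] <- M[cpg, esam_dc] +
        config$meqtl_slope_m * dosage[snp, esam_dc]
    }
  }
  study$m <- M
  study$beta <- m_to_beta(M)
  truth_pairs <- data.frame(snp_id = snps$snp_id[seq_along(target_cpg)],
                            cpg_id = target_cpg, type = type,
                            slope = config$meqtl_slope_m,
                            stringsAsFactors = FALSE)
  structure(list(geno = genotype_matrix(dosage, snps), study = study,
                 truth_pairs = truth_pairs, truth = sim$truth),
            class = "sim_genotypes")
}

#' Simulate expression with antigenomic controls
#'
#' Builds a genes-by-samples expression matrix (log2 intensity scale) for a
#' subset of acute samples. Genes linked to true DMC blocks are coupled to
#' the block's mean M value with slope `+/- expr_coupling`; remaining genes
#' are independent noise around their baseline. Antigenomic control probes
#' define the expressed-gene threshold (mean x 2).
#'
#' @param config The `simulation_config`.
#' @param sim Output of [simulate_study()] (or the study inside
#'   [simulate_genotypes()] output).
#' @return List of class `sim_expression`: `expr` (matrix), `antigenomic`
#'   (control values), `samples` (ids used), `truth_coupling` (`gene`,
#'   `coupled`, `slope`).
#' @export
simulate_expression <- function(config, sim) {
  stopifnot(inherits(sim, "sim_study"))
  set.seed(derive_seed(config$seed, "expression"))
  study <- sim$study
  dc <- study$samples$sample_id[study$samples$timepoint == "DC"]
  ids <- utils::head(dc, config$n_expr_samples)
  if (length(ids) < 3L) stop("not enough DC samples for expression arm")
  genes <- sim$genes$gene[!startsWith(sim$genes$gene, "DECOY")]
  antigenomic <- stats::rnorm(30L, 4, 0.3)
  expressed <- stats::runif(length(genes)) < 0.5
  base <- ifelse(expressed, stats::rnorm(length(genes), 10, 1),
                 stats::rnorm(length(genes), 5, 1))
  # genes over true DMC blocks (and only those) are methylation-coupled;
  # gene i corresponds to block i by construction in simulate_study
  truth_blocks <- unique(sim$truth$block[sim$truth$is_differential])
  coupled <- seq_along(genes) %in% truth_blocks & expressed
  slope <- ifelse(coupled,
                  sample(c(-1, 1), length(genes), replace = TRUE) *
                    config$expr_coupling, 0)
  expr <- matrix(0, length(genes), length(ids),
                 dimnames = list(genes, ids))
  pr_block <- study$probes$block
  for (i in seq_along(genes)) {
    e <- base[i] + stats::rnorm(length(ids), 0, 0.5)
    if (coupled[i]) {
      rows <- which(pr_block == i)
      mm <- if (length(rows) == 1L) study$m[rows, ids] else
        colMeans(study$m[rows, ids, drop = FALSE])
      e <- e + slope[i] * (mm - mean(mm))
    }
    expr[i, ] <- e
  }
  structure(list(expr = expr, antigenomic = antigenomic, samples = ids,
                 truth_coupling = data.frame(gene = genes,
                                             coupled = coupled,
                                             slope = slope,
                                             stringsAsFactors = FALSE)),
            class = "sim_expression")
}

#' Simulate gene-set universes (EFO catalog, HPO map, ontologies)
#'
#' Emits GMT-style gene sets over a configurable universe, optionally
#' enriched for a supplied hit-gene list (planted signal for recovery
#' tests); a null configuration (no hits) yields uniformly calibrated
#' permutation p values.
#'
#' @param config The `simulation_config`.
#' @param universe Optional character gene universe; defaults to
#'   `geneset_universe_size` generated names.
#' @param hit_genes Genes to plant into dedicated enriched sets (may be
#'   empty).
#' @param n_efos,n_hpo_terms,n_ontologies Set counts.
#' @return List of class `sim_genesets`: `efo_catalog` (data frame:
#'   `efo_id`, `efo_label`, `gene`, `snp_count`), `hpo_map`,
#'   `ontology_map` (named lists), `universe`.
#' @export
simulate_genesets <- function(config, universe = NULL,
                              hit_genes = character(), n_efos = 40L,
                              n_hpo_terms = 10L, n_ontologies = 20L) {
  set.seed(derive_seed(config$seed, "genesets"))
  if (is.null(universe))
    universe <- sprintf("UGENE%05d", seq_len(config$geneset_universe_size))
  universe <- unique(c(universe, hit_genes))
  draw_set <- function(sz) sample(universe, min(sz, length(universe)))
  efo <- lapply(seq_len(n_efos), function(k) {
    g <- draw_set(stats::rpois(1L, 15L) + 2L)
    data.frame(efo_id = sprintf("EFO:%04d", k),
               efo_label = sprintf("trait_%02d", k),
               gene = g, snp_count = stats::rpois(length(g), 2L) + 1L,
               stringsAsFactors = FALSE)
  })
  if (length(hit_genes)) {
    # plant a few EFOs concentrated on hit genes
    planted <- lapply(seq_len(3L), function(k) {
      g <- unique(c(sample(hit_genes, min(4L, length(hit_genes))),
                    draw_set(4L)))
      data.frame(efo_id = sprintf("EFO:P%03d", k),
                 efo_label = sprintf("planted_trait_%02d", k),
                 gene = g, snp_count = stats::rpois(length(g), 3L) + 1L,
                 stringsAsFactors = FALSE)
    })
    efo <- c(efo, planted)
  }
  efo_catalog <- do.call(rbind, efo)
  hpo_map <- stats::setNames(
    lapply(seq_len(n_hpo_terms), function(k)
      unique(c(draw_set(50L),
               if (length(hit_genes) && k <= 2L)
                 sample(hit_genes, min(3L, length(hit_genes)))))),
    sprintf("HP:%07d", seq_len(n_hpo_terms)))
  ontology_map <- stats::setNames(
    lapply(seq_len(n_ontologies), function(k) draw_set(30L)),
    sprintf("GO:%07d", seq_len(n_ontologies)))
  if (anyDuplicated(c(names(hpo_map), names(ontology_map))))
    stop("duplicate gene-set names")
  structure(list(efo_catalog = efo_catalog, hpo_map = hpo_map,
                 ontology_map = ontology_map, universe = universe),
            class = "sim_genesets")
}

#' Write simulated data to plain-text files
#'
#' Beta matrix, sample sheet and probe annotation as TSV (via
#' [write_study()]), genotypes as a dosage TSV, gene sets as GMT, the truth
#' ledger as JSON, and the configuration as YAML.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory.
#' @param geno Optional [simulate_genotypes()] output.
#' @param genesets Optional [simulate_genesets()] output.
#' @export
write_simulation <- function(sim, dir, geno = NULL, genesets = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_study(if (is.null(geno)) sim$study else geno$study, dir)
  write_tsv_full(sim$genes, file.path(dir, "genes.tsv"))
  truth <- list(probes = sim$truth)
  if (!is.null(geno)) {
    write_genotypes(geno$geno, file.path(dir, "genotypes.tsv"))
    truth$pairs <- geno$truth_pairs
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (!is.null(genesets)) {
    write_gmt(genesets$hpo_map, file.path(dir, "hpo.gmt"))
    write_gmt(genesets$ontology_map, file.path(dir, "ontology.gmt"))
    write_tsv_full(genesets$efo_catalog, file.path(dir, "efo_catalog.tsv"))
  }
  cfg <- unclass(sim$config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}
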