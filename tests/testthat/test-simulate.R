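test_that("configuration validates its invariants and rejects unknown keys", {
  expect_s3_class(test_config(), "simulation_config")
  expect_error(simulation_config(true_effect_beta = 0.6), "0, 0.5")
  expect_error(simulation_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulation_config(n_probes = 0), "n_probes")
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_probes = 50L, not_a_key = 1), path)
  expect_error(read_config(path), "unknown configuration key")
  path2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_probes = 500L, seed = 3L), path2)
  expect_equal(read_config(path2)$n_probes, 500L)
})

test_that("simulation is deterministic and internally consistent", {
  cfg <- test_config(seed = 7L)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$study$beta, b$study$beta)
  expect_identical(a$truth, b$truth)
  st <- a$study
  expect_true(all(st$beta > 0 & st$beta < 1))
  expect_equal(st$m, beta_to_m(st$beta), tolerance = 1e-12)
  # positions sorted within chromosome
  expect_false(is.unsorted(order(st$probes$chromosome,
                                 st$probes$position)))
  # every differential probe belongs to exactly one true cluster
  tr <- a$truth[a$truth$is_differential, ]
  expect_true(all(!is.na(tr$cluster_id)))
  expect_equal(length(unique(tr$cluster_id)), cfg$n_true_dmcs)
  expect_true(all(tr$true_direction %in% c(-1L, 1L)))
  # true DMC probes are chainable by the 10 kb rule; blocks are not
  for (cl in unique(tr$cluster_id)) {
    pos <- sort(st$probes$position[st$probes$probe_id %in%
                                     tr$probe_id[tr$cluster_id == cl]])
    if (length(pos) > 1L) expect_true(all(diff(pos) <= 10000))
  }
  for (chrom in unique(st$probes$chromosome)) {
    idx <- which(st$probes$chromosome == chrom)
    d <- diff(st$probes$position[idx])
    bchange <- diff(st$probes$block[idx]) != 0
    expect_true(all(d[bchange] > 10000))
  }
})

test_that("null configuration carries no group signal", {
  cfg <- test_config(n_true_dmcs = 0L, seed = 13L)
  sim <- simulate_study(cfg)
  expect_true(all(!sim$truth$is_differential))
  st <- sim$study
  dc <- st$samples$timepoint == "DC"
  esam <- dc & st$samples$group == "ESAM"
  nesam <- dc & st$samples$group == "NESAM"
  dbeta <- rowMeans(st$beta[, esam]) - rowMeans(st$beta[, nesam])
  expect_lt(abs(mean(dbeta)), 0.01)
})

test_that("genotype simulation: dosage law, cis placement and injection", {
  cfg <- test_config(maf_range = c(0.5, 0.5), seed = 17L,
                     n_samples_per_group = 60L)
  sim <- simulate_study(cfg)
  g <- simulate_genotypes(cfg, sim)
  expect_equal(mean(g$geno$dosage), 1, tolerance = 0.05)
  # planted SNPs sit within 10 kb of their target CpG
  tp <- g$truth_pairs
  snp_pos <- g$geno$snps$position[match(tp$snp_id, g$geno$snps$snp_id)]
  cpg_pos <- sim$study$probes$position[match(tp$cpg_id,
                                             sim$study$probes$probe_id)]
  expect_true(all(abs(snp_pos - cpg_pos) <= 10000))
  # interaction pairs: zero additive slope in the NESAM reference subset
  ip <- tp[tp$type == "interaction", ]
  pairs <- data.frame(snp_id = ip$snp_id, target_id = ip$cpg_id)
  nesam <- g$study$samples$group == "NESAM"
  slopes <- fit_meqtl(g$study, g$geno, pairs, subset = nesam,
                      transform = FALSE)$beta1
  expect_lt(max(abs(slopes)), 0.25)
  # determinism
  g2 <- simulate_genotypes(cfg, sim)
  expect_identical(g$geno$dosage, g2$geno$dosage)
  # over-asking for pairs errors
  cfg_bad <- test_config(n_interaction_meqtls = 500L, n_snps = 600L)
  sim_bad <- simulate_study(cfg_bad)
  expect_error(simulate_genotypes(cfg_bad, sim_bad), "more meQTL pairs")
})

test_that("expression simulation couples only true-DMC genes", {
  cfg <- test_config(seed = 23L, n_true_dmcs = 4L, expr_coupling = 2)
  sim <- simulate_study(cfg)
  ex <- simulate_expression(cfg, sim)
  expect_equal(ncol(ex$expr), cfg$n_expr_samples)
  expect_true(all(ex$truth_coupling$slope[!ex$truth_coupling$coupled] == 0))
  # coupled genes correlate with their block's mean methylation
  cp <- ex$truth_coupling[ex$truth_coupling$coupled, ]
  skip_if(nrow(cp) == 0L)
  gene <- cp$gene[1L]
  block <- match(gene, ex$truth_coupling$gene)
  rows <- sim$study$probes$block == block
  mm <- colMeans(sim$study$m[rows, ex$samples, drop = FALSE])
  expect_gt(abs(cor(mm, ex$expr[gene, ])), 0.3)
})

test_that("gene-set simulation plants hits and stays calibrated under null", {
  cfg <- test_config(seed = 29L)
  gs <- simulate_genesets(cfg, hit_genes = sprintf("HIT%02d", 1:10))
  expect_true(all(sprintf("HIT%02d", 1:10) %in% gs$universe))
  expect_true(any(grepl("planted", gs$efo_catalog$efo_label)))
  expect_false(anyDuplicated(names(gs$hpo_map)) > 0)
  # a set equal to the hit list itself is the most enriched
  hits <- sprintf("HIT%02d", 1:10)
  sets <- c(list(self = hits), gs$ontology_map)
  ps <- vapply(sets, function(s) {
    k <- sum(hits %in% s)
    phyper(k - 1, length(s), length(gs$universe) - length(s),
           length(hits), lower.tail = FALSE)
  }, numeric(1L))
  expect_equal(names(which.min(ps)), "self")
  # empty hit list: enrichment ops yield empty results without crashing
  gs0 <- simulate_genesets(cfg)
  expect_equal(nrow(efo_score(character(), gs0$efo_catalog)), 0L)
  out <- hpo_overlap_z(character(), gs0$hpo_map[[1]], gs0$universe,
                       n_perms = 50L, seed = 1L)
  expect_equal(out$observed, 0L)
})

test_that("null gene draws give uniform EFO permutation p values", {
  cfg <- test_config(seed = 31L, geneset_universe_size = 200L)
  gs <- simulate_genesets(cfg)
  set.seed(33)
  ps <- replicate(60, {
    cand <- sample(gs$universe, 15L)
    efo_permutation(cand, gs$universe, gs$efo_catalog, n_perms = 150L,
                    seed = sample.int(1e6, 1L))$empirical_p_raw
  })
  # discrete p values: check coarse uniformity via mean and spread
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.75)
  expect_gt(stats::sd(ps), 0.1)
})

test_that("simulation files round-trip through plain text", {
  cfg <- test_config(n_probes = 120L, n_samples_per_group = 10L,
                     n_samples_per_group_dl = 8L, n_snps = 15L,
                     n_true_dmcs = 1L, n_additive_meqtls = 1L,
                     n_interaction_meqtls = 1L, seed = 37L)
  sim <- simulate_study(cfg)
  g <- simulate_genotypes(cfg, sim)
  gs <- simulate_genesets(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir, geno = g, genesets = gs)
  back <- read_study(dir)
  expect_identical(back$beta, g$study$beta)
  geno_back <- read_genotypes(file.path(dir, "genotypes.tsv"))
  expect_identical(geno_back$dosage, g$geno$dosage)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(sum(truth$probes$is_differential),
               sum(sim$truth$is_differential))
  expect_true(file.exists(file.path(dir, "config.yaml")))
})
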