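test_that("HWE exact test: equilibrium, disequilibrium and enumeration", {
  # perfect Hardy-Weinberg proportions sit at the mode
  expect_gt(hwe_exact_p(50, 25, 25), 0.9)
  # no heterozygotes at 50/50 allele frequency is maximally discordant
  expect_lt(hwe_exact_p(0, 50, 50), 1e-20)
  expect_equal(hwe_exact_p(6, 7, 7), choose_hwe_p(6, 7, 7),
               tolerance = 1e-10)
  # systematic agreement with the choose()-based oracle for n <= 20
  set.seed(41)
  for (rep in 1:60) {
    n <- sample(2:20, 1L)
    na <- sample(0:n, 1L)
    het <- sample(0:(n - na), 1L)
    nb <- n - na - het
    expect_equal(hwe_exact_p(het, na, nb), choose_hwe_p(het, na, nb),
                 tolerance = 1e-10)
  }
})

test_that("genotype QC drops SNPs by missingness, HWE and MAF", {
  set.seed(42)
  n <- 200L
  # enough clean SNPs that per-sample missingness stays below the cutoff
  clean <- t(replicate(60, rbinom(n, 2, 0.3)))
  mono <- rep(0L, n)
  rare <- rbinom(n, 2, 0.01)
  bad_hwe <- c(rep(0L, 100), rep(2L, 100))
  holey <- rbinom(n, 2, 0.3)
  holey[sample(n, 20)] <- NA
  dosage <- rbind(clean, mono, rare, bad_hwe, holey)
  snps <- data.frame(snp_id = c(sprintf("s%02d", 1:60), "s_mono",
                                "s_rare", "s_hwe", "s_holey"),
                     chromosome = 1L, position = 1:64 * 1000L)
  rownames(dosage) <- snps$snp_id
  colnames(dosage) <- sprintf("S%03d", 1:n)
  geno <- genotype_matrix(dosage, snps)
  out <- genotype_qc(geno)
  dropped <- setdiff(snps$snp_id, rownames(out$dosage))
  expect_setequal(dropped, c("s_mono", "s_rare", "s_hwe", "s_holey"))
  qc <- attr(out, "qc_report")
  expect_equal(qc$n_snps_kept, 60L)
  expect_gte(qc$n_snps_maf, 2L)  # monomorphic and rare
  expect_gte(qc$n_snps_hwe, 1L)
  expect_equal(qc$n_snps_missingness, 1L)
  expect_equal(qc$n_samples_removed, 0L)
  expect_error(genotype_matrix(matrix(3L, 1, 2), snps[1, ]), "0, 1, 2")
})

test_that("cis pairing matches a brute-force double loop at the boundary", {
  snps <- data.frame(snp_id = paste0("s", 1:5), chromosome = c(1, 1, 1, 2, 2),
                     position = c(500, 15000, 30500, 100, 90000))
  dosage <- matrix(0L, 5, 4, dimnames = list(snps$snp_id, paste0("S", 1:4)))
  geno <- genotype_matrix(dosage, snps)
  cpgs <- data.frame(probe_id = paste0("c", 1:4), chromosome = c(1, 1, 2, 2),
                     position = c(10500, 20500, 10101, 95000))
  got <- cis_pairs(geno, cpgs, window = 10000)
  brute <- list()
  for (i in seq_len(nrow(snps))) for (j in seq_len(nrow(cpgs))) {
    if (snps$chromosome[i] == cpgs$chromosome[j] &&
          abs(snps$position[i] - cpgs$position[j]) <= 10000)
      brute[[length(brute) + 1L]] <- paste(snps$snp_id[i],
                                           cpgs$probe_id[j])
  }
  expect_setequal(paste(got$snp_id, got$target_id), unlist(brute))
  # distance 10,000 in (s1-c1), 10,001 out (s4-c3); chromosomes never mix
  expect_true("s1 c1" %in% paste(got$snp_id, got$target_id))
  expect_false("s4 c3" %in% paste(got$snp_id, got$target_id))
  expect_false(any(got$snp_id == "s1" & got$target_id == "c3"))
})

test_that("additive meQTL fit recovers the planted slope on raw M values", {
  set.seed(51)
  est <- replicate(20, {
    n <- 120L
    d <- rbinom(n, 2, 0.4)
    st <- tiny_study(n_probes = 3L, n_per_group = n / 2, seed = sample.int(1e6, 1))
    m <- st$m
    m[1, ] <- m[1, ] + 0.4 * d
    st$m <- m
    st$beta <- m_to_beta(m)
    dosage <- matrix(d, 1, n, dimnames = list("s1", st$samples$sample_id))
    geno <- genotype_matrix(dosage,
                            data.frame(snp_id = "s1", chromosome = 1L,
                                       position = 900L))
    pairs <- data.frame(snp_id = "s1", target_id = "cg001")
    fit_meqtl(st, geno, pairs, transform = FALSE)$beta1
  })
  expect_equal(mean(est), 0.4, tolerance = 0.05)
  # permuted genotypes give calibrated p values
  set.seed(52)
  ps <- replicate(150, {
    n <- 60L
    d <- rbinom(n, 2, 0.4)
    st <- tiny_study(n_probes = 1L, n_per_group = n / 2,
                     seed = sample.int(1e6, 1))
    dosage <- matrix(d, 1, n, dimnames = list("s1", st$samples$sample_id))
    geno <- genotype_matrix(dosage,
                            data.frame(snp_id = "s1", chromosome = 1L,
                                       position = 900L))
    fit_meqtl(st, geno, data.frame(snp_id = "s1", target_id = "cg001"))$p_main
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  # constant dosage -> untested, no crash
  st <- tiny_study(n_probes = 1L, n_per_group = 10L)
  dosage <- matrix(1L, 1, 20, dimnames = list("s1", st$samples$sample_id))
  geno <- genotype_matrix(dosage, data.frame(snp_id = "s1", chromosome = 1L,
                                             position = 900L))
  out <- fit_meqtl(st, geno, data.frame(snp_id = "s1", target_id = "cg001"))
  expect_true(out$untested)
  expect_true(is.na(out$p_main))
})

test_that("interaction model isolates the group-specific slope", {
  cfg <- test_config(n_samples_per_group = 60L, n_samples_per_group_dl = 40L,
                     seed = 61L)
  sim <- simulate_study(cfg)
  g <- simulate_genotypes(cfg, sim)
  study <- g$study
  tp <- g$truth_pairs[g$truth_pairs$type == "interaction", ]
  pairs <- data.frame(snp_id = tp$snp_id, target_id = tp$cpg_id)
  dc <- study$samples$timepoint == "DC"
  nesam_dc <- dc & study$samples$group == "NESAM"
  int <- fit_interaction(study, g$geno, pairs, subset = dc)
  # NESAM (reference) slope is approximately zero for interaction-only pairs
  expect_lt(max(abs(int$beta1_ref)), 0.35)
  expect_gt(min(abs(int$beta1_alt - int$beta1_ref)), 0.1)
  # NESAM-only additive fit sees no signal (construction)
  add_nesam <- fit_meqtl(study, g$geno, pairs, subset = nesam_dc)
  expect_gt(min(add_nesam$p_main), 0.001)
  # constant group indicator is inestimable
  expect_error(fit_interaction(study, g$geno, pairs, subset = nesam_dc),
               "inestimable")
})

test_that("nutrition-sensitive classification applies the rule table", {
  rec <- function(p_main, p_int, untested = FALSE)
    data.frame(snp_id = "s", cpg_id = "c", beta1 = 1, p_main = p_main,
               beta1_ref = 0, beta1_alt = 1, p_interaction = p_int,
               untested = untested)
  cls <- classify_nutrition_sensitive(rec(0.01, 0.01), rec(0.5, 0.5))
  expect_equal(cls$classification, "nutrition_sensitive")
  cls2 <- classify_nutrition_sensitive(rec(0.01, 0.01), rec(0.5, 0.01))
  expect_equal(cls2$classification, "insensitive")
  cls3 <- classify_nutrition_sensitive(rec(0.5, 0.01), rec(0.5, 0.5))
  expect_equal(cls3$classification, "untested")  # fails the DC screen
  cls4 <- classify_nutrition_sensitive(rec(0.01, 0.01, untested = TRUE),
                                       rec(0.5, 0.5))
  expect_equal(cls4$classification, "untested")
  # stringent tier
  cls5 <- classify_nutrition_sensitive(rec(0.001, 1e-5), rec(0.5, 0.5))
  expect_true(cls5$stringent)
  cls6 <- classify_nutrition_sensitive(rec(0.001, 1e-3), rec(0.5, 0.5))
  expect_false(cls6$stringent)
})

test_that("Fisher overlap test reproduces printed values and brute force", {
  f1 <- reference_overlap_fisher(162, 10, 1723, 238)
  expect_equal(round(f1$p, 3), 0.005)
  f2 <- reference_overlap_fisher(162, 9, 1723, 200)
  expect_equal(signif(f2$p, 2), 0.018)
  expect_equal(reference_overlap_fisher(10, 5, 10, 5)$p, 1)
  set.seed(71)
  for (i in 1:20) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    got <- reference_overlap_fisher(sum(tab[1, ]), tab[1, 1],
                                    sum(tab[2, ]), tab[2, 1])
    expect_equal(got$p, brute_fisher_p(tab), tolerance = 1e-9)
  }
  expect_error(reference_overlap_fisher(5, 6, 10, 1), "negative")
})

test_that("genotype TSV round trip preserves dosages", {
  set.seed(81)
  dosage <- matrix(sample(c(0:2, NA), 40, replace = TRUE), 4, 10)
  rownames(dosage) <- paste0("s", 1:4)
  colnames(dosage) <- paste0("S", 1:10)
  geno <- genotype_matrix(dosage, data.frame(snp_id = paste0("s", 1:4),
                                             chromosome = 1L,
                                             position = 1:4 * 100L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(geno, path)
  back <- read_genotypes(path)
  expect_identical(back$dosage, geno$dosage)
})
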