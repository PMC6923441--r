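test_that("gene mapping honors the 10 kb rule exactly", {
  genes <- data.frame(gene = c("A", "B", "C", "D"),
                      chromosome = c(1, 1, 1, 2),
                      start = c(1000, 31000, 41001, 5000),
                      end = c(2000, 32000, 42000, 6000))
  spans <- data.frame(cluster_id = "c1", chromosome = 1,
                      start = 1500, end = 21000)
  gm <- map_genes(spans, genes)
  # A overlaps; B at distance 10,000 exactly; C at 10,001; D other chrom
  expect_setequal(gm$gene, c("A", "B"))
  expect_equal(gm$distance[gm$gene == "A"], 0)
  # cluster inside a gene body maps the gene
  inside <- data.frame(cluster_id = "c2", chromosome = 1,
                       start = 1200, end = 1300)
  expect_equal(map_genes(inside, genes)$gene, "A")
  # hand enumeration on a 5-gene / 3-cluster toy
  genes5 <- data.frame(gene = paste0("G", 1:5), chromosome = 1,
                       start = c(100, 5000, 30000, 60000, 90000),
                       end = c(200, 5100, 30100, 60100, 90100))
  cl3 <- data.frame(cluster_id = c("x", "y", "z"), chromosome = 1,
                    start = c(150, 39000, 80000),
                    end = c(160, 41000, 80500))
  gm3 <- map_genes(cl3, genes5)
  want <- list(x = c("G1", "G2"), y = "G3", z = "G5")
  expect_equal(split(gm3$gene, gm3$cluster_id), want)
})

test_that("context enrichment equals hypergeometric brute force", {
  bg <- rep(c("Body", "TSS200", "IGR"), c(12, 5, 3))
  sub <- rep(c("Body", "TSS200"), c(6, 1))
  out <- context_enrichment(sub, bg)
  for (i in seq_len(nrow(out))) {
    k <- out$k_hits[i]; K <- out$K_set[i]
    n <- out$n_drawn[i]; N <- out$N_universe[i]
    xs <- 0:min(K, n)
    pm <- dhyper(xs, K, N - K, n)
    expect_equal(out$p_enrich[i], sum(pm[xs >= k]), tolerance = 1e-12)
    expect_equal(out$p_deplete[i], sum(pm[xs <= k]), tolerance = 1e-12)
  }
  # extreme subset: all Body -> Body enrichment minimal, others depleted
  out2 <- context_enrichment(rep("Body", 8), bg)
  expect_equal(which.min(out2$p_enrich),
               which(out2$context == "Body"))
  expect_lt(out2$p_deplete[out2$context == "TSS200"],
            out2$p_deplete[out2$context == "Body"])
})

test_that("EFO scoring equals an independent join", {
  catalog <- data.frame(
    efo_id = c("E1", "E1", "E1", "E2", "E2", "E3"),
    gene = c("A", "B", "C", "A", "D", "A"),
    snp_count = c(3, 1, 5, 2, 7, 4))
  out <- efo_score(c("A", "B"), catalog)
  # only E1 has >= 2 candidate genes
  expect_equal(unique(out$efo_id), "E1")
  expect_equal(out$snp_count[order(out$gene)], c(3, 1)[order(c("A", "B"))])
  ind <- merge(data.frame(gene = c("A", "B")), catalog)
  ind <- ind[ind$efo_id == "E1", ]
  expect_equal(sort(out$snp_count), sort(ind$snp_count))
  expect_equal(nrow(efo_score("Z", catalog)), 0L)
})

test_that("EFO permutation: degenerate cases and enumeration oracle", {
  catalog <- data.frame(efo_id = c("E1", "E1", "E2", "E2", "E3", "E3"),
                        gene = c("g1", "g2", "g2", "g3", "g4", "g9"),
                        snp_count = 1)
  # universe equal to the candidate set: every draw is identical
  cand <- c("g1", "g2", "g3")
  out <- efo_permutation(cand, cand, catalog, n_perms = 50L, seed = 1L)
  expect_equal(out$empirical_p_raw, 1)
  # empty catalog: observed (0, 0), p = 1
  out0 <- efo_permutation(cand, letters, catalog[0, ], n_perms = 20L,
                          seed = 1L)
  expect_equal(out0$g_obs, 0L)
  expect_equal(out0$empirical_p_raw, 1)
  expect_error(efo_permutation(letters, letters[1:3], catalog), "universe")
  # exhaustive enumeration on a 12-gene universe
  universe <- sprintf("g%d", 1:12)
  cand4 <- c("g1", "g2", "g3", "g10")
  stat <- function(draw) {
    g <- sum(draw %in% catalog$gene)
    tabs <- table(catalog$efo_id[catalog$gene %in% draw])
    c(g, sum(tabs >= 2))
  }
  obs <- stat(cand4)
  combos <- combn(universe, 4L)
  exact <- mean(apply(combos, 2L, function(d) {
    s <- stat(d)
    s[1] >= obs[1] && s[2] >= obs[2]
  }))
  perm <- efo_permutation(cand4, universe, catalog, n_perms = 4000L,
                          seed = 2L)
  expect_equal(perm$g_obs, obs[1])
  expect_equal(perm$e_obs, obs[2])
  expect_lt(abs(perm$empirical_p_raw - exact), 0.03)
  # reproducible under the same seed
  perm2 <- efo_permutation(cand4, universe, catalog, n_perms = 4000L,
                           seed = 2L)
  expect_identical(perm$empirical_p_raw, perm2$empirical_p_raw)
})

test_that("HPO overlap Z matches hypergeometric moments on a small universe", {
  universe <- sprintf("u%d", 1:15)
  hpo <- universe[1:6]
  cand <- universe[c(1, 2, 7, 8, 9)]
  out <- hpo_overlap_z(cand, hpo, universe, n_perms = 20000L, seed = 3L)
  k <- 5; K <- 6; N <- 15
  mu <- k * K / N
  sdv <- sqrt(k * (K / N) * (1 - K / N) * (N - k) / (N - 1))
  expect_equal(out$null_mean, mu, tolerance = 0.02)
  expect_equal(out$null_sd, sdv, tolerance = 0.02)
  expect_equal(out$z, (2 - mu) / sdv, tolerance = 0.05)
  expect_gte(out$empirical_p, 1 / (out$n_perms + 1))
  # degenerate null: candidate subset of hpo with universe = hpo
  dg <- hpo_overlap_z(hpo[1:3], hpo, hpo, n_perms = 100L, seed = 4L)
  expect_true(dg$degenerate)
  expect_true(is.na(dg$z))
})

test_that("SGO-KGO score: caption extremes, hand worksheet and bounds", {
  # top quartile of both lists with proportion 1 -> final 1
  sgo_p <- setNames(c(0.001, 0.2, 0.4, 0.9), paste0("S", 1:4))
  kgo_p <- setNames(c(0.001, 0.3, 0.5, 0.8), c("S1", "K2", "K3", "K4"))
  phen <- list(ph1 = c("A", "B"))
  smap <- list(S1 = c("A", "B", "C"), S2 = "A", S3 = character(),
               S4 = "Z")
  tab <- sgo_kgo_score(sgo_p, kgo_p, phen, smap)
  r1 <- tab[tab$sgo_id == "S1" & tab$phenotype_id == "ph1", ]
  expect_equal(r1$quartile_score, 1)
  expect_equal(r1$final, 1)
  # absent from the KGO list -> quartile score 0, final = proportion / 2
  r2 <- tab[tab$sgo_id == "S2", ]
  expect_equal(r2$quartile_score, 0)
  expect_equal(r2$final, 0.5 / 2)
  # hand worksheet: 8 SGOs, quartile values 1,1,.75,.75,.5,.5,.25,.25
  sgo8 <- setNames((1:8) / 100, paste0("T", 1:8))
  kgo8 <- setNames((1:8) / 100, paste0("T", c(1, 3, 5, 7, 2, 4, 6, 8)))
  tab8 <- sgo_kgo_score(sgo8, kgo8, list(ph = "A"),
                        setNames(rep(list("A"), 8), paste0("T", 1:8)))
  qv <- function(r) (5 - ceiling(4 * r / 8)) / 4
  want_q <- qv(1:8) * qv(match(paste0("T", 1:8),
                               paste0("T", c(1, 3, 5, 7, 2, 4, 6, 8))))
  expect_equal(tab8$quartile_score, unname(want_q))
  expect_equal(tab8$final, unname((want_q + 1) / 2))
  # empty phenotype set flagged
  tabe <- sgo_kgo_score(sgo_p, kgo_p, list(ph0 = character()), smap)
  expect_true(all(tabe$flag_empty_phenotype))
  expect_true(all(is.na(tabe$final)))
})

test_that("effect-by-context matches textbook Kruskal-Wallis and the
           two-group Dunn identity", {
  v <- c(27.0, 14.2, 30.1, 18.5, 38.9, 41.2, 36.3, 54.1, 20.1, 17.3,
         35.7, 22.4)
  g <- rep(c("A", "B", "C"), each = 4L)
  res <- effect_by_context(data.frame(beta_slope = v), g,
                           value = "signed")
  # textbook H = 12/(N(N+1)) * sum n_i Rbar_i^2 - 3(N+1), no ties
  r <- rank(v)
  H <- 12 / (12 * 13) * sum(tapply(r, g, sum)^2 / 4) - 3 * 13
  expect_equal(res$kw_p, kruskal.test(v, factor(g))$p.value)
  expect_equal(res$kw_stat, H, tolerance = 1e-10)
  # two groups: Dunn z^2 equals the KW statistic
  v2 <- v[1:8]; g2 <- rep(c("A", "B"), each = 4L)
  res2 <- effect_by_context(data.frame(beta_slope = v2), g2,
                            value = "signed")
  expect_equal(res2$dunn$z^2, res2$kw_stat, tolerance = 1e-10)
  expect_equal(nrow(res$dunn), 3L)
})

test_that("permuted context labels give calibrated omnibus p values", {
  set.seed(15)
  v <- rnorm(60)
  ps <- replicate(200, {
    g <- sample(rep(c("A", "B", "C"), each = 20L))
    effect_by_context(data.frame(beta_slope = v), g)$kw_p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
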