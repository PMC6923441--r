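# Small in-code fixtures shared across the suite.

# A tiny deterministic study: `n_probes` probes on one chromosome,
# `n_per_group` samples per group, optional exact beta values.
tiny_study <- function(n_probes = 6L, n_per_group = 5L, seed = 1L,
                       beta = NULL, positions = NULL, flags = NULL) {
  set.seed(seed)
  ns <- 2L * n_per_group
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(ns)),
    group = rep(c("ESAM", "NESAM"), each = n_per_group),
    timepoint = "DC",
    age = runif(ns, 1, 4),
    sex = sample(c("M", "F"), ns, replace = TRUE),
    pc1 = rnorm(ns),
    stringsAsFactors = FALSE)
  if (is.null(positions)) positions <- seq_len(n_probes) * 1000L
  probes <- data.frame(probe_id = sprintf("cg%03d", seq_len(n_probes)),
                       chromosome = 1L, position = positions,
                       flags = if (is.null(flags)) "" else flags,
                       stringsAsFactors = FALSE)
  if (is.null(beta)) {
    beta <- matrix(runif(n_probes * ns, 0.2, 0.8), n_probes, ns)
  }
  dimnames(beta) <- list(probes$probe_id, samples$sample_id)
  methylation_study(beta, samples, probes)
}

# fast simulation config for tests
test_config <- function(...) {
  defaults <- list(n_samples_per_group = 30L, n_samples_per_group_dl = 20L,
                   n_probes = 600L, n_snps = 40L, n_true_dmcs = 3L,
                   n_additive_meqtls = 2L, n_interaction_meqtls = 2L,
                   geneset_universe_size = 300L, seed = 99L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# O(n^2) reference clusterer: enumerates all candidate probe intervals per
# chromosome, checks interval validity exhaustively (all adjacent gaps
# <= max_gap, all signs equal), and keeps maximal valid intervals.
naive_cluster_partition <- function(results, effect_window = c(-0.05, 0.05),
                                    max_gap = 10000) {
  res <- results[order(results$chromosome, results$position), , drop = FALSE]
  keep <- !(res$beta_slope > effect_window[1] &
              res$beta_slope < effect_window[2])
  res <- res[keep, , drop = FALSE]
  out <- list()
  for (chrom in unique(res$chromosome)) {
    rr <- res[res$chromosome == chrom, , drop = FALSE]
    n <- nrow(rr)
    valid <- function(i, j) {
      if (i > j) return(FALSE)
      if (i == j) return(TRUE)
      idx <- i:j
      all(diff(rr$position[idx]) <= max_gap) &&
        length(unique(sign(rr$beta_slope[idx]))) == 1L
    }
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (valid(i, j) &&
              (i == 1L || !valid(i - 1L, j)) &&
              (j == n || !valid(i, j + 1L))) {
          out[[length(out) + 1L]] <- rr$probe_id[i:j]
        }
      }
    }
  }
  out
}

# random single-site-like table for clustering property tests
random_cluster_instance <- function(n, seed) {
  set.seed(seed)
  n_chrom <- sample(1:3, 1L)
  chrom <- sort(sample(n_chrom, n, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n), chrom), function(idx)
    sort(sample(1:200000, length(idx)))), use.names = FALSE)
  data.frame(probe_id = sprintf("p%04d", seq_len(n)),
             chromosome = chrom, position = pos,
             beta_slope = round(runif(n, -0.15, 0.15), 3),
             stringsAsFactors = FALSE)
}

# brute-force two-sided Fisher p: sum of hypergeometric point masses not
# exceeding the observed one (independent of stats::fisher.test)
brute_fisher_p <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# choose()-based exact HWE p (independent route from the package's
# log-gamma implementation)
choose_hwe_p <- function(n_het, n_hom_minor, n_hom_major) {
  n <- n_het + n_hom_minor + n_hom_major
  n1 <- 2L * n_hom_minor + n_het
  if (n1 > n) return(choose_hwe_p(n_het, n_hom_major, n_hom_minor))
  if (n1 == 0L) return(1)
  hets <- seq.int(n1 %% 2L, n1, by = 2L)
  probs <- vapply(hets, function(h) {
    na <- (n1 - h) / 2
    nb <- n - na - h
    choose(n, na) * choose(n - na, h) * 2^h / choose(2 * n, n1)
  }, numeric(1L))
  probs <- probs / sum(probs)
  obs <- probs[match(n_het, hets)]
  sum(probs[probs <= obs * (1 + 1e-7)])
}
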