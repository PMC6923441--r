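#' Expressed-gene filter against antigenomic background
#'
#' A gene counts as expressed when its per-gene summarized expression is at
#' least twice the mean of the antigenomic control probes (array probes
#' matching no genomic sequence). The boundary is inclusive.
#'
#' @param expr Numeric matrix, genes x samples (rownames = genes).
#' @param antigenomic_values Numeric vector/matrix of control-probe
#'   intensities.
#' @param summarize Per-gene summary across samples (default [mean]).
#' @param fold Multiple of the control mean required (default 2).
#' @return Character vector of expressed genes; attribute `"threshold"`
#'   holds the cutoff used.
#' @export
expressed_filter <- function(expr, antigenomic_values, summarize = mean,
                             fold = 2) {
  if (length(antigenomic_values) == 0L || all(is.na(antigenomic_values)))
    stop("no antigenomic control values supplied")
  thr <- fold * mean(antigenomic_values, na.rm = TRUE)
  lev <- apply(expr, 1L, summarize)
  out <- rownames(expr)[lev >= thr]
  attr(out, "threshold") <- thr
  out
}

# Spearman rho with average-rank ties (Pearson on ranks) and either the
# t-approximation p value or an exact permutation p for small n.
spearman_test <- function(x, y, method = c("t", "exact")) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- stats::cor(rx, ry)
  if (method == "exact") {
    if (n > 8L) stop("exact permutation supported for n <= 8")
    perms <- permutations_of(n)
    rhos <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p <- .Machine$double.xmin
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
    }
  }
  list(rho = rho, p = max(p, .Machine$double.xmin), n = n)
}

# all permutations of 1..n as a matrix (rows), n <= 8
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' Methylation-expression correlation at DMC CpGs
#'
#' One record per (CpG within a cluster) x (expressed gene mapped to that
#' cluster within the cis window): Spearman correlation between per-sample
#' methylation and expression, on both the beta and M scales (identical by
#' rank invariance under the monotone logit transform; both are emitted for
#' completeness), with the t-approximation p value.
#'
#' @param study A `methylation_study` whose samples match `expr` columns.
#' @param expr Expression matrix, genes x samples.
#' @param cluster_set `cluster_set` providing CpG membership.
#' @param gene_map [map_genes()] output linking clusters to genes.
#' @param expressed_set Character vector from [expressed_filter()].
#' @param contexts Optional named character vector (probe_id -> context).
#' @return Data frame of class `expr_corr_result`: `cpg_id`, `gene`,
#'   `cluster_id`, `context`, `rho`, `rho_m`, `p`, `n`.
#' @export
correlate_expression <- function(study, expr, cluster_set, gene_map,
                                 expressed_set, contexts = NULL) {
  common <- intersect(colnames(study$beta), colnames(expr))
  if (length(common) < 3L) stop("need at least 3 shared samples")
  gm <- gene_map[gene_map$gene %in% expressed_set, , drop = FALSE]
  mem <- cluster_set$members
  out <- list()
  for (i in seq_len(nrow(gm))) {
    cl <- gm$cluster_id[i]; gene <- gm$gene[i]
    if (!gene %in% rownames(expr)) next
    e <- expr[gene, common]
    for (cpg in mem$probe_id[mem$cluster_id == cl]) {
      b <- study$beta[cpg, common]
      m <- study$m[cpg, common]
      st_b <- spearman_test(b, e)
      st_m <- spearman_test(m, e)
      out[[length(out) + 1L]] <- data.frame(
        cpg_id = cpg, gene = gene, cluster_id = cl,
        context = if (!is.null(contexts)) contexts[[cpg]] %||% NA_character_
                  else NA_character_,
        rho = st_b$rho, rho_m = st_m$rho, p = st_b$p, n = st_b$n,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cpg_id = character(), gene = character(),
                      cluster_id = character(), context = character(),
                      rho = numeric(), rho_m = numeric(), p = numeric(),
                      n = integer())
  rownames(res) <- NULL
  class(res) <- c("expr_corr_result", "data.frame")
  res
}

#' Signed-rank test of correlation direction within a gene context
#'
#' Two-sided Wilcoxon signed-rank test of median Spearman rho = 0 among the
#' records annotated to one gene context (e.g. testing whether TSS200
#' methylation is inversely related to expression). Exact distribution for
#' n <= 25, normal approximation with continuity correction otherwise.
#'
#' @param records `expr_corr_result` table with a `context` column.
#' @param context Context label to test.
#' @return List: `context`, `n`, `median_rho`, `p` (`NA` with
#'   `untestable = TRUE` when fewer than 2 records).
#' @export
context_sign_test <- function(records, context) {
  rho <- records$rho[!is.na(records$context) & records$context == context]
  rho <- rho[!is.na(rho)]
  n <- length(rho)
  if (n < 2L)
    return(list(context = context, n = n,
                median_rho = if (n) stats::median(rho) else NA_real_,
                p = NA_real_, untestable = TRUE))
  wt <- suppressWarnings(
    stats::wilcox.test(rho, mu = 0, alternative = "two.sided",
                       exact = n <= 25L, correct = TRUE))
  list(context = context, n = n, median_rho = stats::median(rho),
       p = wt$p.value, untestable = FALSE)
}

# Exact non-null density of the sample correlation coefficient r for a
# bivariate normal sample of size n with population correlation rho
# (Hotelling's form with a 2F1 hypergeometric factor, evaluated by series
# with adaptive truncation).
sample_corr_density <- function(r, rho, n) {
  lc <- log(n - 2) + lgamma(n - 1) + ((n - 1) / 2) * log1p(-rho^2) -
    0.5 * log(2 * pi) - lgamma(n - 0.5)
  h <- vapply(r, function(ri) {
    x <- (1 + rho * ri) / 2
    term <- 1; s <- 1
    a <- 0.5; b <- 0.5; cc <- n - 0.5
    for (k in 0:1000) {
      term <- term * (a + k) * (b + k) / ((cc + k) * (k + 1)) * x
      s <- s + term
      if (abs(term) < 1e-15 * abs(s)) break
    }
    s
  }, numeric(1L))
  exp(lc + ((n - 4) / 2) * log1p(-r^2) - (n - 1.5) * log1p(-rho * r)) * h
}

#' Exact power of the bivariate-normal correlation test
#'
#' Power of the two-sided exact test of zero correlation at level `alpha`:
#' the critical value `r_c` is derived from the null t distribution of
#' `r sqrt((n-2)/(1-r^2))` with `n - 2` df, and the power is the probability
#' mass of `|r| > r_c` under the exact non-null density of the sample
#' correlation for a bivariate normal with correlation `rho`, evaluated by
#' adaptive numeric integration (tolerance 1e-8).
#'
#' @param n Sample size (>= 4).
#' @param rho Population correlation, |rho| < 1.
#' @param alpha Two-sided significance level.
#' @return List: `power` (proportion), `power_pct` (rounded whole percent),
#'   `r_critical`.
#' @export
correlation_power_exact <- function(n, rho, alpha = 0.05) {
  if (n < 4L) stop("n must be at least 4")
  if (abs(rho) >= 1) stop("|rho| must be below 1")
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  rc <- tc / sqrt(n - 2 + tc^2)
  pw <- stats::integrate(sample_corr_density, lower = rc, upper = 1,
                         rho = rho, n = n, rel.tol = 1e-8)$value +
    stats::integrate(sample_corr_density, lower = -1, upper = -rc,
                     rho = rho, n = n, rel.tol = 1e-8)$value
  list(power = pw, power_pct = round(100 * pw), r_critical = rc)
}
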