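# Row-wise ordinary least squares: Y (features x samples) regressed on a
# shared design X (samples x p). Returns estimate, se, t and two-sided p for
# one named coefficient, with residual df = n - ncol(X). Rank-deficient
# designs drop aliased columns (never the target term) with a warning.
ols_by_row <- function(Y, X, term) {
  stopifnot(is.matrix(Y), is.matrix(X), ncol(Y) == nrow(X))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    if (term %in% dropped)
      stop("term '", term, "' is aliased with other design columns")
    warning("dropping collinear design column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  n <- nrow(X)
  df <- n - ncol(X)
  if (df < 1L)
    stop("not enough samples for the design (need n >= k + 3)")
  j <- match(term, colnames(X))
  if (is.na(j)) stop("design has no column '", term, "'")
  xtx_inv <- chol2inv(chol(crossprod(X)))
  B <- Y %*% X %*% xtx_inv                       # features x p
  R <- Y - B %*% t(X)
  sigma2 <- rowSums(R^2) / df
  se <- sqrt(sigma2 * xtx_inv[j, j])
  est <- B[, j]
  tt <- est / se
  p <- 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE)
  p[p == 0] <- .Machine$double.xmin             # keep p in (0, 1]
  data.frame(estimate = est, se = se, t_stat = tt, df = df, p = p,
             row.names = NULL)
}

# Build the regression design [intercept | covariates | group] from a sample
# sheet. Character/factor covariates are expanded via model.matrix; the group
# column becomes a 0/1 indicator with ESAM = 1 (effect = ESAM - NESAM).
build_design <- function(samples, covariate_names, group_col = "group") {
  miss <- setdiff(c(covariate_names, group_col), names(samples))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  g <- samples[[group_col]]
  if (length(unique(g)) != 2L)
    stop("group column must have exactly two levels in the analyzed subset")
  lev <- if (all(unique(g) %in% c("ESAM", "NESAM"))) c("NESAM", "ESAM")
         else sort(unique(g))
  dd <- samples[, covariate_names, drop = FALSE]
  dd[] <- lapply(dd, function(v) if (is.character(v)) factor(v) else v)
  dd$.group <- as.integer(factor(g, levels = lev)) - 1L
  X <- stats::model.matrix(~ ., data = dd)
  colnames(X)[colnames(X) == ".group"] <- "group"
  X
}

#' Per-probe differential methylation regression
#'
#' Fits, for every probe, the linear model
#' \deqn{M_i = C\alpha + Y\beta + e}
#' where `M_i` is the (rank-inverse-normal transformed) M value at probe `i`,
#' `C` the covariate matrix and `Y` the case (ESAM) vs control (NESAM)
#' indicator. Inference (t statistic, two-sided p with `n - k - 2` residual
#' df) is on the transformed-M scale; the effect size `beta_slope` is the
#' group coefficient of an identical OLS fit on the raw beta scale
#' (covariate-adjusted ESAM - NESAM mean beta difference).
#'
#' @param study A QC-filtered `methylation_study`.
#' @param covariates Character vector of sample-sheet covariate columns
#'   (e.g. `c("age", "sex", "pc1")`).
#' @param group_col Sample-sheet column holding the two-group contrast.
#' @param transform If `TRUE` (default) apply [rank_inverse_normal()] to each
#'   probe's M values before fitting.
#' @param alpha Significance level used for the FDR and Bonferroni columns.
#' @return Data frame of class `single_site_result`: `probe_id`,
#'   `chromosome`, `position`, `b_m` (group slope, transformed-M scale),
#'   `t_stat`, `p`, `beta_slope`, `direction` (sign of `beta_slope`),
#'   `fdr_q` (Benjamini-Hochberg), `bonferroni_sig`. The Bonferroni
#'   threshold `alpha / m` is stored in attribute `"bonferroni_threshold"`.
#' @export
fit_single_sites <- function(study, covariates = c("age", "sex"),
                             group_col = "group", transform = TRUE,
                             alpha = 0.05) {
  stopifnot(inherits(study, "methylation_study"))
  X <- build_design(study$samples, covariates, group_col)
  if (nrow(X) < ncol(X) + 1L)
    stop("not enough samples for the design (need n >= k + 3)")
  Ym <- if (transform) rank_inverse_normal(study$m) else study$m
  fit_m <- ols_by_row(Ym, X, "group")
  fit_b <- ols_by_row(study$beta, X, "group")
  thr <- alpha / n_probes(study)
  res <- data.frame(probe_id = study$probes$probe_id,
                    chromosome = study$probes$chromosome,
                    position = study$probes$position,
                    b_m = fit_m$estimate,
                    t_stat = fit_m$t_stat,
                    p = fit_m$p,
                    beta_slope = fit_b$estimate,
                    direction = sign(fit_b$estimate),
                    fdr_q = stats::p.adjust(fit_m$p, method = "BH"),
                    bonferroni_sig = fit_m$p < thr,
                    stringsAsFactors = FALSE)
  attr(res, "bonferroni_threshold") <- thr
  attr(res, "df") <- fit_m$df[1L]
  class(res) <- c("single_site_result", "data.frame")
  res
}

#' Multiple-testing adjustment
#'
#' For `method = "BH"` returns Benjamini-Hochberg step-up q-values; for
#' `method = "bonferroni"` returns the family-wise threshold `alpha / m`,
#' both at full precision and rounded to 2 significant digits (the form in
#' which such thresholds are conventionally quoted, e.g.
#' `0.05 / 420500 = 1.2e-7`).
#'
#' @param p Numeric vector of p values in (0, 1].
#' @param method `"BH"` or `"bonferroni"`.
#' @param alpha Significance level for the Bonferroni threshold.
#' @return q-value vector (BH) or a list `threshold`, `threshold_2sf`, `m`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni"), alpha = 0.05) {
  method <- match.arg(method)
  if (length(p) == 0L) stop("empty p-value list")
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("invalid p values")
  if (method == "BH") return(stats::p.adjust(p, method = "BH"))
  m <- length(p)
  list(threshold = alpha / m, threshold_2sf = signif(alpha / m, 2L), m = m)
}

#' Bonferroni threshold arithmetic
#'
#' @param alpha Family-wise significance level.
#' @param m Number of tests.
#' @return List with the raw threshold `alpha / m` and its 2-significant-digit
#'   rounding.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  list(threshold = alpha / m, threshold_2sf = signif(alpha / m, 2L), m = m)
}

#' Genomic inflation factor (lambda)
#'
#' `lambda = median(chi2) / qchisq(0.5, 1)` where the 1-df chi-square
#' statistics are either recovered from two-sided p values or supplied as
#' squared t statistics. Lambda near 1 indicates a well-calibrated test
#' ensemble; lambda > 1 indicates inflation.
#'
#' @param p Vector of p values (used if `chisq` is NULL).
#' @param chisq Optional vector of 1-df chi-square statistics (e.g. `t^2`).
#' @return Lambda (full precision; report rounded to 2 decimals).
#' @export
genomic_inflation <- function(p = NULL, chisq = NULL) {
  if (is.null(chisq)) {
    if (is.null(p)) stop("supply p or chisq")
    chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  }
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Deflate p values by a genomic inflation factor
#'
#' Divides the implied 1-df chi-square statistic by `lambda` and recomputes
#' the p value; with `lambda > 1` adjusted p values are never smaller than
#' the input.
#'
#' @param p Vector of p values.
#' @param lambda Positive inflation factor.
#' @return Adjusted p values.
#' @export
lambda_adjust <- function(p, lambda) {
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::pchisq(chisq / lambda, df = 1, lower.tail = FALSE)
}

#' Cross-cohort concordance of differential methylation
#'
#' Compares the direction and (lambda-adjusted) significance of per-probe
#' effects between two cohorts analyzed over an identical probe universe.
#' Probes known to be age-sensitive are removed first (country-specific fits
#' omit age as a covariate, so such probes would confound the comparison).
#' Direction agreement is tested against chance with a two-sided exact
#' binomial test.
#'
#' @param results_a,results_b `single_site_result` tables from the two
#'   cohorts (full universes; lambdas are estimated from all their p values).
#' @param probe_subset Probe ids to compare (e.g. the discovery-significant
#'   set).
#' @param age_probes Probe ids to exclude as age-sensitive.
#' @param alpha Per-cohort significance level after lambda adjustment.
#' @return List of class `concordance_report`: `n_probes_compared`,
#'   `n_same_direction`, `binomial_p`, `lambda_a`, `lambda_b`,
#'   `n_lambda_adjusted_sig_both`, `excluded_age_probes`.
#' @export
cohort_concordance <- function(results_a, results_b, probe_subset,
                               age_probes = character(), alpha = 0.05) {
  subset0 <- intersect(probe_subset,
                       intersect(results_a$probe_id, results_b$probe_id))
  excluded <- sum(subset0 %in% age_probes)
  subset <- setdiff(subset0, age_probes)
  if (length(subset) == 0L)
    stop("empty probe intersection after exclusions")
  ia <- match(subset, results_a$probe_id)
  ib <- match(subset, results_b$probe_id)
  da <- results_a$direction[ia]
  db <- results_b$direction[ib]
  comparable <- da != 0 & db != 0
  n_comp <- sum(comparable)
  n_same <- sum(da[comparable] == db[comparable])
  bt <- stats::binom.test(n_same, n_comp, p = 0.5,
                          alternative = "two.sided")
  lambda_a <- genomic_inflation(results_a$p)
  lambda_b <- genomic_inflation(results_b$p)
  pa <- lambda_adjust(results_a$p[ia], max(lambda_a, 1))
  pb <- lambda_adjust(results_b$p[ib], max(lambda_b, 1))
  structure(list(n_probes_compared = n_comp,
                 n_same_direction = n_same,
                 binomial_p = bt$p.value,
                 lambda_a = lambda_a, lambda_b = lambda_b,
                 n_lambda_adjusted_sig_both = sum(pa < alpha & pb < alpha),
                 excluded_age_probes = excluded),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("cohort concordance:", x$n_same_direction, "/", x$n_probes_compared,
      "same direction (binomial p =", format(x$binomial_p, digits = 3),
      ")\n")
  cat("  lambda A =", round(x$lambda_a, 2),
      " lambda B =", round(x$lambda_b, 2), "\n")
  cat("  lambda-adjusted significant in both:",
      x$n_lambda_adjusted_sig_both, "\n")
  cat("  excluded age-sensitive probes:", x$excluded_age_probes, "\n")
  invisible(x)
}

#' Principal-component covariates from the methylation matrix
#'
#' Computes sample-level principal components of the (transformed) M matrix
#' to serve as covariates capturing broad technical/geographic structure.
#'
#' @param study A `methylation_study`.
#' @param n_pcs Number of components to return.
#' @param transform Apply [rank_inverse_normal()] per probe first.
#' @return `study` with columns `pc1..pcK` added/overwritten in the sample
#'   sheet; attribute `"variance_explained"` holds the proportion per PC.
#' @export
add_methylation_pcs <- function(study, n_pcs = 1L, transform = TRUE) {
  stopifnot(inherits(study, "methylation_study"))
  M <- if (transform) rank_inverse_normal(study$m) else study$m
  pc <- stats::prcomp(t(M), center = TRUE, scale. = FALSE, rank. = n_pcs)
  ve <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_pcs)]
  for (k in seq_len(n_pcs))
    study$samples[[paste0("pc", k)]] <- pc$x[, k]
  attr(study, "variance_explained") <- ve
  study
}
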