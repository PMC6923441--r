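#' Construct a genotype matrix object
#'
#' @param dosage Integer matrix of minor-allele dosages (0/1/2, NA =
#'   missing), SNPs as rows, samples as columns; rownames = snp ids.
#' @param snps Data frame: `snp_id`, `chromosome`, `position` (1-based bp).
#' @return Object of class `genotype_matrix` with per-SNP `maf`,
#'   `missingness` and `hwe_p` computed on construction.
#' @export
genotype_matrix <- function(dosage, snps) {
  stopifnot(is.matrix(dosage), is.data.frame(snps),
            nrow(dosage) == nrow(snps))
  if (!all(dosage %in% c(0L, 1L, 2L, NA)))
    stop("dosages must be 0, 1, 2 or NA")
  if (is.null(rownames(dosage))) rownames(dosage) <- snps$snp_id
  freq <- rowMeans(dosage, na.rm = TRUE) / 2
  snps$maf <- pmin(freq, 1 - freq)
  snps$missingness <- rowMeans(is.na(dosage))
  snps$hwe_p <- apply(dosage, 1L, function(d) {
    d <- d[!is.na(d)]
    hwe_exact_p(sum(d == 1L), sum(d == 2L), sum(d == 0L))
  })
  structure(list(dosage = dosage, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "SNPs x", ncol(x$dosage),
      "samples\n")
  cat("  MAF range:", paste(round(range(x$snps$maf), 3), collapse = " - "),
      "\n")
  invisible(x)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact p value conditional on the observed allele counts: enumerates all
#' heterozygote counts of the correct parity, computes each configuration's
#' probability under HWE, and sums the probabilities not exceeding that of
#' the observed configuration (minimum-likelihood two-sided rule).
#'
#' @param n_het Count of heterozygotes.
#' @param n_hom_minor Count of minor-allele homozygotes.
#' @param n_hom_major Count of major-allele homozygotes.
#' @return Exact p value in (0, 1].
#' @export
hwe_exact_p <- function(n_het, n_hom_minor, n_hom_major) {
  n <- n_het + n_hom_minor + n_hom_major
  if (n == 0L) return(1)
  n1 <- 2L * n_hom_minor + n_het          # minor allele count
  if (n1 > n) {                           # ensure n1 is the minor count
    return(hwe_exact_p(n_het, n_hom_major, n_hom_minor))
  }
  if (n1 == 0L) return(1)
  hets <- seq.int(n1 %% 2L, n1, by = 2L)
  hets <- hets[(n1 - hets) %% 2L == 0L & (n1 - hets) / 2L >= 0L &
                 n - (hets + (n1 - hets) / 2L) >= (n1 - hets) / 2L + 0L]
  # log P(het) = log [ n! / (na! nab! nb!) * 2^het ] - log C(2n, n1)
  logp <- vapply(hets, function(h) {
    na <- (n1 - h) / 2L                   # minor homozygotes
    nb <- n - na - h
    lgamma(n + 1) - lgamma(na + 1) - lgamma(h + 1) - lgamma(nb + 1) +
      h * log(2) - (lgamma(2 * n + 1) - lgamma(n1 + 1) -
                      lgamma(2 * n - n1 + 1))
  }, numeric(1L))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n_het, hets)
  if (is.na(obs)) stop("observed heterozygote count has impossible parity")
  min(1, sum(p[p <= p[obs] * (1 + 1e-7)]))
}

#' Genotype quality control
#'
#' Removes samples with excessive missingness, then SNPs failing any of:
#' missingness above `max_missing`, exact Hardy-Weinberg p below
#' `hwe_alpha`, or minor allele frequency below `min_maf` (monomorphic SNPs
#' have MAF 0 and are removed).
#'
#' @param geno A `genotype_matrix`.
#' @param max_missing Maximum per-SNP and per-sample missing fraction.
#' @param hwe_alpha HWE exact-test exclusion threshold.
#' @param min_maf Minimum minor allele frequency.
#' @return Filtered `genotype_matrix` with attribute `"qc_report"` (counts
#'   removed per criterion).
#' @export
genotype_qc <- function(geno, max_missing = 0.02, hwe_alpha = 1e-3,
                        min_maf = 0.05) {
  stopifnot(inherits(geno, "genotype_matrix"))
  smiss <- colMeans(is.na(geno$dosage))
  keep_s <- smiss <= max_missing
  dosage <- geno$dosage[, keep_s, drop = FALSE]
  # per-SNP stats recomputed on retained samples
  freq <- rowMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  miss <- rowMeans(is.na(dosage))
  hwe <- apply(dosage, 1L, function(d) {
    d <- d[!is.na(d)]
    hwe_exact_p(sum(d == 1L), sum(d == 2L), sum(d == 0L))
  })
  fail_miss <- miss > max_missing
  fail_hwe <- hwe < hwe_alpha
  fail_maf <- is.na(maf) | maf < min_maf
  keep <- !(fail_miss | fail_hwe | fail_maf)
  out <- genotype_matrix(dosage[keep, , drop = FALSE],
                         geno$snps[keep, c("snp_id", "chromosome",
                                           "position")])
  attr(out, "qc_report") <- list(
    n_samples_removed = sum(!keep_s),
    n_snps_missingness = sum(fail_miss),
    n_snps_hwe = sum(fail_hwe),
    n_snps_maf = sum(fail_maf),
    n_snps_removed = sum(!keep),
    n_snps_kept = sum(keep))
  out
}

#' Enumerate cis SNP-CpG (or SNP-cluster) pairs
#'
#' Pairs a SNP with a target when both lie on the same chromosome and the
#' SNP position is within `window` bp of the target position (for clusters:
#' of the cluster span, distance 0 inside the span).
#'
#' @param geno A `genotype_matrix`.
#' @param targets Data frame with `chromosome` plus either `probe_id` and
#'   `position`, or `cluster_id` with `start`/`end`.
#' @param window Maximum distance in bp (default 10 kb).
#' @return Data frame: `snp_id`, `target_id`, `distance`.
#' @export
cis_pairs <- function(geno, targets, window = 10000) {
  stopifnot(inherits(geno, "genotype_matrix"))
  targets <- as.data.frame(targets)
  if ("position" %in% names(targets)) {
    targets$start <- targets$position
    targets$end <- targets$position
  }
  id_col <- if ("probe_id" %in% names(targets)) "probe_id" else "cluster_id"
  stopifnot(all(c("chromosome", "start", "end", id_col) %in% names(targets)))
  snps <- geno$snps
  res <- list()
  for (chrom in unique(targets$chromosome)) {
    tt <- targets[targets$chromosome == chrom, , drop = FALSE]
    ss <- snps[snps$chromosome == chrom, , drop = FALSE]
    if (!nrow(ss) || !nrow(tt)) next
    for (i in seq_len(nrow(tt))) {
      d <- pmax(0, pmax(tt$start[i] - ss$position,
                        ss$position - tt$end[i]))
      hit <- d <= window
      if (any(hit))
        res[[length(res) + 1L]] <-
          data.frame(snp_id = ss$snp_id[hit], target_id = tt[[id_col]][i],
                     distance = d[hit], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(snp_id = character(), target_id = character(),
                      distance = numeric())
  rownames(out) <- NULL
  out
}

# per-pair OLS through lm.fit-style computation on a small design
.pair_fit <- function(y, X, term) {
  ok <- stats::complete.cases(cbind(y, X))
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  qx <- qr(X)
  df <- nrow(X) - qx$rank
  if (qx$rank < ncol(X) || df < 3L) return(NULL)
  cf <- qr.coef(qx, y)
  res <- y - X %*% cf
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  j <- match(term, colnames(X))
  se <- sqrt(sigma2 * xtx_inv[j, j])
  tt <- cf[j] / se
  list(estimate = unname(cf[j]), se = unname(se), t = unname(tt),
       p = 2 * stats::pt(abs(tt), df, lower.tail = FALSE), df = df,
       coef = cf)
}

#' Additive cis-meQTL regression
#'
#' Per SNP-CpG pair, within the selected sample subset, fits
#' `probe value = covariates + SNP dosage (0, 1, 2 minor alleles)` on the
#' rank-inverse-normal transformed M values and reports the Wald/t test on
#' the dosage term.
#'
#' @param study A `methylation_study`.
#' @param geno A `genotype_matrix` sharing sample ids with the study.
#' @param pairs Data frame from [cis_pairs()] (`snp_id`, `target_id` =
#'   probe id).
#' @param covariates Sample-sheet covariate columns.
#' @param subset Optional logical/character selector of samples (e.g.
#'   `study$samples$timepoint == "DC"`).
#' @param transform Apply [rank_inverse_normal()] within the subset.
#' @return Data frame of class `meqtl_result`: `snp_id`, `cpg_id`, `beta1`
#'   (dosage slope), `se`, `t`, `p_main`, `n`, `untested` (flag: degenerate
#'   dosage or insufficient residual df).
#' @export
fit_meqtl <- function(study, geno, pairs, covariates = c("age", "sex"),
                      subset = NULL, transform = TRUE) {
  sel <- .resolve_subset(study, subset)
  samp <- study$samples[sel, , drop = FALSE]
  common <- intersect(samp$sample_id, colnames(geno$dosage))
  if (length(common) < 8L) stop("too few genotyped samples in subset")
  samp <- samp[match(common, samp$sample_id), , drop = FALSE]
  M <- study$m[, common, drop = FALSE]
  if (transform) M <- rank_inverse_normal(M)
  G <- geno$dosage[, common, drop = FALSE]
  C <- .covariate_matrix(samp, covariates)
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    cpg <- pairs$target_id[i]; snp <- pairs$snp_id[i]
    y <- M[cpg, ]
    d <- G[snp, ]
    X <- cbind(C, dosage = d)
    fit <- if (length(unique(d[!is.na(d)])) < 2L) NULL
           else .pair_fit(y, X, "dosage")
    out[[i]] <- data.frame(snp_id = snp, cpg_id = cpg,
                           beta1 = fit$estimate %||% NA_real_,
                           se = fit$se %||% NA_real_,
                           t = fit$t %||% NA_real_,
                           p_main = fit$p %||% NA_real_,
                           n = sum(!is.na(y) & !is.na(d)),
                           untested = is.null(fit),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("meqtl_result", "data.frame")
  res
}

#' SNP-by-condition interaction meQTL regression
#'
#' Per pair, fits `probe value = covariates + dosage + group + dosage:group`
#' and reports the t test on the product term alongside the per-group dosage
#' slopes (reference group = NESAM).
#'
#' @inheritParams fit_meqtl
#' @param group_col Two-level sample-sheet column (ESAM/NESAM).
#' @return Data frame of class `meqtl_result`: `snp_id`, `cpg_id`,
#'   `beta1_ref` (dosage slope, reference group), `beta1_alt` (other group),
#'   `p_interaction`, `n`, `untested`.
#' @export
fit_interaction <- function(study, geno, pairs,
                            covariates = c("age", "sex"),
                            group_col = "group", subset = NULL,
                            transform = TRUE) {
  sel <- .resolve_subset(study, subset)
  samp <- study$samples[sel, , drop = FALSE]
  common <- intersect(samp$sample_id, colnames(geno$dosage))
  if (length(common) < 10L) stop("too few genotyped samples in subset")
  samp <- samp[match(common, samp$sample_id), , drop = FALSE]
  g <- samp[[group_col]]
  if (length(unique(g)) < 2L)
    stop("interaction inestimable: group indicator constant in subset")
  lev <- if (all(unique(g) %in% c("ESAM", "NESAM"))) c("NESAM", "ESAM")
         else sort(unique(g))
  gi <- as.integer(factor(g, levels = lev)) - 1L
  M <- study$m[, common, drop = FALSE]
  if (transform) M <- rank_inverse_normal(M)
  G <- geno$dosage[, common, drop = FALSE]
  C <- .covariate_matrix(samp, covariates)
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    cpg <- pairs$target_id[i]; snp <- pairs$snp_id[i]
    y <- M[cpg, ]
    d <- G[snp, ]
    X <- cbind(C, dosage = d, group = gi, dosage_group = d * gi)
    ok_d <- d[!is.na(d)]
    estimable <- length(unique(ok_d)) >= 2L &&
      length(unique(ok_d[gi[!is.na(d)] == 1L])) >= 2L &&
      length(unique(ok_d[gi[!is.na(d)] == 0L])) >= 2L
    fit <- if (estimable) .pair_fit(y, X, "dosage_group") else NULL
    out[[i]] <- data.frame(
      snp_id = snp, cpg_id = cpg,
      beta1_ref = if (is.null(fit)) NA_real_ else
        unname(fit$coef["dosage"]),
      beta1_alt = if (is.null(fit)) NA_real_ else
        unname(fit$coef["dosage"] + fit$coef["dosage_group"]),
      p_interaction = fit$p %||% NA_real_,
      n = sum(!is.na(y) & !is.na(d)),
      untested = is.null(fit), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("meqtl_result", "data.frame")
  res
}

.resolve_subset <- function(study, subset) {
  if (is.null(subset)) return(rep(TRUE, n_samples(study)))
  if (is.logical(subset)) {
    stopifnot(length(subset) == n_samples(study))
    return(subset)
  }
  study$samples$sample_id %in% subset
}

.covariate_matrix <- function(samples, covariates) {
  dd <- samples[, covariates, drop = FALSE]
  dd[] <- lapply(dd, function(v) if (is.character(v)) factor(v) else v)
  stats::model.matrix(~ ., data = dd)
}

#' Merge additive and interaction meQTL fits into joint records
#'
#' @param add Output of [fit_meqtl()].
#' @param int Output of [fit_interaction()] over the same pairs.
#' @return Data frame keyed by (snp_id, cpg_id) with `beta1`, `p_main`,
#'   `beta1_ref`, `beta1_alt`, `p_interaction`, `untested`.
#' @export
meqtl_records <- function(add, int) {
  m <- merge(add[, c("snp_id", "cpg_id", "beta1", "p_main", "untested")],
             int[, c("snp_id", "cpg_id", "beta1_ref", "beta1_alt",
                     "p_interaction", "untested")],
             by = c("snp_id", "cpg_id"), suffixes = c("_add", "_int"))
  m$untested <- m$untested_add | m$untested_int
  m$untested_add <- m$untested_int <- NULL
  m
}

#' Classify meQTLs as nutrition-sensitive
#'
#' A SNP-CpG pair is called nutrition-sensitive when (i) it is a nominal
#' meQTL among acute (DC) samples (`p_main <= p_main_cut`), (ii) the
#' SNP-by-group interaction is significant in DC (`p_interaction <=
#' p_int_cut`), and (iii) there is no evidence of a similar interaction
#' among recovered (DL) samples (`p_interaction > p_int_cut` in DL).
#' Eligible pairs failing (ii) or (iii) are classified insensitive; pairs
#' with any inestimable fit are `untested`. A stringent tier additionally
#' requires DC `p_interaction < stringent_p`.
#'
#' @param dc_records,dl_records Outputs of [meqtl_records()] for the DC and
#'   DL subsets (DL `p_main` is not used).
#' @param p_main_cut DC main-effect screen threshold.
#' @param p_int_cut Interaction threshold (`<=` in DC, `>` in DL).
#' @param stringent_p Stringent DC interaction threshold (`<`).
#' @return Data frame: pair keys, DC/DL statistics, `classification`
#'   (`"nutrition_sensitive"`, `"insensitive"`, `"untested"`), `stringent`.
#' @export
classify_nutrition_sensitive <- function(dc_records, dl_records,
                                         p_main_cut = 0.05,
                                         p_int_cut = 0.05,
                                         stringent_p = 1e-4) {
  m <- merge(dc_records, dl_records[, c("snp_id", "cpg_id",
                                        "p_interaction", "untested")],
             by = c("snp_id", "cpg_id"), suffixes = c("_dc", "_dl"))
  m <- m[order(m$snp_id, m$cpg_id), , drop = FALSE]
  eligible <- !m$untested_dc & !m$untested_dl &
    !is.na(m$p_main) & m$p_main <= p_main_cut
  sens <- eligible & m$p_interaction_dc <= p_int_cut &
    m$p_interaction_dl > p_int_cut
  m$classification <- ifelse(!(!m$untested_dc & !m$untested_dl), "untested",
                             ifelse(!eligible, "untested",
                                    ifelse(sens, "nutrition_sensitive",
                                           "insensitive")))
  m$stringent <- sens & m$p_interaction_dc < stringent_p
  rownames(m) <- NULL
  m
}

#' Fisher exact test of meQTL overlap with a reference catalog
#'
#' Two-sided exact test (minimum-likelihood / point-probability rule, the
#' convention of [stats::fisher.test()]) on the 2x2 table of
#' nutrition-sensitive vs insensitive meQTLs found vs not found in an
#' external reference meQTL set.
#'
#' @param n_sensitive,k_sensitive_in_ref Totals and reference hits among
#'   nutrition-sensitive pairs.
#' @param n_insensitive,k_insensitive_in_ref Same for insensitive pairs.
#' @return List: `odds_ratio` (conditional MLE), `p`, `table`.
#' @export
reference_overlap_fisher <- function(n_sensitive, k_sensitive_in_ref,
                                     n_insensitive, k_insensitive_in_ref) {
  tab <- matrix(c(k_sensitive_in_ref, n_sensitive - k_sensitive_in_ref,
                  k_insensitive_in_ref,
                  n_insensitive - k_insensitive_in_ref),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("sensitive", "insensitive"),
                                c("in_ref", "not_in_ref")))
  if (any(tab < 0)) stop("negative cell count")
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab)
}

#' Write / read a genotype matrix as a dosage TSV
#'
#' Rows are SNPs (columns `snp_id`, `chromosome`, `position`, then one
#' column per sample holding 0/1/2/NA dosages).
#'
#' @param geno A `genotype_matrix`.
#' @param path Output file.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(geno$snps[, c("snp_id", "chromosome", "position")],
                   geno$dosage, check.names = FALSE)
  write_tsv_full(df, path)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read_tsv(path)
  meta <- c("snp_id", "chromosome", "position")
  dosage <- as.matrix(df[, setdiff(names(df), meta), drop = FALSE])
  mode(dosage) <- "integer"
  rownames(dosage) <- df$snp_id
  genotype_matrix(dosage, df[, meta])
}
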