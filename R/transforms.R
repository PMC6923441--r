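#' Convert methylation beta values to M values
#'
#' M values are the log2 odds of methylation, `M = log2(beta / (1 - beta))`.
#' Statistical testing is performed on the M scale (approximately
#' homoscedastic), while effect sizes are reported on the beta scale.
#'
#' @param beta Numeric vector or matrix of methylation fractions. Values must
#'   lie in `[0, 1]`; exact 0/1 values are clamped to `[1e-6, 1 - 1e-6]` with
#'   a warning.
#' @return Object of the same shape as `beta` holding M values.
#' @seealso [m_to_beta()]
#' @export
#' @examples
#' beta_to_m(0.5) # 0
#' beta_to_m(0.8) # 2
beta_to_m <- function(beta) {
  if (any(!is.finite(beta)))
    stop("beta values must be finite")
  if (any(beta < 0 | beta > 1))
    stop("beta values must lie in [0, 1]")
  if (any(beta == 0 | beta == 1)) {
    warning("beta values of exactly 0 or 1 clamped to [1e-6, 1 - 1e-6]")
    beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  }
  log2(beta / (1 - beta))
}

#' Convert M values to methylation beta values
#'
#' Exact inverse of [beta_to_m()]: `beta = 2^M / (1 + 2^M)`.
#'
#' @param m Numeric vector or matrix of finite M values.
#' @return Beta values in (0, 1), same shape as `m`.
#' @export
m_to_beta <- function(m) {
  if (any(!is.finite(m)))
    stop("M values must be finite")
  # logistic in base 2, computed via plogis for numerical stability
  stats::plogis(m * log(2))
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles of their Blom-offset rank fractions,
#' `qnorm((r - 3/8) / (n + 1/4))`, with ties receiving the average rank.
#' Applied per probe (per row of a matrix) across samples before linear-model
#' testing, mirroring quantile normalization of M values prior to regression.
#'
#' @param x Numeric vector, or matrix with probes as rows and samples as
#'   columns (each row transformed independently).
#' @return Transformed object of the same shape. A constant vector maps to
#'   all zeros with a warning.
#' @export
rank_inverse_normal <- function(x) {
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, rank_inverse_normal_vec, warn = FALSE))
    dimnames(out) <- dimnames(x)
    return(out)
  }
  rank_inverse_normal_vec(x, warn = TRUE)
}

rank_inverse_normal_vec <- function(x, warn = TRUE) {
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3L)
    stop("rank_inverse_normal needs at least 3 non-missing values")
  out <- rep(NA_real_, length(x))
  xs <- x[ok]
  if (max(xs) == min(xs)) {
    if (warn) warning("constant vector: transform returns zeros")
    out[ok] <- 0
    return(out)
  }
  r <- rank(xs, ties.method = "average")
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}
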