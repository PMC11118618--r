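#' Encode a clock time on the 24-hour circle
#'
#' Converts clock times to radians with midnight (12am) at angle 0 and to the
#' sine/cosine pair used as regression predictors. The encoding is continuous
#' across midnight: 23:59 and 00:01 map to nearby points on the unit circle,
#' which is the reason circular phenotypes are not analyzed as plain numbers.
#'
#' @param hours numeric vector of clock times in decimal hours, in
#'   `[0, 24)`. `10.5` means 10:30.
#' @return A data.frame with columns `angle` (radians in `[0, 2*pi)`),
#'   `sin_term`, `cos_term`.
#' @examples
#' encode_circular(c(0, 6, 12, 18))
#' @export
encode_circular <- function(hours) {
  if (anyNA(hours)) stop("clock times must not be missing")
  if (any(hours < 0 | hours >= 24))
    stop("clock times must lie in [0, 24) hours")
  angle <- 2 * pi * hours / 24
  data.frame(angle = angle, sin_term = sin(angle), cos_term = cos(angle))
}

#' Pool estimates across multiple imputations by Rubin's rules
#'
#' Combines m per-imputation coefficient estimates and their variances:
#' pooled estimate `beta_bar = mean(betas)`, within variance `W_bar =
#' mean(variances)`, between variance `B = var(betas)`, total `T = W_bar +
#' (1 + 1/m) B`. Inference uses a t reference with the Barnard-Rubin
#' small-sample degrees of freedom, which never exceeds the complete-data df.
#' With `m = 1` the single-imputation result is returned unchanged.
#'
#' @param betas numeric vector of per-imputation estimates.
#' @param variances matching vector of per-imputation squared standard errors.
#' @param complete_df complete-data degrees of freedom (here: the survey
#'   design df of the fits).
#' @return List with `m`, `beta_bar`, `W_bar`, `B`, `T`, `df_adj`, `se`, `p`.
#' @export
rubin_pool <- function(betas, variances, complete_df) {
  m <- length(betas)
  if (length(variances) != m)
    stop("betas and variances must have equal length")
  if (m < 1) stop("need at least one imputation")
  if (any(variances <= 0)) stop("variances must be positive")
  beta_bar <- mean(betas)
  W_bar <- mean(variances)
  if (m == 1) {
    B <- 0
    T_var <- W_bar
    df_adj <- complete_df
  } else {
    B <- stats::var(betas)
    T_var <- W_bar + (1 + 1 / m) * B
    if (B == 0) {
      df_adj <- complete_df
    } else {
      lambda <- (1 + 1 / m) * B / T_var
      nu_old <- (m - 1) / lambda^2
      nu_obs <- (complete_df + 1) / (complete_df + 3) *
        complete_df * (1 - lambda)
      df_adj <- nu_old * nu_obs / (nu_old + nu_obs)
    }
  }
  df_adj <- min(df_adj, complete_df)
  se <- sqrt(T_var)
  p <- 2 * stats::pt(abs(beta_bar) / se, df = df_adj, lower.tail = FALSE)
  list(m = m, beta_bar = beta_bar, W_bar = W_bar, B = B, T = T_var,
       df_adj = df_adj, se = se, p = p)
}

#' Aggregated Cauchy association test (ACAT)
#'
#' Combines possibly correlated p-values through the Cauchy transform:
#' `T = sum(w_i * tan((0.5 - p_i) * pi))`, combined `p = 0.5 - atan(T)/pi`.
#' Validity does not require independence of the components, which is what
#' makes it suitable for pooling Wald p-values computed on multiply-imputed
#' versions of the same data. p-values are clamped to
#' `[1e-15, 1 - 1e-15]`; below the lower clamp the tangent is replaced by its
#' asymptote `1/(p * pi)`.
#'
#' @param p numeric vector of p-values in (0, 1).
#' @param weights nonnegative weights; defaults to equal. Internally
#'   normalized to sum to one.
#' @return The combined p-value, a single number in (0, 1).
#' @examples
#' acat_combine(c(0.01, 0.04, 0.3))
#' @export
acat_combine <- function(p, weights = NULL) {
  if (length(p) == 0) stop("no p-values to combine")
  if (anyNA(p) || any(p <= 0) || any(p >= 1))
    stop("p-values must lie strictly in (0, 1)")
  if (is.null(weights)) weights <- rep(1, length(p))
  if (length(weights) != length(p) || any(weights < 0) || sum(weights) == 0)
    stop("weights must be nonnegative, matching length, not all zero")
  w <- weights / sum(weights)
  small <- p < 1e-15
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  tans <- ifelse(small, 1 / (p * pi), tan((0.5 - p) * pi))
  T_stat <- sum(w * tans)
  out <- 0.5 - atan(T_stat) / pi
  # keep the result inside (0, 1) against rounding at the extremes
  min(max(out, 1e-300), 1 - 1e-16)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, applied to one
#' group of p-values at a time. The atlas groups p-values within each sleep
#' phenotype across all metabolites and both models jointly before adjusting.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) stop("empty p-value group")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
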