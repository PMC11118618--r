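#' Survey design object
#'
#' Bundle the per-subject stratum, primary sampling unit (PSU) and sampling
#' weight that define the variance-estimation structure of a stratified
#' two-stage sample. Variances downstream are Taylor-linearized "with
#' replacement" estimators: PSU totals are centered within stratum, so every
#' stratum must contribute at least two PSUs.
#'
#' @param stratum vector of stratum labels, one per subject.
#' @param psu vector of PSU labels, one per subject. A PSU label must occur
#'   in exactly one stratum.
#' @param weight positive sampling weights, one per subject.
#' @return An object of class `svy_design` with elements `stratum`, `psu`,
#'   `weight`, `n`, `n_psu`, `n_strata` and `design_df` (PSUs minus strata).
#' @examples
#' d <- svy_design(rep(1:2, each = 6), rep(1:4, each = 3), runif(12, 1, 3))
#' d$design_df
#' @export
svy_design <- function(stratum, psu, weight) {
  n <- length(weight)
  if (length(stratum) != n || length(psu) != n)
    stop("stratum, psu and weight must have equal length")
  if (anyNA(stratum) || anyNA(psu) || anyNA(weight))
    stop("design columns must not contain missing values")
  if (any(weight <= 0)) stop("weights must be strictly positive")
  stratum <- as.character(stratum)
  psu <- as.character(psu)
  # a PSU may not straddle strata
  psu_strat <- tapply(stratum, psu, function(s) length(unique(s)))
  if (any(psu_strat > 1))
    stop("each PSU must belong to exactly one stratum: ",
         paste(names(psu_strat)[psu_strat > 1], collapse = ", "))
  psu_per_str <- tapply(psu, stratum, function(p) length(unique(p)))
  if (any(psu_per_str < 2))
    stop("every stratum needs >= 2 PSUs (lonely PSU in stratum ",
         paste(names(psu_per_str)[psu_per_str < 2], collapse = ", "), ")")
  n_psu <- length(unique(psu))
  n_strata <- length(unique(stratum))
  structure(
    list(stratum = stratum, psu = psu, weight = as.numeric(weight),
         n = n, n_psu = n_psu, n_strata = n_strata,
         design_df = n_psu - n_strata),
    class = "svy_design")
}

#' Subset a survey design
#'
#' @param design a [svy_design()] object.
#' @param idx logical or integer index of subjects to keep.
#' @return A new `svy_design` on the kept subjects. Strata reduced to a
#'   single PSU by the subset trigger the lonely-PSU error.
#' @export
svy_design_subset <- function(design, idx) {
  svy_design(design$stratum[idx], design$psu[idx], design$weight[idx])
}

#' Design-based weighted linear regression
#'
#' Fits the weighted least-squares model `y ~ X` and estimates the
#' coefficient covariance by Taylor linearization for a stratified cluster
#' sample: per-PSU totals of the weighted score `w_i x_i e_i` are centered
#' within stratum, their outer products scaled by `n_h / (n_h - 1)` (n_h =
#' PSUs in stratum h), summed, and sandwiched between the inverse weighted
#' information `(X'WX)^{-1}`. No finite-population correction is applied.
#'
#' @param y numeric response vector.
#' @param X numeric design matrix (including the intercept column).
#' @param design a [svy_design()] aligned row-wise with `y` and `X`.
#' @return An object of class `svy_fit`: `beta` (named coefficients), `vcov`,
#'   `design_df` (= PSUs - strata), `n`, `residuals`.
#' @examples
#' set.seed(1)
#' n <- 40
#' d <- svy_design(rep(1:2, each = 20), rep(1:8, each = 5), runif(n, 1, 2))
#' X <- cbind(1, x = rnorm(n))
#' fit <- svy_lm(rnorm(n), X, d)
#' fit$beta
#' @export
svy_lm <- function(y, X, design) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n || design$n != n)
    stop("y, X and design must have aligned rows")
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  w <- design$weight
  p <- ncol(X)

  qx <- qr(X * sqrt(w))
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  XtWX <- crossprod(X, w * X)
  A <- chol2inv(chol(XtWX))                       # (X'WX)^{-1}
  beta <- drop(A %*% crossprod(X, w * y))
  names(beta) <- colnames(X)
  e <- y - drop(X %*% beta)

  # per-PSU totals of the weighted scores u_i = w_i x_i e_i
  U <- X * (w * e)
  psu_key <- paste(design$stratum, design$psu, sep = "\r")
  Z <- rowsum(U, psu_key, reorder = FALSE)
  z_strat <- sub("\r.*$", "", rownames(Z))
  G <- matrix(0, p, p)
  for (h in unique(z_strat)) {
    Zh <- Z[z_strat == h, , drop = FALSE]
    nh <- nrow(Zh)
    Zc <- sweep(Zh, 2, colMeans(Zh))
    G <- G + (nh / (nh - 1)) * crossprod(Zc)
  }
  V <- A %*% G %*% A
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(
    list(beta = beta, vcov = V, design_df = design$design_df,
         n = n, residuals = e),
    class = "svy_fit")
}

#' Design-based Wald test on a coefficient subset
#'
#' Tests H0: beta_S = 0 with `F = beta_S' V_S^{-1} beta_S / q`, `q = |S|`,
#' referred to an F distribution on `(q, design_df - q + 1)` degrees of
#' freedom — the standard design-based convention. For `q = 1` this is the
#' square of the design-df t-test.
#'
#' @param fit an object returned by [svy_lm()].
#' @param coef_indices integer or character index of the tested coefficients.
#' @return List with `statistic`, `df1`, `df2`, `p`.
#' @export
svy_wald <- function(fit, coef_indices) {
  if (length(coef_indices) == 0) stop("coef_indices must be nonempty")
  if (is.character(coef_indices))
    coef_indices <- match(coef_indices, names(fit$beta))
  if (anyNA(coef_indices) || any(coef_indices < 1) ||
      any(coef_indices > length(fit$beta)))
    stop("coef_indices out of range")
  q <- length(coef_indices)
  df2 <- fit$design_df - q + 1
  if (df2 < 1) stop("design degrees of freedom too small for a ", q,
                    "-df Wald test")
  b <- fit$beta[coef_indices]
  V <- fit$vcov[coef_indices, coef_indices, drop = FALSE]
  Vc <- tryCatch(chol(V), error = function(e)
    stop("singular covariance submatrix in Wald test"))
  stat <- drop(crossprod(backsolve(Vc, b, transpose = TRUE))) / q
  list(statistic = stat, df1 = q, df2 = df2,
       p = stats::pf(stat, q, df2, lower.tail = FALSE))
}
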