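# Metabolite tables are data.frames with columns subject_id, batch, then one
# abundance column per metabolite (nonnegative or NA).

met_cols <- function(table) {
  setdiff(colnames(table), c("subject_id", "batch"))
}

check_met_table <- function(table) {
  if (!all(c("subject_id", "batch") %in% colnames(table)))
    stop("metabolite table needs subject_id and batch columns")
  mc <- met_cols(table)
  if (length(mc) == 0) stop("no metabolite columns")
  vals <- as.matrix(table[mc])
  if (any(vals < 0, na.rm = TRUE))
    stop("abundances must be nonnegative; this table looks already ",
         "transformed and must not be preprocessed again")
  invisible(mc)
}

#' Filter metabolites by per-batch missingness
#'
#' Drops a metabolite when its missing proportion exceeds `threshold` in
#' EITHER batch ("more than" is strict: exactly `threshold` is retained).
#'
#' @param table metabolite table (`subject_id`, `batch`, abundances).
#' @param threshold missingness proportion in (0, 1]; default 0.75.
#' @return List with `table` (kept columns) and `excluded`, a data.frame of
#'   dropped metabolites with the batch that triggered the exclusion and its
#'   missing proportion.
#' @export
filter_missingness <- function(table, threshold = 0.75) {
  mc <- check_met_table(table)
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  batches <- sort(unique(table$batch))
  if (any(tabulate(factor(table$batch, levels = batches)) == 0))
    stop("empty batch")
  excl <- list()
  drop <- character(0)
  for (m in mc) {
    miss <- vapply(batches, function(b) {
      mean(is.na(table[[m]][table$batch == b]))
    }, 0)
    over <- which(miss > threshold)
    if (length(over)) {
      drop <- c(drop, m)
      excl[[m]] <- data.frame(metabolite = m,
                              batch = batches[over[1]],
                              missing_prop = miss[over[1]])
    }
  }
  excluded <- if (length(excl)) do.call(rbind, c(excl, make.row.names = FALSE))
    else data.frame(metabolite = character(), batch = integer(),
                    missing_prop = numeric())
  list(table = table[, !(colnames(table) %in% drop), drop = FALSE],
       excluded = excluded)
}

#' Half-minimum imputation for left-censored xenobiotics
#'
#' Within each batch separately, missing values of a xenobiotic metabolite
#' are replaced by half of the lowest observed value of that metabolite in
#' that batch — the detection-limit convention for compounds whose
#' missingness means "below the platform's limit", not "not measured".
#'
#' @param table metabolite table.
#' @param xenobiotic_ids names of the xenobiotic metabolite columns.
#' @return The table with those columns completed; observed values unchanged.
#' @export
impute_half_min <- function(table, xenobiotic_ids) {
  check_met_table(table)
  xenobiotic_ids <- intersect(xenobiotic_ids, colnames(table))
  for (m in xenobiotic_ids) {
    for (b in unique(table$batch)) {
      idx <- which(table$batch == b)
      v <- table[[m]][idx]
      if (all(is.na(v)))
        stop("xenobiotic ", m, " fully missing in batch ", b,
             " (should have been filtered)")
      if (anyNA(v))
        table[[m]][idx[is.na(v)]] <- 0.5 * min(v, na.rm = TRUE)
    }
  }
  table
}

#' Fully conditional multiple imputation by predictive mean matching
#'
#' Imputes the missing entries of the given metabolite columns `m` times.
#' Each sweep visits every variable with missing data in turn and refits a
#' linear model of that variable on the covariates plus all other metabolite
#' columns (current completed values). Coefficients and the residual
#' variance are drawn from their approximate posterior, missing entries are
#' matched to the `k` observed donors with nearest predicted means, and one
#' donor's observed value is copied — so every imputed value is a member of
#' the observed support of its variable. Imputation index i uses its own
#' random substream of `seed`.
#'
#' @param table single-batch metabolite table (non-xenobiotic columns).
#' @param covariates data.frame of fully observed imputation covariates,
#'   aligned row-wise with `table`.
#' @param m number of completed datasets (default 5).
#' @param n_iter sweeps of the variable-by-variable cycle (default 10).
#' @param k donor pool size for predictive mean matching (default 5).
#' @param seed integer seed.
#' @return An `imputation_set`: list with `m`, `datasets` (m completed
#'   tables), `method` (named tag per metabolite), `seed`.
#' @export
impute_fcs <- function(table, covariates, m = 5, n_iter = 10, k = 5, seed = 1) {
  m <- as.integer(m)
  mc <- check_met_table(table)
  if (nrow(covariates) != nrow(table))
    stop("covariates must align row-wise with the metabolite table")
  if (anyNA(covariates))
    stop("imputation covariates with missing values are not part of the ",
         "iteration scheme; complete them or drop them")
  X_cov <- stats::model.matrix(~ ., data = covariates)
  vars_na <- mc[vapply(mc, function(v) anyNA(table[[v]]), TRUE)]
  for (v in vars_na) {
    if (all(is.na(table[[v]])))
      stop("metabolite ", v, " has no observed values in this batch")
  }
  datasets <- vector("list", m)
  for (i in seq_len(m)) {
    set.seed(seed * 1000L + i)
    filled <- table
    # start from a random observed-value fill
    for (v in vars_na) {
      obs <- filled[[v]][!is.na(filled[[v]])]
      nas <- which(is.na(filled[[v]]))
      filled[[v]][nas] <- sample(obs, length(nas), replace = TRUE)
    }
    if (length(vars_na)) {
      for (it in seq_len(n_iter)) {
        for (v in vars_na) {
          mis <- which(is.na(table[[v]]))
          obs <- which(!is.na(table[[v]]))
          others <- setdiff(mc, v)
          X <- cbind(X_cov, as.matrix(filled[others]))
          filled[[v]][mis] <- pmm_draw(
            y_obs = table[[v]][obs],
            X_obs = X[obs, , drop = FALSE],
            X_mis = X[mis, , drop = FALSE], k = k)
        }
      }
    }
    datasets[[i]] <- filled
  }
  structure(list(m = m, datasets = datasets,
                 method = stats::setNames(
                   ifelse(mc %in% vars_na, "multiple_imputation",
                          "multiple_imputation"), mc),
                 seed = seed),
            class = "imputation_set")
}

# One predictive-mean-matching draw: Bayesian linear regression of y on X
# (ridge-stabilized), type-1 matching of posterior-draw predictions for the
# missing rows against least-squares predictions for the observed rows.
pmm_draw <- function(y_obs, X_obs, X_mis, k = 5) {
  n_obs <- length(y_obs)
  p <- ncol(X_obs)
  XtX <- crossprod(X_obs) + diag(1e-6, p)
  XtXi <- chol2inv(chol(XtX))
  beta_hat <- drop(XtXi %*% crossprod(X_obs, y_obs))
  res <- y_obs - drop(X_obs %*% beta_hat)
  df <- max(n_obs - p, 1)
  sigma2_star <- sum(res^2) / stats::rchisq(1, df)
  beta_star <- beta_hat + drop(chol(XtXi) %*% stats::rnorm(p)) *
    sqrt(sigma2_star)
  yhat_obs <- drop(X_obs %*% beta_hat)
  yhat_mis <- drop(X_mis %*% beta_star)
  vapply(yhat_mis, function(yh) {
    d <- abs(yhat_obs - yh)
    pool <- order(d)[seq_len(min(k, n_obs))]
    y_obs[sample(pool, 1)]
  }, 0)
}

#' Rank-based inverse normal transformation
#'
#' Maps values to normal quantiles of `(rank - c) / (n - 2c + 1)` with the
#' Blom offset `c = 3/8` by default; ties share the average rank. The
#' transform is monotone and gives every untied vector of a given length the
#' same multiset of transformed values.
#'
#' @param values numeric vector, no missing values.
#' @param offset the rank offset `c`; 3/8 (Blom) by default, configurable.
#' @return Transformed values, approximately standard normal for large n.
#' @examples
#' rank_inverse_normal(c(1, 5, 2))
#' @export
rank_inverse_normal <- function(values, offset = 3 / 8) {
  if (anyNA(values)) stop("values must be complete before rank normalization")
  n <- length(values)
  if (n < 2 || length(unique(values)) == 1)
    stop("rank transform undefined for constant input")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - offset) / (n - 2 * offset + 1))
}

#' Aggregate per-batch imputation sets
#'
#' Row-concatenates dataset i of each batch into dataset i of the output, so
#' the "first" completed batch-1 data is paired with the "first" completed
#' batch-2 data, and so on. Metabolite columns must match exactly, in order;
#' mismatches raise rather than silently reordering.
#'
#' @param sets_by_batch list of `imputation_set` objects, one per batch.
#' @return A single `imputation_set` over the concatenated subjects.
#' @export
aggregate_batches <- function(sets_by_batch) {
  if (length(sets_by_batch) == 0) stop("no batches")
  ms <- vapply(sets_by_batch, `[[`, 0L, "m")
  if (length(unique(ms)) != 1) stop("mismatched m across batches")
  cols <- lapply(sets_by_batch, function(s) colnames(s$datasets[[1]]))
  if (!all(vapply(cols, identical, TRUE, cols[[1]])))
    stop("metabolite columns differ across batches (names or order)")
  m <- ms[1]
  datasets <- lapply(seq_len(m), function(i) {
    do.call(rbind, lapply(sets_by_batch, function(s) s$datasets[[i]]))
  })
  structure(list(m = m, datasets = datasets,
                 method = sets_by_batch[[1]]$method,
                 seed = sets_by_batch[[1]]$seed),
            class = "imputation_set")
}

#' Run the full metabolite preprocessing pipeline
#'
#' Order: missingness filter (per batch, strict 75% rule) -> half-minimum
#' fill for xenobiotics (per batch) -> fully conditional multiple imputation
#' for the rest (per batch) -> rank-based inverse normal transformation of
#' every metabolite within each batch and each completed dataset -> batch
#' aggregation. Xenobiotic metabolites are imputed once and therefore
#' identical across the m completed datasets.
#'
#' @param table metabolite table (both batches).
#' @param annotation annotation data.frame with `metabolite` and
#'   `xenobiotic` columns.
#' @param covariates data.frame of imputation covariates aligned with
#'   `table` rows.
#' @param m,n_iter,k,seed,threshold,offset tuning knobs passed through to
#'   the stage functions.
#' @return List with `imputations` (an `imputation_set` of rank-normalized,
#'   aggregated data), `excluded` (filter log), `method` (named tag per kept
#'   metabolite: `half_min` or `multiple_imputation`).
#' @export
preprocess_metabolites <- function(table, annotation, covariates,
                                   m = 5, n_iter = 10, k = 5, seed = 1,
                                   threshold = 0.75, offset = 3 / 8) {
  filt <- filter_missingness(table, threshold)
  tab <- filt$table
  kept <- met_cols(tab)
  xeno <- annotation$metabolite[annotation$xenobiotic]
  xeno <- intersect(xeno, kept)
  nonx <- setdiff(kept, xeno)
  tab <- impute_half_min(tab, xeno)

  batches <- sort(unique(tab$batch))
  sets <- lapply(batches, function(b) {
    idx <- tab$batch == b
    bt <- tab[idx, , drop = FALSE]
    if (length(nonx)) {
      s <- impute_fcs(bt[, c("subject_id", "batch", nonx), drop = FALSE],
                      covariates[idx, , drop = FALSE],
                      m = m, n_iter = n_iter, k = k,
                      seed = seed + match(b, batches))
      # re-attach the (already complete) xenobiotic columns
      s$datasets <- lapply(s$datasets, function(d) {
        d[xeno] <- bt[xeno]
        d[, c("subject_id", "batch", kept), drop = FALSE]
      })
    } else {
      m <- as.integer(m)
      s <- structure(list(m = m, datasets = rep(list(
        bt[, c("subject_id", "batch", kept), drop = FALSE]), m),
        method = character(0), seed = seed), class = "imputation_set")
    }
    # rank-normalize every metabolite within this batch, each dataset
    s$datasets <- lapply(s$datasets, function(d) {
      for (v in kept) d[[v]] <- rank_inverse_normal(d[[v]], offset)
      d
    })
    s
  })
  agg <- aggregate_batches(sets)
  method <- stats::setNames(
    ifelse(kept %in% xeno, "half_min", "multiple_imputation"), kept)
  agg$method <- method
  list(imputations = agg, excluded = filt$excluded, method = method)
}

#' Write an imputation set as parallel delimited files plus a manifest
#'
#' @param set an `imputation_set`.
#' @param dir output directory.
#' @return Invisibly, the manifest path.
#' @export
write_imputation_set <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(set$m)) {
    utils::write.table(set$datasets[[i]],
                       file.path(dir, sprintf("imputation_%02d.tsv", i)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  manifest <- list(m = set$m, seed = set$seed,
                   method = as.list(set$method))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
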