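#' Covariate sets of the two nested adjustment models
#'
#' Model 1 adjusts for batch plus demographic and baseline clinical
#' variables (age, sex, center, background, BMI); Model 2 further adjusts
#' for lifestyle (alcohol, smoking, physical activity, diet score).
#'
#' @param model `"Model1"` or `"Model2"`.
#' @return Character vector of covariate column names.
#' @export
model_covariates <- function(model = c("Model1", "Model2")) {
  model <- match.arg(model)
  m1 <- c("batch", "age", "sex", "center", "background", "bmi")
  if (model == "Model1") m1
  else c(m1, "alcohol", "smoking", "physical_activity", "diet_score")
}

# Design matrix for exposure columns + covariates; categorical covariates
# expand to treatment contrasts. Covariates constant in the (possibly
# subgroup-filtered) sample are dropped and reported via attribute.
build_model_matrix <- function(subjects, exposure_cols, covariate_cols) {
  missing_cov <- setdiff(covariate_cols, colnames(subjects))
  if (length(missing_cov))
    stop("covariates missing from subject table: ",
         paste(missing_cov, collapse = ", "))
  dat <- subjects[, c(exposure_cols, covariate_cols), drop = FALSE]
  if (!is.null(dat$batch)) dat$batch <- factor(dat$batch)
  constant <- covariate_cols[vapply(covariate_cols, function(v)
    length(unique(dat[[v]])) < 2, TRUE)]
  if (length(constant))
    dat <- dat[, setdiff(colnames(dat), constant), drop = FALSE]
  X <- stats::model.matrix(~ ., data = dat)
  attr(X, "dropped_constant") <- constant
  X
}

#' Test a linear (continuous or binary) phenotype against one metabolite
#'
#' Fits `metabolite ~ phenotype + model covariates` by design-based weighted
#' least squares in each completed dataset, then pools the phenotype
#' coefficient across imputations by Rubin's rules. Metabolites imputed once
#' (half-minimum xenobiotics) take the single-dataset result.
#'
#' @param phenotype phenotype column name (continuous or 0/1 binary).
#' @param metabolite metabolite column name.
#' @param subjects subject table (design columns + covariates + phenotypes).
#' @param imputations an `imputation_set` aligned to `subjects` by
#'   `subject_id`.
#' @param design a [svy_design()] over `subjects` rows.
#' @param model `"Model1"` or `"Model2"`.
#' @param single_dataset if TRUE use only the first completed dataset
#'   (the xenobiotic path).
#' @return List with `effect` (pooled beta), `se`, `p`, `test_df = 1`, `m`.
#' @export
test_linear <- function(phenotype, metabolite, subjects, imputations, design,
                        model = "Model1", single_dataset = FALSE) {
  x <- subjects[[phenotype]]
  if (length(unique(x)) < 2) stop("phenotype ", phenotype,
                                  " is constant in this sample")
  X <- build_model_matrix(subjects, phenotype, model_covariates(model))
  n_use <- if (single_dataset) 1L else imputations$m
  betas <- vars <- numeric(n_use)
  for (i in seq_len(n_use)) {
    y <- aligned_column(imputations$datasets[[i]], subjects$subject_id,
                        metabolite)
    fit <- svy_lm(y, X, design)
    betas[i] <- fit$beta[[phenotype]]
    vars[i] <- fit$vcov[phenotype, phenotype]
  }
  pooled <- rubin_pool(betas, vars, complete_df = design$design_df)
  list(effect = pooled$beta_bar, se = pooled$se, p = pooled$p,
       test_df = 1L, m = n_use)
}

#' Test a circular (clock-time) phenotype against one metabolite
#'
#' Encodes the phenotype as sine and cosine of its 24 h angle (midnight = 0),
#' fits `metabolite ~ sin + cos + covariates` per completed dataset, takes
#' the 2-df design-based Wald p-value, and aggregates the m p-values with
#' ACAT (equal weights). There is no pooled effect: the sine/cosine
#' covariance cannot be combined across imputations, which is why testing is
#' pooled on the p-value scale.
#'
#' @inheritParams test_linear
#' @return List with `effect = NA`, `p`, `test_df = 2`, `m`, `p_per_dataset`.
#' @export
test_circular <- function(phenotype, metabolite, subjects, imputations,
                          design, model = "Model1", single_dataset = FALSE) {
  x <- subjects[[phenotype]]
  if (length(unique(x)) < 2)
    stop("circular phenotype ", phenotype, " has zero circular variance")
  enc <- encode_circular(x)
  sub2 <- subjects
  sin_col <- paste0(phenotype, "_sin")
  cos_col <- paste0(phenotype, "_cos")
  sub2[[sin_col]] <- enc$sin_term
  sub2[[cos_col]] <- enc$cos_term
  X <- build_model_matrix(sub2, c(sin_col, cos_col), model_covariates(model))
  n_use <- if (single_dataset) 1L else imputations$m
  ps <- numeric(n_use)
  for (i in seq_len(n_use)) {
    y <- aligned_column(imputations$datasets[[i]], subjects$subject_id,
                        metabolite)
    fit <- svy_lm(y, X, design)
    ps[i] <- svy_wald(fit, c(sin_col, cos_col))$p
  }
  list(effect = NA_real_, p = acat_combine(ps), test_df = 2L, m = n_use,
       p_per_dataset = ps)
}

aligned_column <- function(dataset, subject_ids, column) {
  idx <- match(subject_ids, dataset$subject_id)
  if (anyNA(idx)) stop("imputation datasets do not cover all subjects")
  dataset[[column]][idx]
}

#' Run the full phenotype x metabolite association scan
#'
#' One record per (phenotype, metabolite, model). Linear phenotypes are
#' pooled by Rubin's rules; circular phenotypes by 2-df Wald + ACAT.
#' Benjamini-Hochberg FDR is applied within each phenotype across all
#' metabolites and all models jointly (the default; `fdr_group =
#' "per_model"` adjusts each model separately). Significance is declared at
#' `p_fdr < alpha` under Model 1 only.
#'
#' @param subjects subject table with design columns, covariates and
#'   phenotypes.
#' @param imputations `imputation_set` of preprocessed metabolite data.
#' @param phenotypes data.frame registry with columns `name`, `domain`,
#'   `scale`.
#' @param annotation metabolite annotation (`metabolite`, `superpathway`,
#'   `subpathway`, `xenobiotic`).
#' @param models character subset of `c("Model1", "Model2")`.
#' @param subgroup optional `list(column =, value =)` filter, e.g.
#'   `list(column = "sex", value = "Female")` for sex-stratified runs;
#'   covariates made constant by the filter are dropped from the models.
#' @param alpha FDR significance level (default 0.05).
#' @param fdr_group `"joint"` (default) or `"per_model"`.
#' @return A data.frame of class `association_table`: phenotype, domain,
#'   metabolite, superpathway, subpathway, model, effect, test_df, p_raw,
#'   p_fdr, significant.
#' @export
run_scan <- function(subjects, imputations, phenotypes, annotation,
                     models = c("Model1", "Model2"), subgroup = NULL,
                     alpha = 0.05, fdr_group = c("joint", "per_model")) {
  fdr_group <- match.arg(fdr_group)
  models <- match.arg(models, c("Model1", "Model2"), several.ok = TRUE)
  if (!is.null(subgroup)) {
    keep <- subjects[[subgroup$column]] == subgroup$value
    subjects <- subjects[keep, , drop = FALSE]
  }
  design <- svy_design(subjects$stratum, subjects$psu, subjects$weight)
  mets <- intersect(met_cols(imputations$datasets[[1]]),
                    annotation$metabolite)
  single <- imputations$method[mets] == "half_min"
  rows <- vector("list", nrow(phenotypes) * length(mets) * length(models))
  r <- 0L
  for (pi in seq_len(nrow(phenotypes))) {
    ph <- phenotypes$name[pi]
    sc <- phenotypes$scale[pi]
    for (model in models) {
      for (mi in seq_along(mets)) {
        met <- mets[mi]
        res <- if (sc == "circular") {
          test_circular(ph, met, subjects, imputations, design, model,
                        single_dataset = single[mi])
        } else {
          test_linear(ph, met, subjects, imputations, design, model,
                      single_dataset = single[mi])
        }
        r <- r + 1L
        ai <- match(met, annotation$metabolite)
        rows[[r]] <- data.frame(
          phenotype = ph, domain = phenotypes$domain[pi], metabolite = met,
          superpathway = annotation$superpathway[ai],
          subpathway = annotation$subpathway[ai],
          model = model, effect = res$effect, test_df = res$test_df,
          p_raw = res$p, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- NA_real_
  for (ph in unique(out$phenotype)) {
    if (fdr_group == "joint") {
      idx <- out$phenotype == ph
      out$p_fdr[idx] <- bh_fdr(out$p_raw[idx])
    } else {
      for (model in models) {
        idx <- out$phenotype == ph & out$model == model
        out$p_fdr[idx] <- bh_fdr(out$p_raw[idx])
      }
    }
  }
  out$significant <- out$model == "Model1" & out$p_fdr < alpha
  class(out) <- c("association_table", "data.frame")
  out
}

#' Write an association table as TSV and JSON-lines
#'
#' @param results an `association_table`.
#' @param path output path without extension; writes `<path>.tsv` and
#'   `<path>.jsonl`.
#' @return Invisibly, the two paths.
#' @export
write_association_table <- function(results, path) {
  tsv <- paste0(path, ".tsv")
  jsonl <- paste0(path, ".jsonl")
  utils::write.table(results, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  con <- file(jsonl, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(results))) {
    writeLines(jsonlite::toJSON(as.list(results[i, ]), auto_unbox = TRUE,
                                na = "null", digits = NA), con)
  }
  invisible(c(tsv, jsonl))
}
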