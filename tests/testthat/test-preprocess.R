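make_met_table <- function(vals, batch) {
  data.frame(subject_id = sprintf("S%02d", seq_along(batch)), batch = batch,
             vals, check.names = FALSE, stringsAsFactors = FALSE)
}

test_that("missingness filter drops on the strict per-batch rule", {
  batch <- rep(1:2, each = 20)
  bad <- c(ifelse(seq_len(20) <= 16, NA, 1), rnorm(20, 10))   # 80% / 10%
  edge <- c(ifelse(seq_len(20) <= 15, NA, 1),
            ifelse(seq_len(20) <= 15, NA, 1))                 # exactly 75%
  full <- runif(40, 1, 2)
  tab <- make_met_table(list(bad = bad, edge = edge, full = full), batch)
  res <- filter_missingness(tab, 0.75)
  expect_setequal(met_cols(res$table), c("edge", "full"))
  expect_equal(res$excluded$metabolite, "bad")
  expect_equal(res$excluded$batch, 1)
  expect_equal(res$excluded$missing_prop, 0.8)
})

test_that("half-minimum fill works per batch and leaves observed values alone", {
  tab <- make_met_table(list(x = c(4, 2, NA, NA, 6, 12)),
                        batch = rep(1:2, each = 3))
  out <- impute_half_min(tab, "x")
  expect_equal(out$x, c(4, 2, 1, 3, 6, 12))
  # no missing values: unchanged
  tab2 <- make_met_table(list(x = c(1, 2, 3, 4)), rep(1:2, each = 2))
  expect_identical(impute_half_min(tab2, "x"), tab2)
  # fully missing within a batch is a hard error
  tab3 <- make_met_table(list(x = c(NA, NA, 1, 2)), rep(1:2, each = 2))
  expect_error(impute_half_min(tab3, "x"), "fully missing")
})

test_that("FCS imputation is PMM: donors from the observed support, seeded", {
  set.seed(8)
  n <- 80
  cov <- data.frame(age = rnorm(n, 45, 10), bmi = rnorm(n, 29, 5))
  z1 <- 0.05 * cov$age + rnorm(n)
  z2 <- 0.3 * z1 + rnorm(n)
  tab <- make_met_table(list(a = exp(z1), b = exp(z2)), rep(1L, n))
  tab$a[sample(n, 15)] <- NA
  tab$b[sample(n, 10)] <- NA
  s1 <- impute_fcs(tab, cov, m = 3, n_iter = 4, seed = 42)
  expect_equal(s1$m, 3L)
  for (i in 1:3) {
    d <- s1$datasets[[i]]
    expect_false(anyNA(d$a) || anyNA(d$b))
    expect_true(all(d$a[is.na(tab$a)] %in% tab$a[!is.na(tab$a)]))
    expect_true(all(d$b[is.na(tab$b)] %in% tab$b[!is.na(tab$b)]))
    # observed entries untouched
    expect_identical(d$a[!is.na(tab$a)], tab$a[!is.na(tab$a)])
  }
  # imputations differ across m but reruns with the same seed are identical
  expect_false(identical(s1$datasets[[1]]$a, s1$datasets[[2]]$a))
  s2 <- impute_fcs(tab, cov, m = 3, n_iter = 4, seed = 42)
  expect_identical(s1$datasets, s2$datasets)
  # complete input: m identical copies of the input
  tabc <- make_met_table(list(a = exp(z1)), rep(1L, n))
  sc <- impute_fcs(tabc, cov, m = 5, seed = 1)
  expect_true(all(vapply(sc$datasets, identical, TRUE, tabc)))
  # covariates with missing values are rejected
  covNA <- cov; covNA$age[1] <- NA
  expect_error(impute_fcs(tab, covNA, m = 2, seed = 1), "covariates")
})

test_that("rank inverse normal transform follows the offset formula", {
  # Blom offset: qnorm((r - 3/8) / (n + 1 - 3/4))
  got <- rank_inverse_normal(c(1, 2, 3))
  want <- qnorm((1:3 - 3 / 8) / (3 - 2 * 3 / 8 + 1))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(got[2], 0)
  expect_equal(got[1], -got[3])
  # rank invariance: any strictly increasing triple maps identically
  expect_equal(rank_inverse_normal(c(-5, 0.1, 999)), want)
  # ties share the average rank
  t2 <- rank_inverse_normal(c(2, 2, 7))
  expect_equal(t2[1], t2[2])
  expect_error(rank_inverse_normal(rep(3, 4)), "constant")
  expect_error(rank_inverse_normal(c(1, NA, 2)), "complete")
  # approximate standardization at large n
  v <- rank_inverse_normal(rexp(2000))
  expect_equal(mean(v), 0, tolerance = 1e-6)
  expect_equal(sd(v), 1, tolerance = 0.01)
  # untied vectors of equal length share the same transformed multiset
  a <- sort(rank_inverse_normal(rnorm(50)))
  b <- sort(rank_inverse_normal(rexp(50)))
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("batch aggregation concatenates dataset-wise and checks contracts", {
  mk_set <- function(n, m, cols, batch, start = 1) {
    ds <- lapply(seq_len(m), function(i) {
      d <- make_met_table(setNames(lapply(cols, function(c) rnorm(n)), cols),
                          rep(batch, n))
      d$subject_id <- sprintf("B%d_%02d", batch, seq_len(n))
      d
    })
    structure(list(m = as.integer(m), datasets = ds,
                   method = setNames(rep("multiple_imputation",
                                         length(cols)), cols), seed = 1L),
              class = "imputation_set")
  }
  s1 <- mk_set(100, 5, c("a", "b"), 1)
  s2 <- mk_set(60, 5, c("a", "b"), 2)
  agg <- aggregate_batches(list(s1, s2))
  expect_equal(agg$m, 5L)
  expect_true(all(vapply(agg$datasets, nrow, 0L) == 160))
  # subject order stable: batch-1 rows first
  expect_equal(agg$datasets[[1]]$subject_id[1:100], s1$datasets[[1]]$subject_id)
  # single batch: identity
  one <- aggregate_batches(list(s1))
  expect_identical(one$datasets, s1$datasets)
  # mismatched m and reordered columns are rejected
  s3 <- mk_set(60, 4, c("a", "b"), 2)
  expect_error(aggregate_batches(list(s1, s3)), "mismatched m")
  s4 <- mk_set(60, 5, c("b", "a"), 2)
  expect_error(aggregate_batches(list(s1, s4)), "columns differ")
})

test_that("the full preprocessing pipeline refuses already-processed data", {
  coh <- generate_cohort(cohort_config(120, n_strata = 2, seed = 6),
                         small_registry(), small_mets())
  covars <- coh$subjects[, c("age", "bmi")]
  prep <- preprocess_metabolites(coh$metabolites, coh$annotation, covars,
                                 m = 2, n_iter = 2, seed = 9)
  out <- prep$imputations$datasets[[1]]
  expect_false(anyNA(out))
  # rank-normalized output contains negatives -> pipeline raises on re-entry
  expect_error(preprocess_metabolites(out, coh$annotation, covars,
                                      m = 2, seed = 9),
               "nonnegative")
})

test_that("xenobiotics are identical across completed datasets, others vary", {
  mets <- c(small_mets(n = 6, n_xeno = 2),
            list(metabolite_spec("c01", "Lipid", "Lipid sub1",
                                 missing_rate = 0),
                 metabolite_spec("c02", "Peptide", "Peptide sub1",
                                 missing_rate = 0)))
  coh <- generate_cohort(cohort_config(200, n_strata = 2, seed = 14),
                         small_registry(), mets)
  covars <- coh$subjects[, c("age", "bmi")]
  prep <- preprocess_metabolites(coh$metabolites, coh$annotation, covars,
                                 m = 3, n_iter = 2, seed = 10)
  sets <- prep$imputations$datasets
  expect_identical(sets[[1]]$m01, sets[[2]]$m01)
  expect_identical(sets[[1]]$m02, sets[[3]]$m02)
  expect_equal(unname(prep$method[c("m01", "m02")]), rep("half_min", 2))
  # at least one multiply-imputed metabolite differs between datasets
  nonx <- names(prep$method)[prep$method == "multiple_imputation"]
  differs <- vapply(nonx, function(v)
    !identical(sets[[1]][[v]], sets[[2]][[v]]), TRUE)
  expect_true(any(differs))
  # within each batch and dataset, untied metabolites share the same
  # quantile grid regardless of their raw distribution (imputed columns
  # carry donor/fill ties, so the exact multiset identity holds for the
  # untied ones)
  d1 <- sets[[1]]
  for (b in 1:2) {
    rows <- d1$batch == b
    untied <- Filter(function(v) !anyDuplicated(d1[[v]][rows]),
                     met_cols(d1))
    grids <- lapply(untied, function(v) sort(d1[[v]][rows]))
    expect_gte(length(grids), 2)
    for (g in grids[-1]) expect_equal(g, grids[[1]], tolerance = 1e-12)
  }
})

test_that("pooled estimates recover planted effects through imputation", {
  hits <- 0
  n_rep <- 25
  for (r in seq_len(n_rep)) {
    coh <- generate_cohort(cohort_config(300, n_strata = 3, seed = 100 + r),
                           small_registry(),
                           small_mets(n = 4, n_xeno = 0),
                           list(effect_spec("dur", "m03", slope = 0.4)))
    covars <- coh$subjects[, c("age", "bmi")]
    prep <- preprocess_metabolites(coh$metabolites, coh$annotation, covars,
                                   m = 3, n_iter = 2, seed = 200 + r)
    design <- svy_design(coh$subjects$stratum, coh$subjects$psu,
                         coh$subjects$weight)
    res <- test_linear("dur", "m03", coh$subjects, prep$imputations, design)
    # planted slope on the latent scale corresponds to roughly the same
    # coefficient after rank normalization of a standard-normal latent;
    # recovery is judged against the planted value with pooled-T radius
    if (abs(res$effect - 0.4 / sqrt(1 + 0.4^2 * var(coh$subjects$dur))) <
          3 * res$se) hits <- hits + 1
  }
  expect_gte(hits, ceiling(0.88 * n_rep))
})
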