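#' Configuration for a synthetic survey cohort
#'
#' Describes the sampling structure the generator emulates: a stratified
#' two-stage sample with unequal weights and two metabolomics batches whose
#' cohort composition may differ (batch 2 can be shifted older, as happens
#' when a second profiling wave recruits later).
#'
#' @param n_subjects number of subjects; must be at least
#'   `n_strata * psus_per_stratum` so every PSU is populated.
#' @param n_strata number of sampling strata.
#' @param psus_per_stratum PSUs per stratum (>= 2 so each stratum contributes
#'   to the variance).
#' @param weight_range length-2 positive vector, min and max sampling weight.
#' @param batch_fractions length-2 proportions summing to 1, the share of
#'   subjects profiled in metabolomics batch 1 and batch 2.
#' @param seed integer seed; identical configs produce bit-identical cohorts.
#' @param weight_age_corr strength of the association between age and the
#'   sampling weight on the logistic scale; nonzero values make the design
#'   informative (weighted and unweighted means differ).
#' @param batch_age_shift years added to the mean age of batch-2 subjects.
#' @param phenotype_corr exchangeable correlation among the latent normals
#'   behind the continuous phenotypes; 0 (default) draws them independently.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects, n_strata = 5, psus_per_stratum = 4,
                          weight_range = c(0.5, 3), batch_fractions = c(0.6, 0.4),
                          seed = 1, weight_age_corr = 0.4,
                          batch_age_shift = 4, phenotype_corr = 0) {
  if (n_subjects < n_strata * psus_per_stratum)
    stop("n_subjects must be >= n_strata * psus_per_stratum")
  if (psus_per_stratum < 2) stop("need >= 2 PSUs per stratum")
  if (length(weight_range) != 2 || any(weight_range <= 0) ||
      diff(weight_range) < 0)
    stop("weight_range must be an increasing positive pair")
  if (length(batch_fractions) != 2 || any(batch_fractions <= 0) ||
      any(batch_fractions >= 1) || abs(sum(batch_fractions) - 1) > 1e-8)
    stop("batch_fractions must be two proportions in (0,1) summing to 1")
  if (phenotype_corr < 0 || phenotype_corr >= 1)
    stop("phenotype_corr must be in [0, 1)")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_strata = as.integer(n_strata),
                 psus_per_stratum = as.integer(psus_per_stratum),
                 weight_range = weight_range,
                 batch_fractions = batch_fractions,
                 seed = as.integer(seed),
                 weight_age_corr = weight_age_corr,
                 batch_age_shift = batch_age_shift,
                 phenotype_corr = phenotype_corr),
            class = "cohort_config")
}

#' Declare a sleep phenotype
#'
#' @param name identifier, unique within a registry.
#' @param domain one of `"Duration"`, `"HR"`, `"Insomnia"`, `"SDB"`,
#'   `"Timing"`.
#' @param scale `"continuous"`, `"binary"` or `"circular"`. Timing-domain
#'   phenotypes must be circular (clock times on the 24 h circle).
#' @param mean,sd generation parameters for continuous phenotypes.
#' @param prevalence event probability for binary phenotypes, in (0, 1).
#' @param mean_time,concentration circular parameters: mean clock time in
#'   decimal hours and a nonnegative von Mises concentration (0 = uniform
#'   over the day).
#' @return A list of class `phenotype_spec`.
#' @export
phenotype_spec <- function(name, domain, scale,
                           mean = 0, sd = 1, prevalence = 0.5,
                           mean_time = 23, concentration = 8) {
  domain <- match.arg(domain, c("Duration", "HR", "Insomnia", "SDB", "Timing"))
  scale <- match.arg(scale, c("continuous", "binary", "circular"))
  if (domain == "Timing" && scale != "circular")
    stop("Timing-domain phenotypes must have scale = 'circular'")
  if (scale == "circular" && domain != "Timing")
    stop("circular phenotypes belong to the Timing domain")
  if (scale == "binary" && (prevalence <= 0 || prevalence >= 1))
    stop("binary prevalence must lie in (0, 1)")
  if (scale == "circular" && concentration < 0)
    stop("concentration must be nonnegative")
  structure(list(name = name, domain = domain, scale = scale,
                 mean = mean, sd = sd, prevalence = prevalence,
                 mean_time = mean_time, concentration = concentration),
            class = "phenotype_spec")
}

#' Declare a metabolite and its missingness mechanism
#'
#' Xenobiotic metabolites are left-censored at a detection limit: the lowest
#' `detection_limit_quantile` share of abundances is set missing, so every
#' observed value exceeds every censored one. Non-xenobiotic metabolites get
#' covariate-dependent (missing-at-random) missingness driven by standardized
#' age on the logistic scale, which is what makes multiple imputation, rather
#' than a detection-limit fill, the appropriate tool for them.
#'
#' @param name identifier, unique within a registry.
#' @param superpathway,subpathway biochemical annotation labels.
#' @param xenobiotic logical flag.
#' @param detection_limit_quantile censoring quantile in `[0, 0.95]`
#'   (xenobiotics only).
#' @param missing_rate marginal missingness proportion in `[0, 0.95]`
#'   (non-xenobiotics only).
#' @param missingness_covariate_slope log-odds shift of missingness per SD of
#'   age (non-xenobiotics only).
#' @return A list of class `metabolite_spec`.
#' @export
metabolite_spec <- function(name, superpathway, subpathway,
                            xenobiotic = FALSE,
                            detection_limit_quantile = 0.2,
                            missing_rate = 0.1,
                            missingness_covariate_slope = 0.5) {
  if (xenobiotic) {
    if (detection_limit_quantile < 0 || detection_limit_quantile > 0.95)
      stop("detection_limit_quantile must lie in [0, 0.95]")
  } else {
    if (missing_rate < 0 || missing_rate > 0.95)
      stop("missing_rate must lie in [0, 0.95]")
  }
  structure(list(name = name, superpathway = superpathway,
                 subpathway = subpathway, xenobiotic = isTRUE(xenobiotic),
                 detection_limit_quantile = detection_limit_quantile,
                 missing_rate = missing_rate,
                 missingness_covariate_slope = missingness_covariate_slope),
            class = "metabolite_spec")
}

#' Plant a phenotype -> metabolite effect
#'
#' Linear effects add `slope * (x - mean(x))` to the metabolite's
#' standard-normal latent, so the planted slope is in metabolite SD per unit
#' exposure. Circular effects add a sinusoid
#' `amplitude * cos(angle - acrophase)` of the phenotype's clock angle.
#'
#' @param phenotype,metabolite identifiers matching the registries.
#' @param slope linear effect size (continuous/binary phenotypes).
#' @param amplitude,acrophase sinusoid parameters (circular phenotypes);
#'   `amplitude >= 0`, `acrophase` in `[0, 2*pi)`.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(phenotype, metabolite, slope = NULL,
                        amplitude = NULL, acrophase = 0) {
  if (is.null(slope) == is.null(amplitude))
    stop("give exactly one of slope (linear) or amplitude (circular)")
  if (!is.null(amplitude)) {
    if (amplitude < 0) stop("amplitude must be nonnegative")
    if (acrophase < 0 || acrophase >= 2 * pi)
      stop("acrophase must lie in [0, 2*pi)")
  }
  structure(list(phenotype = phenotype, metabolite = metabolite,
                 type = if (is.null(slope)) "circular_sinusoid" else "linear_slope",
                 slope = slope, amplitude = amplitude, acrophase = acrophase),
            class = "effect_spec")
}

#' Draw clock times from a wrapped (von Mises) distribution
#'
#' Best-Fisher rejection sampling on the circle, mapped to decimal hours in
#' `[0, 24)`. Zero concentration gives uniform clock times.
#'
#' @param mean_time mean clock time in decimal hours.
#' @param concentration von Mises concentration parameter, `>= 0`.
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return Numeric vector of `n` clock times in `[0, 24)`.
#' @export
draw_clock_times <- function(mean_time, concentration, n, seed = NULL) {
  if (concentration < 0) stop("concentration must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  mu <- 2 * pi * (mean_time %% 24) / 24
  theta <- if (concentration == 0) {
    stats::runif(n, 0, 2 * pi)
  } else {
    rvonmises(n, mu, concentration)
  }
  (theta %% (2 * pi)) * 24 / (2 * pi)
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution.
rvonmises <- function(n, mu, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling(1.5 * (n - length(out))))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3 - 0.5) * acos(pmax(pmin(f, 1), -1))
    out <- c(out, (theta[ok] + mu) %% (2 * pi))
  }
  out[seq_len(n)]
}

#' Default sleep phenotype registry
#'
#' Ten phenotypes spanning the five domains: self-reported sleep duration,
#' heart rate during sleep, insomnia symptoms, sleep-disordered breathing and
#' sleep timing, mixing continuous, binary and circular scales.
#'
#' @return A list of [phenotype_spec()] objects.
#' @export
default_phenotypes <- function() {
  list(
    phenotype_spec("slp_duration", "Duration", "continuous", mean = 7.5, sd = 1.2),
    phenotype_spec("short_sleep", "Duration", "binary", prevalence = 0.25),
    phenotype_spec("hr_mean_sleep", "HR", "continuous", mean = 62, sd = 8),
    phenotype_spec("hr_sd_sleep", "HR", "continuous", mean = 5, sd = 2),
    phenotype_spec("whiirs", "Insomnia", "continuous", mean = 6, sd = 4),
    phenotype_spec("sleeping_pills", "Insomnia", "binary", prevalence = 0.1),
    phenotype_spec("rei", "SDB", "continuous", mean = 8, sd = 6),
    phenotype_spec("snoring", "SDB", "binary", prevalence = 0.35),
    phenotype_spec("bedtime", "Timing", "circular", mean_time = 23.25,
                   concentration = 8),
    phenotype_spec("sleep_midpoint", "Timing", "circular", mean_time = 3.2,
                   concentration = 8))
}

#' Default metabolite registry
#'
#' Metabolites spread over eight superpathways with two or three subpathways
#' each; a fixed fraction is flagged xenobiotic (superpathway
#' "Xenobiotics") and left-censored, the rest get covariate-dependent
#' missingness.
#'
#' @param n_metabolites total number of metabolites.
#' @param frac_xenobiotic fraction flagged xenobiotic.
#' @param seed seed controlling annotation assignment and missingness rates.
#' @return A list of [metabolite_spec()] objects.
#' @export
default_metabolites <- function(n_metabolites = 40, frac_xenobiotic = 0.15,
                                seed = 11) {
  set.seed(seed)
  supers <- c("Lipid", "Amino Acid", "Carbohydrate", "Cofactors and Vitamins",
              "Energy", "Nucleotide", "Peptide")
  n_x <- round(frac_xenobiotic * n_metabolites)
  out <- vector("list", n_metabolites)
  for (i in seq_len(n_metabolites)) {
    nm <- sprintf("met_%03d", i)
    if (i <= n_x) {
      out[[i]] <- metabolite_spec(
        nm, "Xenobiotics", paste0("Xenobiotics sub", 1 + i %% 3),
        xenobiotic = TRUE,
        detection_limit_quantile = stats::runif(1, 0.05, 0.4))
    } else {
      sp <- sample(supers, 1)
      out[[i]] <- metabolite_spec(
        nm, sp, paste0(sp, " sub", sample(3, 1)),
        missing_rate = stats::runif(1, 0, 0.25),
        missingness_covariate_slope = 0.5)
    }
  }
  out
}

#' Generate a synthetic cohort with planted effects
#'
#' Draws the full data a metabolome-wide sleep association analysis consumes:
#' a subject table with design columns (stratum, PSU, weight, batch), Model 1
#' covariates (age, sex, center, background, BMI), Model 2 additions
#' (alcohol, smoking, physical activity, diet score) and all phenotypes; a
#' batched metabolite abundance matrix with the declared missingness
#' mechanisms applied; the annotation table; and the truth table of planted
#' effects. Metabolite values arise as standard-normal latents plus planted
#' effects, exponentiated to a positive abundance scale before
#' censoring/missingness.
#'
#' @param config a [cohort_config()].
#' @param phenotypes list of [phenotype_spec()]; defaults to
#'   [default_phenotypes()].
#' @param metabolites list of [metabolite_spec()]; defaults to
#'   [default_metabolites()].
#' @param effects list of [effect_spec()] (possibly empty).
#' @return A list of class `sleep_cohort` with elements `subjects`,
#'   `metabolites` (abundances with NAs), `annotation`, `truth`, `latent`
#'   (the pre-censoring latent matrix, kept for generator diagnostics) and
#'   `config`.
#' @export
generate_cohort <- function(config, phenotypes = default_phenotypes(),
                            metabolites = default_metabolites(),
                            effects = list()) {
  stopifnot(inherits(config, "cohort_config"))
  ph_names <- vapply(phenotypes, `[[`, "", "name")
  met_names <- vapply(metabolites, `[[`, "", "name")
  if (anyDuplicated(ph_names) || anyDuplicated(met_names))
    stop("phenotype and metabolite names must be unique")
  for (ef in effects) {
    if (!ef$phenotype %in% ph_names)
      stop("effect references unknown phenotype: ", ef$phenotype)
    if (!ef$metabolite %in% met_names)
      stop("effect references unknown metabolite: ", ef$metabolite)
    sc <- phenotypes[[match(ef$phenotype, ph_names)]]$scale
    if (ef$type == "circular_sinusoid" && sc != "circular")
      stop("circular_sinusoid effect on non-circular phenotype ", ef$phenotype)
    if (ef$type == "linear_slope" && sc == "circular")
      stop("linear_slope effect on circular phenotype ", ef$phenotype)
  }
  set.seed(config$seed)
  n <- config$n_subjects

  # --- design: round-robin PSU fill guarantees every PSU is populated
  stratum <- sort(rep_len(seq_len(config$n_strata), n))
  psu <- integer(n)
  for (h in seq_len(config$n_strata)) {
    idx <- which(stratum == h)
    psu[idx] <- (h - 1) * config$psus_per_stratum +
      rep_len(seq_len(config$psus_per_stratum), length(idx))
  }
  batch <- sample(1:2, n, replace = TRUE, prob = config$batch_fractions)

  # --- covariates
  age <- pmin(pmax(stats::rnorm(n, 45, 12), 18), 75) +
    ifelse(batch == 2, config$batch_age_shift, 0)
  u <- stats::plogis(config$weight_age_corr * as.numeric(scale(age)) +
                       stats::rnorm(n))
  weight <- config$weight_range[1] + diff(config$weight_range) * u
  subjects <- data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    stratum = stratum, psu = psu, weight = weight, batch = batch,
    age = age,
    sex = sample(c("Female", "Male"), n, TRUE, prob = c(0.52, 0.48)),
    center = sample(paste0("center_", 1:4), n, TRUE),
    background = sample(paste0("bg_", 1:6), n, TRUE,
                        prob = c(0.35, 0.2, 0.15, 0.12, 0.1, 0.08)),
    bmi = pmin(pmax(stats::rnorm(n, 29.5, 5.5), 16), 55),
    alcohol = sample(c("never", "former", "current"), n, TRUE,
                     prob = c(0.4, 0.3, 0.3)),
    smoking = sample(c("never", "former", "current"), n, TRUE,
                     prob = c(0.6, 0.2, 0.2)),
    physical_activity = exp(stats::rnorm(n, log(600), 0.8)),
    diet_score = stats::rnorm(n, 47.5, 7.5),
    stringsAsFactors = FALSE)

  # --- phenotypes (continuous share an optional exchangeable correlation)
  rho <- config$phenotype_corr
  common <- stats::rnorm(n)
  for (ph in phenotypes) {
    val <- switch(ph$scale,
      continuous = {
        z <- sqrt(rho) * common + sqrt(1 - rho) * stats::rnorm(n)
        ph$mean + ph$sd * z
      },
      binary = stats::rbinom(n, 1, ph$prevalence),
      circular = draw_clock_times(ph$mean_time, ph$concentration, n))
    subjects[[ph$name]] <- val
  }

  # --- metabolite latents + planted effects
  M <- length(metabolites)
  Z <- matrix(stats::rnorm(n * M), n, M, dimnames = list(NULL, met_names))
  for (ef in effects) {
    x <- subjects[[ef$phenotype]]
    if (ef$type == "linear_slope") {
      Z[, ef$metabolite] <- Z[, ef$metabolite] + ef$slope * (x - mean(x))
    } else {
      ang <- 2 * pi * x / 24
      Z[, ef$metabolite] <- Z[, ef$metabolite] +
        ef$amplitude * cos(ang - ef$acrophase)
    }
  }
  abund <- exp(Z)

  # --- missingness
  age_z <- as.numeric(scale(age))
  for (j in seq_len(M)) {
    sp <- metabolites[[j]]
    if (sp$xenobiotic) {
      if (sp$detection_limit_quantile > 0) {
        for (b in 1:2) {
          idx <- which(batch == b)
          thr <- stats::quantile(abund[idx, j], sp$detection_limit_quantile,
                                 names = FALSE)
          abund[idx[abund[idx, j] < thr], j] <- NA
        }
      }
    } else if (sp$missing_rate > 0) {
      pm <- stats::plogis(stats::qlogis(sp$missing_rate) +
                            sp$missingness_covariate_slope * age_z)
      abund[stats::runif(n) < pm, j] <- NA
    }
  }

  met_tab <- data.frame(subject_id = subjects$subject_id, batch = batch,
                        abund, stringsAsFactors = FALSE,
                        check.names = FALSE)
  annotation <- data.frame(
    metabolite = met_names,
    superpathway = vapply(metabolites, `[[`, "", "superpathway"),
    subpathway = vapply(metabolites, `[[`, "", "subpathway"),
    xenobiotic = vapply(metabolites, `[[`, TRUE, "xenobiotic"),
    stringsAsFactors = FALSE)
  truth <- if (length(effects)) {
    data.frame(
      phenotype = vapply(effects, `[[`, "", "phenotype"),
      metabolite = vapply(effects, `[[`, "", "metabolite"),
      effect_type = vapply(effects, `[[`, "", "type"),
      size = vapply(effects, function(e)
        if (e$type == "linear_slope") e$slope else e$amplitude, 0),
      acrophase = vapply(effects, function(e)
        if (e$type == "circular_sinusoid") e$acrophase else NA_real_, 0),
      stringsAsFactors = FALSE)
  } else {
    data.frame(phenotype = character(), metabolite = character(),
               effect_type = character(), size = numeric(),
               acrophase = numeric())
  }
  phen_registry <- data.frame(
    name = ph_names,
    domain = vapply(phenotypes, `[[`, "", "domain"),
    scale = vapply(phenotypes, `[[`, "", "scale"),
    stringsAsFactors = FALSE)
  structure(list(subjects = subjects, metabolites = met_tab,
                 annotation = annotation, truth = truth, latent = Z,
                 phenotypes = phen_registry, config = config),
            class = "sleep_cohort")
}

#' Write a synthetic cohort to tab-delimited files
#'
#' Writes `subjects.tsv`, `metabolites.tsv`, `annotation.tsv`,
#' `truth.tsv` and `phenotypes.tsv` under `dir`.
#'
#' @param cohort a `sleep_cohort` from [generate_cohort()].
#' @param dir output directory, created if needed.
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sleep_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  parts <- c("subjects", "metabolites", "annotation", "truth", "phenotypes")
  paths <- file.path(dir, paste0(parts, ".tsv"))
  names(paths) <- parts
  utils::write.table(cohort$subjects, paths["subjects"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$metabolites, paths["metabolites"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$annotation, paths["annotation"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$truth, paths["truth"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$phenotypes, paths["phenotypes"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}
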