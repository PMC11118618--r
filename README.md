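# sleepmwas

Metabolome-wide association atlases for sleep phenotypes in complex survey
samples.

Sleep health is multidimensional: sleep-disordered breathing, duration,
timing, insomnia symptoms and heart rate during sleep each capture a
different facet, and their metabolic correlates overlap only partially.
`sleepmwas` implements the full analysis chain for building an *atlas* of
sleep phenotype × metabolite associations from untargeted metabolomics
measured in a stratified, clustered, unequal-probability sample — the
setting of large population cohorts — together with a seeded synthetic
cohort generator that makes every statistical property of the pipeline
testable against planted truth.

It is aimed at biostatisticians and epidemiologists running
metabolome-wide association studies (MWAS) where

- metabolites were profiled in **batches** with differing cohort
  composition and left-censored or covariate-dependent missingness,
- phenotypes mix **continuous, binary and circular (clock-time)** scales,
- inference must respect a **survey design** (strata, PSUs, weights).

## The statistical core

**Preprocessing.** Metabolites missing in more than 75% of either batch are
excluded. Xenobiotic metabolites (missing = below detection limit) are
completed per batch with half the minimum observed value. The rest are
multiply imputed (m = 5) by fully conditional specification with
predictive-mean matching, then every metabolite is rank-based
inverse-normal transformed within batch and imputation, and batches are
aggregated imputation-wise.

**Association.** For each phenotype × metabolite × model, the metabolite
(outcome) is regressed on the phenotype with survey-weighted least squares;
the coefficient covariance is the Taylor-linearization (sandwich) estimator
over stratum-centered PSU score totals, with design degrees of freedom
`#PSU − #strata`. Two nested covariate sets are fitted: Model 1 (batch,
age, sex, center, background, BMI) and Model 2 (+ alcohol, smoking,
physical activity, diet score). Results are pooled across imputations:

- linear/binary phenotypes — Rubin's rules,
  `T = W̄ + (1 + 1/m) B`, t reference with Barnard–Rubin df;
- circular phenotypes — encoded as `(sin θ, cos θ)` with midnight ↦ 0,
  tested by a 2-df design-based Wald F, and the m p-values combined with
  the aggregated Cauchy association test (ACAT):
  `T = Σ wᵢ tan((½ − pᵢ)π)`, `p = ½ − arctan(T)/π`.

Benjamini–Hochberg FDR is applied within each phenotype across all
metabolites and both models jointly; `p_FDR < 0.05` under Model 1 declares
significance.

**Atlas summaries.** Per-phenotype counts, top-10%-connected metabolites,
and Dice similarity `DSC = 2|X∩Y| / (|X|+|Y|)` between the significance
sets of phenotype domains.

**Bipartite network.** The significant pairs form a bipartite incidence
matrix, consolidated to domains × subpathways with a weight matrix of
association counts. Reported structural metrics: connectance (links over
possible links), NODF nestedness and a rank-based weighted variant, Barber
bipartite modularity Q maximized by seeded label switching, and a
Fruchterman–Reingold layout for plotting.

## Worked example

```r
library(sleepmwas)

cfg <- cohort_config(n_subjects = 600, n_strata = 8,
                     psus_per_stratum = 6, seed = 42)
effects <- list(
  effect_spec("slp_duration",  "met_010", slope = 0.4),
  effect_spec("hr_mean_sleep", "met_012", slope = 0.05),
  effect_spec("bedtime",       "met_015", amplitude = 1.0, acrophase = 4.5))
cohort <- generate_cohort(cfg, default_phenotypes(),
                          default_metabolites(20), effects)
run <- atlas_run(cohort, list(seed = 42, m = 5, n_iter = 3))
subset(run$results, significant)[, c("phenotype", "metabolite", "model",
                                     "effect", "p_raw", "p_fdr")]
```

```
        phenotype metabolite  model effect    p_raw    p_fdr
10   slp_duration    met_010 Model1 0.3171 3.16e-09 6.33e-08
92  hr_mean_sleep    met_012 Model1 0.0486 4.25e-10 1.70e-08
335       bedtime    met_015 Model1     NA 1.35e-08 5.41e-07
```

All three planted effects — and nothing else — are recovered at FDR < 0.05.
The pooled `effect` for `slp_duration` (0.32 SD per hour) is the planted
0.4 attenuated by the rank normalization of a latent whose variance the
planted signal itself inflates; circular tests report no single
coefficient (the sine/cosine pair is tested jointly), hence `NA`. The run
object also carries per-domain counts, the Dice matrix, and the network
report:

```r
m <- run$network$report$All
sprintf("links/node %.2f | connectance %.2f | Q %.2f",
        m$links_per_node, m$cluster_coefficient, m$modularity_Q)
#> "links/node 0.50 | connectance 0.33 | Q 0.67"
```

A thin command-line wrapper over the same functions lives at
`inst/cli/sleepmwas.R` (`simulate` and `run-all` subcommands driven by a
YAML config).

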