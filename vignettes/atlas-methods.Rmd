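---
title: "Methods behind the sleep-metabolite association atlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the sleep-metabolite association atlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepmwas)
```

## Scope and model

`sleepmwas` estimates, for every (sleep phenotype, metabolite, model)
triple, a design-based association in a stratified two-stage sample, and
condenses the resulting atlas into significance counts, domain overlap
(Dice) and bipartite-network structure. The metabolite — rank-based
inverse-normal transformed, hence approximately standard normal — is
always the outcome; the phenotype is the exposure. Binary phenotypes enter
as 0/1 predictors of the Gaussian outcome, so no logistic machinery is
needed anywhere.

### Survey-weighted regression

For response $y$ and design matrix $X$ with per-subject weights $w_i$,
coefficients solve the weighted normal equations. The covariance is the
Taylor-linearization estimator: per-PSU totals of the score $w_i x_i e_i$
are centered within stratum, their outer products scaled by
$n_h/(n_h-1)$ and summed, then pre- and post-multiplied by
$(X'WX)^{-1}$. Design degrees of freedom are `#PSU − #strata`. Assumptions
and conventions:

* sampling is treated as with replacement at the PSU stage; no
  finite-population correction (sampling fractions are rarely published
  and the correction is conservative to omit);
* every stratum must contribute ≥ 2 PSUs; a lonely PSU is a hard error
  rather than a silent grand-mean fixup, because synthetic designs can
  always satisfy the requirement and silent fixes hide real subsetting
  problems;
* the multivariate Wald statistic for a coefficient subset $S$ is
  $F = \beta_S' V_S^{-1} \beta_S / q$ on $(q,\; \mathrm{df} - q + 1)$
  degrees of freedom — the usual design-based convention; for $q = 1$ it
  reduces exactly to the design-df t-test.

### Circular exposures

Clock times map to angles with midnight at zero,
$\theta = 2\pi\,\text{hours}/24$, and the pair $(\sin\theta, \cos\theta)$
enters the regression; a 2-df Wald test assesses the joint association.
The sine/cosine span is rotation invariant, so the test does not depend on
the (arbitrary) choice of time origin — a property the tests assert to
$10^{-8}$. Because the covariance between the sine and cosine coefficients
cannot be pooled across imputations, the circular path pools *p-values*
with ACAT (equal weights) instead of pooling coefficients.

### Pooling across imputations

Linear phenotypes use Rubin's rules with between-imputation variance $B$,
within $\bar W$, total $T = \bar W + (1 + 1/m)B$, and the Barnard–Rubin
small-sample degrees of freedom capped at the design df. Xenobiotic
metabolites are imputed once (their missingness is a detection limit, not
a stochastic process worth multiple imputation), so they take the
single-dataset result; inside the scan they behave as $m$ identical
copies.

ACAT clamps p-values to $[10^{-15}, 1-10^{-15}]$ and switches to the
asymptote $1/(p\pi)$ below the lower clamp — the standard numerical guard
for the Cauchy tangent transform.

### Multiple testing

Benjamini–Hochberg is applied within each phenotype across all metabolites
and **both** models jointly (the per-model alternative is available behind
`fdr_group = "per_model"`). Significance is declared only on Model 1 at
FDR < 0.05; Model 2 exists to probe robustness to lifestyle adjustment,
not to generate headlines.

## Preprocessing pipeline

Order is fixed: missingness filter (strictly more than 75% missing in
either batch excludes a metabolite) → per-batch half-minimum fill for
xenobiotics → per-batch fully conditional multiple imputation for the rest
→ rank-based inverse-normal transform within batch and imputation →
imputation-wise batch aggregation. Feeding already-processed (hence
negative-valued) data back into the pipeline raises immediately: the
stages are not idempotent and pretending otherwise invites silent
double-transformation.

Numerical and tuning choices:

* **Rank-normal offset** c = 3/8 (Blom), configurable; ties share average
  ranks. The transform maps every untied vector of length $n$ to the same
  quantile grid, which the tests exploit as an exact invariant.
* **FCS/PMM**: 10 sweeps by default (2 in the test fixtures, where the
  predictor set makes convergence immediate), donor pool k = 5,
  ridge-stabilized Bayesian regression draws, type-1 matching (posterior
  draw predictions for missing rows matched against least-squares
  predictions for observed rows). Every imputed value is an observed value
  of its variable — the defining PMM property, asserted directly.
* **Imputation covariates** are passed explicitly (defaults:
  age, sex, BMI, physical activity, diet score) rather than hard-coded,
  because real-data runs will have a richer metabolic-environment panel.
  Covariates must be complete; a covariate with missing values is a
  configuration error, not something to impute silently.

## The synthetic cohort generator

The generator is the package's test bed: it draws a stratified two-stage
sample with unequal weights (optionally correlated with age, making the
design informative), two metabolomics batches with a configurable age
shift (batch 2 older by default), five phenotype domains mixing
continuous, binary and circular scales, and metabolites whose missingness
is left-censoring for xenobiotics (lowest quantile removed per batch) or
age-dependent MAR for the rest — the two mechanisms that justify
half-minimum fills and multiple imputation respectively.

Planted effects add `slope · (x − x̄)` (linear) or
`amplitude · cos(θ − acrophase)` (circular) to a standard-normal latent,
which is exponentiated to a positive abundance scale before censoring.
Because downstream rank normalization only sees ranks, the marginal
abundance shape is irrelevant; positivity is what makes half-minimum fills
meaningful. A planted linear slope $s$ on the latent reappears after rank
normalization as approximately $s/\sqrt{1 + s^2\,\mathrm{var}(x)}$ — the
signal inflates the latent's variance, and the transform rescales to unit
SD; recovery tests target that attenuated value.

Deliberate simplifications (what passing tests do *not* show about real
data): no batch drift in abundances beyond cohort composition, no
metabolite-metabolite biochemical correlation beyond an optional
exchangeable phenotype correlation, covariate distributions are invented
(only their correlation structure with weights, batches and missingness
matters), and clock times are von Mises draws — a single-mode idealization
of real bedtime distributions. Default circular concentration is 8
(circular SD ≈ 1.3 h), matching typical population bedtime spread.

## Calibration experiments and problem sizes

The acceptance tests run the engine at sizes chosen for desk-scale
runtime, stated here as the package's own experimental design:

* **Type-I error** of the design-based Wald test: 2,000 replicates of a
  population of 4,000 with selection probability increasing in the
  response (strongly informative weights), ~700 sampled subjects in 20
  strata × 10 PSUs. Rejection at α = 0.05 must land in [0.035, 0.065].
* **Circular null calibration**: 500 full pipeline runs (n = 600, 10
  strata × 6 PSUs, 15% MAR missingness, m = 5), KS-tested against
  uniformity at α = 0.01.
* **Circular power**: amplitude 0.4 SD at n = 1500, acrophase a quarter
  turn off the mean bedtime direction (an acrophase aligned with the
  population mean direction is nearly unidentifiable when clock times are
  concentrated — the sinusoid is then locally flat), detection required in
  ≥ 80% of 100 replicates.
* **FDR control**: 50 atlases of 4 phenotypes × 20 metabolites at n = 400
  with 10% of pairs carrying strong planted signals; the average false
  discovery proportion among flagged pairs must stay ≤ 0.10.

### A known limitation worth stating plainly

ACAT's validity guarantee under dependence concerns the *tails*: type-I
error at conventional α is controlled for arbitrarily correlated
components. Its null distribution over the whole unit interval, however,
is provably non-uniform when components are correlated but not identical —
exactly the regime multiple imputation creates (the m Wald p-values share
the observed data and differ only through imputation noise). The
mid-range deviation grows as the inter-imputation correlation falls. At
the fixture scale above, a whole-distribution KS check of the combined
null p-value can therefore fail even though the rejection rate at
α = 0.05 is controlled; the corresponding acceptance assertion documents
this rather than hiding it. Separately, the linearization variance is
mildly liberal when the number of PSUs is small relative to the number of
model parameters — the classic survey small-sample effect — which shrinks
as PSUs grow; the type-I experiment therefore uses a PSU-rich design, the
regime the method is built for.

## Network metrics

The consolidated domain × subpathway weight matrix counts significant
pairs per cell (their total is conserved through consolidation, a tested
invariant). Metrics:

* **Connectance / cluster coefficient**: realized links over possible
  links, $L/(R \times C)$.
* **Nestedness**: NODF — for ordered row (column) pairs with strictly
  decreasing marginal totals, the percentage of the sparser node's links
  contained in the denser node's, averaged over all pairs. 100 = perfect
  staircase; the complementary orientation (0 = highly nested) is reported
  alongside. NODF was chosen over matrix-temperature algorithms because it
  is fully specified, deterministic, and checkable by brute-force pair
  enumeration; the ecology toolkits' temperature measure is
  under-determined for reimplementation.
* **Weighted nestedness**: a rank-based weighted NODF on [0, 1]; a pair
  contributes the fraction of the sparser node's nonzero cells whose
  weights are strictly below the busier node's. Scale-invariant by
  construction; a constant positive matrix scores 0 (no strictly
  dominating pairs), a strict weight staircase scores 1.
* **Modularity**: Barber's bipartite Q,
  $Q = \frac{1}{W}\sum_{ij}(A_{ij} - k_i d_j / W)\,[g_i = g_j]$,
  maximized by label switching from singleton, single-module and random
  initializations with seeded restarts (default 20). On every network with
  ≤ 7 nodes the heuristic matches exhaustive partition search (tested over
  50 random instances); on larger networks restarts make the usual
  local-optimum caveat apply.
* **Layout**: a plain Fruchterman–Reingold embedder (repulsion $k^2/d$,
  attraction $d^2/k$, 200 iterations, linear cooling from 0.1,
  $k=\sqrt{1/n}$) — only determinism given the seed and
  connected-closer-than-unconnected proximity are contractual; aesthetics
  are not.

Degenerate inputs follow explicit conventions: Dice of two empty sets is
an error (0/0), a single-node layout sits at the origin, nestedness of a
1×1 matrix is an error, and an all-equal positive weight matrix has
weighted nestedness 0, not an error.

## Reproducibility

Every stochastic stage takes an explicit seed; `atlas_run` fans one seed
into per-stage substreams so stages can be rerun independently. Identical
seeds give bit-identical subject tables, imputations, association tables
and layouts — asserted down to file hashes in the tests.
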