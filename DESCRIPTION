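Package: sleepmwas
Title: Sleep Phenotype x Metabolite Association Atlas with Design-Based
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds metabolome-wide association atlases relating sleep
    phenotypes (continuous, binary, and circular clock-time exposures) to
    metabolite levels in complex survey samples. Implements batch-aware
    missingness filtering, half-minimum imputation for left-censored
    xenobiotics, fully conditional multiple imputation by predictive mean
    matching, per-batch rank-based inverse normal transformation,
    survey-weighted linear regression with stratified-cluster Taylor
    linearized variance and design degrees of freedom, multivariate Wald
    tests for sine/cosine encoded circular exposures, pooling across
    imputations by Rubin's rules or the aggregated Cauchy association test
    (ACAT), Benjamini-Hochberg false discovery rate control per phenotype,
    Dice similarity between phenotype-domain significance sets, and
    bipartite network summaries (connectance, NODF nestedness, weighted
    nestedness, Barber modularity, force-directed layout). A seeded
    synthetic-cohort generator with planted effects supports calibration
    and recovery testing throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
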