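Package: cordsig
Title: Cross-Cohort Meta-Analysis and Replication of Perinatal Asthma-Risk
    Gene Expression Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery pipeline for cord-blood gene expression signatures of
    childhood asthma risk. Combines per-gene standardized effects across
    heterogeneous microarray cohorts with DerSimonian-Laird random-effects
    meta-analysis, pools the four risk-factor z-scores (newborn sex,
    gestational age, birthweight, maternal pre-pregnancy BMI) into a single
    risk-oriented score, runs pre-ranked weighted Kolmogorov-Smirnov gene-set
    enrichment with permutation significance, replicates the signature in an
    independent RNA-seq cohort through negative-binomial risk-factor-count
    models and a replication score, summarises replicating genes as a
    principal-component signature, and associates serum protein levels with
    asthma and lung-function outcomes under covariate-adjusted models with
    relative-importance decomposition. Includes simulators with planted
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    fgsea,
    jsonlite
Config/testthat/edition: 3
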