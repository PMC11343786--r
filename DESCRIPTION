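Package: gdmclust
Title: Data-Driven Subtyping of Gestational Diabetes from Routine Clinical Variables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and validates subgroups of gestational diabetes
    mellitus (GDM) by unsupervised clustering of five routine clinical
    variables: maternal age, pre-pregnancy BMI and the three glucose values
    of the diagnostic 75 g OGTT (fasting, 60 and 120 min).  Provides a
    calibrated synthetic-cohort generator with latent subgroups matched to
    published quartile profiles, train/test partitioning and standardisation,
    k-means/k-medoids/hierarchical candidate models, selection of the number
    of clusters (gap statistic, silhouette maximisation, multi-index majority
    vote, elbow), internal validation gates (clusterwise bootstrap Jaccard
    stability, non-negative mean silhouette, across-cluster significance of
    every input variable), twofold cross-validation, centroid-transfer
    external validation with optimal cluster matching, cluster-wise outcome
    comparison (ANOVA with Fisher's protected LSD, Kruskal-Wallis with Dunn
    post hoc tests, chi-square/Fisher tests, logistic regression with
    likelihood-ratio tests and pairwise odds ratios), and nearest-centroid
    assignment of new patients from a portable JSON model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    clue,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
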