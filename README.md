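# gdmclust

Data-driven subtyping of gestational diabetes mellitus (GDM) from five
routine clinical variables, with the full validation machinery needed to
trust — or reject — a clustering solution.

## The problem

GDM is diagnosed by uniform OGTT thresholds (IADPSG: fasting ≥ 5.1,
60 min ≥ 10, 120 min ≥ 8.5 mmol/l) but is clinically heterogeneous: some
women need basal insulin for fasting hyperglycaemia, others rapid-acting
insulin for post-load excursions, many need no medication at all.
`gdmclust` is for biostatisticians and clinical researchers who want to
discover, validate and deploy GDM subgroups from variables every clinic
already records: maternal age, pre-pregnancy BMI (BMIPG), and OGTT glucose
at 0/60/120 min (OGTT0/OGTT60/OGTT120).

## What it implements

For a standardised input matrix `Z` (z-scores with training-set means and
SDs), the pipeline evaluates k-means, k-medoids (PAM) and agglomerative
hierarchical candidates, chooses the number of clusters k by four methods
(gap statistic `Gap(k) = E*[log W_ref] − log W_k` with the 1-SE rule,
silhouette maximisation, a 7-index majority vote with a runner-up escape
hatch, WCSS elbow), and accepts a solution only if it passes three gates:

1. clusterwise bootstrap Jaccard stability `J = |A∩B| / |A∪B| > 0.75`;
2. non-negative mean silhouette `s(i) = (b−a)/max(a,b)` per cluster;
3. every input variable significantly different across clusters (p < 0.05,
   Shapiro–Wilk-routed ANOVA/Kruskal–Wallis).

Accepted models are validated by twofold cross-validation (input
similarity, result similarity, outcome-significance consistency) and by
centroid transfer to test sets, where the estimated partition Ĉ_test
(nearest centroid, training scaler) is compared against the reference
C_test (refit on the test set) via optimally matched per-cluster Jaccard
indices, the adjusted Rand index and one-vs-rest classification metrics.
Clinical outcomes are compared across clusters exactly as an explorative
clinical analysis would: protected post hoc tests, χ²/Fisher switching at
expected counts of 5, logistic likelihood-ratio tests with pairwise odds
ratios, no multiplicity adjustment by default.

Because the underlying cohorts are not publicly deposited, the package
ships a first-class synthetic-cohort generator whose subgroup marginals
are quartile-calibrated (exact shifted-log-normal/normal fits to
median-and-IQR summaries), constrained to the IADPSG criterion with
bias-compensated rejection sampling, and carrying subgroup-conditional
outcome rates and missingness.

## Worked example

```r
library(gdmclust)

cohort <- generate_cohort(default_cohort_config(), n = 1649, seed = 42)
sp  <- split_train_test(cohort, 0.7, seed = 42)   # 1154 / 495
fit <- fit_cohort_clusters(sp$train, k = 3, seed = 42)
fit$model
#> <gdm_cluster_model> kmeans, k = 3, distance = euclidean
#>   centroids (clinical units):
#>     age bmipg ogtt0 ogtt60 ogtt120
#> 1 32.69 36.90  6.36  12.22    9.67
#> 2 31.55 27.64  5.51   8.14    6.10
#> 3 34.68 25.10  5.01  10.61    8.26

ev <- external_validate(fit$model, sp$test, seed = 42)
ev
#> <gdm_external_validation>
#>   per-cluster Jaccard: 0.747 / 0.847 / 0.824
#>   ARI = 0.719, accuracy = 90.1%
#>   cluster-proportion chi-square p = 0.887

assign_patient(fit$model, c(age = 34, bmipg = 32.3, ogtt0 = 5.99,
                            ogtt60 = 11.6, ogtt120 = 8.66))
#> $cluster
#> [1] 1
#> $distances
#> [1] 0.9467359 2.2316380 1.5047946
```

Cluster 1 is the obese subgroup with globally elevated glucose, cluster 2
the elevated-fasting subgroup, cluster 3 the lean post-load subgroup —
labels are renumbered canonically (descending fasting-glucose centroid) so
they are comparable across fits, folds and sites.  The external-validation
block says that nearest-centroid transfer to the held-out 30% agrees
strongly with a fresh refit on that set (per-cluster Jaccard 0.75–0.85,
accuracy 90%), and that cluster proportions do not differ from training
(χ² p = 0.89).  The `assign_patient` call places a patient with the
cluster-1 median profile into cluster 1, returning all standardised
centroid distances for transparency.

The gated, fully automatic route is
`run_end_to_end(seed = 1)`, which simulates, splits, selects k, checks all
gates, cross-validates, transfers to the held-out set and summarises
outcomes, returning a single bundle with a reproducibility manifest.  A
thin CLI over the same functions is installed at
`inst/cli/gdmclust.R` (`simulate`, `split`, `fit`, `validate`, `outcomes`,
`assign`, `run-all`).

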