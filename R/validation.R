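# Internal validation (clusterwise bootstrap Jaccard stability, twofold
# cross-validation) and external validation (centroid transfer versus a
# reference refit on the test set), with optimal cluster matching and
# partition-agreement metrics.

# Fit the configured algorithm on an already-standardised matrix and return
# canonical labels only (used by bootstrap and refit routines).
fit_labels_on_matrix <- function(X, k, algorithm = "kmeans",
                                 distance = "euclidean",
                                 linkage = "ward.D2", n_starts = 25,
                                 seed = NULL) {
  fit <- switch(algorithm,
    kmeans = kmeans_fit(X, k, n_starts = n_starts, seed = seed),
    kmedoids = kmedoids_fit(X, k, distance = distance, seed = seed),
    hierarchical = hierarchical_fit(X, k, distance = distance,
                                    linkage = linkage),
    stop_invalid("unknown algorithm: ", algorithm))
  fit$partition$labels
}

#' Per-cluster Jaccard index between two partitions
#'
#' `J(A_c, B_m(c)) = |A_c intersect B_m(c)| / |A_c union B_m(c)|` over the
#' common row universe, for each cluster `c` of the reference partition and
#' its mapped counterpart.
#'
#' @param labels_ref,labels_est Integer label vectors over the same rows.
#' @param mapping Integer vector: `mapping[c]` is the cluster of
#'   `labels_est` matched to reference cluster `c` (default identity).
#' @return Numeric vector of Jaccard indices in \[0, 1\]; an empty union
#'   yields 0 with a warning.
#' @export
jaccard_per_cluster <- function(labels_ref, labels_est,
                                mapping = seq_len(max(labels_ref))) {
  stopifnot(length(labels_ref) == length(labels_est))
  k <- length(mapping)
  vapply(seq_len(k), function(c) {
    a <- labels_ref == c
    b <- labels_est == mapping[c]
    uni <- sum(a | b)
    if (uni == 0) {
      warning("empty cluster pair (", c, "); Jaccard set to 0")
      return(0)
    }
    sum(a & b) / uni
  }, numeric(1))
}

#' Optimal bijective matching between two partitions' clusters
#'
#' Solves the assignment problem (Hungarian algorithm) on the k x k matrix
#' of pairwise cluster Jaccard indices, maximising the summed Jaccard
#' agreement — so the matched per-cluster Jaccard indices dominate every
#' other bijection.  Both partitions must have the same number of clusters.
#'
#' @param labels_ref,labels_est Integer label vectors over the same rows.
#' @return Integer vector `m` with `m[c]` = cluster of `labels_est` matched
#'   to reference cluster `c`.
#' @export
match_clusters <- function(labels_ref, labels_est) {
  stopifnot(length(labels_ref) == length(labels_est))
  k_ref <- max(labels_ref)
  k_est <- max(labels_est)
  if (k_ref != k_est) {
    stop_invalid("partitions have different numbers of clusters (",
                 k_ref, " vs ", k_est, "); no partial matching is attempted")
  }
  tab <- table(factor(labels_ref, levels = 1:k_ref),
               factor(labels_est, levels = 1:k_est))
  # J(c, j) = n_cj / (n_c. + n_.j - n_cj)
  jac <- tab / (outer(rowSums(tab), colSums(tab), `+`) - tab)
  jac[!is.finite(jac)] <- 0
  as.integer(clue::solve_LSAP(jac, maximum = TRUE))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement under the permutation model,
#' computed from the contingency table; invariant to label permutations and
#' symmetric in its arguments.
#'
#' @param labels_a,labels_b Label vectors over the same rows (n >= 2).
#' @return Numeric value <= 1 (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  n <- length(labels_a)
  if (n < 2) stop_invalid("ARI undefined for n < 2")
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    # degenerate expected index: identical pair structure (e.g. both all
    # singletons, both one cluster) scores 1, anything else 0
    return(if (sum_ij == max_index && sum_a == sum_b) 1 else 0)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' One-vs-rest classification metrics between matched partitions
#'
#' Treats the reference labels as truth and computes, per cluster after
#' mapping, sensitivity, specificity and F1 from the one-vs-rest confusion
#' table, plus the total accuracy (trace of the matched contingency table
#' over n).
#'
#' @inheritParams jaccard_per_cluster
#' @return List with `per_cluster` (data.frame: sensitivity, specificity,
#'   f1) and `accuracy`.
#' @export
classification_metrics <- function(labels_ref, labels_est,
                                   mapping = seq_len(max(labels_ref))) {
  stopifnot(length(labels_ref) == length(labels_est))
  k <- length(mapping)
  est_mapped <- match(labels_est, mapping) # back to reference numbering
  per <- t(vapply(seq_len(k), function(c) {
    tp <- sum(labels_ref == c & est_mapped == c)
    fn <- sum(labels_ref == c & est_mapped != c)
    fp <- sum(labels_ref != c & est_mapped == c)
    tn <- sum(labels_ref != c & est_mapped != c)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
    c(sensitivity = sens, specificity = spec, f1 = f1)
  }, numeric(3)))
  list(per_cluster = as.data.frame(per),
       accuracy = mean(labels_ref == est_mapped, na.rm = FALSE))
}

#' Clusterwise bootstrap stability (Jaccard)
#'
#' Hennig-style scheme: draw `B` nonparametric bootstrap resamples of the
#' rows, refit the configured clustering on each, and match every original
#' cluster to the refit cluster maximising the Jaccard index over the
#' resampled rows.  A cluster is stable when its mean Jaccard across
#' replicates exceeds the threshold (default 0.75).
#'
#' @param X Standardised input matrix.
#' @param k,algorithm,distance,linkage,n_starts Clustering configuration.
#' @param B Number of bootstrap replicates (>= 20).
#' @param threshold Stability gate (mean Jaccard must exceed it).
#' @param labels Optional original labels; refitted on `X` when omitted.
#' @param seed Optional integer seed.
#' @return A list (`gdm_stability` report): `B`, `mean_jaccard` per original
#'   cluster, `threshold`, `pass` flags, and the count of failed refits.
#' @export
bootstrap_stability <- function(X, k, algorithm = "kmeans",
                                distance = "euclidean", linkage = "ward.D2",
                                B = 100, threshold = 0.75, n_starts = 25,
                                labels = NULL, seed = NULL) {
  X <- as.matrix(X)
  if (B < 1) stop_invalid("B must be >= 1")
  n <- nrow(X)
  if (is.null(labels)) {
    labels <- fit_labels_on_matrix(X, k, algorithm, distance, linkage,
                                   n_starts, seed = derive_seed(seed, 0))
  }
  jac <- matrix(NA_real_, B, k)
  failures <- 0L
  local_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      new_labels <- tryCatch(
        fit_labels_on_matrix(X[idx, , drop = FALSE], k, algorithm, distance,
                             linkage, n_starts, seed = NULL),
        error = function(e) NULL)
      if (is.null(new_labels)) {
        failures <- failures + 1L
        next
      }
      orig_on_resample <- labels[idx]
      for (c in seq_len(k)) {
        a <- orig_on_resample == c
        if (!any(a)) next
        jac[b, c] <- max(vapply(seq_len(k), function(j) {
          bset <- new_labels == j
          sum(a & bset) / sum(a | bset)
        }, numeric(1)))
      }
    }
  })
  mean_jac <- colMeans(jac, na.rm = TRUE)
  structure(list(B = B, mean_jaccard = mean_jac, threshold = threshold,
                 pass = mean_jac > threshold, failed_refits = failures,
                 labels = labels),
            class = "gdm_stability")
}

#' @export
print.gdm_stability <- function(x, ...) {
  cat(sprintf("<gdm_stability> B = %d, threshold = %.2f\n", x$B, x$threshold))
  cat(sprintf("  mean Jaccard: %s (%s)\n",
              paste(sprintf("%.3f", x$mean_jaccard), collapse = " / "),
              if (all(x$pass)) "all stable" else "gate fired"))
  invisible(x)
}

#' Twofold cross-validation of a clustering solution
#'
#' Splits the training set into two random halves, fits a "partial model"
#' on each (its own scaler and fit), and compares each to the original model
#' on the half's rows across three aspects:
#' \itemize{
#'   \item input similarity — matched-centroid distances (L2, in the
#'     original standardised space) and scaler deltas;
#'   \item result similarity — ARI and per-cluster sensitivity/specificity/
#'     F1 of the partial labels against the original labels;
#'   \item outcome significance consistency — for each outcome, whether the
#'     omnibus test lands on the same side of `alpha` under the partial
#'     partition as under the original one.
#' }
#'
#' @param train Training cohort `data.frame`.
#' @param model Fitted `gdm_cluster_model` (the original model).
#' @param partition Original `gdm_partition` on `train`.
#' @param outcomes Character vector of outcome columns to re-test (optional).
#' @param alpha Significance level for the consistency flags.
#' @param n_starts,seed Fitting controls.
#' @return A list (`gdm_crossval`) with one report per fold.
#' @export
twofold_crossval <- function(train, model, partition, outcomes = character(0),
                             alpha = 0.05, n_starts = 25, seed = NULL) {
  stopifnot(inherits(model, "gdm_cluster_model"))
  n <- nrow(train)
  k <- model$k
  if (n < 2 * k) stop_invalid("training set too small for twofold cross-validation")
  halves <- local_seed(seed, {
    idx <- sample.int(n, floor(n / 2))
    list(sort(idx), setdiff(seq_len(n), idx))
  })
  folds <- lapply(seq_along(halves), function(h) {
    rows <- halves[[h]]
    half <- train[rows, , drop = FALSE]
    fit <- fit_cohort_clusters(half, k, algorithm = model$algorithm,
                               variable_set_id = model$variable_set %||% "full5",
                               distance = model$distance,
                               linkage = model$linkage,
                               n_starts = n_starts,
                               seed = derive_seed(seed, 20 + h))
    orig_labels <- partition$labels[rows]
    part_labels <- fit$partition$labels
    mapping <- match_clusters(orig_labels, part_labels)
    # centroids of both models expressed in the original standardised space
    part_cent_units <- destandardize(fit$model$centroids, fit$model$scaling)
    part_cent_z <- sweep(sweep(part_cent_units, 2, model$scaling$center), 2,
                         model$scaling$scale, `/`)
    cent_dist <- sqrt(rowSums((model$centroids -
                                 part_cent_z[mapping, , drop = FALSE])^2))
    metrics <- classification_metrics(orig_labels, part_labels, mapping)
    outcome_tab <- NULL
    if (length(outcomes)) {
      outcome_tab <- do.call(rbind, lapply(outcomes, function(o) {
        p_orig <- outcome_omnibus_p(train[[o]], partition$labels)
        mapped <- match(part_labels, mapping)
        p_fold <- outcome_omnibus_p(half[[o]], mapped)
        data.frame(outcome = o, p_original = p_orig, p_fold = p_fold,
                   significant_original = !is.na(p_orig) & p_orig < alpha,
                   significant_fold = !is.na(p_fold) & p_fold < alpha,
                   agree = (!is.na(p_orig) & !is.na(p_fold)) &
                     ((p_orig < alpha) == (p_fold < alpha)))
      }))
    }
    list(rows = rows, mapping = mapping,
         scaler_delta = list(center = fit$model$scaling$center - model$scaling$center,
                             scale = fit$model$scaling$scale / model$scaling$scale),
         centroid_distance = cent_dist,
         ari = adjusted_rand(orig_labels, part_labels),
         metrics = metrics,
         outcome_consistency = outcome_tab)
  })
  structure(list(folds = folds), class = "gdm_crossval")
}

# Omnibus p for an outcome under a partition: binary -> contingency test,
# continuous -> normality-routed ANOVA / Kruskal-Wallis.
outcome_omnibus_p <- function(values, labels) {
  keep <- !is.na(values)
  if (sum(keep) < 3 || length(unique(labels[keep])) < 2) return(NA_real_)
  v <- values[keep]
  l <- labels[keep]
  if (is_binary(v)) {
    tryCatch(contingency_test(v, l)$omnibus_p, error = function(e) NA_real_)
  } else {
    tryCatch(compare_continuous(v, l)$omnibus_p, error = function(e) NA_real_)
  }
}

#' External validation of a fitted model on a test set
#'
#' Computes the estimated test partition (nearest-centroid transfer with the
#' training scaler) and the reference partition (refit of the same
#' algorithm/k on the test set with its own scaler), matches their clusters
#' optimally, and reports per-cluster Jaccard indices, the adjusted Rand
#' index, total accuracy and a chi-square comparison of cluster proportions
#' against the training partition.
#'
#' @param model Fitted `gdm_cluster_model`.
#' @param test Test cohort `data.frame`.
#' @param n_starts,seed Refit controls.
#' @return A list (`gdm_external_validation`) with `estimated`, `reference`
#'   (partitions), `mapping`, `jaccard`, `ari`, `accuracy`,
#'   `proportion_chisq_p` and `metrics`; when the refit fails the report
#'   carries the transfer results only, with `refit_failed = TRUE`.
#' @export
external_validate <- function(model, test, n_starts = 25, seed = NULL) {
  stopifnot(inherits(model, "gdm_cluster_model"))
  est <- assign_nearest_centroid(model, test)
  ref_fit <- tryCatch(
    fit_cohort_clusters(test, model$k, algorithm = model$algorithm,
                        variable_set_id = model$variable_set %||% "full5",
                        distance = model$distance, linkage = model$linkage,
                        n_starts = n_starts, seed = seed),
    error = function(e) NULL)
  prop_p <- tryCatch({
    tab <- rbind(training = model$sizes, test = est$sizes)
    suppressWarnings(chisq.test(tab)$p.value)
  }, error = function(e) NA_real_)
  if (is.null(ref_fit)) {
    return(structure(list(estimated = est, reference = NULL, mapping = NULL,
                          jaccard = NULL, ari = NA_real_,
                          accuracy = NA_real_,
                          proportion_chisq_p = prop_p,
                          refit_failed = TRUE),
                     class = "gdm_external_validation"))
  }
  ref <- ref_fit$partition
  ref$role <- "C_test_reference"
  mapping <- match_clusters(ref$labels, est$labels)
  metrics <- classification_metrics(ref$labels, est$labels, mapping)
  structure(list(
    estimated = est, reference = ref, mapping = mapping,
    jaccard = jaccard_per_cluster(ref$labels, est$labels, mapping),
    ari = adjusted_rand(ref$labels, est$labels),
    accuracy = metrics$accuracy,
    metrics = metrics,
    proportion_chisq_p = prop_p,
    refit_failed = FALSE),
    class = "gdm_external_validation")
}

#' @export
print.gdm_external_validation <- function(x, ...) {
  cat("<gdm_external_validation>\n")
  if (isTRUE(x$refit_failed)) {
    cat("  reference refit failed; transfer-only results\n")
  } else {
    cat(sprintf("  per-cluster Jaccard: %s\n",
                paste(sprintf("%.3f", x$jaccard), collapse = " / ")))
    cat(sprintf("  ARI = %.3f, accuracy = %.1f%%\n", x$ari,
                100 * x$accuracy))
  }
  cat(sprintf("  cluster-proportion chi-square p = %.3g\n",
              x$proportion_chisq_p))
  invisible(x)
}
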