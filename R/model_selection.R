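# Choice of the number of clusters and of the algorithm configuration.
#
# Four k-selection methods are computed on the training matrix: the gap
# statistic (uniform reference in the PCA-aligned bounding box, 1-SE rule),
# silhouette maximisation, a majority vote over seven internal validity
# indices (Calinski-Harabasz, Davies-Bouldin, Dunn, Hartigan, Krzanowski-Lai,
# C-index, silhouette), and the WCSS elbow curve for visual inspection.
# Candidate solutions are then screened by three acceptance gates:
# clusterwise bootstrap Jaccard stability > 0.75, non-negative mean
# silhouette per cluster, and significant across-cluster differences
# (p < 0.05) for every input variable.

kmeans_partition_fun <- function(n_starts) {
  function(x, k) list(cluster = kmeans(x, k, nstart = n_starts,
                                       iter.max = 300)$cluster)
}

#' Gap statistic for the number of clusters
#'
#' `Gap(k) = E*[log(W_ref)] - log(W_obs)` with `B` uniform reference data
#' sets drawn in the PCA-aligned bounding box of `X` and `W` the total
#' within-cluster sum of squared distances; the simulation SE includes the
#' `sqrt(1 + 1/B)` factor.  `k` is selected by the 1-SE rule: the smallest
#' `k` with `Gap(k) >= Gap(k+1) - SE(k+1)`.
#'
#' @param X Standardised input matrix.
#' @param k_range Consecutive candidate values of k starting at 1.
#' @param B Number of reference data sets (>= 10).
#' @param n_starts k-means restarts per fit.
#' @param seed Optional integer seed.
#' @return List with `k` (the selection), `gap`, `se` (per candidate k) and
#'   the underlying `clusGap` table.
#' @export
gap_statistic <- function(X, k_range = 1:8, B = 100, n_starts = 25,
                          seed = NULL) {
  X <- as.matrix(X)
  if (B < 10) stop_invalid("B must be >= 10")
  if (any(apply(X, 2, sd) == 0)) stop_invalid("zero-variance column in X")
  k_max <- max(k_range)
  gs <- local_seed(seed,
    cluster::clusGap(X, FUNcluster = kmeans_partition_fun(n_starts),
                     K.max = k_max, B = B, d.power = 2,
                     spaceH0 = "scaledPCA", verbose = FALSE))
  tab <- gs$Tab[k_range, , drop = FALSE]
  k_gap <- k_range[cluster::maxSE(tab[, "gap"], tab[, "SE.sim"],
                                  method = "Tibs2001SEmax")]
  list(k = k_gap, gap = unname(tab[, "gap"]), se = unname(tab[, "SE.sim"]),
       logW = unname(tab[, "logW"]), k_range = k_range, table = gs$Tab)
}

#' Choose k by silhouette maximisation
#'
#' Fits k-means for each candidate k and returns the k maximising the mean
#' silhouette width (ties to the smaller k).
#'
#' @inheritParams gap_statistic
#' @param k_range Candidate values, all >= 2.
#' @return List with `k` and the `mean_silhouette` curve.
#' @export
silhouette_selection <- function(X, k_range = 2:8, n_starts = 25,
                                 seed = NULL) {
  X <- as.matrix(X)
  if (any(k_range < 2)) stop_invalid("silhouette selection needs k >= 2")
  d <- dist(X)
  ms <- local_seed(seed, vapply(k_range, function(k) {
    labels <- kmeans(X, k, nstart = n_starts, iter.max = 300)$cluster
    mean(silhouette_values(d, labels))
  }, numeric(1)))
  list(k = k_range[which.max(ms)], mean_silhouette = ms, k_range = k_range)
}

#' WCSS curve for the elbow heuristic
#'
#' @inheritParams gap_statistic
#' @return List with `k_range` and `wcss` (total within-cluster sum of
#'   squares per k), for plotting; no automatic selection is made.
#' @export
wcss_curve <- function(X, k_range = 1:8, n_starts = 25, seed = NULL) {
  X <- as.matrix(X)
  w <- local_seed(seed, vapply(k_range, function(k) {
    kmeans(X, k, nstart = n_starts, iter.max = 300)$tot.withinss
  }, numeric(1)))
  list(k_range = k_range, wcss = w)
}

# --- internal validity indices (each with its published optimum rule) -----

index_ch <- function(X, labels, k, W) {
  n <- nrow(X)
  tot <- sum(sweep(X, 2, colMeans(X))^2)
  ((tot - W) / (k - 1)) / (W / (n - k))
}

index_db <- function(X, labels, k) {
  cent <- cluster_means(X, labels, k)
  s <- vapply(seq_len(k), function(c) {
    rows <- X[labels == c, , drop = FALSE]
    mean(sqrt(rowSums(sweep(rows, 2, cent[c, ])^2)))
  }, numeric(1))
  r <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (s[i] + s[j]) / sqrt(sum((cent[i, ] - cent[j, ])^2))
    }, numeric(1)))
  }, numeric(1))
  mean(r)
}

index_dunn <- function(d, labels, k) {
  dm <- as.matrix(d)
  diam <- max(vapply(seq_len(k), function(c) {
    rows <- which(labels == c)
    if (length(rows) < 2) 0 else max(dm[rows, rows])
  }, numeric(1)))
  sep <- min(vapply(seq_len(k - 1), function(i) {
    min(vapply((i + 1):k, function(j) {
      min(dm[labels == i, labels == j])
    }, numeric(1)))
  }, numeric(1)))
  sep / diam
}

index_cindex <- function(d, labels) {
  dv <- as.numeric(d)
  dm <- as.matrix(d)
  within <- numeric(0)
  for (c in unique(labels)) {
    rows <- which(labels == c)
    if (length(rows) >= 2) {
      within <- c(within, dm[rows, rows][lower.tri(diag(length(rows)))])
    }
  }
  nw <- length(within)
  if (nw == 0) return(NA_real_)
  sorted <- sort(dv)
  s_min <- sum(sorted[seq_len(nw)])
  s_max <- sum(sorted[seq(length(sorted) - nw + 1, length(sorted))])
  (sum(within) - s_min) / (s_max - s_min)
}

#' Majority vote over internal validity indices
#'
#' Computes seven indices (Calinski-Harabasz, Davies-Bouldin, Dunn,
#' Hartigan, Krzanowski-Lai, C-index, mean silhouette) on k-means fits over
#' `k_range`, applies each index's published optimum rule, and selects the k
#' proposed by the majority.  The runner-up (second-most-voted k) is also
#' reported: it is the escape hatch when the winning k later fails the
#' acceptance gates.
#'
#' @inheritParams silhouette_selection
#' @return List with `votes` (named count per k), `k_majority`,
#'   `k_runner_up` (NA when undisputed) and the per-index choices.
#' @export
index_ensemble_vote <- function(X, k_range = 2:8, n_starts = 25,
                                seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (max(k_range) >= n) stop_invalid("k_range must stay below nrow(X)")
  d <- dist(X)
  ks_ext <- sort(unique(c(k_range, min(k_range) - 1, max(k_range) + 1)))
  ks_ext <- ks_ext[ks_ext >= 1 & ks_ext < n]
  fits <- local_seed(seed, lapply(ks_ext, function(k) {
    kmeans(X, k, nstart = n_starts, iter.max = 300)
  }))
  names(fits) <- as.character(ks_ext)
  W <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  getW <- function(k) W[[as.character(k)]]

  per_k <- lapply(k_range, function(k) {
    labels <- fits[[as.character(k)]]$cluster
    list(
      ch = index_ch(X, labels, k, getW(k)),
      db = index_db(X, labels, k),
      dunn = index_dunn(d, labels, k),
      cindex = index_cindex(d, labels),
      silhouette = mean(silhouette_values(d, labels)))
  })
  val <- function(name) vapply(per_k, `[[`, numeric(1), name)

  # Hartigan: H(k) = (W_k / W_{k+1} - 1) * (n - k - 1); smallest k with
  # H(k) <= 10, else the k with the largest drop H(k-1) - H(k).
  hart <- vapply(k_range, function(k) {
    if (!as.character(k + 1) %in% names(W)) return(NA_real_)
    (getW(k) / getW(k + 1) - 1) * (n - k - 1)
  }, numeric(1))
  k_hart <- if (any(hart <= 10, na.rm = TRUE)) {
    k_range[which(hart <= 10)[1]]
  } else {
    drops <- -diff(hart)
    if (all(is.na(drops))) NA_integer_ else k_range[which.max(drops) + 1]
  }

  # Krzanowski-Lai: DIFF(k) = (k-1)^(2/p) W_{k-1} - k^(2/p) W_k;
  # maximise |DIFF(k) / DIFF(k+1)|.
  diff_k <- function(k) {
    if (!all(c(k - 1, k) %in% ks_ext)) return(NA_real_)
    (k - 1)^(2 / p) * getW(k - 1) - k^(2 / p) * getW(k)
  }
  kl <- vapply(k_range, function(k) {
    d1 <- diff_k(k); d2 <- diff_k(k + 1)
    if (is.na(d1) || is.na(d2) || d2 == 0) NA_real_ else abs(d1 / d2)
  }, numeric(1))

  pick <- function(values, maximise) {
    if (all(is.na(values))) return(NA_integer_)
    k_range[if (maximise) which.max(values) else which.min(values)]
  }
  choices <- c(
    calinski_harabasz = pick(val("ch"), TRUE),
    davies_bouldin = pick(val("db"), FALSE),
    dunn = pick(val("dunn"), TRUE),
    hartigan = k_hart,
    krzanowski_lai = pick(kl, TRUE),
    c_index = pick(val("cindex"), FALSE),
    silhouette = pick(val("silhouette"), TRUE))
  if (all(is.na(choices))) stop_invalid("all indices undefined on this input")

  votes <- table(factor(choices[!is.na(choices)], levels = k_range))
  ord <- order(votes, -k_range, decreasing = TRUE) # ties -> smaller k
  k_majority <- as.integer(names(votes)[ord[1]])
  k_runner_up <- if (length(ord) > 1 && votes[ord[2]] > 0) {
    as.integer(names(votes)[ord[2]])
  } else NA_integer_
  list(votes = votes, k_majority = k_majority, k_runner_up = k_runner_up,
       choices = choices, k_range = k_range)
}

default_algorithm_roster <- function() {
  list(
    list(algorithm = "kmeans", distance = "euclidean", linkage = "none"),
    list(algorithm = "kmedoids", distance = "euclidean", linkage = "none"),
    list(algorithm = "kmedoids", distance = "manhattan", linkage = "none"),
    list(algorithm = "hierarchical", distance = "euclidean", linkage = "ward.D2"),
    list(algorithm = "hierarchical", distance = "euclidean", linkage = "complete"),
    list(algorithm = "hierarchical", distance = "euclidean", linkage = "average"),
    list(algorithm = "hierarchical", distance = "manhattan", linkage = "complete"),
    list(algorithm = "hierarchical", distance = "manhattan", linkage = "average"))
}

# Gate: every input variable must differ across clusters (p < 0.05),
# routed by Shapiro-Wilk normality exactly like the outcome comparisons.
variable_significance_gate <- function(table, labels, variables,
                                       alpha = 0.05) {
  table <- add_derived_variables(table)
  p <- vapply(variables, function(v) {
    tryCatch(suppressWarnings(compare_continuous(table[[v]], labels)$omnibus_p),
             error = function(e) NA_real_) # untestable candidate fails the gate
  }, numeric(1))
  list(p_values = p, pass = all(!is.na(p) & p < alpha))
}

#' Select the optimal clustering configuration under acceptance gates
#'
#' Determines candidate numbers of clusters from the index-ensemble majority
#' vote (winner, then runner-up; the gap-statistic and silhouette selections
#' are computed and reported alongside), fits each algorithm in the roster
#' in preference order (k-means, then k-medoids, then hierarchical), and
#' returns the first candidate that passes all three internal validation
#' gates:
#' \enumerate{
#'   \item clusterwise bootstrap Jaccard stability > `gates$jaccard`,
#'   \item non-negative mean silhouette for every cluster,
#'   \item every input variable significantly different across clusters
#'     (omnibus p < `gates$alpha`).
#' }
#' A full audit trail of every gate evaluation is returned.  When no
#' candidate passes, `model` is `NULL` and `status` is
#' `"no acceptable clustering"`.
#'
#' @param train Training cohort `data.frame`.
#' @param variable_set_id Input variable set (see [variable_set()]).
#' @param roster List of algorithm configurations in preference order.
#' @param k_range Candidate k values for the selection methods.
#' @param gates List with `jaccard` (default 0.75), `silhouette` (0) and
#'   `alpha` (0.05).
#' @param B_gap,B_boot Reference sets for the gap statistic / bootstrap
#'   replicates for the stability gate.
#' @param n_starts k-means restarts.
#' @param seed Optional integer seed driving every stochastic step.
#' @return List with `model`, `partition`, `status`, `k_selection`
#'   (gap/silhouette/ensemble/elbow reports) and `audit` (one row per gate
#'   evaluation).
#' @export
select_model <- function(train, variable_set_id = "full5",
                         roster = default_algorithm_roster(),
                         k_range = 2:8,
                         gates = list(jaccard = 0.75, silhouette = 0,
                                      alpha = 0.05),
                         B_gap = 50, B_boot = 50, n_starts = 25,
                         seed = NULL) {
  if (!length(roster)) stop_invalid("empty algorithm roster")
  vars <- variable_set(variable_set_id)
  scaling <- standardize_fit(train, vars)
  X <- standardize_apply(train, scaling)

  gap <- gap_statistic(X, k_range = 1:max(k_range), B = B_gap,
                       n_starts = n_starts, seed = derive_seed(seed, 1))
  silsel <- silhouette_selection(X, k_range = k_range, n_starts = n_starts,
                                 seed = derive_seed(seed, 2))
  vote <- index_ensemble_vote(X, k_range = k_range, n_starts = n_starts,
                              seed = derive_seed(seed, 3))
  elbow <- wcss_curve(X, k_range = 1:max(k_range), n_starts = n_starts,
                      seed = derive_seed(seed, 4))
  k_candidates <- unique(c(vote$k_majority, vote$k_runner_up))
  k_candidates <- k_candidates[!is.na(k_candidates) & k_candidates >= 2]

  audit <- list()
  selected <- NULL
  for (k in k_candidates) {
    for (cfg in roster) {
      fit <- fit_cohort_clusters(train, k, algorithm = cfg$algorithm,
                                 variable_set_id = variable_set_id,
                                 distance = cfg$distance,
                                 linkage = cfg$linkage %||% "ward.D2",
                                 n_starts = n_starts,
                                 seed = derive_seed(seed, 10 + k))
      sil_ok <- all(fit$partition$cluster_silhouette >= gates$silhouette)
      sig <- variable_significance_gate(train, fit$partition$labels, vars,
                                        gates$alpha)
      jac_ok <- NA
      jac_min <- NA_real_
      if (sil_ok && sig$pass) { # bootstrap is the expensive gate; run last
        stab <- bootstrap_stability(X, k = k, algorithm = cfg$algorithm,
                                    distance = cfg$distance,
                                    linkage = cfg$linkage %||% "ward.D2",
                                    B = B_boot, n_starts = n_starts,
                                    threshold = gates$jaccard,
                                    seed = derive_seed(seed, 100 + k))
        jac_min <- min(stab$mean_jaccard)
        jac_ok <- all(stab$pass)
      }
      pass <- isTRUE(sil_ok) && isTRUE(sig$pass) && isTRUE(jac_ok)
      audit[[length(audit) + 1]] <- data.frame(
        k = k, algorithm = cfg$algorithm, distance = cfg$distance,
        linkage = cfg$linkage %||% "none",
        min_cluster_silhouette = min(fit$partition$cluster_silhouette),
        silhouette_gate = sil_ok,
        max_variable_p = max(sig$p_values),
        significance_gate = sig$pass,
        min_jaccard = jac_min, jaccard_gate = jac_ok,
        pass = pass)
      if (pass && is.null(selected)) {
        selected <- fit
        selected$stability <- stab
        break
      }
    }
    if (!is.null(selected)) break
  }
  list(
    model = selected$model,
    partition = selected$partition,
    stability = selected$stability,
    status = if (is.null(selected)) "no acceptable clustering" else "accepted",
    k_selection = list(gap = gap, silhouette = silsel, ensemble = vote,
                       elbow = elbow, k_candidates = k_candidates),
    audit = do.call(rbind, audit))
}
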