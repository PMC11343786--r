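# Candidate clustering algorithms (k-means, k-medoids/PAM, agglomerative
# hierarchical) on the standardised input matrix, plus the nearest-centroid
# assignment primitive used for external validation and new-patient
# assignment.  All fits return canonically numbered clusters (see
# canonical_cluster_order) so labels are comparable across fits and sites.

# Canonical cluster numbering: descending centroid fasting glucose (ogtt0)
# when that variable is in the set, else descending mean OGTT, else
# descending BMI.  This reproduces the clinical numbering convention:
# cluster 1 = highest fasting glucose / most obese, cluster 3 = post-load
# pattern with normal fasting glucose.  Standardisation preserves order, so
# the rule is applied to standardised centroids directly.
canonical_cluster_order <- function(centroids) {
  vars <- colnames(centroids)
  ord_col <- 1L
  if (!is.null(vars)) {
    hit <- intersect(c("ogtt0", "mean_ogtt", "bmipg"), vars)
    if (length(hit)) ord_col <- match(hit[1], vars)
  }
  order(centroids[, ord_col], decreasing = TRUE)
}

# Relabel a fit so cluster ids follow the canonical order.  `ord[i]` is the
# old label that becomes new label i.
relabel_canonical <- function(labels, centroids) {
  ord <- canonical_cluster_order(centroids)
  new_of_old <- order(ord) # inverse permutation
  cent <- centroids[ord, , drop = FALSE]
  rownames(cent) <- seq_len(nrow(cent))
  list(labels = new_of_old[labels], centroids = cent, order = ord)
}

new_partition <- function(labels, k, X = NULL, distance = "euclidean",
                          role = "C_training", d = NULL) {
  sizes <- tabulate(labels, nbins = k)
  sil <- rep(NA_real_, length(labels))
  sil_cluster <- rep(NA_real_, k)
  if (k >= 2 && all(sizes > 0) && (!is.null(X) || !is.null(d))) {
    sil <- silhouette_values(X %||% d, labels, distance = distance)
    sil_cluster <- vapply(seq_len(k), function(c) mean(sil[labels == c]),
                          numeric(1))
  }
  structure(list(labels = labels, k = k, role = role, sizes = sizes,
                 silhouette = sil, cluster_silhouette = sil_cluster),
            class = "gdm_partition")
}

#' @export
print.gdm_partition <- function(x, ...) {
  cat(sprintf("<gdm_partition %s> k = %d, sizes: %s\n", x$role, x$k,
              paste(x$sizes, collapse = "/")))
  if (!all(is.na(x$cluster_silhouette))) {
    cat(sprintf("  mean silhouette per cluster: %s\n",
                paste(sprintf("%.3f", x$cluster_silhouette), collapse = " / ")))
  }
  invisible(x)
}

new_cluster_model <- function(algorithm, distance, linkage, k, centroids,
                              scaling, variable_set_id, seed, n_starts, wcss,
                              sizes) {
  structure(list(algorithm = algorithm, distance = distance,
                 linkage = linkage, k = as.integer(k),
                 centroids = centroids, scaling = scaling,
                 variable_set = variable_set_id, seed = seed,
                 n_starts = n_starts, wcss = wcss,
                 sizes = as.integer(sizes), version = "1"),
            class = "gdm_cluster_model")
}

#' @export
print.gdm_cluster_model <- function(x, ...) {
  cat(sprintf("<gdm_cluster_model> %s, k = %d, distance = %s%s\n",
              x$algorithm, x$k, x$distance,
              if (x$algorithm == "hierarchical") paste0(", linkage = ", x$linkage) else ""))
  cat("  centroids (clinical units):\n")
  print(round(destandardize(x$centroids, x$scaling), 2))
  invisible(x)
}

#' Fit k-means on a standardised matrix
#'
#' Multi-start Lloyd-type k-means (Hartigan-Wong refinement) keeping the
#' restart with the lowest total within-cluster sum of squares; clusters are
#' relabelled to canonical order.
#'
#' @param X Numeric matrix of standardised inputs (rows = participants).
#' @param k Number of clusters, `1 <= k <= nrow(X)`.
#' @param n_starts Number of random restarts.
#' @param seed Optional integer seed.
#' @param scaling,variable_set_id Optional provenance stored in the model.
#' @return `list(model = gdm_cluster_model, partition = gdm_partition)`.
#' @export
kmeans_fit <- function(X, k, n_starts = 50, seed = NULL, scaling = NULL,
                       variable_set_id = NULL) {
  X <- as.matrix(X)
  if (k < 1 || k > nrow(X)) stop_invalid("k must lie in 1..nrow(X)")
  fit <- local_seed(seed, kmeans(X, centers = k, nstart = n_starts,
                                 iter.max = 300))
  cent <- fit$centers
  colnames(cent) <- colnames(X)
  rl <- relabel_canonical(fit$cluster, cent)
  model <- new_cluster_model("kmeans", "euclidean", "none", k, rl$centroids,
                             scaling, variable_set_id, seed, n_starts,
                             fit$tot.withinss, tabulate(rl$labels, k))
  list(model = model,
       partition = new_partition(rl$labels, k, X = X))
}

#' Fit k-medoids (PAM) on a standardised matrix
#'
#' Partitioning around medoids (build + swap); the model's centroids are the
#' medoids themselves (standardised data points).
#'
#' @inheritParams kmeans_fit
#' @param distance `"euclidean"` or `"manhattan"`.
#' @export
kmedoids_fit <- function(X, k, distance = c("euclidean", "manhattan"),
                         seed = NULL, scaling = NULL, variable_set_id = NULL) {
  X <- as.matrix(X)
  distance <- match.arg(distance)
  if (k < 1 || k > nrow(X)) stop_invalid("k must lie in 1..nrow(X)")
  if (k == nrow(X)) { # every point its own medoid, total dissimilarity 0
    fit <- list(clustering = seq_len(k), id.med = seq_len(k))
  } else {
    fit <- local_seed(seed, cluster::pam(X, k, metric = distance,
                                         keep.diss = FALSE,
                                         keep.data = FALSE))
  }
  cent <- X[fit$id.med, , drop = FALSE]
  rownames(cent) <- NULL
  rl <- relabel_canonical(fit$clustering, cent)
  model <- new_cluster_model("kmedoids", distance, "none", k, rl$centroids,
                             scaling, variable_set_id, seed, NA_integer_,
                             NA_real_, tabulate(rl$labels, k))
  model$medoid_rows <- fit$id.med[rl$order]
  list(model = model,
       partition = new_partition(rl$labels, k, X = X, distance = distance))
}

#' Fit agglomerative hierarchical clustering
#'
#' Builds the merge tree with the requested linkage and cuts it into `k`
#' groups; centroids (member means in standardised space) are derived so the
#' model can be transferred by the nearest-centroid rule.
#'
#' @inheritParams kmedoids_fit
#' @param linkage `"complete"`, `"average"` or `"ward.D2"` (ward.D2 requires
#'   Euclidean distances).
#' @export
hierarchical_fit <- function(X, k, distance = c("euclidean", "manhattan"),
                             linkage = c("complete", "average", "ward.D2"),
                             scaling = NULL, variable_set_id = NULL) {
  X <- as.matrix(X)
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (linkage == "ward.D2" && distance != "euclidean") {
    stop_invalid("ward.D2 linkage requires euclidean distances")
  }
  if (k < 1 || k > nrow(X)) stop_invalid("k must lie in 1..nrow(X)")
  d <- dist(X, method = distance)
  tree <- hclust(d, method = linkage)
  labels <- cutree(tree, k = k)
  cent <- cluster_means(X, labels, k)
  rl <- relabel_canonical(labels, cent)
  model <- new_cluster_model("hierarchical", distance, linkage, k,
                             rl$centroids, scaling, variable_set_id, NULL,
                             NA_integer_, NA_real_, tabulate(rl$labels, k))
  model$merge_heights <- tree$height
  list(model = model,
       partition = new_partition(rl$labels, k, X = X, distance = distance),
       tree = tree)
}

cluster_means <- function(X, labels, k) {
  cent <- matrix(NA_real_, k, ncol(X), dimnames = list(NULL, colnames(X)))
  for (c in seq_len(k)) {
    cent[c, ] <- colMeans(X[labels == c, , drop = FALSE])
  }
  cent
}

#' Fit a clustering model on a cohort table
#'
#' High-level wrapper: selects the input variables, learns the
#' standardisation on the table, fits the requested algorithm and returns a
#' transferable model.
#'
#' @param table Cohort `data.frame`.
#' @param k Number of clusters.
#' @param algorithm `"kmeans"`, `"kmedoids"` or `"hierarchical"`.
#' @param variable_set_id Variable set id (see [variable_set()]).
#' @param distance,linkage Passed to the respective fitting routine.
#' @param n_starts Restarts for k-means.
#' @param seed Optional integer seed.
#' @return `list(model, partition)`.
#' @export
fit_cohort_clusters <- function(table, k, algorithm = c("kmeans", "kmedoids",
                                                        "hierarchical"),
                                variable_set_id = "full5",
                                distance = "euclidean", linkage = "ward.D2",
                                n_starts = 50, seed = NULL) {
  algorithm <- match.arg(algorithm)
  vars <- variable_set(variable_set_id)
  scaling <- standardize_fit(table, vars)
  X <- standardize_apply(table, scaling)
  switch(algorithm,
    kmeans = kmeans_fit(X, k, n_starts = n_starts, seed = seed,
                        scaling = scaling, variable_set_id = variable_set_id),
    kmedoids = kmedoids_fit(X, k, distance = distance, seed = seed,
                            scaling = scaling,
                            variable_set_id = variable_set_id),
    hierarchical = hierarchical_fit(X, k, distance = distance,
                                    linkage = linkage, scaling = scaling,
                                    variable_set_id = variable_set_id))
}

# Distances from each row of Z to each centroid under the model's metric.
centroid_distances <- function(Z, centroids, distance = "euclidean") {
  k <- nrow(centroids)
  D <- matrix(NA_real_, nrow(Z), k)
  for (c in seq_len(k)) {
    diffs <- sweep(Z, 2, centroids[c, ])
    D[, c] <- if (distance == "manhattan") rowSums(abs(diffs))
              else sqrt(rowSums(diffs^2))
  }
  D
}

#' Assign participants to the nearest cluster centroid
#'
#' Standardises the table with the model's training scaler and assigns each
#' row to the cluster whose centroid is nearest under the model's distance
#' metric (ties broken to the lowest cluster index).  This is the procedure
#' used to transfer a fitted model to a test set or a new clinic.
#'
#' @param model A fitted `gdm_cluster_model` (with scaling).
#' @param table Cohort `data.frame` containing the model's input variables.
#' @return A `gdm_partition` with role `C_test_estimated`; attribute
#'   `"distances"` holds the n x k matrix of standardised distances and
#'   `"rejected"` the ids of rows dropped for missing inputs.
#' @export
assign_nearest_centroid <- function(model, table) {
  stopifnot(inherits(model, "gdm_cluster_model"))
  if (is.null(model$scaling)) stop_invalid("model carries no scaling parameters")
  Z <- standardize_apply(table, model$scaling)
  D <- centroid_distances(Z, model$centroids, model$distance)
  labels <- max.col(-D, ties.method = "first")
  part <- new_partition(labels, model$k, X = Z, distance = model$distance,
                        role = "C_test_estimated")
  attr(part, "distances") <- D
  attr(part, "rejected") <- attr(Z, "rejected")
  part
}

#' Per-sample silhouette values
#'
#' Standard silhouette `s(i) = (b - a) / max(a, b)`; members of singleton
#' clusters get 0.
#'
#' @param X Numeric matrix of standardised inputs, or a `dist` object.
#' @param labels Integer cluster labels in `1..k`.
#' @param distance Metric used when `X` is a matrix.
#' @return Numeric vector of per-sample silhouettes in \[-1, 1\].
#' @export
silhouette_values <- function(X, labels, distance = "euclidean") {
  k <- length(unique(labels))
  if (k < 2) stop_invalid("silhouette undefined for k = 1")
  if (k == length(labels)) return(rep(0, length(labels))) # all singletons
  d <- if (inherits(X, "dist")) X else dist(as.matrix(X), method = distance)
  sil <- cluster::silhouette(labels, d)
  as.numeric(sil[, "sil_width"])
}

#' Persist / restore a cluster model as JSON
#'
#' The JSON artifact carries everything needed to assign new patients
#' (algorithm, k, variable names, scaling center/scale, centroid matrix,
#' seed, version) with full floating-point precision, so assignment from a
#' restored model is bit-identical.
#'
#' @param model A `gdm_cluster_model`.
#' @param path File path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "gdm_cluster_model"))
  lst <- list(
    algorithm = model$algorithm, distance = model$distance,
    linkage = model$linkage, k = model$k,
    variables = model$scaling$variables,
    center = unname(model$scaling$center),
    scale = unname(model$scaling$scale),
    centroids = unname(as.vector(t(model$centroids))), # row-major
    # C99 hex-float twins of every numeric block: decimal JSON numbers lose
    # the last bit or two, these restore the exact IEEE values on read
    center_hex = sprintf("%a", unname(model$scaling$center)),
    scale_hex = sprintf("%a", unname(model$scaling$scale)),
    centroids_hex = sprintf("%a", unname(as.vector(t(model$centroids)))),
    variable_set = model$variable_set,
    seed = model$seed, n_starts = model$n_starts,
    wcss = model$wcss, sizes = model$sizes, version = model$version)
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  vars <- lst$variables
  p <- length(vars)
  cent_vals <- if (!is.null(lst$centroids_hex)) as.numeric(lst$centroids_hex)
               else lst$centroids
  centroids <- matrix(cent_vals, nrow = lst$k, ncol = p, byrow = TRUE,
                      dimnames = list(NULL, vars))
  center <- if (!is.null(lst$center_hex)) as.numeric(lst$center_hex)
            else lst$center
  scale <- if (!is.null(lst$scale_hex)) as.numeric(lst$scale_hex)
           else lst$scale
  scaling <- structure(list(center = setNames(center, vars),
                            scale = setNames(scale, vars),
                            variables = vars),
                       class = "gdm_scaling")
  new_cluster_model(lst$algorithm, lst$distance, lst$linkage %||% "none",
                    lst$k, centroids, scaling, lst$variable_set,
                    lst$seed, lst$n_starts, lst$wcss %||% NA_real_,
                    lst$sizes)
}
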