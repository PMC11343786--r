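test_that("k-means handles trivial cases and separates tight blobs", {
  withr::with_seed(1, X <- matrix(rnorm(40), 20, 2))
  one <- kmeans_fit(X, 1, seed = 1)
  expect_equal(unname(one$model$centroids[1, ]), unname(colMeans(X)))
  expect_equal(one$model$wcss, sum(sweep(X, 2, colMeans(X))^2))

  blobs <- make_blobs(15, rbind(c(0, 0), c(10, 10)), sd = 0.3, seed = 2)
  fit <- kmeans_fit(blobs$X, 2, seed = 1)
  expect_equal(adjusted_rand(blobs$labels, fit$partition$labels), 1)
  m <- match_clusters(blobs$labels, fit$partition$labels)
  for (c in 1:2) {
    expect_equal(unname(fit$model$centroids[m[c], ]),
                 unname(colMeans(blobs$X[blobs$labels == c, ])),
                 tolerance = 1e-12)
  }
  expect_error(kmeans_fit(X, 21), "1..nrow")
})

test_that("multi-start k-means attains the enumerated global optimum on small instances", {
  withr::with_seed(7, X <- matrix(rnorm(16), 8, 2))
  best <- brute_force_kmeans_wcss(X, 2)
  fit <- kmeans_fit(X, 2, n_starts = 50, seed = 3)
  expect_equal(fit$model$wcss, best, tolerance = 1e-8)
})

test_that("k-means WCSS never increases with k (elbow monotonicity)", {
  cfg <- default_cohort_config()
  tab <- generate_cohort(cfg, n = 200, seed = 6)
  X <- standardize_apply(tab, standardize_fit(tab, "full5"))
  curve <- wcss_curve(X, 1:6, n_starts = 20, seed = 1)
  expect_true(all(diff(curve$wcss) <= 1e-8))
})

test_that("PAM k-medoids matches exhaustive medoid search on a line", {
  x <- matrix(c(0, 1, 2, 10, 11, 12, 30), ncol = 1)
  # brute force over all medoid pairs under manhattan distance
  best_cost <- Inf
  for (i in 1:6) for (j in (i + 1):7) {
    cost <- sum(pmin(abs(x - x[i]), abs(x - x[j])))
    if (cost < best_cost) best_cost <- cost
  }
  fit <- kmedoids_fit(x, 2, distance = "manhattan", seed = 1)
  med <- x[fit$model$medoid_rows, 1]
  cost <- sum(pmin(abs(x - med[1]), abs(x - med[2])))
  expect_equal(cost, best_cost)

  # k = n: every point its own medoid, zero cost
  full <- kmedoids_fit(x, 7, seed = 1)
  expect_equal(sort(full$model$medoid_rows), 1:7)

  # medoids are data points
  cfg <- default_cohort_config()
  tab <- generate_cohort(cfg, n = 80, seed = 8)
  X <- standardize_apply(tab, standardize_fit(tab, "full5"))
  pf <- kmedoids_fit(X, 3, seed = 1)
  for (c in 1:3) {
    expect_true(any(apply(X, 1, function(r) all(r == pf$model$centroids[c, ]))))
  }
})

test_that("hierarchical clustering reproduces hand-computed complete-linkage heights", {
  x <- matrix(c(0, 1, 3.5, 10, 11), ncol = 1)
  fit <- hierarchical_fit(x, 2, linkage = "complete")
  # merges: {0,1} at 1; {10,11} at 1; {0,1,3.5} at 3.5; all at 11
  expect_equal(sort(fit$model$merge_heights), c(1, 1, 3.5, 11))
  expect_true(all(diff(fit$tree$height) >= 0))
  expect_equal(sort(fit$partition$sizes), c(2, 3))

  # 3 equidistant points, k = 3 -> singletons
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  singl <- hierarchical_fit(tri, 3, linkage = "average")
  expect_equal(singl$partition$sizes, c(1, 1, 1))

  # k = 1 -> one cluster with everything
  all_one <- hierarchical_fit(x, 1, linkage = "ward.D2")
  expect_equal(all_one$partition$sizes, 5)

  expect_error(hierarchical_fit(x, 2, distance = "manhattan",
                                linkage = "ward.D2"), "ward.D2")
})

test_that("clusters are numbered canonically by descending fasting glucose", {
  cfg <- default_cohort_config()
  tab <- generate_cohort(cfg, n = 600, seed = 5)
  for (algorithm in c("kmeans", "kmedoids", "hierarchical")) {
    fit <- fit_cohort_clusters(tab, 3, algorithm = algorithm, seed = 2)
    cent <- gdmclust:::destandardize(fit$model$centroids, fit$model$scaling)
    expect_true(all(diff(cent[, "ogtt0"]) < 0),
                label = paste("ogtt0 ordering for", algorithm))
  }
})

test_that("silhouette values match hand computation and flag k = 1", {
  # 6 points on a line, clusters {0, 1, 2} and {10, 11, 12}
  x <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  labels <- rep(1:2, each = 3)
  s <- silhouette_values(x, labels)
  dm <- as.matrix(dist(x))
  hand <- vapply(1:6, function(i) {
    own <- labels == labels[i]
    a <- mean(dm[i, own & seq_len(6) != i])
    b <- mean(dm[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(s, hand, tolerance = 1e-12)
  expect_error(silhouette_values(x, rep(1, 6)), "k = 1")

  # equidistant point between clusters scores ~ 0
  y <- matrix(c(0, 0.02, 10, 10.02, 5.01), ncol = 1)
  ly <- c(1, 1, 2, 2, 1)
  sy <- silhouette_values(y, ly)
  expect_lt(abs(sy[5]), 0.01)
})

test_that("partitions are invariant to uniform scaling of the inputs", {
  blobs <- make_blobs(20, rbind(c(0, 0, 0), c(4, 4, 0), c(0, 4, 4)),
                      sd = 0.4, seed = 9)
  f1 <- kmeans_fit(blobs$X, 3, seed = 5)
  f2 <- kmeans_fit(blobs$X * 7.3, 3, seed = 5)
  expect_identical(f1$partition$labels, f2$partition$labels)
  h1 <- hierarchical_fit(blobs$X, 3, linkage = "ward.D2")
  h2 <- hierarchical_fit(blobs$X * 7.3, 3, linkage = "ward.D2")
  expect_identical(h1$partition$labels, h2$partition$labels)
})

test_that("nearest-centroid assignment is a fixed point of converged k-means and is idempotent", {
  cfg <- default_cohort_config()
  tab <- generate_cohort(cfg, n = 500, seed = 10)
  fit <- fit_cohort_clusters(tab, 3, seed = 4)
  part <- assign_nearest_centroid(fit$model, tab)
  expect_identical(part$labels, fit$partition$labels)
  expect_identical(part$role, "C_test_estimated")

  # idempotent and order-independent
  again <- assign_nearest_centroid(fit$model, tab)
  expect_identical(again$labels, part$labels)
  perm <- withr::with_seed(1, sample.int(nrow(tab)))
  shuffled <- assign_nearest_centroid(fit$model, tab[perm, ])
  expect_identical(shuffled$labels, part$labels[perm])

  # a row equal to a de-standardised centroid lands in that cluster
  cent <- gdmclust:::destandardize(fit$model$centroids, fit$model$scaling)
  rec <- as.data.frame(cent)
  at_cent <- assign_nearest_centroid(fit$model, rec)
  expect_identical(at_cent$labels, 1:3)
  expect_equal(diag(attr(at_cent, "distances")), rep(0, 3), tolerance = 1e-10)
})

test_that("the model JSON artifact round-trips bit-exactly", {
  cfg <- default_cohort_config()
  tab <- generate_cohort(cfg, n = 300, seed = 12)
  fit <- fit_cohort_clusters(tab, 3, seed = 6)
  path <- tempfile(fileext = ".json")
  write_model_json(fit$model, path)
  back <- read_model_json(path)
  expect_identical(unname(back$centroids), unname(fit$model$centroids))
  expect_identical(unname(back$scaling$center), unname(fit$model$scaling$center))
  expect_identical(unname(back$scaling$scale), unname(fit$model$scaling$scale))
  expect_identical(back$k, fit$model$k)
  # assignments from the restored model are identical
  p1 <- assign_nearest_centroid(fit$model, tab)
  p2 <- assign_nearest_centroid(back, tab)
  expect_identical(p1$labels, p2$labels)
  expect_identical(attr(p1, "distances"), attr(p2, "distances"))
})
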