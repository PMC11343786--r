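test_that("quartile-calibrated distributions reproduce their targets exactly", {
  # published example triple (right-skewed fasting glucose)
  sp <- fit_quantile_distribution(5.61, 5.99, 6.44)
  expect_equal(quantile_gdm_dist(sp, c(0.25, 0.5, 0.75)),
               c(5.61, 5.99, 6.44), tolerance = 1e-12)
  expect_identical(sp$family, "shifted-lognormal")

  # symmetric triple falls back to the normal family with sd = IQR/1.34898
  sym <- fit_quantile_distribution(-1, 0, 1)
  expect_identical(sym$family, "normal")
  expect_equal(sym$mean, 0)
  expect_equal(sym$sd, 2 / (2 * qnorm(0.75)), tolerance = 1e-12)

  # skewed triple: verify quantiles by numerically inverting the CDF
  sp2 <- fit_quantile_distribution(2, 3, 5)
  expect_identical(sp2$family, "shifted-lognormal")
  grid <- seq(quantile_gdm_dist(sp2, 1e-6), quantile_gdm_dist(sp2, 1 - 1e-6),
              length.out = 200001)
  for (p in c(0.25, 0.5, 0.75)) {
    inv <- grid[which.max(pdist_gdm_dist(sp2, grid) >= p)]
    expect_equal(inv, quantile_gdm_dist(sp2, p), tolerance = 1e-3)
  }

  # property: 1000 random monotone triples, 1e-9 relative error
  withr::with_seed(42, {
    for (i in 1:1000) {
      q <- sort(runif(3, -10, 10))
      if (min(diff(q)) < 1e-3) next
      spi <- fit_quantile_distribution(q[1], q[2], q[3])
      got <- quantile_gdm_dist(spi, c(0.25, 0.5, 0.75))
      expect_equal(got, q, tolerance = 1e-9)
    }
  })

  expect_error(fit_quantile_distribution(5, 4, 6), "q1 < median < q3")
  expect_error(fit_quantile_distribution(1, 1, 2), "q1 < median < q3")
})

test_that("generated cohorts recover calibration targets and satisfy the diagnostic constraint", {
  cfg <- default_cohort_config()
  tab <- generate_cohort(cfg, n = 10000, seed = 1)
  expect_equal(nrow(tab), 10000)

  # every row is a GDM case
  expect_true(all(meets_gdm_criteria(tab$ogtt0, tab$ogtt60, tab$ogtt120)))
  # plausibility ranges
  expect_true(all(tab$age > 12 & tab$age < 60))
  expect_true(all(tab[c("ogtt0", "ogtt60", "ogtt120")] > 2 &
                    tab[c("ogtt0", "ogtt60", "ogtt120")] < 25))

  # per-cluster sample medians within +/- 2% of the configured targets
  for (c in 1:3) {
    for (v in c("age", "bmipg", "ogtt0", "ogtt60", "ogtt120")) {
      target <- cfg$clusters[[c]]$variables[[v]]$targets[["median"]]
      obs <- median(tab[tab$true_cluster == c, v])
      expect_lt(abs(obs / target - 1), 0.02,
                label = sprintf("median of %s in cluster %d (%g vs %g)",
                                v, c, obs, target))
    }
  }

  # mixing proportions within multinomial sampling error
  props <- tabulate(tab$true_cluster, 3) / nrow(tab)
  expect_true(all(abs(props - cfg$mixing_proportions) < 0.02))
})

test_that("cluster-conditional outcome rates are recovered within exact binomial bounds", {
  cfg <- default_cohort_config()
  tab <- generate_cohort(cfg, n = 20000, seed = 11)
  for (c in 1:3) {
    rates <- cfg$clusters[[c]]$outcomes
    sub <- tab[tab$true_cluster == c, ]
    for (o in names(rates)) {
      x <- sub[[o]][!is.na(sub[[o]])]
      ci <- qbinom(c(0.005, 0.995), length(x), rates[[o]]) / length(x)
      expect_gte(mean(x), ci[1])
      expect_lte(mean(x), ci[2])
    }
  }
})

test_that("generation is byte-identical under a fixed seed and leaves the global RNG alone", {
  cfg <- default_cohort_config()
  set.seed(999)
  before <- runif(1)
  set.seed(999)
  t1 <- generate_cohort(cfg, n = 500, seed = 7)
  t2 <- generate_cohort(cfg, n = 500, seed = 7)
  expect_identical(t1, t2)
  after <- runif(1)
  expect_identical(before, after) # generator used a local RNG stream
  t3 <- generate_cohort(cfg, n = 500, seed = 8)
  expect_false(identical(t1$age, t3$age))
})

test_that("degenerate and empty configurations behave", {
  # n = 0: empty table with the full schema
  cfg <- default_cohort_config()
  empty <- generate_cohort(cfg, n = 0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("id", "age", "bmipg", "ogtt0", "ogtt60", "ogtt120",
                    "drugs_prescribed", "lga", "true_cluster", "site")
                  %in% names(empty)))

  # near-point-mass variable: all values ~ median
  pm <- cohort_config(100, 1, list(list(
    variables = list(ogtt0 = c(5 - 1e-7, 5, 5 + 1e-7)), outcomes = NULL)))
  tab <- generate_cohort(pm, seed = 3)
  expect_true(all(abs(tab$ogtt0 - 5) < 1e-5))

  # invalid configs
  expect_error(cohort_config(10, c(0.5, 0.4), list(list(variables = list(
    ogtt0 = c(4, 5, 6))), list(variables = list(ogtt0 = c(4, 5, 6))))),
    "sum to 1")
  expect_error(cohort_config(10, 1, list(list(
    variables = list(ogtt0 = c(4, 5, 6)),
    outcomes = c(bad = 1.2)))), "\\[0, 1\\]")
})

test_that("an infeasible constraint configuration is refused", {
  # all three OGTT distributions concentrated far below the thresholds
  bad <- cohort_config(50, 1, list(list(variables = list(
    age = c(30, 32, 34), bmipg = c(24, 25, 26),
    ogtt0 = c(3.0, 3.1, 3.2), ogtt60 = c(5.0, 5.1, 5.2),
    ogtt120 = c(4.0, 4.1, 4.2)))))
  expect_error(generate_cohort(bad, seed = 1), "infeasible")
})

test_that("missingness injection masks outcomes at the configured rate and never inputs", {
  cfg <- default_cohort_config()
  tab <- generate_cohort(cfg, n = 10000, seed = 5)
  tab$drugs_prescribed <- 1L # reset to fully observed

  none <- inject_missingness(tab, c(drugs_prescribed = 0), seed = 1)
  expect_identical(none$drugs_prescribed, tab$drugs_prescribed)

  all_gone <- inject_missingness(tab, c(drugs_prescribed = 1), seed = 1)
  expect_true(all(is.na(all_gone$drugs_prescribed)))

  some <- inject_missingness(tab, c(drugs_prescribed = 0.12), seed = 2)
  frac <- mean(is.na(some$drugs_prescribed))
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.12) / 10000
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
  expect_false(anyNA(some$ogtt0))

  expect_error(inject_missingness(tab, c(drugs_prescribed = 1.5)), "\\[0, 1\\]")
  expect_error(inject_missingness(tab, c(ogtt0 = 0.1)), "cannot be masked")
})

test_that("the Gaussian-copula hook imposes rank correlation without breaking marginals", {
  base <- list(variables = list(
    age = c(28, 33, 37), bmipg = c(23.25, 27.7, 32.85),
    ogtt0 = c(5.22, 5.33, 5.61), ogtt60 = c(7.19, 8.16, 9.1),
    ogtt120 = c(5.52, 6.22, 6.94)))
  R <- diag(5)
  R[3, 4] <- R[4, 3] <- 0.7 # ogtt0 ~ ogtt60
  cfg <- cohort_config(5000, 1, list(base), correlation = R)
  tab <- generate_cohort(cfg, seed = 9)
  expect_gt(cor(tab$ogtt0, tab$ogtt60, method = "spearman"), 0.5)
  expect_lt(abs(cor(tab$age, tab$bmipg, method = "spearman")), 0.1)
  expect_lt(abs(median(tab$ogtt0) / 5.33 - 1), 0.02)
  expect_error(cohort_config(10, 1, list(base), correlation = diag(4)),
               "5x5")
})

test_that("cohort tables and configurations round-trip through CSV / YAML", {
  cfg <- default_cohort_config(n = 60, seed = 4)
  tab <- generate_cohort(cfg)
  csv <- tempfile(fileext = ".csv")
  write_cohort(tab, csv)
  back <- read_cohort(csv)
  expect_equal(back$ogtt0, tab$ogtt0, tolerance = 1e-12)
  expect_equal(sum(is.na(back$drugs_prescribed)),
               sum(is.na(tab$drugs_prescribed)))

  yml <- tempfile(fileext = ".yaml")
  write_cohort_config(cfg, yml)
  cfg2 <- read_cohort_config(yml)
  expect_equal(cfg2$mixing_proportions, cfg$mixing_proportions)
  expect_equal(cfg2$clusters[[1]]$variables$ogtt0$targets,
               cfg$clusters[[1]]$variables$ogtt0$targets)
  expect_equal(cfg2$clusters[[2]]$outcomes, cfg$clusters[[2]]$outcomes)
})
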