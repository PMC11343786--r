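test_that("normality routing follows the Shapiro-Wilk decision at its nominal level", {
  normal_hits <- 0
  exp_hits <- 0
  withr::with_seed(31, {
    for (i in 1:100) {
      if (normality_route(rnorm(500)) == "normal") normal_hits <- normal_hits + 1
      if (normality_route(rexp(500)) == "non-normal") exp_hits <- exp_hits + 1
    }
  })
  expect_gte(normal_hits, 90) # nominal level 0.05
  expect_gte(exp_hits, 99)
  expect_error(normality_route(c(1, 2)), ">= 3")
  expect_warning(r <- normality_route(rep(5, 10)), "constant")
  expect_identical(r, "non-normal")
  # residuals about group medians: a strong group shift must not break routing
  withr::with_seed(32, {
    v <- c(rnorm(200), rnorm(200, 50))
    l <- rep(1:2, each = 200)
  })
  expect_identical(normality_route(v, l), "normal")
})

test_that("ANOVA omnibus and protected LSD behave on null, shifted and two-group data", {
  base <- withr::with_seed(33, rnorm(60))
  null_cmp <- anova_fisher_lsd(rep(base, 3), rep(1:3, each = 60))
  expect_lt(null_cmp$omnibus_statistic, 1e-20)
  expect_null(null_cmp$pairwise) # no post hoc without a significant omnibus

  withr::with_seed(34, {
    v <- c(rnorm(50, 0), rnorm(50, 0), rnorm(50, 2))
    l <- rep(1:3, each = 50)
  })
  shifted <- anova_fisher_lsd(v, l)
  expect_lt(shifted$omnibus_p, 0.001)
  pw <- shifted$pairwise
  expect_equal(nrow(pw), 3)
  expect_lt(pw$p[pw$cluster_i == 1 & pw$cluster_j == 3], 0.001)
  expect_lt(pw$p[pw$cluster_i == 2 & pw$cluster_j == 3], 0.001)
  expect_gt(pw$p[pw$cluster_i == 1 & pw$cluster_j == 2], 0.05)

  # two groups: F = t^2 and identical p
  withr::with_seed(35, {
    v2 <- c(rnorm(30), rnorm(30, 0.7))
    l2 <- rep(1:2, each = 30)
  })
  a2 <- anova_fisher_lsd(v2, l2)
  tt <- t.test(v2 ~ l2, var.equal = TRUE)
  expect_equal(a2$omnibus_statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a2$omnibus_p, tt$p.value, tolerance = 1e-10)
})

test_that("Kruskal-Wallis H matches the rank formula and ties are corrected", {
  # ranks 1..9 in thirds: H = 12/(9*10) * (36/3 + 225/3 + 576/3) - 30 = 7.2
  kw <- kruskal_dunn(1:9, rep(1:3, each = 3))
  expect_equal(kw$omnibus_statistic, 7.2, tolerance = 1e-12)
  expect_equal(kw$omnibus_statistic,
               unname(kruskal.test(1:9, rep(1:3, each = 3))$statistic),
               tolerance = 1e-12)
  expect_equal(kw$omnibus_p,
               kruskal.test(1:9, rep(1:3, each = 3))$p.value,
               tolerance = 1e-12)

  # heavy ties: must match the independent tie-corrected implementation
  withr::with_seed(36, {
    v <- sample(1:4, 90, replace = TRUE)
    l <- rep(1:3, each = 30)
  })
  expect_equal(kruskal_dunn(v, l)$omnibus_statistic,
               unname(kruskal.test(v, l)$statistic), tolerance = 1e-12)

  # all values tied -> H = 0, p = 1, no post hoc
  tied <- kruskal_dunn(rep(3, 30), rep(1:3, each = 10))
  expect_equal(tied$omnibus_statistic, 0)
  expect_equal(tied$omnibus_p, 1)
  expect_null(tied$pairwise)

  # Dunn post hoc flags the separated pair
  withr::with_seed(37, {
    v <- c(rexp(40), rexp(40), rexp(40) + 3)
    l <- rep(1:3, each = 40)
  })
  kd <- kruskal_dunn(v, l)
  expect_lt(kd$omnibus_p, 0.001)
  expect_lt(kd$pairwise$p[3], 0.01) # (2,3)
  expect_gt(kd$pairwise$p[1], 0.05) # (1,2)
})

test_that("contingency tests switch between chi-square and Fisher and protect pairwise stages", {
  # published drug-by-cluster counts: 84/212, 47/364, 44/440
  fx <- make_binary_fixture(c(84, 47, 44), c(212, 364, 440),
                            c(246, 407, 501))
  cmp <- contingency_test(fx$outcome, fx$cluster)
  expect_identical(cmp$route, "chisq")
  expect_lt(cmp$omnibus_p, 0.0001)
  expect_equal(nrow(cmp$pairwise), 3)
  expect_lt(cmp$pairwise$p[1], 1e-10) # cluster 1 vs 2
  expect_lt(cmp$pairwise$p[2], 1e-10) # cluster 1 vs 3

  # identical rates: p ~ 1, no pairwise
  same <- contingency_test(rep(c(0, 1), 150), rep(1:3, each = 100))
  expect_gt(same$omnibus_p, 0.9)
  expect_null(same$pairwise)

  # small expected counts route to Fisher and match hypergeometric
  # enumeration (expected successes 4.8 / 3.2 here)
  v <- c(rep(1, 2), rep(0, 10), rep(1, 6), rep(0, 2))
  l <- rep(1:2, c(12, 8))
  f <- contingency_test(v, l)
  expect_identical(f$route, "fisher")
  tab <- table(factor(v, levels = c(0, 1)), l)
  expect_equal(f$omnibus_p, hypergeom_fisher_p(tab), tolerance = 1e-9)
  expect_equal(f$omnibus_p, fisher.test(tab)$p.value, tolerance = 1e-12)

  expect_error(contingency_test(c(0.5, 1, 0), c(1, 2, 3)), "binary")
})

test_that("logistic regression LRT agrees with the contingency view and its ORs with cross-products", {
  fx <- make_binary_fixture(c(84, 47, 44), c(212, 364, 440),
                            c(246, 407, 501))
  lr <- logistic_lrt(fx$outcome, fx$cluster)
  expect_lt(lr$omnibus_p, 1e-10)
  or13 <- lr$odds_ratios[lr$odds_ratios$cluster_i == 1 &
                           lr$odds_ratios$cluster_j == 3, ]
  # saturated model: OR(1 vs 3) equals the 2x2 cross-product (84/128)/(44/396)
  expect_equal(or13$odds_ratio, (84 / 128) / (44 / 396), tolerance = 1e-6)
  expect_true(or13$ci_lower < or13$odds_ratio &
                or13$odds_ratio < or13$ci_upper)

  # saturation identity: fitted rates equal observed rates
  rates <- with(fx[!is.na(fx$outcome), ], tapply(outcome, cluster, mean))
  b <- c(84 / 212, 47 / 364, 44 / 440)
  expect_equal(as.numeric(rates), b, tolerance = 1e-12)

  # equal rates: LRT p ~ 1, no odds ratios emitted
  flat <- logistic_lrt(rep(c(0, 1), 150), rep(1:3, each = 100))
  expect_gt(flat$omnibus_p, 0.9)
  expect_null(flat$odds_ratios)

  # separation: flagged unbounded, LRT still computed
  sep <- logistic_lrt(c(rep(1, 20), rep(0, 20), rep(c(0, 1), 10)),
                      rep(1:3, each = 20))
  expect_identical(sep$notes, "separation")
  expect_false(is.na(sep$omnibus_p))
  expect_true(all(sep$odds_ratios$unbounded[
    sep$odds_ratios$cluster_i == 1 | sep$odds_ratios$cluster_j == 2]))
})

test_that("chi-square and logistic LRT agree in significance on non-degenerate tables", {
  agree <- 0
  n_tables <- 0
  withr::with_seed(38, {
    for (i in 1:200) {
      rates <- runif(3, 0.15, 0.85)
      v <- rbinom(300, 1, rates[rep(1:3, each = 100)])
      l <- rep(1:3, each = 100)
      tab <- table(v, l)
      if (any(tab < 5)) next
      n_tables <- n_tables + 1
      p1 <- contingency_test(v, l)$omnibus_p
      p2 <- logistic_lrt(v, l)$omnibus_p
      if ((p1 < 0.05) == (p2 < 0.05)) agree <- agree + 1
    }
  })
  expect_gte(agree / n_tables, 0.99)
})

test_that("cluster profiles reproduce the printed percentage convention and account for missingness", {
  fx <- make_binary_fixture(c(84, 47, 44), c(212, 364, 440),
                            c(246, 407, 501))
  tab <- data.frame(drugs_prescribed = fx$outcome)
  prof <- cluster_profile(tab, fx$cluster)
  row <- prof[prof$variable == "drugs_prescribed", ]
  expect_equal(row$n_tot, 1016)
  expect_equal(c(row$n_cluster_1, row$n_cluster_2, row$n_cluster_3),
               c(212, 364, 440))
  expect_identical(c(row$cluster_1, row$cluster_2, row$cluster_3),
                   c("84 (39.62)", "47 (12.91)", "44 (10.00)"))

  # continuous summaries and a fully missing outcome
  cfg <- default_cohort_config()
  coh <- generate_cohort(cfg, n = 300, seed = 41)
  coh$gone <- NA_integer_
  labels <- coh$true_cluster
  p2 <- cluster_profile(coh, labels,
                        variables = c("ogtt0", "gone", "lga"))
  expect_equal(p2$n_tot[p2$variable == "gone"], 0)
  og <- p2[p2$variable == "ogtt0", ]
  expect_equal(og$median_cluster_1,
               median(coh$ogtt0[labels == 1]))
  # no missingness on inputs: denominators equal cluster sizes
  expect_equal(c(og$n_cluster_1, og$n_cluster_2, og$n_cluster_3),
               unname(as.vector(table(labels))))

  # drug prevalence in the synthetic default cohort tracks the calibrated rate
  big <- generate_cohort(cfg, n = 20000, seed = 42)
  c1 <- big[big$true_cluster == 1, "drugs_prescribed"]
  c1 <- c1[!is.na(c1)]
  ci <- qbinom(c(0.005, 0.995), length(c1), 84 / 212) / length(c1)
  expect_gte(mean(c1), ci[1])
  expect_lte(mean(c1), ci[2])
})

test_that("compare_outcomes dispatches by outcome type and never emits unprotected post hocs", {
  cfg <- default_cohort_config()
  coh <- generate_cohort(cfg, n = 800, seed = 43)
  coh$bw_percentile <- withr::with_seed(44, runif(800, 0, 100))
  res <- compare_outcomes(coh, coh$true_cluster,
                          c("drugs_prescribed", "bw_percentile"))
  expect_identical(res$drugs_prescribed$type, "binary")
  expect_identical(res$bw_percentile$type, "continuous")
  expect_lt(res$drugs_prescribed$omnibus_p, 0.0001)
  # protection: a null outcome must not carry pairwise results
  if (res$bw_percentile$omnibus_p >= 0.05) {
    expect_null(res$bw_percentile$pairwise)
  }
  expect_error(compare_outcomes(coh, coh$true_cluster, "nope"), "absent")
})
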