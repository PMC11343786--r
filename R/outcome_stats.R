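# Across-cluster comparison of input variables and clinical outcomes.
#
# Continuous variables are routed by a Shapiro-Wilk normality check:
# ANOVA with Fisher's protected LSD post hoc tests when normal,
# Kruskal-Wallis with Dunn post hoc tests otherwise.  Binary outcomes get a
# chi-square test (Fisher's exact test when an expected count falls below
# 5) and a logistic regression with a likelihood-ratio omnibus test and
# pairwise odds ratios.  Post hoc results are only computed when the
# omnibus test is significant (protected testing), and p values are left
# unadjusted by default, matching an explorative analysis stance.

is_binary <- function(values) {
  v <- values[!is.na(values)]
  length(v) > 0 && all(v %in% c(0, 1))
}

new_outcome_comparison <- function(outcome, type, route, statistic, p,
                                   pairwise = NULL, odds_ratios = NULL,
                                   n_per_cluster = NULL, notes = character(0)) {
  structure(list(outcome = outcome, type = type, route = route,
                 omnibus_statistic = statistic, omnibus_p = p,
                 pairwise = pairwise, odds_ratios = odds_ratios,
                 n_per_cluster = n_per_cluster, notes = notes),
            class = "gdm_outcome_comparison")
}

#' @export
print.gdm_outcome_comparison <- function(x, ...) {
  cat(sprintf("<gdm_outcome_comparison> %s [%s]: statistic = %.4g, p = %.4g\n",
              x$outcome %||% "?", x$route, x$omnibus_statistic, x$omnibus_p))
  if (!is.null(x$pairwise)) {
    print(x$pairwise, row.names = FALSE)
  } else {
    cat("  (no post hoc stage: omnibus not significant)\n")
  }
  invisible(x)
}

#' Route a continuous variable by normality
#'
#' Shapiro-Wilk test (p >= 0.05 -> `"normal"`); when group labels are
#' supplied the test is run on pooled residuals about group medians, and
#' samples larger than 5000 are subsampled (the test is defined for
#' n <= 5000).  Constant input routes to `"non-normal"` with a warning.
#'
#' @param values Numeric vector (>= 3 non-missing values).
#' @param labels Optional group labels.
#' @param seed Seed for the (rare) subsampling step.
#' @return `"normal"` or `"non-normal"`.
#' @export
normality_route <- function(values, labels = NULL, seed = NULL) {
  keep <- !is.na(values)
  v <- values[keep]
  if (length(v) < 3) stop_invalid("normality check needs >= 3 non-missing values")
  if (!is.null(labels)) {
    l <- labels[keep]
    med <- tapply(v, l, median)
    v <- v - med[as.character(l)]
  }
  if (sd(v) == 0) {
    warning("constant input; routed as non-normal")
    return("non-normal")
  }
  if (length(v) > 5000) {
    v <- local_seed(seed, sample(v, 5000))
  }
  p <- shapiro.test(v)$p.value
  if (p >= 0.05) "normal" else "non-normal"
}

group_sizes <- function(labels, k = max(labels)) {
  tabulate(labels, nbins = k)
}

pairs_of <- function(k) {
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    out[[length(out) + 1]] <- c(i, j)
  }
  out
}

#' One-way ANOVA with Fisher's protected LSD post hoc tests
#'
#' Omnibus F test across clusters; when (and only when) the omnibus p is
#' below `alpha`, pairwise t tests using the pooled within-group mean
#' square (the classical LSD, unadjusted p values) are added.
#'
#' @param values Numeric outcome.
#' @param labels Integer cluster labels.
#' @param alpha Protection level for the post hoc stage.
#' @return A `gdm_outcome_comparison` with route `"ANOVA+LSD"`.
#' @export
anova_fisher_lsd <- function(values, labels, alpha = 0.05) {
  keep <- !is.na(values)
  v <- values[keep]
  l <- labels[keep]
  k <- max(labels)
  sizes <- group_sizes(l, k)
  small <- which(sizes > 0 & sizes < 2)
  if (length(small)) {
    warning("group(s) with < 2 observations excluded: ",
            paste(small, collapse = ", "))
    drop <- l %in% small
    v <- v[!drop]; l <- l[!drop]
  }
  groups <- sort(unique(l))
  if (length(groups) < 2) stop_invalid("ANOVA needs >= 2 groups")
  fit <- aov(v ~ factor(l))
  an <- anova(fit)
  fstat <- an[1, "F value"]
  p <- an[1, "Pr(>F)"]
  mse <- an[2, "Mean Sq"]
  df_err <- an[2, "Df"]
  pairwise <- NULL
  if (!is.na(p) && p < alpha) {
    means <- tapply(v, l, mean)
    ns <- tapply(v, l, length)
    pw <- lapply(pairs_of(length(groups)), function(pr) {
      gi <- groups[pr[1]]; gj <- groups[pr[2]]
      se <- sqrt(mse * (1 / ns[[as.character(gi)]] + 1 / ns[[as.character(gj)]]))
      tval <- (means[[as.character(gi)]] - means[[as.character(gj)]]) / se
      data.frame(cluster_i = gi, cluster_j = gj, statistic = tval,
                 p = 2 * pt(-abs(tval), df_err))
    })
    pairwise <- do.call(rbind, pw)
  }
  new_outcome_comparison(NULL, "continuous", "ANOVA+LSD", fstat, p,
                         pairwise = pairwise,
                         n_per_cluster = group_sizes(l, k))
}

# Tie-corrected Kruskal-Wallis H computed from ranks (stats::kruskal.test
# provides the same value; kept inline so the Dunn z statistics share the
# rank/tie bookkeeping).
#' Kruskal-Wallis test with Dunn post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis omnibus test; when the omnibus p is below
#' `alpha`, Dunn z statistics on mean ranks (two-sided, unadjusted by
#' default) are added for every cluster pair.
#'
#' @inheritParams anova_fisher_lsd
#' @param p_adjust Adjustment method passed to [stats::p.adjust()] for the
#'   Dunn p values (`"none"` by default).
#' @return A `gdm_outcome_comparison` with route `"KW+Dunn"`.
#' @export
kruskal_dunn <- function(values, labels, alpha = 0.05, p_adjust = "none") {
  keep <- !is.na(values)
  v <- values[keep]
  l <- labels[keep]
  k <- max(labels)
  groups <- sort(unique(l))
  if (length(groups) < 2) stop_invalid("Kruskal-Wallis needs >= 2 groups")
  n <- length(v)
  r <- rank(v)
  ties <- table(v)
  tie_sum <- sum(ties^3 - ties)
  sum_term <- sum(tapply(r, l, function(x) sum(x)^2 / length(x)))
  h_raw <- 12 / (n * (n + 1)) * sum_term - 3 * (n + 1)
  correction <- 1 - tie_sum / (n^3 - n)
  if (correction == 0) { # every value tied
    h <- 0
    p <- 1
  } else {
    h <- h_raw / correction
    p <- pchisq(h, df = length(groups) - 1, lower.tail = FALSE)
  }
  pairwise <- NULL
  if (p < alpha) {
    mean_ranks <- tapply(r, l, mean)
    ns <- tapply(r, l, length)
    tie_adj <- tie_sum / (12 * (n - 1))
    pw <- lapply(pairs_of(length(groups)), function(pr) {
      gi <- groups[pr[1]]; gj <- groups[pr[2]]
      se <- sqrt((n * (n + 1) / 12 - tie_adj) *
                   (1 / ns[[as.character(gi)]] + 1 / ns[[as.character(gj)]]))
      z <- (mean_ranks[[as.character(gi)]] - mean_ranks[[as.character(gj)]]) / se
      data.frame(cluster_i = gi, cluster_j = gj, statistic = z,
                 p = 2 * pnorm(-abs(z)))
    })
    pairwise <- do.call(rbind, pw)
    pairwise$p <- stats::p.adjust(pairwise$p, method = p_adjust)
  }
  new_outcome_comparison(NULL, "continuous", "KW+Dunn", h, p,
                         pairwise = pairwise,
                         n_per_cluster = group_sizes(l, k))
}

#' Compare a continuous variable across clusters (normality-routed)
#'
#' Applies [normality_route()] (Shapiro-Wilk on residuals about group
#' medians) and dispatches to [anova_fisher_lsd()] or [kruskal_dunn()].
#'
#' @inheritParams anova_fisher_lsd
#' @export
compare_continuous <- function(values, labels, alpha = 0.05) {
  route <- suppressWarnings(normality_route(values, labels))
  if (route == "normal") anova_fisher_lsd(values, labels, alpha)
  else kruskal_dunn(values, labels, alpha)
}

# chi-square when all expected counts >= 5, else Fisher's exact test.
test_2xk <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(route = "chisq", statistic = unname(ht$statistic),
         p = ht$p.value)
  } else {
    ht <- fisher.test(tab)
    list(route = "fisher", statistic = NA_real_, p = ht$p.value)
  }
}

#' Chi-square / Fisher test of a binary outcome across clusters
#'
#' Builds the 2 x k available-case table and applies Pearson's chi-square
#' test (without continuity correction) when all expected counts are at
#' least 5, otherwise Fisher's exact test.  Pairwise 2 x 2 tests (same
#' switching rule) are added only when the omnibus p is below `alpha`.
#'
#' @param values Binary (0/1/NA) outcome vector.
#' @param labels Integer cluster labels.
#' @param alpha Protection level for the pairwise stage.
#' @return A `gdm_outcome_comparison` with route `"chisq"` or `"fisher"`.
#' @export
contingency_test <- function(values, labels, alpha = 0.05) {
  keep <- !is.na(values)
  v <- values[keep]
  l <- labels[keep]
  if (!is_binary(v)) stop_invalid("outcome must be binary (0/1)")
  k <- max(labels)
  groups <- sort(unique(l))
  if (length(groups) < 2) stop_invalid("contingency test needs >= 2 clusters")
  tab <- table(factor(v, levels = c(0, 1)), factor(l, levels = groups))
  if (any(rowSums(tab) == 0)) {
    return(new_outcome_comparison(NULL, "binary", "chisq", NA_real_,
                                  NA_real_,
                                  n_per_cluster = group_sizes(l, k),
                                  notes = "degenerate margin"))
  }
  omni <- test_2xk(tab)
  pairwise <- NULL
  if (!is.na(omni$p) && omni$p < alpha) {
    pw <- lapply(pairs_of(length(groups)), function(pr) {
      gi <- groups[pr[1]]; gj <- groups[pr[2]]
      sub <- tab[, c(pr[1], pr[2])]
      res <- test_2xk(sub)
      data.frame(cluster_i = gi, cluster_j = gj, route = res$route,
                 statistic = res$statistic, p = res$p)
    })
    pairwise <- do.call(rbind, pw)
  }
  new_outcome_comparison(NULL, "binary", omni$route, omni$statistic, omni$p,
                         pairwise = pairwise,
                         n_per_cluster = group_sizes(l, k))
}

#' Logistic regression of a binary outcome on cluster membership
#'
#' Fits `outcome ~ cluster` by maximum likelihood, tests the cluster factor
#' with a likelihood-ratio test against the intercept-only model, and (only
#' when the LRT is significant) reports pairwise odds ratios
#' `exp(b_i - b_j)` with Wald 95% confidence intervals.  Complete
#' separation (a cluster with all-0 or all-1 outcomes) flags the affected
#' odds ratios as unbounded; the LRT is still computed.
#'
#' @inheritParams contingency_test
#' @return A `gdm_outcome_comparison` with route `"logistic-LRT"` and an
#'   `odds_ratios` data.frame.
#' @export
logistic_lrt <- function(values, labels, alpha = 0.05) {
  keep <- !is.na(values)
  v <- values[keep]
  l <- labels[keep]
  if (!is_binary(v)) stop_invalid("outcome must be binary (0/1)")
  if (length(unique(v)) < 2) stop_invalid("outcome must carry both levels")
  k <- max(labels)
  groups <- sort(unique(l))
  if (length(groups) < 2) stop_invalid("logistic comparison needs >= 2 clusters")
  f <- factor(l, levels = groups)
  fit <- suppressWarnings(glm(v ~ f, family = binomial()))
  null_fit <- glm(v ~ 1, family = binomial())
  lrt_stat <- as.numeric(2 * (logLik(fit) - logLik(null_fit)))
  lrt_p <- pchisq(lrt_stat, df = length(groups) - 1, lower.tail = FALSE)
  rates <- tapply(v, f, mean)
  separated <- rates %in% c(0, 1)
  odds_ratios <- NULL
  if (!is.na(lrt_p) && lrt_p < alpha) {
    # coefficient vector per group on the logit scale (reference = 0)
    b <- c(0, coef(fit)[-1])
    V <- vcov(fit)
    contrast_var <- function(i, j) {
      # var(b_i - b_j) with b_1 = reference
      ci <- cj <- rep(0, length(coef(fit)))
      if (i > 1) ci[i] <- 1
      if (j > 1) cj[j] <- 1
      cc <- ci - cj
      as.numeric(t(cc) %*% V %*% cc)
    }
    odds_ratios <- do.call(rbind, lapply(pairs_of(length(groups)), function(pr) {
      i <- pr[1]; j <- pr[2]
      est <- b[i] - b[j]
      se <- sqrt(contrast_var(i, j))
      unbounded <- separated[i] || separated[j]
      data.frame(cluster_i = groups[i], cluster_j = groups[j],
                 odds_ratio = exp(est),
                 ci_lower = if (unbounded) NA_real_ else exp(est - 1.96 * se),
                 ci_upper = if (unbounded) NA_real_ else exp(est + 1.96 * se),
                 p = if (unbounded) NA_real_ else 2 * pnorm(-abs(est / se)),
                 unbounded = unbounded)
    }))
  }
  new_outcome_comparison(NULL, "binary", "logistic-LRT", lrt_stat, lrt_p,
                         odds_ratios = odds_ratios,
                         n_per_cluster = group_sizes(l, k),
                         notes = if (any(separated)) "separation" else character(0))
}

#' Compare a set of outcomes across clusters
#'
#' Dispatches each outcome by type: binary outcomes get the chi-square /
#' Fisher contingency test and the logistic likelihood-ratio analysis;
#' continuous outcomes are normality-routed to ANOVA + LSD or
#' Kruskal-Wallis + Dunn.
#'
#' @param table Cohort `data.frame`.
#' @param labels Integer cluster labels aligned with `table` rows.
#' @param outcomes Character vector of outcome column names.
#' @param alpha Protection level.
#' @return Named list of `gdm_outcome_comparison` objects (binary outcomes
#'   carry a `logistic` sub-result).
#' @export
compare_outcomes <- function(table, labels, outcomes, alpha = 0.05) {
  stopifnot(nrow(table) == length(labels))
  res <- lapply(outcomes, function(o) {
    v <- table[[o]]
    if (is.null(v)) stop_invalid("outcome column absent: ", o)
    if (is_binary(v)) {
      cmp <- tryCatch(contingency_test(v, labels, alpha),
                      error = function(e) {
                        new_outcome_comparison(o, "binary", "chisq",
                                               NA_real_, NA_real_,
                                               notes = conditionMessage(e))
                      })
      cmp$outcome <- o
      cmp$logistic <- tryCatch(logistic_lrt(v, labels, alpha),
                               error = function(e) NULL)
      cmp
    } else {
      cmp <- tryCatch(compare_continuous(v, labels, alpha),
                      error = function(e) {
                        new_outcome_comparison(o, "continuous", "KW+Dunn",
                                               NA_real_, NA_real_,
                                               notes = conditionMessage(e))
                      })
      cmp$outcome <- o
      cmp
    }
  })
  names(res) <- outcomes
  res
}

format_pct <- function(count, denom) {
  ifelse(denom > 0, sprintf("%.2f", 100 * count / denom), NA_character_)
}

#' Cluster profile table (median/IQR and n (%) summaries)
#'
#' Builds the per-cluster summary used to describe clustering solutions:
#' continuous variables as `median (Q1-Q3)`, binary variables as `n (%)`
#' with percentages over the per-cluster available-case denominator
#' (printed with 2 decimals), plus the total and per-cluster available-case
#' counts for every row.
#'
#' @param table Cohort `data.frame`.
#' @param labels Integer cluster labels aligned with `table` rows.
#' @param variables Character vector of columns to profile (defaults to the
#'   clinical inputs present plus every 0/1 column).
#' @param digits Decimals used for continuous summaries.
#' @return A `data.frame` with one row per variable: `variable`, `type`,
#'   `n_tot`, `n_cluster_*`, numeric summary columns and formatted
#'   `cluster_*` display columns.
#' @export
cluster_profile <- function(table, labels, variables = NULL, digits = 2) {
  stopifnot(nrow(table) == length(labels))
  k <- max(labels)
  if (is.null(variables)) {
    candidates <- setdiff(names(table), c("id", "site", "true_cluster"))
    variables <- candidates[vapply(candidates, function(v) {
      is.numeric(table[[v]]) || is_binary(table[[v]])
    }, logical(1))]
  }
  rows <- lapply(variables, function(v) {
    x <- table[[v]]
    avail <- !is.na(x)
    n_cl <- vapply(seq_len(k), function(c) sum(avail & labels == c),
                   integer(1))
    row <- data.frame(variable = v, n_tot = sum(avail))
    if (is_binary(x)) {
      row$type <- "binary"
      for (c in seq_len(k)) {
        cnt <- sum(x == 1 & avail & labels == c)
        row[[paste0("n_cluster_", c)]] <- n_cl[c]
        row[[paste0("count_cluster_", c)]] <- cnt
        row[[paste0("pct_cluster_", c)]] <- if (n_cl[c] > 0) {
          100 * cnt / n_cl[c]
        } else NA_real_
        row[[paste0("cluster_", c)]] <- if (n_cl[c] > 0) {
          sprintf("%d (%s)", cnt, format_pct(cnt, n_cl[c]))
        } else NA_character_
      }
    } else {
      row$type <- "continuous"
      for (c in seq_len(k)) {
        xc <- x[avail & labels == c]
        row[[paste0("n_cluster_", c)]] <- n_cl[c]
        if (length(xc)) {
          q <- quantile(xc, c(0.25, 0.5, 0.75), names = FALSE)
          row[[paste0("median_cluster_", c)]] <- q[2]
          row[[paste0("q1_cluster_", c)]] <- q[1]
          row[[paste0("q3_cluster_", c)]] <- q[3]
          row[[paste0("cluster_", c)]] <-
            sprintf(paste0("%.", digits, "f (%.", digits, "f-%.", digits, "f)"),
                    q[2], q[1], q[3])
        } else {
          row[[paste0("median_cluster_", c)]] <- NA_real_
          row[[paste0("q1_cluster_", c)]] <- NA_real_
          row[[paste0("q3_cluster_", c)]] <- NA_real_
          row[[paste0("cluster_", c)]] <- NA_character_
        }
      }
    }
    row
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(unique(unlist(lapply(rows, names))), names(r))] <- NA
    r[unique(unlist(lapply(rows, names)))]
  }))
  rownames(out) <- NULL
  out
}
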