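# Synthetic GDM cohort generator.
#
# The generator draws participants from a finite mixture of latent subgroups.
# Within a subgroup each clinical input variable follows a quartile-calibrated
# distribution (see fit_quantile_distribution) and binary outcomes follow
# subgroup-conditional Bernoulli rates; rows that would not meet the IADPSG
# diagnostic criterion are resampled so every generated participant is a GDM
# case.  The shipped default configuration is calibrated to published
# three-cluster training-set profiles; a second configuration emulates an
# external-site cohort with shifted variable locations.

#' Build a cohort generator configuration
#'
#' @param n Default cohort size.
#' @param mixing_proportions Numeric vector over latent subgroups; must sum
#'   to 1 (within 1e-12).
#' @param clusters A list (one element per subgroup) of lists with elements
#'   `variables` (named list mapping each input variable to either a
#'   `gdm_dist` or a numeric `c(q1, median, q3)` triple) and `outcomes`
#'   (named numeric vector of Bernoulli rates in \[0, 1\]).
#' @param missingness Named numeric vector of per-outcome missingness rates
#'   in \[0, 1\] (inputs are never masked).
#' @param correlation Optional within-cluster correlation matrix (one
#'   matrix shared by all clusters, or a list with one per cluster) applied
#'   through a Gaussian copula; `NULL` (the default) draws variables
#'   independently within cluster.  The copula preserves every marginal's
#'   quartile calibration exactly.
#' @param seed Default integer seed for [generate_cohort()].
#' @param site Site tag stored with every generated row.
#' @return An object of class `gdm_cohort_config`.
#' @export
cohort_config <- function(n, mixing_proportions, clusters,
                          missingness = numeric(0), correlation = NULL,
                          seed = NULL, site = "synthetic") {
  if (length(clusters) != length(mixing_proportions)) {
    stop_invalid("one mixing proportion per cluster is required")
  }
  if (abs(sum(mixing_proportions) - 1) > 1e-12) {
    stop_invalid("mixing proportions must sum to 1")
  }
  if (any(mixing_proportions < 0)) stop_invalid("mixing proportions must be >= 0")
  clusters <- lapply(clusters, function(cl) {
    cl$variables <- lapply(cl$variables, function(v) {
      if (inherits(v, "gdm_dist")) v
      else fit_quantile_distribution(v[[1]], v[[2]], v[[3]])
    })
    rates <- unlist(cl$outcomes %||% numeric(0))
    if (length(rates) && (any(rates < 0) || any(rates > 1))) {
      stop_invalid("outcome rates must lie in [0, 1]")
    }
    cl$outcomes <- rates
    # proposal distributions pre-compensated for the diagnostic-constraint
    # rejection (identical to the target fit when the constraint never bites)
    cl$proposal <- compensate_gdm_truncation(cl$variables)
    cl
  })
  vars <- names(clusters[[1]]$variables)
  for (cl in clusters) {
    if (!identical(names(cl$variables), vars)) {
      stop_invalid("all clusters must define the same variables in the same order")
    }
  }
  miss <- unlist(missingness)
  if (length(miss) && (any(miss < 0) || any(miss > 1))) {
    stop_invalid("missingness rates must lie in [0, 1]")
  }
  p <- length(vars)
  chol_list <- NULL
  if (!is.null(correlation)) {
    corrs <- if (is.list(correlation)) correlation
             else rep(list(correlation), length(clusters))
    if (length(corrs) != length(clusters)) {
      stop_invalid("one correlation matrix per cluster is required")
    }
    chol_list <- lapply(corrs, function(R) {
      R <- as.matrix(R)
      if (!identical(dim(R), c(p, p)) || any(abs(R - t(R)) > 1e-12) ||
          any(abs(diag(R) - 1) > 1e-12)) {
        stop_invalid("correlation must be a symmetric ", p, "x", p,
                     " matrix with unit diagonal")
      }
      tryCatch(chol(R),
               error = function(e) stop_invalid("correlation matrix is not positive definite"))
    })
  }
  structure(list(n = as.integer(n), mixing_proportions = mixing_proportions,
                 clusters = clusters, variables = vars,
                 missingness = miss, copula_chol = chol_list,
                 seed = seed, site = site),
            class = "gdm_cohort_config")
}

#' Default training-set-like cohort configuration
#'
#' Three latent GDM subgroups calibrated to published training-set cluster
#' profiles: subgroup 1 (21.3%) with obesity and globally elevated OGTT
#' glucose, subgroup 2 (35.3%) with intermediate BMI and elevated fasting
#' glucose, subgroup 3 (43.4%) with normal BMI and a post-load glucose
#' pattern.  Binary outcome rates (glucose-lowering medication, LGA,
#' birthweight > 4000 g, pre-eclampsia) and per-outcome availability mirror
#' the same profiles.
#'
#' @param n Cohort size (default 1154, the published training-set size).
#' @param seed Default seed used by [generate_cohort()].
#' @return A `gdm_cohort_config`.
#' @export
default_cohort_config <- function(n = 1154, seed = NULL) {
  clusters <- list(
    list( # subgroup 1: obesity, highest glucose throughout the OGTT
      variables = list(
        age    = c(30.25, 34, 37),
        bmipg  = c(27.90, 32.30, 38.70),
        ogtt0  = c(5.61, 5.99, 6.44),
        ogtt60 = c(10.66, 11.60, 12.81),
        ogtt120 = c(7.71, 8.66, 10.27)),
      outcomes = c(drugs_prescribed = 84 / 212, lga = 75 / 246,
                   birthweight_gt4000 = 46 / 233, preeclampsia = 18 / 246)),
    list( # subgroup 2: intermediate BMI, elevated fasting glucose
      variables = list(
        age    = c(28, 33, 37),
        bmipg  = c(23.25, 27.70, 32.85),
        ogtt0  = c(5.22, 5.33, 5.61),
        ogtt60 = c(7.19, 8.16, 9.10),
        ogtt120 = c(5.52, 6.22, 6.94)),
      outcomes = c(drugs_prescribed = 47 / 364, lga = 91 / 406,
                   birthweight_gt4000 = 47 / 389, preeclampsia = 27 / 407)),
    list( # subgroup 3: normal BMI, post-load hyperglycaemia
      variables = list(
        age    = c(30, 34, 38),
        bmipg  = c(22.00, 24.90, 28.00),
        ogtt0  = c(4.66, 5.05, 5.33),
        ogtt60 = c(9.71, 10.32, 11.16),
        ogtt120 = c(7.21, 8.32, 9.16)),
      outcomes = c(drugs_prescribed = 44 / 440, lga = 110 / 501,
                   birthweight_gt4000 = 62 / 472, preeclampsia = 21 / 500))
  )
  cohort_config(
    n = n,
    mixing_proportions = c(246, 407, 501) / 1154,
    clusters = clusters,
    missingness = c(drugs_prescribed = 1 - 1016 / 1154,
                    lga = 1 - 1153 / 1154,
                    birthweight_gt4000 = 1 - 1094 / 1154,
                    preeclampsia = 1 - 1153 / 1154),
    seed = seed, site = "synthetic-berlin")
}

#' External-validation-like cohort configuration
#'
#' Same three-subgroup structure as [default_cohort_config()] but with the
#' variable locations, mixing proportions and treatment-outcome rates of an
#' external site whose case mix differs (lower fasting glucose, different
#' cluster proportions, higher medication rates) — the situation faced when
#' transferring a fitted model to another clinic.
#'
#' @param n Cohort size (default 769).
#' @param seed Default seed used by [generate_cohort()].
#' @return A `gdm_cohort_config`.
#' @export
vienna_like_cohort_config <- function(n = 769, seed = NULL) {
  clusters <- list(
    list(
      variables = list(
        age    = c(30, 34, 37),
        bmipg  = c(29.36, 33.30, 38.51),
        ogtt0  = c(5.49, 5.77, 6.16),
        ogtt60 = c(10.60, 11.65, 12.54),
        ogtt120 = c(8.21, 9.05, 10.38)),
      outcomes = c(drugs_prescribed = 87 / 113, insulin = 77 / 113,
                   nph_insulin = 62 / 113, rapid_insulin = 39 / 113,
                   lga = 23 / 113)),
    list(
      variables = list(
        age    = c(27, 31, 35),
        bmipg  = c(24.00, 27.04, 32.11),
        ogtt0  = c(5.16, 5.33, 5.55),
        ogtt60 = c(7.03, 8.10, 9.38),
        ogtt120 = c(5.31, 5.88, 6.66)),
      outcomes = c(drugs_prescribed = 98 / 242, insulin = 80 / 243,
                   nph_insulin = 78 / 243, rapid_insulin = 16 / 241,
                   lga = 45 / 241)),
    list(
      variables = list(
        age    = c(30, 34, 36),
        bmipg  = c(22.25, 24.98, 27.97),
        ogtt0  = c(4.50, 4.77, 5.16),
        ogtt60 = c(9.93, 10.49, 11.10),
        ogtt120 = c(7.16, 8.16, 9.00)),
      outcomes = c(drugs_prescribed = 148 / 407, insulin = 119 / 410,
                   nph_insulin = 101 / 409, rapid_insulin = 60 / 409,
                   lga = 47 / 410))
  )
  cohort_config(
    n = n,
    mixing_proportions = c(113, 244, 412) / 769,
    clusters = clusters,
    missingness = c(drugs_prescribed = 1 - 762 / 769,
                    insulin = 1 - 766 / 769,
                    nph_insulin = 1 - 765 / 769,
                    rapid_insulin = 1 - 763 / 769,
                    lga = 1 - 764 / 769),
    seed = seed, site = "synthetic-vienna")
}

# Rejection under the diagnostic criterion removes the joint lower-left
# corner of the OGTT distribution, which would bias the accepted glucose
# marginals upward (by up to ~2.5% on the median for a mostly-post-load
# cluster).  Under within-cluster independence the accepted marginal CDF has
# the closed form
#   F_acc(x) = (F(x) - F(min(x, th_v)) * prod_{w != v} F_w(th_w)) / (1 - prod F(th))
# so we pre-compensate: iterate adjusting each OGTT proposal's quartile
# triple until the *accepted* quartiles hit the printed targets.
compensate_gdm_truncation <- function(variables, tol = 1e-9,
                                      max_iter = 60L) {
  ogtt <- names(IADPSG_THRESHOLDS)
  if (!all(ogtt %in% names(variables))) return(variables)
  proposal <- variables
  prop_targets <- lapply(variables[ogtt], function(s) s$targets)
  for (iter in seq_len(max_iter)) {
    Fth <- vapply(ogtt, function(v) {
      pdist_gdm_dist(proposal[[v]], IADPSG_THRESHOLDS[[v]])
    }, numeric(1))
    p_all_below <- prod(Fth)
    if (p_all_below < 1e-8) break
    # near-total rejection: leave the proposal alone and let generation
    # raise the config-infeasible error
    if (p_all_below > 0.95) return(variables)
    max_err <- 0
    for (v in ogtt) {
      sp <- proposal[[v]]
      th <- IADPSG_THRESHOLDS[[v]]
      prod_other <- prod(Fth[setdiff(ogtt, v)])
      Z <- 1 - p_all_below
      f_acc <- function(x) {
        (pdist_gdm_dist(sp, x) -
           pdist_gdm_dist(sp, pmin(x, th)) * prod_other) / Z
      }
      lo <- quantile_gdm_dist(sp, 1e-10)
      hi <- quantile_gdm_dist(sp, 1 - 1e-10)
      acc_q <- tryCatch(vapply(c(0.25, 0.5, 0.75), function(p) {
        stats::uniroot(function(x) f_acc(x) - p, c(lo, hi),
                       tol = 1e-12)$root
      }, numeric(1)), error = function(e) NULL)
      if (is.null(acc_q)) return(variables)
      target <- variables[[v]]$targets
      err <- target - acc_q
      max_err <- max(max_err, max(abs(err) / pmax(abs(target), 1)))
      new_t <- prop_targets[[v]] + err
      if (new_t[1] < new_t[2] && new_t[2] < new_t[3]) {
        prop_targets[[v]] <- new_t
        proposal[[v]] <- fit_quantile_distribution(new_t[1], new_t[2],
                                                   new_t[3])
      }
    }
    if (max_err < tol) break
  }
  proposal
}

# Draw `n` rows of input variables for one cluster spec, resampling rows that
# violate the diagnostic criterion or plausibility ranges.  Optional Gaussian
# copula: correlated standard normals are pushed through each margin's
# quantile function, so the quartile calibration is unaffected.
draw_cluster_inputs <- function(cl, n, copula_chol = NULL, max_tries = 200L) {
  specs <- cl$proposal %||% cl$variables
  vars <- names(specs)
  p <- length(vars)
  out <- matrix(NA_real_, nrow = n, ncol = p, dimnames = list(NULL, vars))
  need <- seq_len(n)
  drawn <- 0
  accepted <- 0
  for (try in seq_len(max_tries)) {
    if (!length(need)) break
    m <- length(need)
    if (is.null(copula_chol)) {
      block <- vapply(specs, rdist_gdm_dist, numeric(m), n = m)
      block <- matrix(block, nrow = m, dimnames = list(NULL, vars))
    } else {
      Zn <- matrix(rnorm(m * p), m, p) %*% copula_chol
      U <- pnorm(Zn)
      block <- vapply(seq_len(p), function(j) {
        quantile_gdm_dist(specs[[j]], U[, j])
      }, numeric(m))
      block <- matrix(block, nrow = m, dimnames = list(NULL, vars))
    }
    ok <- rep(TRUE, m)
    for (v in vars) {
      rng <- PLAUSIBLE_RANGES[[v]] %||% c(0, Inf)
      ok <- ok & block[, v] > rng[1] & block[, v] < rng[2]
    }
    if (all(c("ogtt0", "ogtt60", "ogtt120") %in% vars)) {
      ok <- ok & meets_gdm_criteria(block[, "ogtt0"], block[, "ogtt60"],
                                    block[, "ogtt120"])
    }
    drawn <- drawn + m
    accepted <- accepted + sum(ok)
    out[need[ok], ] <- block[ok, , drop = FALSE]
    need <- need[!ok]
    if (try >= 5 && accepted / drawn < 0.01) {
      stop_invalid("cohort configuration infeasible: rejection rate above 99%")
    }
  }
  if (length(need)) {
    stop_invalid("cohort configuration infeasible: constraint resampling did not converge")
  }
  attr(out, "acceptance_rate") <- if (drawn > 0) accepted / drawn else 1
  out
}

#' Generate a synthetic GDM cohort
#'
#' Draws `n` participants: latent subgroup from the mixing proportions, input
#' variables independently from each subgroup's quartile-calibrated
#' distributions (rows violating the IADPSG criterion or plausibility ranges
#' are resampled), binary outcomes from subgroup-conditional Bernoulli rates,
#' then per-outcome missingness.  Fully reproducible from `seed`.
#'
#' @param config A `gdm_cohort_config`.
#' @param n Number of rows (defaults to `config$n`).
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A `data.frame` with columns `id`, the input variables, the
#'   outcome columns (0/1/NA), `true_cluster` (the latent subgroup, for
#'   recovery checks only) and `site`.  Attribute `acceptance_rates` records
#'   the per-subgroup rejection-sampling acceptance rate.
#' @export
generate_cohort <- function(config, n = config$n, seed = config$seed) {
  stopifnot(inherits(config, "gdm_cohort_config"))
  n <- as.integer(n)
  if (n < 0) stop_invalid("n must be non-negative")
  vars <- config$variables
  outcome_names <- unique(unlist(lapply(config$clusters,
                                        function(cl) names(cl$outcomes))))
  empty <- data.frame(id = integer(0))
  for (v in vars) empty[[v]] <- numeric(0)
  for (o in outcome_names) empty[[o]] <- integer(0)
  empty$true_cluster <- integer(0)
  empty$site <- character(0)
  if (n == 0) return(empty)

  local_seed(seed, {
    k <- length(config$clusters)
    z <- sample.int(k, n, replace = TRUE, prob = config$mixing_proportions)
    tab <- empty[rep(1L, n), , drop = FALSE]
    rownames(tab) <- NULL
    tab$id <- seq_len(n)
    tab$true_cluster <- z
    tab$site <- config$site
    acc <- rep(NA_real_, k)
    for (c_idx in seq_len(k)) {
      rows <- which(z == c_idx)
      if (!length(rows)) next
      block <- draw_cluster_inputs(config$clusters[[c_idx]], length(rows),
                                   config$copula_chol[[c_idx]])
      acc[c_idx] <- attr(block, "acceptance_rate")
      for (v in vars) tab[rows, v] <- block[, v]
      rates <- config$clusters[[c_idx]]$outcomes
      for (o in names(rates)) {
        tab[rows, o] <- rbinom(length(rows), 1L, rates[[o]])
      }
    }
    for (o in setdiff(outcome_names, unlist(lapply(config$clusters,
                                                   function(cl) names(cl$outcomes))))) {
      tab[[o]] <- NA_integer_
    }
    tab <- inject_missingness(tab, config$missingness, seed = NULL)
    attr(tab, "acceptance_rates") <- acc
    tab
  })
}

#' Apply per-outcome missingness to a cohort table
#'
#' Each listed outcome cell is independently set to `NA` with its rate;
#' input variables are never masked.
#'
#' @param table A cohort `data.frame`.
#' @param rates Named numeric vector of rates in \[0, 1\]; names are outcome
#'   columns of `table`.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return The table with missingness applied.
#' @export
inject_missingness <- function(table, rates, seed = NULL) {
  if (!length(rates)) return(table)
  rates <- unlist(rates)
  if (any(rates < 0) || any(rates > 1)) {
    stop_invalid("missingness rates must lie in [0, 1]")
  }
  bad <- intersect(names(rates), GDM_INPUT_VARIABLES)
  if (length(bad)) {
    stop_invalid("input variables cannot be masked: ", paste(bad, collapse = ", "))
  }
  local_seed(seed, {
    for (o in names(rates)) {
      if (!o %in% names(table)) next
      mask <- runif(nrow(table)) < rates[[o]]
      table[mask, o] <- NA
    }
    table
  })
}

#' Read / write a cohort table as CSV
#'
#' CSV with header, UTF-8, `.` decimal separator, empty cell = missing.
#'
#' @param table A cohort `data.frame`.
#' @param path File path.
#' @return `read_cohort` returns the `data.frame`; `write_cohort` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(table, path) {
  write.csv(table, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  read.csv(path, fileEncoding = "UTF-8")
}

#' Read / write a cohort configuration as YAML
#'
#' The on-disk form stores each variable as its `[q1, median, q3]` triple.
#'
#' @param config A `gdm_cohort_config`.
#' @param path File path.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "gdm_cohort_config"))
  lst <- list(
    n = config$n,
    seed = config$seed,
    site = config$site,
    mixing_proportions = as.numeric(config$mixing_proportions),
    missingness = as.list(config$missingness),
    clusters = lapply(config$clusters, function(cl) {
      list(variables = lapply(cl$variables,
                              function(sp) as.numeric(sp$targets)),
           outcomes = as.list(cl$outcomes))
    }))
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  lst <- yaml::read_yaml(path)
  cohort_config(
    n = lst$n,
    mixing_proportions = unlist(lst$mixing_proportions),
    clusters = lapply(lst$clusters, function(cl) {
      list(variables = lapply(cl$variables, unlist),
           outcomes = unlist(cl$outcomes) %||% numeric(0))
    }),
    missingness = unlist(lst$missingness) %||% numeric(0),
    seed = lst$seed, site = lst$site %||% "synthetic")
}

#' @export
print.gdm_cohort_config <- function(x, ...) {
  cat(sprintf("<gdm_cohort_config> %d clusters, n = %d, variables: %s\n",
              length(x$clusters), x$n, paste(x$variables, collapse = ", ")))
  cat(sprintf("  mixing: %s\n",
              paste(sprintf("%.3f", x$mixing_proportions), collapse = " / ")))
  invisible(x)
}
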