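# Distribution specs calibrated to a (Q1, median, Q3) summary.
#
# Clinical tables report continuous variables as median and IQR.  To build a
# generator around such tables we fit, per cluster and variable, a
# three-parameter distribution whose quartiles reproduce the printed triple
# exactly:
#   * right-skewed triple (q1 + q3 > 2*median): shifted log-normal
#       X = c + exp(Y), Y ~ N(mu, sigma), with
#       c = (q1*q3 - median^2) / (q1 + q3 - 2*median),
#     which makes (q1-c), (median-c), (q3-c) a geometric progression so the
#     log-scale quartiles are symmetric and all three targets are matched.
#   * left-skewed triple: the reflected form X = c - exp(Y) with the same
#     shift formula (c lands above q3); again exact.
#   * symmetric triple: N(median, IQR / (2 * qnorm(0.75))).
# Degenerate shifts (non-finite, or support touching q1) fall back to the
# normal fit, flagged so the calibration error is visible to callers.

Z75 <- qnorm(0.75)

#' Fit a distribution to a quartile triple
#'
#' Returns a distribution specification whose 25/50/75% quantiles equal
#' `q1`, `med`, `q3`.  Skewed triples are fitted with a (possibly reflected)
#' shifted log-normal; symmetric triples with a normal distribution.
#'
#' @param q1,med,q3 Target quartiles in the variable's units; must be
#'   strictly increasing.
#' @param sym_tol Relative asymmetry below which the triple is treated as
#'   symmetric (normal fit).
#' @return An object of class `gdm_dist` with elements `family`
#'   (`"shifted-lognormal"` or `"normal"`), parameters, the `targets`
#'   triple, and `fallback` (`TRUE` when a skewed triple had to be fitted
#'   with the symmetric family).
#' @examples
#' spec <- fit_quantile_distribution(5.61, 5.99, 6.44)
#' quantile_gdm_dist(spec, c(0.25, 0.5, 0.75))
#' @export
fit_quantile_distribution <- function(q1, med, q3, sym_tol = 1e-8) {
  if (!is.finite(q1) || !is.finite(med) || !is.finite(q3)) {
    stop_invalid("quartile targets must be finite")
  }
  if (!(q1 < med && med < q3)) {
    stop_invalid("quartile targets must satisfy q1 < median < q3 (got ",
                 q1, ", ", med, ", ", q3, ")")
  }
  targets <- c(q1 = q1, median = med, q3 = q3)
  iqr <- q3 - q1
  asym <- q1 + q3 - 2 * med

  normal_spec <- function(fallback) {
    structure(list(family = "normal", mean = med, sd = iqr / (2 * Z75),
                   targets = targets, fallback = fallback),
              class = "gdm_dist")
  }
  if (abs(asym) <= sym_tol * iqr) return(normal_spec(FALSE))

  # Exact factored forms (no cancellation even for |shift| >> IQR):
  #   |med - shift|  = (med-q1)(q3-med) / |asym|
  #   |q1   - shift| = (med-q1)^2       / |asym|
  #   |q3   - shift| = (q3-med)^2       / |asym|
  lo <- med - q1
  hi <- q3 - med
  shift <- med - sign(asym) * lo * hi / abs(asym)
  if (!is.finite(shift)) return(normal_spec(TRUE))
  meanlog <- log(lo) + log(hi) - log(abs(asym))
  if (asym > 0) {
    # right skew: support (shift, Inf), shift < q1 always
    sdlog <- (log(hi) - log(lo)) / Z75
    sign <- 1
  } else {
    # left skew: reflected support (-Inf, shift), shift > q3 always
    sdlog <- (log(lo) - log(hi)) / Z75
    sign <- -1
  }
  structure(list(family = "shifted-lognormal", shift = shift, sign = sign,
                 meanlog = meanlog, sdlog = sdlog, median = med,
                 targets = targets, fallback = FALSE),
            class = "gdm_dist")
}

#' Quantile function of a fitted quartile distribution
#'
#' @param spec A `gdm_dist` from [fit_quantile_distribution()].
#' @param p Probabilities.
#' @return Quantiles in the variable's units.
#' @export
quantile_gdm_dist <- function(spec, p) {
  stopifnot(inherits(spec, "gdm_dist"), all(p >= 0 & p <= 1))
  if (spec$family == "normal") {
    return(qnorm(p, spec$mean, spec$sd))
  }
  # expm1 form: q(p) = median + sign * (median - shift) * expm1(z * sdlog)
  # is exact algebra but keeps precision when |shift| >> IQR
  scale <- exp(spec$meanlog)
  if (spec$sign > 0) {
    spec$median + scale * expm1(qnorm(p) * spec$sdlog)
  } else {
    spec$median - scale * expm1(qnorm(1 - p) * spec$sdlog)
  }
}

#' Cumulative distribution function of a fitted quartile distribution
#'
#' @inheritParams quantile_gdm_dist
#' @param x Values in the variable's units.
#' @export
pdist_gdm_dist <- function(spec, x) {
  stopifnot(inherits(spec, "gdm_dist"))
  if (spec$family == "normal") return(pnorm(x, spec$mean, spec$sd))
  if (spec$sign > 0) {
    ifelse(x <= spec$shift, 0,
           pnorm((log(pmax(x - spec$shift, .Machine$double.xmin)) -
                    spec$meanlog) / spec$sdlog))
  } else {
    ifelse(x >= spec$shift, 1,
           pnorm((log(pmax(spec$shift - x, .Machine$double.xmin)) -
                    spec$meanlog) / spec$sdlog,
                 lower.tail = FALSE))
  }
}

# Random draws; runs in the caller's RNG stream.
rdist_gdm_dist <- function(spec, n) {
  stopifnot(inherits(spec, "gdm_dist"))
  if (spec$family == "normal") return(rnorm(n, spec$mean, spec$sd))
  spec$shift + spec$sign * rlnorm(n, spec$meanlog, spec$sdlog)
}

#' @export
print.gdm_dist <- function(x, ...) {
  t <- x$targets
  cat(sprintf("<gdm_dist %s%s> quartiles %.4g / %.4g / %.4g\n",
              x$family,
              if (isTRUE(x$fallback)) " (fallback)" else "",
              t[1], t[2], t[3]))
  invisible(x)
}
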