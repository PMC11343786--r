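#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov anova as.dist chisq.test coef cutree dist fisher.test
#'   glm hclust kmeans kruskal.test median pchisq pf pnorm prcomp pt qnorm
#'   quantile rbinom rlnorm rnorm runif sd setNames shapiro.test vcov
#'   complete.cases binomial logLik rmultinom var
#' @importFrom utils read.csv write.csv head
NULL

# Run `expr` under a local RNG state seeded with `seed`; global RNG untouched.
# seed = NULL runs under the current RNG stream.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Spawn a deterministic sub-seed from a base seed (kept below 2^31).
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + offset) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(..., call. = FALSE)

# Variables used as clustering inputs, fixed order.
GDM_INPUT_VARIABLES <- c("age", "bmipg", "ogtt0", "ogtt60", "ogtt120")

# IADPSG diagnostic thresholds for the 75 g OGTT (mmol/l at 0/60/120 min).
IADPSG_THRESHOLDS <- c(ogtt0 = 5.1, ogtt60 = 10, ogtt120 = 8.5)

# Plausibility ranges for clinical inputs (units: years, kg/m^2, mmol/l).
PLAUSIBLE_RANGES <- list(
  age    = c(12, 60),
  bmipg  = c(12, 70),
  ogtt0  = c(2, 25),
  ogtt60 = c(2, 25),
  ogtt120 = c(2, 25)
)

#' Does a row of OGTT values meet the IADPSG GDM criteria?
#'
#' A participant is diagnosed with gestational diabetes when at least one of
#' the three OGTT glucose values reaches its threshold: fasting >= 5.1,
#' 60 min >= 10, or 120 min >= 8.5 mmol/l.
#'
#' @param ogtt0,ogtt60,ogtt120 Numeric vectors of glucose values (mmol/l).
#' @return Logical vector, `TRUE` where the diagnostic criterion is met.
#' @export
meets_gdm_criteria <- function(ogtt0, ogtt60, ogtt120) {
  ogtt0 >= IADPSG_THRESHOLDS[["ogtt0"]] |
    ogtt60 >= IADPSG_THRESHOLDS[["ogtt60"]] |
    ogtt120 >= IADPSG_THRESHOLDS[["ogtt120"]]
}
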