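# Train/test partitioning, input-variable sets, and z-score standardisation
# with parameters learned on training data only.

#' Input-variable sets considered for clustering
#'
#' Four candidate sets of routine clinical inputs: all five variables; the
#' same without age; age + BMI + mean OGTT glucose; age + BMI + fasting
#' glucose only.
#'
#' @param id One of `"full5"`, `"no-age"`, `"age-bmi-meanOGTT"`,
#'   `"age-bmi-fasting"`.
#' @return Character vector of member variable names (the mean-OGTT set uses
#'   the derived column `mean_ogtt`, see [add_derived_variables()]).
#' @export
variable_set <- function(id = c("full5", "no-age", "age-bmi-meanOGTT",
                                "age-bmi-fasting")) {
  id <- match.arg(id)
  switch(id,
    "full5"            = c("age", "bmipg", "ogtt0", "ogtt60", "ogtt120"),
    "no-age"           = c("bmipg", "ogtt0", "ogtt60", "ogtt120"),
    "age-bmi-meanOGTT" = c("age", "bmipg", "mean_ogtt"),
    "age-bmi-fasting"  = c("age", "bmipg", "ogtt0"))
}

#' Add derived input variables to a cohort table
#'
#' Currently only `mean_ogtt`, the arithmetic mean of the three OGTT glucose
#' values, computed before any standardisation.
#'
#' @param table A cohort `data.frame`.
#' @export
add_derived_variables <- function(table) {
  if (all(c("ogtt0", "ogtt60", "ogtt120") %in% names(table))) {
    table$mean_ogtt <- (table$ogtt0 + table$ogtt60 + table$ogtt120) / 3
  }
  table
}

#' Randomly partition a cohort into training and test sets
#'
#' Disjoint, exhaustive row split with the training share rounded down
#' (`floor(n * train_fraction)`), remainder to test; e.g. 1649 rows at 0.7
#' give 1154 training / 495 test rows.
#'
#' @param table A cohort `data.frame` with at least 2 rows.
#' @param train_fraction Fraction in (0, 1) assigned to training.
#' @param seed Integer seed making the split reproducible.
#' @return `list(train = , test = )`.
#' @export
split_train_test <- function(table, train_fraction = 0.7, seed = NULL) {
  n <- nrow(table)
  if (n < 2) stop_invalid("need at least 2 rows to split")
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop_invalid("train_fraction must lie strictly between 0 and 1")
  }
  n_train <- floor(n * train_fraction)
  if (n_train < 1 || n_train >= n) {
    stop_invalid("split would leave an empty partition")
  }
  idx <- local_seed(seed, sample.int(n, n_train))
  list(train = table[sort(idx), , drop = FALSE],
       test = table[setdiff(seq_len(n), sort(idx)), , drop = FALSE])
}

#' Learn standardisation parameters on training data
#'
#' Column means and SDs (denominator n - 1) of the selected input variables.
#' The five inputs carry incommensurate units (years, kg/m^2, mmol/l), so
#' distances are only meaningful in this standardised space; test data and
#' new patients must be scaled with the *training* parameters.
#'
#' @param train Training cohort `data.frame` (no missing values in the
#'   selected variables).
#' @param variables Character vector of input-variable names (or a variable
#'   set id accepted by [variable_set()]).
#' @return A `gdm_scaling` object with `center`, `scale` and `variables`.
#' @export
standardize_fit <- function(train, variables = "full5") {
  if (length(variables) == 1 && !variables %in% names(train)) {
    variables <- variable_set(variables)
  }
  train <- add_derived_variables(train)
  missing_cols <- setdiff(variables, names(train))
  if (length(missing_cols)) {
    stop_invalid("variables absent from table: ", paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(train[, variables, drop = FALSE])
  if (nrow(X) < 2) stop_invalid("need at least 2 rows to standardise")
  if (anyNA(X)) stop_invalid("missing values in input variables; complete cases required")
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  if (any(scale <= 0)) {
    stop_invalid("zero-variance input variable: ",
                 paste(variables[scale <= 0], collapse = ", "))
  }
  structure(list(center = center, scale = scale, variables = variables),
            class = "gdm_scaling")
}

#' Apply standardisation parameters to a table
#'
#' Computes `z = (x - center) / scale` columnwise.  Rows with a missing
#' input value are dropped; their identifiers are recorded in the
#' `"rejected"` attribute of the result.
#'
#' @param table A cohort `data.frame` (or a matrix with named columns).
#' @param params A `gdm_scaling` from [standardize_fit()].
#' @return Numeric matrix of z-values, columns in the scaler's variable
#'   order, with attribute `"rejected"` (row ids dropped for missingness).
#' @export
standardize_apply <- function(table, params) {
  stopifnot(inherits(params, "gdm_scaling"))
  table <- add_derived_variables(as.data.frame(table))
  missing_cols <- setdiff(params$variables, names(table))
  if (length(missing_cols)) {
    stop_invalid("variables absent from table: ", paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(table[, params$variables, drop = FALSE])
  keep <- complete.cases(X)
  rejected <- if (all(keep)) integer(0) else {
    ids <- if ("id" %in% names(table)) table$id[!keep] else which(!keep)
    warning(sum(!keep), " row(s) dropped for missing input values")
    ids
  }
  Z <- sweep(sweep(X[keep, , drop = FALSE], 2, params$center), 2,
             params$scale, `/`)
  attr(Z, "rejected") <- rejected
  Z
}

# Inverse transform, used to report centroids in clinical units.
destandardize <- function(Z, params) {
  out <- sweep(sweep(Z, 2, params$scale, `*`), 2, params$center, `+`)
  attr(out, "rejected") <- NULL
  out
}

#' @export
print.gdm_scaling <- function(x, ...) {
  cat("<gdm_scaling>\n")
  print(rbind(center = x$center, scale = x$scale))
  invisible(x)
}
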