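# Orchestration: end-to-end runs (simulate -> split -> fit/select ->
# validate -> outcomes) and the bedside primitive of the whole exercise —
# assigning a new patient to a cluster from the portable model artifact.

#' Assign a new patient to a cluster
#'
#' Standardises the patient's five inputs with the model's training scaler
#' and assigns the cluster whose centroid is nearest (the model's distance
#' metric; ties to the lowest cluster index).  Inputs are checked against
#' plausibility ranges (age 12-60 years, BMI 12-70 kg/m^2, OGTT glucose
#' 2-25 mmol/l) and assignments are refused for missing or out-of-range
#' values.
#'
#' @param model A `gdm_cluster_model` (e.g. from [read_model_json()]).
#' @param record A one-row `data.frame`, list or named vector with the
#'   model's input variables.
#' @return List with `cluster` (the assigned label) and `distances`
#'   (standardised distance to every centroid).
#' @examples
#' \donttest{
#' cohort <- generate_cohort(default_cohort_config(seed = 1))
#' fit <- fit_cohort_clusters(cohort, k = 3, seed = 1)
#' assign_patient(fit$model,
#'                c(age = 34, bmipg = 32.3, ogtt0 = 5.99,
#'                  ogtt60 = 11.6, ogtt120 = 8.66))
#' }
#' @export
assign_patient <- function(model, record) {
  stopifnot(inherits(model, "gdm_cluster_model"))
  rec <- as.data.frame(as.list(record))
  rec <- add_derived_variables(rec)
  base_vars <- intersect(GDM_INPUT_VARIABLES, union(model$scaling$variables,
                                                    names(rec)))
  for (v in setdiff(model$scaling$variables, names(rec))) {
    stop_invalid("missing input variable: ", v)
  }
  check_vars <- intersect(names(PLAUSIBLE_RANGES),
                          union(model$scaling$variables, base_vars))
  for (v in intersect(check_vars, names(rec))) {
    x <- rec[[v]]
    if (is.na(x)) stop_invalid("missing value for ", v)
    rng <- PLAUSIBLE_RANGES[[v]]
    if (x <= rng[1] || x >= rng[2]) {
      stop_invalid(v, " = ", x, " outside the plausible range (",
                   rng[1], ", ", rng[2], ")")
    }
  }
  z <- (unlist(rec[model$scaling$variables]) - model$scaling$center) /
    model$scaling$scale
  D <- centroid_distances(matrix(z, nrow = 1), model$centroids,
                          model$distance)
  list(cluster = which.min(D[1, ]), distances = as.numeric(D[1, ]))
}

#' Project standardised inputs onto the first two principal components
#'
#' Used for the cluster scatter plots: mean-centred projection onto the
#' first two principal components, with explained-variance fractions.
#'
#' @param X Standardised input matrix (p >= 2, rank >= 2).
#' @return List with `scores` (n x 2), `explained` (fractions for PC1/PC2)
#'   and `rotation`.
#' @export
pca_project <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop_invalid("PCA projection needs >= 2 variables")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 2 || pc$sdev[2] < .Machine$double.eps^0.5 * pc$sdev[1]) {
    stop_invalid("input matrix has rank < 2")
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, 1:2, drop = FALSE], explained = expl[1:2],
       rotation = pc$rotation[, 1:2, drop = FALSE])
}

#' Run the full subtyping pipeline end to end
#'
#' Generates (or accepts) a cohort, splits it, selects and gates a
#' clustering model on the training set, validates it internally (bootstrap
#' stability, twofold cross-validation) and externally (centroid transfer
#' versus refit on the held-out test set), compares outcomes across
#' clusters and emits profile tables.  Idempotent given the seed.
#'
#' @param cohort A cohort `data.frame`, or `NULL` to simulate from
#'   `config`.
#' @param config A `gdm_cohort_config` used when `cohort` is `NULL`
#'   (default [default_cohort_config()]).
#' @param outcomes Outcome columns to analyse (defaults to every 0/1 column
#'   of the cohort).
#' @param variable_set_id,roster,k_range,gates,B_gap,B_boot,n_starts Passed
#'   to [select_model()].
#' @param train_fraction Training share of the split.
#' @param seed Integer seed driving every stochastic step.
#' @param out_dir Optional directory; when given, the model JSON and all
#'   reports are written there.
#' @return List (`gdm_run`) with `selection`, `model`, `training`
#'   (partition, profile, outcome comparisons), `crossval`, `external`,
#'   `pca`, and a `manifest` recording configuration and seeds.
#' @export
run_end_to_end <- function(cohort = NULL, config = default_cohort_config(),
                           outcomes = NULL, variable_set_id = "full5",
                           roster = default_algorithm_roster(),
                           k_range = 2:8,
                           gates = list(jaccard = 0.75, silhouette = 0,
                                        alpha = 0.05),
                           train_fraction = 0.7, B_gap = 50, B_boot = 50,
                           n_starts = 25, seed = 1, out_dir = NULL) {
  if (!length(roster)) stop_invalid("empty algorithm roster")
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  tick <- function(name) {
    stages[[name]] <<- proc.time()[["elapsed"]] - t0
  }
  if (is.null(cohort)) {
    cohort <- generate_cohort(config, seed = derive_seed(seed, 1))
  }
  tick("simulate")
  if (is.null(outcomes)) {
    outcomes <- names(cohort)[vapply(names(cohort), function(v) {
      !v %in% c("id", "true_cluster", "site", GDM_INPUT_VARIABLES,
                "mean_ogtt") && is_binary(cohort[[v]])
    }, logical(1))]
  }
  split <- split_train_test(cohort, train_fraction, seed = derive_seed(seed, 2))
  tick("split")
  selection <- select_model(split$train, variable_set_id = variable_set_id,
                            roster = roster, k_range = k_range,
                            gates = gates, B_gap = B_gap, B_boot = B_boot,
                            n_starts = n_starts, seed = derive_seed(seed, 3))
  tick("select")
  if (is.null(selection$model)) {
    return(structure(list(selection = selection, model = NULL,
                          status = selection$status,
                          manifest = list(seed = seed, stages = stages)),
                     class = "gdm_run"))
  }
  model <- selection$model
  training <- list(
    partition = selection$partition,
    profile = cluster_profile(split$train, selection$partition$labels),
    outcomes = compare_outcomes(split$train, selection$partition$labels,
                                outcomes))
  tick("outcomes")
  crossval <- twofold_crossval(split$train, model, selection$partition,
                               outcomes = outcomes,
                               n_starts = n_starts,
                               seed = derive_seed(seed, 4))
  tick("crossval")
  external <- external_validate(model, split$test, n_starts = n_starts,
                                seed = derive_seed(seed, 5))
  tick("external")
  Z <- standardize_apply(split$train, model$scaling)
  pca <- pca_project(Z)
  tick("pca")
  run <- structure(list(
    selection = selection, model = model, status = "accepted",
    cohort = cohort, split = split, training = training,
    crossval = crossval, external = external, pca = pca,
    manifest = list(seed = seed,
                    derived_seeds = vapply(1:5, function(i) derive_seed(seed, i),
                                           integer(1)),
                    variable_set = variable_set_id,
                    gates = gates, k_range = k_range,
                    train_fraction = train_fraction,
                    B_gap = B_gap, B_boot = B_boot, n_starts = n_starts,
                    package_version = as.character(utils::packageVersion("gdmclust")),
                    stages = stages)),
    class = "gdm_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_model_json(model, file.path(out_dir, "model.json"))
    jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(training$profile, file.path(out_dir, "training_profile.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(jaccard = external$jaccard, ari = external$ari,
           accuracy = external$accuracy,
           proportion_chisq_p = external$proportion_chisq_p),
      file.path(out_dir, "external_validation.json"),
      auto_unbox = TRUE, digits = NA)
  }
  run
}

#' @export
print.gdm_run <- function(x, ...) {
  cat("<gdm_run>", x$status, "\n")
  if (!is.null(x$model)) {
    cat(sprintf("  model: %s, k = %d; cluster sizes %s\n", x$model$algorithm,
                x$model$k, paste(x$model$sizes, collapse = "/")))
    cat(sprintf("  external validation: ARI = %.3f, accuracy = %.1f%%\n",
                x$external$ari, 100 * x$external$accuracy))
  }
  invisible(x)
}
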