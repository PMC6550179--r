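#' Configuration for an end-to-end run
#'
#' One master seed drives everything: the cohort simulation, fold
#' shuffling, and every per-fold forest. Stage seeds are derived
#' deterministically from it, so a config fully reproduces a run.
#'
#' @param n_high,n_low Cohort sizes.
#' @param duration_s,rate_hz Tracing length and sampling rate.
#' @param seed Master seed.
#' @param archetype_overrides Overrides passed to [make_archetypes()].
#' @param window_s,overlap,vm_std_threshold,min_walking_fraction
#'   Preprocessing parameters.
#' @param acc_lag Autocorrelation lag mode for [signal_features()].
#' @param k Cross-validation folds.
#' @param group_by_subject,stratified Fold-assignment modes.
#' @param positive Positive-class label for the metrics.
#' @param n_trees,max_depth Forest parameters.
#' @param importance_sets Feature-set ids for which mean-decrease-
#'   impurity importance is computed on a forest refit to all instances.
#' @param spot_check Whether to run the default-parameter classifier
#'   comparison.
#' @return A `run_config` list.
#' @export
run_config <- function(n_high = 19, n_low = 48, duration_s = 320,
                       rate_hz = 30, seed = 1,
                       archetype_overrides = list(),
                       window_s = 10, overlap = 0.5,
                       vm_std_threshold = 0.01,
                       min_walking_fraction = 0.5,
                       acc_lag = "dominant",
                       k = 10, group_by_subject = FALSE,
                       stratified = FALSE, positive = "low",
                       n_trees = 500, max_depth = 10,
                       importance_sets = c(10L, 11L),
                       spot_check = FALSE) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline: simulate, preprocess, featurize, model
#'
#' Executes every stage on a synthetic cohort and writes the stage
#' outputs under `out_dir`: the cohort table, a per-window QC table, the
#' feature table, the 11-feature-set cross-validation table, importance
#' tables for the configured sets, the optional classifier spot-check,
#' and a JSON manifest recording seeds and the instance counts at every
#' filter. Re-running with the same config reproduces all outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @return Invisibly, a list with `cohort`, `qc`, `features`,
#'   `cv_table`, `reports`, `importance`, `spot_check`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (config$n_high + config$n_low == 0) {
    stop_input("ingest: empty cohort (n_high + n_low = 0)")
  }
  arch <- make_archetypes(config$archetype_overrides)
  spec <- cohort_spec(config$n_high, config$n_low, config$duration_s,
                      config$rate_hz, config$seed,
                      high_profile = arch$high, low_profile = arch$low)
  sim <- simulate_cohort(spec)

  fz <- featurize_cohort(sim$tracings, sim$cohort,
                         window_s = config$window_s,
                         overlap = config$overlap,
                         vm_std_threshold = config$vm_std_threshold,
                         min_walking_fraction = config$min_walking_fraction,
                         acc_lag = config$acc_lag)
  if (is.null(fz$features)) stop_input("featurize: no accepted windows")

  sets <- build_feature_sets()
  ev <- evaluate_feature_sets(
    fz$features, sets, k = config$k, seed = config$seed,
    group_by_subject = config$group_by_subject,
    stratified = config$stratified, positive = config$positive,
    n_trees = config$n_trees, max_depth = config$max_depth
  )

  importance <- list()
  for (sid in config$importance_sets) {
    set <- sets[[sid]]
    cols <- set$columns
    ok <- stats::complete.cases(fz$features[cols]) &
      apply(as.matrix(fz$features[cols]), 1, function(r) all(is.finite(r)))
    dat <- fz$features[ok, , drop = FALSE]
    forest <- train_random_forest(dat[cols], factor(dat$label),
                                  n_trees = config$n_trees,
                                  max_depth = config$max_depth,
                                  seed = config$seed + 100 + sid)
    rep_i <- feature_importance(forest, dat[cols], factor(dat$label))
    importance[[as.character(sid)]] <- rep_i
  }

  spot <- NULL
  if (isTRUE(config$spot_check)) {
    spot <- spot_check_models(fz$features, k = config$k,
                              seed = config$seed,
                              positive = config$positive)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("gaitrisk")),
    seed = config$seed,
    n_high = config$n_high, n_low = config$n_low,
    duration_s = config$duration_s, rate_hz = config$rate_hz,
    windows_total = nrow(fz$qc),
    windows_active = sum(fz$qc$active),
    windows_accepted = sum(fz$qc$accepted),
    instances_per_set = stats::setNames(
      ev$table$n_used, paste0("set_", ev$table$set_id)),
    cv = list(k = config$k, group_by_subject = config$group_by_subject,
              stratified = config$stratified,
              positive = config$positive),
    forest = list(n_trees = config$n_trees, max_depth = config$max_depth)
  )
  stopifnot(manifest$windows_active <= manifest$windows_total,
            manifest$windows_accepted <= manifest$windows_active)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_csv(sim$cohort, file.path(out_dir, "cohort.csv"))
    utils::write.csv(fz$qc, file.path(out_dir, "window_qc.csv"),
                     row.names = FALSE)
    utils::write.csv(fz$features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(ev$table, file.path(out_dir, "cv_metrics.csv"),
                     row.names = FALSE)
    for (sid in names(importance)) {
      utils::write.csv(importance[[sid]],
                       file.path(out_dir,
                                 sprintf("importance_set%s.csv", sid)),
                       row.names = FALSE)
    }
    if (!is.null(spot)) {
      utils::write.csv(spot, file.path(out_dir, "spot_check.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(cohort = sim$cohort, qc = fz$qc, features = fz$features,
                 cv_table = ev$table, reports = ev$reports,
                 importance = importance, spot_check = spot,
                 manifest = manifest))
}
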