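#' Pipeline configuration
#'
#' Bundles every stage's configuration for [run_pipeline()].
#'
#' @param seed Master seed; every stochastic component consumes a seed
#'   derived from it.
#' @param generator A [generator_config()].
#' @param preproc A [preproc_config()].
#' @param spectral A [spectral_config()].
#' @param models Character vector of classifier families to run.
#' @param cv A [cv_config()].
#' @param fixed_k Number of top-ranked features to keep (reference
#'   analysis: 50).
#' @param rank_method Univariate scorer for [rank_features()].
#' @param scale_mode `"per-dataset"` (each dataset scaled with its own
#'   fitted min/max, mirroring independent data management) or
#'   `"train-only"` (external sets transformed with the training scaler).
#' @param selection_scope `"global"` (rank and select once on the full
#'   training table) or `"nested"` (selection re-run inside each CV
#'   training fold; leakage-free internal validation).
#' @param search Run [grid_search()] per model before fitting (slow);
#'   default FALSE uses each family's default (reference-optimum)
#'   hyperparameters.
#' @param hyper Optional named list (by algorithm) of hyperparameter
#'   overrides, e.g. `list(adaboost = list(n_estimators = 100))`.
#' @param calibration_bins Bins for calibration curves.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            generator = generator_config(),
                            preproc = preproc_config(),
                            spectral = spectral_config(),
                            models = c("adaboost", "lda", "logreg", "nb",
                                       "rf", "svm", "xgboost"),
                            cv = cv_config(k = 10),
                            fixed_k = 50,
                            rank_method = "anova_f",
                            scale_mode = c("per-dataset", "train-only"),
                            selection_scope = c("global", "nested"),
                            search = FALSE,
                            hyper = list(),
                            calibration_bins = 10) {
  scale_mode <- match.arg(scale_mode)
  selection_scope <- match.arg(selection_scope)
  models <- match.arg(models, ALGORITHMS, several.ok = TRUE)
  required <- list(generator = generator, preproc = preproc,
                   spectral = spectral, cv = cv)
  for (nm in names(required)) {
    if (is.null(required[[nm]])) {
      stop_painerd(sprintf("Missing config section '%s'.", nm),
                   "painerd_config_error")
    }
  }
  structure(list(seed = as.integer(seed), generator = generator,
                 preproc = preproc, spectral = spectral, models = models,
                 cv = cv, fixed_k = fixed_k, rank_method = rank_method,
                 scale_mode = scale_mode, selection_scope = selection_scope,
                 search = search, hyper = hyper,
                 calibration_bins = calibration_bins),
            class = "pipeline_config")
}

# simulate -> preprocess -> spectral -> candidate features for one study
study_features <- function(design, config, seed) {
  set <- simulate_study(design, config$generator, seed = seed)
  set <- preprocess_epochs(set, config$preproc)
  be <- band_erd_from_epochs(set, config$spectral)
  trial_features(be)
}

#' Run the full classification pipeline on synthetic data
#'
#' Executes the complete two-study analysis: simulate the training study
#' (study one) and the external-validation study (study two), preprocess,
#' transform to band-collapsed ERD, extract the candidate feature grid,
#' clean (MAD-outlier interpolation) and scale, rank and select features,
#' fit every requested classifier (optionally after a grid search),
#' cross-validate on the training study, and evaluate the frozen models on
#' external validation one (fast rise, matching stimulation) and two (slow
#' rise, different stimulation). Touch trials from study one are dropped
#' before classification. Fully reproducible from the config's seed.
#'
#' @param config A [pipeline_config()].
#' @return An `evaluation_report`: list with tibbles `metrics` (per stage x
#'   model x metric, with across-fold SDs for the CV stage), `confusion`,
#'   `roc`, `calibration`, plus `ranking`, `selected_features`, `ratings`
#'   (simulated behavioural ratings with summary), `hyper` (per model),
#'   `config` and `seed`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  seed <- config$seed
  d1 <- study_design("one")
  d2 <- study_design("two")

  train_raw <- study_features(d1, config, derive_seed(seed, 101))
  train_raw <- train_raw[!is.na(train_raw$.label), , drop = FALSE]  # drop touch
  train_raw <- fill_outliers(train_raw)
  sc <- scale_minmax(train_raw)
  train <- sc$table

  ranking <- rank_features(train, method = config$rank_method)
  sel <- sequential_select(train, ranking, cv = config$cv,
                           fixed_k = config$fixed_k)
  features <- sel$selected

  ev_raw <- study_features(d2, config, derive_seed(seed, 202))
  ev_raw <- fill_outliers(ev_raw)
  split_ev <- split(seq_len(nrow(ev_raw)), ifelse(ev_raw$.rise_time == 1, "ev1", "ev2"))
  ev_tables <- lapply(split_ev, function(idx) {
    tab <- ev_raw[idx, , drop = FALSE]
    if (config$scale_mode == "per-dataset") scale_minmax(tab)$table
    else scale_minmax(tab, sc$params)$table
  })

  cvseed <- derive_seed(seed, 303)
  models <- list(); hypers <- list()
  rows_m <- list(); rows_c <- list(); rows_r <- list(); rows_k <- list()
  cv_detail <- list()
  for (mi in seq_along(config$models)) {
    alg <- config$models[[mi]]
    spec <- model_spec(alg, seed = derive_seed(seed, 400 + mi))
    hp <- NULL
    if (!is.null(config$hyper[[alg]])) hp <- config$hyper[[alg]]
    if (config$search && length(spec$grid) > 0) {
      gs <- grid_search(spec, train, cv = cv_config(k = config$cv$k, seed = cvseed),
                        feature_subset = features)
      hp <- utils::modifyList(gs$best, hp %||% list())
    }
    select_fun <- NULL
    cv_subset <- features
    if (config$selection_scope == "nested") {
      cv_subset <- NULL
      select_fun <- function(tr) {
        sc_f <- scale_minmax(tr)
        rk <- rank_features(sc_f$table, method = config$rank_method)
        list(features = utils::head(rk$feature, config$fixed_k),
             scaler = sc_f$params)
      }
    }
    cvres <- cross_validate(spec, train,
                            cv = cv_config(k = config$cv$k, seed = cvseed),
                            feature_subset = cv_subset, hyper = hp,
                            select_fun = select_fun)
    fit <- fit_model(spec, train, feature_subset = features, hyper = hp)
    models[[alg]] <- fit
    hypers[[alg]] <- fit$hyper
    cv_detail[[alg]] <- cvres$folds
    rows_m[[alg]] <- dplyr::bind_cols(
      tibble::tibble(stage = "cv", model = alg),
      tidyr::pivot_wider(cvres$metrics[, c("metric", "mean")],
                         names_from = "metric", values_from = "mean"))
    # pooled held-out predictions give the CV-stage curves
    pooled <- cvres$predictions
    rows_c[[alg]] <- dplyr::bind_cols(tibble::tibble(stage = "cv", model = alg),
                                      confusion(pooled$y, pooled$proba))
    rows_r[[alg]] <- dplyr::bind_cols(tibble::tibble(stage = "cv", model = alg),
                                      roc_points(pooled$proba, pooled$y))
    rows_k[[alg]] <- dplyr::bind_cols(
      tibble::tibble(stage = "cv", model = alg),
      calibration_curve(pooled$proba, pooled$y, config$calibration_bins))
  }

  ev <- external_validate(models, ev_tables, n_bins = config$calibration_bins)
  cv_sd <- dplyr::bind_rows(lapply(names(cv_detail), function(alg) {
    long <- tidyr::pivot_longer(cv_detail[[alg]], -"fold",
                                names_to = "metric", values_to = "value")
    out <- dplyr::summarise(dplyr::group_by(long, .data$metric),
                            sd = sd(.data$value), .groups = "drop")
    dplyr::bind_cols(tibble::tibble(stage = "cv", model = alg), out)
  }))

  metrics <- dplyr::bind_rows(dplyr::bind_rows(rows_m), ev$metrics)
  metrics <- tidyr::pivot_longer(metrics, -c("stage", "model"),
                                 names_to = "metric", values_to = "value")
  metrics <- dplyr::left_join(metrics, cv_sd,
                              by = c("stage", "model", "metric"))

  sched1 <- make_schedule(d1, seed = derive_seed(seed, 1))
  sched1$study <- "one"
  sched2 <- make_schedule(d2, seed = derive_seed(derive_seed(seed, 202), 1))
  sched2$study <- "two"
  ratings <- dplyr::bind_rows(
    simulate_ratings(sched1, config$generator, derive_seed(seed, 501)),
    simulate_ratings(sched2, config$generator, derive_seed(seed, 502)))

  structure(list(
    metrics = metrics,
    confusion = dplyr::bind_rows(dplyr::bind_rows(rows_c), ev$confusion),
    roc = dplyr::bind_rows(dplyr::bind_rows(rows_r), ev$roc),
    calibration = dplyr::bind_rows(dplyr::bind_rows(rows_k), ev$calibration),
    ranking = ranking, selected_features = features,
    selection_curve = sel$curve,
    ratings = ratings, hyper = hypers, models = models,
    cv_detail = cv_detail,
    config = config, seed = seed
  ), class = "evaluation_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d models x %d stages, seed %d\n",
              length(unique(x$metrics$model)),
              length(unique(x$metrics$stage)), x$seed))
  acc <- x$metrics[x$metrics$metric == "accuracy", c("stage", "model", "value")]
  print(tidyr::pivot_wider(acc, names_from = "stage", values_from = "value"),
        n = Inf)
  invisible(x)
}
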