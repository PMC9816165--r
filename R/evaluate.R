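#' Cross-validation configuration
#'
#' @param k Number of folds (default 10).
#' @param stratified Preserve class proportions per fold (default TRUE).
#' @param shuffle Shuffle trials before assignment (seeded; default TRUE).
#' @param seed Integer seed for the shuffle.
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(k = 10, stratified = TRUE, shuffle = TRUE, seed = 1L) {
  stopifnot(is_count(k), k >= 2)
  structure(list(k = as.integer(k), stratified = isTRUE(stratified),
                 shuffle = isTRUE(shuffle), seed = as.integer(seed)),
            class = "cv_config")
}

#' Stratified fold assignment
#'
#' Assigns every trial to exactly one of `k` folds so that per-fold class
#' counts differ by at most one from perfect proportionality.
#'
#' @param labels 0/1 label vector.
#' @param cv A [cv_config()].
#' @return Integer vector of fold ids (1..k), one per trial.
#' @export
stratified_folds <- function(labels, cv = cv_config()) {
  n <- length(labels)
  if (cv$k > n) {
    stop_painerd("More folds than trials.", "painerd_config_error")
  }
  folds <- integer(n)
  if (cv$stratified) {
    if (min(table(labels)) < cv$k) {
      warn("A class has fewer members than folds; some folds will miss it.")
    }
    with_seed(cv$seed, {
      for (cl in sort(unique(labels))) {
        idx <- which(labels == cl)
        if (cv$shuffle) idx <- sample(idx)
        folds[idx] <- rep_len(seq_len(cv$k), length(idx))
      }
    })
  } else {
    with_seed(cv$seed, {
      idx <- if (cv$shuffle) sample.int(n) else seq_len(n)
      folds[idx] <- rep_len(seq_len(cv$k), n)
    })
  }
  folds
}

#' Confusion matrix (class 1 = high pain)
#'
#' @param y_true,y_pred Equal-length binary vectors; `y_pred` may be
#'   probabilities, thresholded at 0.5.
#' @return One-row tibble `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop_painerd("y_true and y_pred must have equal length.",
                 "painerd_config_error")
  }
  yp <- as.integer(y_pred > 0.5)
  tibble::tibble(
    tp = sum(y_true == 1 & yp == 1),
    fp = sum(y_true == 0 & yp == 1),
    fn = sum(y_true == 1 & yp == 0),
    tn = sum(y_true == 0 & yp == 0)
  )
}

# rank-statistic AUC: probability a random positive outranks a random
# negative, ties counted 1/2 (midranks)
auc_rank <- function(proba, y_true) {
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(proba)
  (sum(r[y_true == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Discrimination metrics from probabilities and labels
#'
#' Accuracy, precision, recall and F1 at the 0.5 threshold; AUC as the
#' rank statistic (ties counted 1/2); Brier score as the mean squared
#' difference between probability and outcome. Metrics with a zero
#' denominator are reported as 0 with a warning.
#'
#' @param proba Class-1 probabilities in `[0, 1]`.
#' @param y_true 0/1 labels.
#' @return One-row tibble `accuracy`, `precision`, `recall`, `f1`, `auc`,
#'   `brier`.
#' @export
discrimination_metrics <- function(proba, y_true) {
  if (any(proba < 0 | proba > 1)) {
    stop_painerd("Probabilities must lie in [0, 1].", "painerd_config_error")
  }
  cm <- confusion(y_true, proba)
  n <- length(y_true)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s undefined (zero denominator); reporting 0.", what))
      0
    } else num / den
  }
  precision <- safe_div(cm$tp, cm$tp + cm$fp, "precision")
  recall <- safe_div(cm$tp, cm$tp + cm$fn, "recall")
  f1 <- if (precision + recall == 0) {
    warn("f1 undefined (zero denominator); reporting 0.")
    0
  } else 2 * precision * recall / (precision + recall)
  tibble::tibble(
    accuracy = (cm$tp + cm$tn) / n,
    precision = precision, recall = recall, f1 = f1,
    auc = auc_rank(proba, y_true),
    brier = mean((proba - y_true)^2)
  )
}

#' ROC curve points
#'
#' Threshold sweep over the unique predicted probabilities; the curve runs
#' from (0, 0) to (1, 1) and its trapezoidal area equals the rank-statistic
#' AUC.
#'
#' @param proba Class-1 probabilities.
#' @param y_true 0/1 labels (both classes required).
#' @return Tibble `threshold`, `fpr`, `tpr`, ordered by increasing fpr.
#' @export
roc_points <- function(proba, y_true) {
  n1 <- sum(y_true == 1); n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) {
    stop_painerd("ROC needs both classes present.", "painerd_config_error")
  }
  ord <- order(proba, decreasing = TRUE)
  p <- proba[ord]; y <- y_true[ord]
  grp_end <- which(c(p[-1] != p[-length(p)], TRUE))
  tp <- cumsum(y == 1)[grp_end]
  fp <- cumsum(y == 0)[grp_end]
  tibble::tibble(
    threshold = c(Inf, p[grp_end]),
    fpr = c(0, fp / n0),
    tpr = c(0, tp / n1)
  )
}

trapezoid_area <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Calibration (reliability) curve
#'
#' Equal-width probability bins on `[0, 1]`; per bin: mean predicted
#' probability, observed class-1 frequency and count. Empty bins are
#' reported with count 0 and `NA` coordinates.
#'
#' @param proba Class-1 probabilities.
#' @param y_true 0/1 labels.
#' @param n_bins Number of bins (>= 2; default 10).
#' @return Tibble `bin`, `bin_lo`, `bin_hi`, `mean_pred`, `obs_freq`, `n`.
#' @export
calibration_curve <- function(proba, y_true, n_bins = 10) {
  if (n_bins < 2) {
    stop_painerd("Calibration needs at least 2 bins.", "painerd_config_error")
  }
  if (any(proba < 0 | proba > 1)) {
    stop_painerd("Probabilities must lie in [0, 1].", "painerd_config_error")
  }
  edges <- seq(0, 1, length.out = n_bins + 1)
  b <- findInterval(proba, edges, rightmost.closed = TRUE, all.inside = TRUE)
  purrr::map_dfr(seq_len(n_bins), function(i) {
    sel <- b == i
    tibble::tibble(
      bin = i, bin_lo = edges[i], bin_hi = edges[i + 1],
      mean_pred = if (any(sel)) mean(proba[sel]) else NA_real_,
      obs_freq = if (any(sel)) mean(y_true[sel]) else NA_real_,
      n = sum(sel)
    )
  })
}

#' Stratified k-fold cross-validation of one model
#'
#' For each fold: fit on the other k-1 folds, evaluate all discrimination
#' metrics on the held-out fold; report their mean and SD across folds.
#' With `select_fun`, feature selection (and optionally scaling) is re-run
#' inside every training fold (nested, leakage-free mode): the function
#' receives the training-fold table and must return
#' `list(features = <chr>, scaler = <params or NULL>)`.
#'
#' @param spec A [model_spec()].
#' @param table Feature table with `.label`.
#' @param cv A [cv_config()].
#' @param labels Optional label override.
#' @param feature_subset Optional fixed feature subset.
#' @param hyper Optional hyperparameter overrides.
#' @param select_fun Optional per-fold selection function (nested mode).
#' @return List with `metrics` (tibble `metric`, `mean`, `sd`), `folds`
#'   (per-fold metric tibble), `fold_id` (assignment vector) and
#'   `predictions` (pooled held-out probabilities, one row per trial).
#' @export
cross_validate <- function(spec, table, cv = cv_config(), labels = NULL,
                           feature_subset = NULL, hyper = NULL,
                           select_fun = NULL) {
  if (is.null(labels)) labels <- table$.label
  folds <- stratified_folds(labels, cv)
  per_fold <- vector("list", cv$k)
  preds <- vector("list", cv$k)
  for (f in seq_len(cv$k)) {
    tr <- table[folds != f, , drop = FALSE]
    te <- table[folds == f, , drop = FALSE]
    ytr <- labels[folds != f]; yte <- labels[folds == f]
    subset_f <- feature_subset
    if (!is.null(select_fun)) {
      sel <- select_fun(tr)
      subset_f <- sel$features
      if (!is.null(sel$scaler)) {
        tr <- scale_minmax(tr, sel$scaler)$table
        te <- scale_minmax(te, sel$scaler)$table
      }
    }
    fit <- fit_model(spec, tr, labels = ytr, feature_subset = subset_f,
                     hyper = hyper)
    proba <- predict(fit, te, type = "prob")
    per_fold[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f),
                                      discrimination_metrics(proba, yte))
    preds[[f]] <- tibble::tibble(fold = f, row = which(folds == f),
                                 proba = proba, y = yte)
  }
  folds_tbl <- dplyr::bind_rows(per_fold)
  long <- tidyr::pivot_longer(folds_tbl, -"fold", names_to = "metric",
                              values_to = "value")
  metrics <- dplyr::summarise(dplyr::group_by(long, .data$metric),
                              mean = mean(.data$value), sd = sd(.data$value),
                              .groups = "drop")
  metrics <- metrics[match(c("accuracy", "precision", "recall", "f1",
                             "auc", "brier"), metrics$metric), ]
  list(metrics = metrics, folds = folds_tbl, fold_id = folds,
       predictions = dplyr::bind_rows(preds))
}

#' Evaluate frozen models on external-validation tables
#'
#' Applies models fitted on the training study to one or more held-out
#' datasets -- no refitting -- and computes the full metric set, ROC points
#' and calibration curve per model and stage.
#'
#' @param models Named list of `pain_model` objects.
#' @param ev_tables Named list of feature tables (e.g. `ev1`, `ev2`).
#' @param n_bins Calibration bins.
#' @return List with tibbles `metrics`, `confusion`, `roc`, `calibration`
#'   (all keyed by `stage` and `model`).
#' @export
external_validate <- function(models, ev_tables, n_bins = 10) {
  if (!length(ev_tables) || any(!vapply(ev_tables, nrow, 1L))) {
    stop_painerd("External-validation tables must be non-empty.",
                 "painerd_config_error")
  }
  rows_m <- list(); rows_c <- list(); rows_r <- list(); rows_k <- list()
  for (stage in names(ev_tables)) {
    tab <- ev_tables[[stage]]
    y <- tab$.label
    for (mn in names(models)) {
      proba <- predict(models[[mn]], tab, type = "prob")
      m <- discrimination_metrics(proba, y)
      rows_m[[length(rows_m) + 1]] <-
        dplyr::bind_cols(tibble::tibble(stage = stage, model = mn), m)
      rows_c[[length(rows_c) + 1]] <-
        dplyr::bind_cols(tibble::tibble(stage = stage, model = mn),
                         confusion(y, proba))
      rows_r[[length(rows_r) + 1]] <-
        dplyr::bind_cols(tibble::tibble(stage = stage, model = mn),
                         roc_points(proba, y))
      rows_k[[length(rows_k) + 1]] <-
        dplyr::bind_cols(tibble::tibble(stage = stage, model = mn),
                         calibration_curve(proba, y, n_bins))
    }
  }
  list(metrics = dplyr::bind_rows(rows_m),
       confusion = dplyr::bind_rows(rows_c),
       roc = dplyr::bind_rows(rows_r),
       calibration = dplyr::bind_rows(rows_k))
}
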