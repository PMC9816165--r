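#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted pain-intensity classifier
#'
#' One row per feature the model uses, with an algorithm-appropriate
#' importance measure where the backend provides one (absolute
#' coefficients for the linear families, impurity importance for the
#' random forest, summed stump weights for AdaBoost, gain for XGBoost;
#' `NA` for SVM and naive Bayes).
#'
#' @param x A `pain_model`.
#' @param ... Unused.
#' @return Tibble `feature`, `importance`.
#' @export
tidy.pain_model <- function(x, ...) {
  imp <- rep(NA_real_, length(x$features))
  names(imp) <- x$features
  if (x$algorithm == "logreg") {
    co <- as.numeric(coef(x$fit))[-1]
    imp[] <- abs(co)
  } else if (x$algorithm == "lda") {
    imp[] <- abs(x$fit$b1 - x$fit$b0)
  } else if (x$algorithm == "adaboost") {
    for (m in seq_along(x$fit$stumps)) {
      j <- x$fit$stumps[[m]]$feature
      imp[j] <- sum(imp[j], abs(x$fit$alphas[m]), na.rm = TRUE)
    }
  } else if (x$algorithm == "xgboost") {
    gi <- tryCatch(xgboost::xgb.importance(model = x$fit), error = function(e) NULL)
    if (!is.null(gi)) imp[gi$Feature] <- gi$Gain
  }
  tibble::tibble(feature = x$features, importance = unname(imp))
}

#' @rdname tidy.pain_model
#' @return `glance()` returns a one-row tibble: `algorithm`, `n_features`,
#'   and the hyperparameters as a packed list column.
#' @export
glance.pain_model <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm,
                 n_features = length(x$features),
                 hyper = list(x$hyper))
}

#' Tidy an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return The long metrics tibble (`stage`, `model`, `metric`, `value`,
#'   `sd` for the CV stage).
#' @export
tidy.evaluation_report <- function(x, ...) x$metrics

#' @rdname tidy.evaluation_report
#' @return `glance()` returns one row per model with accuracy and AUC per
#'   stage in wide form.
#' @export
glance.evaluation_report <- function(x, ...) {
  acc <- x$metrics[x$metrics$metric %in% c("accuracy", "auc"),
                   c("stage", "model", "metric", "value")]
  tidyr::pivot_wider(acc, names_from = c("stage", "metric"),
                     values_from = "value")
}

#' ROC curves for every model and validation stage
#'
#' @param report An `evaluation_report`.
#' @param stages Stages to include (default all present).
#' @return A ggplot object.
#' @export
plot_roc <- function(report, stages = unique(report$roc$stage)) {
  df <- report$roc[report$roc$stage %in% stages, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "blue") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~stage) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  colour = NULL) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Calibration (reliability) curves per model and stage
#'
#' Predicted probability on the x-axis against observed class-1 frequency
#' on the y-axis; the dotted diagonal marks perfect calibration.
#'
#' @param report An `evaluation_report`.
#' @param stages Stages to include.
#' @return A ggplot object.
#' @export
plot_calibration <- function(report, stages = unique(report$calibration$stage)) {
  df <- report$calibration[report$calibration$stage %in% stages &
                             report$calibration$n > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_pred, y = .data$obs_freq,
                                   colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "blue") +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~stage) +
    ggplot2::lims(x = c(0, 1), y = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted probability",
                  y = "Observed frequency (high pain)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Time course of band-collapsed ERD
#'
#' Averages the ERD time course over trials (optionally per condition) and
#' channels, one panel per band.
#'
#' @param banderd A `band_erd`.
#' @param channels Channels to average (default all).
#' @param by_condition Facet colour by the metadata condition column.
#' @return A ggplot object.
#' @export
plot_band_erd <- function(banderd, channels = NULL, by_condition = TRUE) {
  d <- dim(banderd$values)
  if (is.null(channels)) channels <- seq_len(d[2])
  cond <- if (by_condition && !is.null(banderd$meta)) banderd$meta$condition
          else rep("all", d[1])
  rows <- list()
  for (cd in unique(cond)) {
    tr <- which(cond == cd)
    m <- apply(banderd$values[tr, channels, , , drop = FALSE], c(3, 4), mean)
    rows[[cd]] <- tibble::tibble(
      condition = cd,
      band = rep(banderd$bands$band, times = d[4]),
      time = rep(banderd$times, each = d[3]),
      erd = as.vector(m))
  }
  ggplot2::ggplot(dplyr::bind_rows(rows),
                  ggplot2::aes(x = .data$time, y = .data$erd,
                               colour = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~band, scales = "free_y") +
    ggplot2::labs(x = "Time relative to stimulus onset (s)",
                  y = "ERD (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.evaluation_report <- function(object, ...) plot_roc(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
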