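#' Write / read an epoch set as plain-text CSV plus JSON sidecar
#'
#' Each epoch is stored as one CSV (samples x channels, columns
#' `ch01`...); `meta.json` records the sampling rate, epoch start time and
#' the per-trial schedule metadata. Round-trips numerically at full double
#' precision.
#'
#' @param set An `epoch_set`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(set$epochs)) {
    m <- t(set$epochs[[i]]$data)
    colnames(m) <- sprintf("ch%02d", seq_len(ncol(m)))
    utils::write.csv(format(as.data.frame(m), digits = 17, trim = TRUE),
                     file.path(dir, sprintf("epoch_%04d.csv", i)),
                     row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(fs = set$fs, t0 = set$t0, n_epochs = length(set$epochs),
         meta = set$meta),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_epochs
#' @return `read_epochs()` returns the reconstructed `epoch_set`.
#' @export
read_epochs <- function(dir) {
  info <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  meta <- tibble::as_tibble(info$meta)
  epochs <- lapply(seq_len(info$n_epochs), function(i) {
    m <- utils::read.csv(file.path(dir, sprintf("epoch_%04d.csv", i)))
    d <- t(as.matrix(m))
    dimnames(d) <- NULL
    structure(list(data = d, fs = info$fs, t0 = info$t0,
                   meta = as.list(meta[i, ])),
              class = "eeg_epoch")
  })
  structure(list(epochs = epochs, meta = meta, fs = info$fs, t0 = info$t0),
            class = "epoch_set")
}

#' Write / read a feature table as CSV plus JSON sidecar
#'
#' The CSV holds metadata and feature columns; the sidecar records scaler
#' parameters and the outlier-mask summary when present.
#'
#' @param table A feature table.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param params Optional scaler params to record.
#' @return `path`, invisibly.
#' @export
write_features <- function(table, path, params = NULL) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  side <- list(
    n_trials = nrow(table),
    n_features = length(feature_cols(table)),
    outlier_fraction = attr(table, "outlier_fraction"),
    scaler = params
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_features
#' @return `read_features()` returns the feature table (tibble).
#' @export
read_features <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Write / read band-collapsed ERD as long-format CSV plus JSON sidecar
#'
#' One CSV row per (trial, channel, band, time) value; the sidecar holds
#' the band scheme, time grid and trial metadata.
#'
#' @param banderd A `band_erd`.
#' @param path CSV path; sidecar written as `<path>.json`.
#' @return `path` invisibly; `read_band_erd()` returns the `band_erd`.
#' @export
write_band_erd <- function(banderd, path) {
  d <- dim(banderd$values)
  df <- data.frame(
    trial = rep(seq_len(d[1]), times = d[2] * d[3] * d[4]),
    channel = rep(rep(seq_len(d[2]), each = d[1]), times = d[3] * d[4]),
    band = rep(rep(banderd$bands$band, each = d[1] * d[2]), times = d[4]),
    time = rep(banderd$times, each = d[1] * d[2] * d[3]),
    erd = as.vector(banderd$values)
  )
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(dims = d, bands = banderd$bands, times = banderd$times,
         meta = banderd$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_band_erd
#' @export
read_band_erd <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path)
  vals <- array(df$erd, dim = side$dims)
  structure(list(values = vals, bands = tibble::as_tibble(side$bands),
                 times = side$times,
                 meta = if (!is.null(side$meta)) tibble::as_tibble(side$meta)),
            class = "band_erd")
}

#' Save / load a fitted classifier
#'
#' Serialises the model artefact (algorithm id, hyperparameters, feature
#' subset, seed and fitted state) so that reloaded models reproduce their
#' predictions bit-identically.
#'
#' @param model A `pain_model`.
#' @param path Destination file (RDS).
#' @return `path` invisibly; `load_model()` returns the `pain_model`.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "pain_model")) {
    stop_painerd("File does not contain a pain_model artefact.",
                 "painerd_config_error")
  }
  m
}

#' Write an evaluation report to JSON and flat CSV
#'
#' `report.json` nests stages, models, metrics and curves; `metrics.csv`
#' is one row per stage x model x metric; ROC and calibration points go to
#' `roc.csv` and `calibration.csv` for external plotting.
#'
#' @param report An `evaluation_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(report$metrics),
                   file.path(dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$roc), file.path(dir, "roc.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$calibration),
                   file.path(dir, "calibration.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = report$seed,
         selected_features = report$selected_features,
         hyper = report$hyper,
         metrics = report$metrics,
         confusion = report$confusion,
         roc = report$roc,
         calibration = report$calibration),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
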