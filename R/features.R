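#' The 15-statistic candidate-feature catalogue
#'
#' Ordered, stable list of the per-trial summary statistics computed on each
#' channel-by-band ERD time course. Definitions follow the originating
#' numerical environment's built-in conventions (see [compute_statistic()]).
#'
#' @return Character vector of 15 statistic ids.
#' @export
stat_catalog <- function() {
  c("mean", "mode", "median", "min", "max", "sd", "rms", "variance",
    "skewness", "kurtosis", "abs_mean", "shannon_entropy",
    "log_energy_entropy", "range", "squared_mean")
}

#' Compute one catalogue statistic of a sequence
#'
#' Conventions: sample (n-1) variance and SD; skewness and kurtosis in
#' biased population form with kurtosis raw (a normal sample gives ~3, not
#' 0); `rms = sqrt(mean(x^2))`; `abs_mean = mean(|x|)`;
#' `range = max - min`; `squared_mean = (mean x)^2`; `mode` is the most
#' frequent value with ties broken toward the smallest (on continuous data
#' this approaches the minimum; retained for fidelity to the named
#' built-ins); `shannon_entropy = -sum(x^2 log(x^2))` and
#' `log_energy_entropy = sum(log(x^2))` with `0*log 0 := 0` and
#' `log(0) := 0` (wavelet-entropy conventions).
#'
#' @param x Numeric vector (length >= 2 for dispersion statistics).
#' @param stat_id One of [stat_catalog()].
#' @return A single numeric value.
#' @export
#' @examples
#' compute_statistic(c(1, 2, 3), "rms")  # sqrt(14/3)
compute_statistic <- function(x, stat_id) {
  if (!stat_id %in% stat_catalog()) {
    stop_painerd(sprintf("Unknown statistic id '%s'.", stat_id),
                 "painerd_config_error")
  }
  if (stat_id %in% c("sd", "variance", "skewness", "kurtosis") && length(x) < 2) {
    stop_painerd("Dispersion statistics need at least two observations.",
                 "painerd_config_error")
  }
  switch(stat_id,
    mean = mean(x),
    mode = stat_mode(x),
    median = median(x),
    min = min(x),
    max = max(x),
    sd = sd(x),
    rms = sqrt(mean(x^2)),
    variance = var(x),
    skewness = stat_skewness(x),
    kurtosis = stat_kurtosis(x),
    abs_mean = mean(abs(x)),
    shannon_entropy = stat_shannon(x),
    log_energy_entropy = stat_log_energy(x),
    range = max(x) - min(x),
    squared_mean = mean(x)^2
  )
}

stat_mode <- function(x) {
  ux <- sort(unique(x))
  tab <- tabulate(match(x, ux))
  ux[which.max(tab)]  # which.max takes the first (= smallest) on ties
}

stat_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

stat_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^4) / m2^2
}

stat_shannon <- function(x) {
  x2 <- x^2
  -sum(ifelse(x2 == 0, 0, x2 * log(x2)))
}

stat_log_energy <- function(x) {
  x2 <- x^2
  sum(ifelse(x2 == 0, 0, log(x2)))
}

#' Candidate feature table from band-collapsed ERD
#'
#' Computes all 15 catalogue statistics of every channel-by-band ERD time
#' course over the full epoch, yielding `channels x bands x 15` features
#' per trial (9600 for the 128-channel montage). Columns are ordered
#' channel-major, then band, then statistic, and named
#' `chXX_band_statistic`. Trial metadata is carried in dot-prefixed columns.
#'
#' @param banderd A `band_erd` (with `meta`).
#' @param catalog Statistic ids, default [stat_catalog()].
#' @return A feature table: tibble of trials x (metadata + features).
#' @export
trial_features <- function(banderd, catalog = stat_catalog()) {
  d <- dim(banderd$values)
  n_trials <- d[1]; n_ch <- d[2]; n_band <- d[3]; n_time <- d[4]
  if (n_time == 0) {
    stop_painerd("Empty time axis; cannot compute trial features.",
                 "painerd_config_error")
  }
  bands <- banderd$bands$band
  feat_names <- as.vector(vapply(seq_len(n_ch), function(ch) {
    as.vector(vapply(bands, function(b) {
      paste0(sprintf("ch%02d", ch), "_", b, "_", catalog)
    }, character(length(catalog))))
  }, character(n_band * length(catalog))))
  mat <- matrix(NA_real_, n_trials, length(feat_names))
  col <- 0L
  for (ch in seq_len(n_ch)) {
    for (b in seq_len(n_band)) {
      series <- banderd$values[, ch, b, , drop = FALSE]
      dim(series) <- c(n_trials, n_time)
      for (s in catalog) {
        col <- col + 1L
        mat[, col] <- apply(series, 1, compute_statistic, stat_id = s)
      }
    }
  }
  colnames(mat) <- feat_names
  meta <- banderd$meta
  out <- tibble::tibble(
    .trial = if ("trial_global" %in% names(meta)) meta$trial_global else seq_len(n_trials),
    .block = if ("block" %in% names(meta)) meta$block else NA_integer_,
    .condition = if ("condition" %in% names(meta)) meta$condition else NA_character_,
    .intensity = if ("intensity" %in% names(meta)) meta$intensity else NA_character_,
    .rise_time = if ("rise_time" %in% names(meta)) meta$rise_time else NA_real_,
    .study = if ("study" %in% names(meta)) meta$study else NA_character_,
    .participant = if ("participant" %in% names(meta)) meta$participant else NA_integer_,
    .label = if ("label" %in% names(meta)) meta$label else NA_integer_
  )
  dplyr::bind_cols(out, tibble::as_tibble(mat))
}

#' Replace outliers and missing values by linear interpolation
#'
#' Within each (feature, condition group) series in trial (acquisition)
#' order, values farther than `threshold_mads` scaled MADs
#' (1.4826 x median absolute deviation) from the group median -- and any
#' missing values -- are replaced by linear interpolation between the
#' nearest non-flagged neighbours; flags at the boundary take the nearest
#' non-flagged value. Grouping uses the intensity class crossed with study
#' when available (each dataset is cleaned independently).
#'
#' @param table A feature table.
#' @param threshold_mads Flagging threshold in scaled MADs (default 3).
#' @return The cleaned table, with attributes `outlier_mask` (logical
#'   trials x features matrix) and `outlier_fraction`.
#' @export
fill_outliers <- function(table, threshold_mads = 3) {
  fc <- feature_cols(table)
  grp <- rep("all", nrow(table))
  if (".intensity" %in% names(table) && !all(is.na(table$.intensity))) {
    grp <- paste(table$.intensity, if (".study" %in% names(table)) table$.study else "")
  }
  mask <- matrix(FALSE, nrow(table), length(fc),
                 dimnames = list(NULL, fc))
  out <- table
  for (g in unique(grp)) {
    rows <- which(grp == g)
    for (j in fc) {
      x <- out[[j]][rows]
      med <- median(x, na.rm = TRUE)
      smad <- 1.4826 * median(abs(x - med), na.rm = TRUE)
      # a zero MAD gives threshold 0: identical values stay unflagged
      # (deviation 0 is never > 0) but any deviating value is flagged
      bad <- is.na(x) | abs(x - med) > threshold_mads * smad
      if (!any(bad)) next
      if (all(bad)) {
        stop_painerd(sprintf(
          "Feature '%s' in condition group '%s' is entirely flagged; cannot interpolate.",
          j, g), "painerd_outlier_error")
      }
      good <- which(!bad)
      x[bad] <- approx(good, x[good], xout = which(bad), rule = 2)$y
      out[[j]][rows] <- x
      mask[rows[bad], j] <- TRUE
    }
  }
  attr(out, "outlier_mask") <- mask
  attr(out, "outlier_fraction") <- mean(mask)
  if (mean(mask) > 0.15) {
    warn(sprintf("Interpolated fraction %.1f%% exceeds 15%%; inspect the data.",
                 100 * mean(mask)))
  }
  out
}

#' Min-max scale features to [0, 1]
#'
#' With `params = NULL`, fits per-feature min/max on `table` and transforms
#' it; with fitted `params`, transforms only (values outside the fit range
#' map outside [0, 1]; no clipping). Constant features map to 0.
#'
#' @param table A feature table.
#' @param params Optional scaler params from a previous fit.
#' @return List with `table` (scaled) and `params` (tibble
#'   `feature`, `min`, `max`).
#' @export
scale_minmax <- function(table, params = NULL) {
  fc <- feature_cols(table)
  if (is.null(params)) {
    params <- tibble::tibble(
      feature = fc,
      min = vapply(table[fc], min, numeric(1)),
      max = vapply(table[fc], max, numeric(1))
    )
  } else {
    missing <- setdiff(fc, params$feature)
    if (length(missing) > 0) {
      stop_painerd(paste0("Scaler params missing features: ",
                          paste(head(missing, 5), collapse = ", ")),
                   "painerd_config_error")
    }
  }
  p <- params[match(fc, params$feature), ]
  out <- table
  for (i in seq_along(fc)) {
    rng <- p$max[i] - p$min[i]
    out[[fc[i]]] <- if (rng == 0) rep(0, nrow(table)) else (table[[fc[i]]] - p$min[i]) / rng
  }
  list(table = out, params = params)
}
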