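#' Canonical frequency-band scheme
#'
#' Inclusive integer-Hz band edges: theta 4-7, alpha 8-12, lower beta 16-24,
#' upper beta 25-32, gamma 33-70 Hz. The 13-15 Hz bins between alpha and
#' lower beta are deliberately unassigned.
#'
#' @return Tibble with columns `band`, `lo`, `hi` (Hz).
#' @export
band_scheme <- function() {
  tibble::tibble(
    band = c("theta", "alpha", "lower_beta", "upper_beta", "gamma"),
    lo = c(4, 8, 16, 25, 33),
    hi = c(7, 12, 24, 32, 70)
  )
}

#' Spectral-analysis configuration
#'
#' Sliding-window multitaper PSD settings: 1 s windows stepped by 0.05 s
#' over the -4..6 s epoch, 1-70 Hz at 1 Hz resolution (the 1 s window fixes
#' `df = 1` Hz), with Slepian tapers of 2 Hz half-bandwidth (time-bandwidth
#' product 2, 3 tapers). Baseline period -3.5..-0.5 s; a window belongs to
#' the baseline iff its centre lies inside the interval.
#'
#' @param window_len Window length, s.
#' @param step Window step, s.
#' @param fmin,fmax Frequency range, Hz.
#' @param df Frequency resolution, Hz; must equal `1 / window_len`.
#' @param n_tapers Number of Slepian tapers.
#' @param taper_bandwidth Half-bandwidth of the tapers, Hz.
#' @param baseline Baseline interval `c(lo, hi)`, s.
#' @param span Epoch span `c(lo, hi)`, s.
#' @return A list of class `spectral_config`.
#' @export
spectral_config <- function(window_len = 1, step = 0.05, fmin = 1, fmax = 70,
                            df = 1, n_tapers = 3, taper_bandwidth = 2,
                            baseline = c(-3.5, -0.5), span = c(-4, 6)) {
  if (abs(df - 1 / window_len) > 1e-12) {
    stop_painerd("`df` must equal 1/window_len (frequency resolution of one window).",
                 "painerd_config_error")
  }
  if (!(baseline[1] >= span[1] && baseline[2] <= span[2])) {
    stop_painerd("Baseline must lie inside the epoch span.", "painerd_config_error")
  }
  structure(list(window_len = window_len, step = step, fmin = fmin,
                 fmax = fmax, df = df, n_tapers = n_tapers,
                 taper_bandwidth = taper_bandwidth, baseline = baseline,
                 span = span),
            class = "spectral_config")
}

# Discrete prolate spheroidal (Slepian) tapers from the symmetric
# tridiagonal commuting matrix; columns normalised to unit energy, sign
# fixed so each taper's mean (or first lobe) is positive.
dpss_tapers <- local({
  cache <- new.env(parent = emptyenv())
  function(n, nw, k) {
    key <- paste(n, nw, k, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    t_ <- 0:(n - 1)
    w <- nw / n
    dg <- ((n - 1 - 2 * t_) / 2)^2 * cos(2 * pi * w)
    od <- t_[-1] * (n - t_[-1]) / 2
    m <- diag(dg)
    m[cbind(2:n, 1:(n - 1))] <- od
    m[cbind(1:(n - 1), 2:n)] <- od
    e <- eigen(m, symmetric = TRUE)
    v <- e$vectors[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
      s <- sum(v[, j])
      if (j %% 2 == 1) { # even-order tapers: positive mean
        if (s < 0) v[, j] <- -v[, j]
      } else {           # odd-order: positive initial slope
        if (v[2, j] - v[1, j] < 0) v[, j] <- -v[, j]
      }
    }
    cache[[key]] <- v
    v
  }
})

#' Sliding-window multitaper spectrogram of one epoch
#'
#' One PSD per window: the average of Slepian-tapered periodograms
#' (density scaling, one-sided). Window centres run from
#' `span_lo + window_len/2` to `span_hi - window_len/2` in steps of
#' `cfg$step`; the frequency axis is `fmin..fmax` in `df` steps.
#'
#' @param epoch An `eeg_epoch` (already preprocessed/resampled).
#' @param cfg A [spectral_config()].
#' @return A `tf_map`: list with `values` (trial x channel x frequency x
#'   time array, here one trial), `freqs` (Hz), `times` (window centres, s).
#' @export
multitaper_spectrogram <- function(epoch, cfg = spectral_config()) {
  fs <- epoch$fs
  if (fs < 2 * cfg$fmax) {
    stop_painerd("Sampling rate below 2*fmax; increase fs or lower fmax.",
                 "painerd_config_error")
  }
  wl <- round(cfg$window_len * fs)
  n <- ncol(epoch$data)
  if (n < wl) {
    stop_painerd("Epoch shorter than one analysis window.", "painerd_config_error")
  }
  t0 <- epoch$t0
  span <- c(t0, t0 + n / fs)
  centres <- seq(span[1] + cfg$window_len / 2, span[2] - cfg$window_len / 2 + 1e-9,
                 by = cfg$step)
  starts <- round((centres - cfg$window_len / 2 - t0) * fs) + 1
  starts <- pmin(pmax(starts, 1L), n - wl + 1L)
  freqs <- seq(cfg$fmin, cfg$fmax, by = cfg$df)
  fbins <- round(freqs * cfg$window_len) + 1L  # FFT bin indices (df = 1/window_len)
  nw <- cfg$taper_bandwidth * cfg$window_len   # time-bandwidth product
  tapers <- dpss_tapers(wl, nw, cfg$n_tapers)

  nch <- nrow(epoch$data)
  nwin <- length(starts)
  idx <- outer(seq_len(wl) - 1L, starts, "+")
  vals <- array(0, c(1, nch, length(freqs), nwin))
  for (ch in seq_len(nch)) {
    wmat <- matrix(epoch$data[ch, idx], wl, nwin)
    acc <- matrix(0, length(freqs), nwin)
    for (k in seq_len(cfg$n_tapers)) {
      ft <- stats::mvfft(wmat * tapers[, k])
      acc <- acc + (Mod(ft[fbins, , drop = FALSE])^2)
    }
    # one-sided density: 2/(fs*K) * sum_k |FFT|^2 (unit-energy tapers)
    vals[1, ch, , ] <- acc * 2 / (fs * cfg$n_tapers)
  }
  structure(list(values = vals, freqs = freqs, times = centres),
            class = "tf_map")
}

#' Stack spectrograms over an epoch set
#'
#' @param set An `epoch_set`.
#' @param cfg A [spectral_config()].
#' @return A `tf_map` with one trial per epoch; trial metadata in `meta`.
#' @export
spectrogram_set <- function(set, cfg = spectral_config()) {
  tfs <- lapply(set$epochs, multitaper_spectrogram, cfg = cfg)
  first <- tfs[[1]]
  d <- dim(first$values)
  vals <- array(0, c(length(tfs), d[2], d[3], d[4]))
  for (i in seq_along(tfs)) vals[i, , , ] <- tfs[[i]]$values[1, , , ]
  structure(list(values = vals, freqs = first$freqs, times = first$times,
                 meta = set$meta),
            class = "tf_map")
}

#' Average a time-frequency map over trials
#'
#' Collapses the trial dimension by the arithmetic mean of power. Feeding
#' the result to [compute_erd()] gives the classical grand-average ERD
#' estimate, which is consistent for the true band-power change: the
#' averaged baseline power concentrates around its expectation, so the
#' ratio bias that affects single-trial ERD (a noisy per-trial baseline in
#' the denominator inflates the expected ratio) vanishes as trials grow.
#' Optionally restricted to a subset of trials (e.g. one condition).
#'
#' @param tf A `tf_map`.
#' @param trials Optional integer/logical subset of trials.
#' @return A `tf_map` with a single (averaged) trial.
#' @export
tf_average <- function(tf, trials = NULL) {
  d <- dim(tf$values)
  if (is.null(trials)) trials <- seq_len(d[1])
  if (is.logical(trials)) trials <- which(trials)
  m <- apply(tf$values[trials, , , , drop = FALSE], c(2, 3, 4), mean)
  vals <- array(m, c(1, d[2], d[3], d[4]))
  structure(list(values = vals, freqs = tf$freqs, times = tf$times),
            class = "tf_map")
}

#' Event-related desynchronisation (percent change from baseline)
#'
#' For each (trial, channel, frequency): `erd = (A - R)/R * 100`, where `A`
#' is the power at each time point and `R` the mean power over all windows
#' whose centre lies in the baseline interval.
#'
#' @param tf A `tf_map`.
#' @param baseline Baseline interval `c(lo, hi)` in seconds.
#' @return An `erd_map`: list with `values` (same dims, %), `baseline_power`
#'   (trial x channel x frequency), `freqs`, `times` (+ `meta` if present).
#' @export
compute_erd <- function(tf, baseline = c(-3.5, -0.5)) {
  bidx <- which(tf$times >= baseline[1] - 1e-9 & tf$times <= baseline[2] + 1e-9)
  if (length(bidx) < 1) {
    stop_painerd("No window centre falls inside the baseline interval.",
                 "painerd_config_error")
  }
  d <- dim(tf$values)
  r <- rowMeans(tf$values[, , , bidx, drop = FALSE], dims = 3)
  if (any(r <= 0)) {
    bad <- which(r <= 0, arr.ind = TRUE)
    stop_painerd(paste0("Degenerate baseline power (R <= 0) at (trial, channel, frequency) = ",
                        paste(apply(utils::head(bad, 5), 1, paste, collapse = ","),
                              collapse = "; ")),
                 "painerd_degenerate_baseline_error")
  }
  vals <- 100 * (sweep(tf$values, c(1, 2, 3), r, "/") - 1)
  structure(list(values = vals, baseline_power = r, freqs = tf$freqs,
                 times = tf$times, meta = tf$meta),
            class = "erd_map")
}

#' Collapse an ERD map over canonical frequency bands
#'
#' Band value = unweighted mean of ERD over the band's inclusive integer-Hz
#' bins, per trial, channel and time point.
#'
#' @param erd An `erd_map`.
#' @param scheme A [band_scheme()] tibble.
#' @return A `band_erd`: list with `values` (trial x channel x band x time),
#'   `bands`, `times` (+ `meta` if present).
#' @export
collapse_bands <- function(erd, scheme = band_scheme()) {
  d <- dim(erd$values)
  out <- array(0, c(d[1], d[2], nrow(scheme), d[4]))
  for (b in seq_len(nrow(scheme))) {
    fidx <- which(erd$freqs >= scheme$lo[b] & erd$freqs <= scheme$hi[b])
    if (length(fidx) == 0) {
      stop_painerd(sprintf("Band '%s' has no bins on the frequency grid.",
                           scheme$band[b]), "painerd_config_error")
    }
    sub <- aperm(erd$values[, , fidx, , drop = FALSE], c(1, 2, 4, 3))
    out[, , b, ] <- rowMeans(sub, dims = 3)
  }
  structure(list(values = out, bands = scheme, times = erd$times,
                 meta = erd$meta),
            class = "band_erd")
}

#' Band-collapsed ERD straight from an epoch set
#'
#' Memory-lean pipeline driver: spectrogram, ERD transform and band
#' collapse are computed one epoch at a time and stacked.
#'
#' @param set An `epoch_set` (preprocessed).
#' @param cfg A [spectral_config()].
#' @param scheme A [band_scheme()].
#' @param baseline Baseline interval; defaults to `cfg$baseline`.
#' @return A `band_erd` with trial metadata attached.
#' @export
band_erd_from_epochs <- function(set, cfg = spectral_config(),
                                 scheme = band_scheme(),
                                 baseline = cfg$baseline) {
  n <- length(set$epochs)
  first <- collapse_bands(compute_erd(multitaper_spectrogram(set$epochs[[1]], cfg),
                                      baseline), scheme)
  d <- dim(first$values)
  vals <- array(0, c(n, d[2], d[3], d[4]))
  vals[1, , , ] <- first$values[1, , , ]
  if (n > 1) {
    for (i in 2:n) {
      bi <- collapse_bands(compute_erd(multitaper_spectrogram(set$epochs[[i]], cfg),
                                       baseline), scheme)
      vals[i, , , ] <- bi$values[1, , , ]
    }
  }
  structure(list(values = vals, bands = scheme, times = first$times,
                 meta = set$meta),
            class = "band_erd")
}
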