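#' Preprocessing configuration
#'
#' Temporal filtering and resampling applied to every epoch before spectral
#' analysis: 0.5 Hz high-pass, 70 Hz low-pass, 50 +/- 2 Hz notch, then
#' resampling to 256 Hz (output Nyquist 128 Hz).
#'
#' @param hp_cutoff High-pass cutoff, Hz.
#' @param lp_cutoff Low-pass cutoff, Hz.
#' @param notch_center,notch_halfwidth Notch band `center +/- halfwidth`, Hz.
#' @param target_fs Resampling target rate, Hz.
#' @return A list of class `preproc_config`.
#' @export
preproc_config <- function(hp_cutoff = 0.5, lp_cutoff = 70,
                           notch_center = 50, notch_halfwidth = 2,
                           target_fs = 256) {
  if (!(hp_cutoff > 0 && hp_cutoff < lp_cutoff && lp_cutoff < target_fs / 2)) {
    stop_painerd("Need 0 < hp_cutoff < lp_cutoff < target_fs/2.",
                 "painerd_config_error")
  }
  lo <- notch_center - notch_halfwidth
  hi <- notch_center + notch_halfwidth
  if (!(lo > hp_cutoff && hi < lp_cutoff)) {
    stop_painerd("Notch band must lie inside the analysis pass-band.",
                 "painerd_config_error")
  }
  structure(list(hp_cutoff = hp_cutoff, lp_cutoff = lp_cutoff,
                 notch_center = notch_center,
                 notch_halfwidth = notch_halfwidth,
                 target_fs = target_fs),
            class = "preproc_config")
}

#' Apply analysis filters to one epoch
#'
#' Zero-phase filtering with the cascade of a 2nd-order Butterworth
#' high-pass at `hp_cutoff`, a 4th-order Butterworth low-pass at
#' `lp_cutoff` and a 2nd-order Butterworth band-stop over the notch band.
#' The cascade is applied as a zero-phase frequency-response multiplication
#' with each filter's squared magnitude (the response a forward-backward
#' IIR pass realises), so no group delay is introduced and event latencies
#' are preserved; attenuation in dB is twice the single-pass design.
#' Shape and sampling rate are unchanged.
#'
#' @param epoch An `eeg_epoch`.
#' @param cfg A [preproc_config()].
#' @return The filtered `eeg_epoch`.
#' @export
apply_filters <- function(epoch, cfg = preproc_config()) {
  fs <- epoch$fs
  if (fs <= 2 * cfg$lp_cutoff) {
    stop_painerd("Sampling rate too low for the requested low-pass cutoff.",
                 "painerd_config_error")
  }
  n <- ncol(epoch$data)
  f <- fs * (seq_len(n) - 1) / n
  f <- pmin(f, fs - f)  # two-sided folded frequency axis
  # squared Butterworth magnitudes (zero-phase = |H|^2)
  h_lp <- 1 / (1 + (f / cfg$lp_cutoff)^(2 * 4))
  h_hp <- ifelse(f == 0, 0, 1 / (1 + (cfg$hp_cutoff / f)^(2 * 2)))
  lo <- cfg$notch_center - cfg$notch_halfwidth
  hi <- cfg$notch_center + cfg$notch_halfwidth
  bw <- hi - lo; f0sq <- lo * hi
  h_ns <- ifelse(abs(f^2 - f0sq) < 1e-12, 0,
                 1 / (1 + (bw * f / (f0sq - f^2))^(2 * 2)))
  gain <- h_lp * h_hp * h_ns
  x <- stats::mvfft(t(epoch$data))
  epoch$data <- t(Re(stats::mvfft(x * gain, inverse = TRUE)) / n)
  epoch
}

#' Resample one epoch to a lower rate
#'
#' Fourier resampling: the spectrum is truncated at the new Nyquist
#' frequency (ideal anti-aliasing) and inverse-transformed on the coarser
#' grid. Duration is preserved exactly; the output has
#' `duration * target_fs` samples and a Nyquist frequency of
#' `target_fs / 2`; in-band content (frequency and amplitude) is
#' unchanged.
#'
#' @param epoch An `eeg_epoch`.
#' @param target_fs Target sampling rate, Hz; must be below the current
#'   rate and give an integer output length.
#' @return The resampled `eeg_epoch`.
#' @export
resample_epoch <- function(epoch, target_fs = 256) {
  if (target_fs >= epoch$fs) {
    stop_painerd("Upsampling is not supported; `target_fs` must be below the epoch's rate.",
                 "painerd_unsupported_error")
  }
  n <- ncol(epoch$data)
  m_exact <- n * target_fs / epoch$fs
  m <- round(m_exact)
  if (abs(m - m_exact) > 1e-9) {
    stop_painerd("Epoch duration times target_fs must be an integer sample count.",
                 "painerd_config_error")
  }
  x <- stats::mvfft(t(epoch$data))
  half <- m %/% 2
  y <- matrix(0 + 0i, m, nrow(epoch$data))
  y[seq_len(half), ] <- x[seq_len(half), ]
  y[half + 1, ] <- Re(x[half + 1, ])  # new Nyquist bin kept real
  if (half > 1) {
    y[(half + 2):m, ] <- x[(n - half + 2):n, ]
  }
  epoch$data <- t(Re(stats::mvfft(y, inverse = TRUE)) / n)
  epoch$fs <- target_fs
  epoch
}

#' Preprocess every epoch of a set
#'
#' Applies [apply_filters()] then [resample_epoch()] to each epoch.
#'
#' @param set An `epoch_set`.
#' @param cfg A [preproc_config()].
#' @return The preprocessed `epoch_set` (metadata unchanged).
#' @export
preprocess_epochs <- function(set, cfg = preproc_config()) {
  set$epochs <- lapply(set$epochs, function(ep) {
    resample_epoch(apply_filters(ep, cfg), cfg$target_fs)
  })
  set$fs <- cfg$target_fs
  set
}

#' Maximum assessable frequencies after resampling
#'
#' Bookkeeping helper: the theoretical (Shannon) maximum assessable
#' frequency is `fs / 2`; a conservative engineering rule requiring a
#' sampling rate of 2.5 times the highest frequency of interest gives
#' `fs / 2.5`.
#'
#' @param fs Sampling rate, Hz.
#' @return Tibble with columns `nyquist` and `conservative` (Hz).
#' @export
#' @examples
#' max_assessable_frequency(256)  # 128 and 102.4 Hz
max_assessable_frequency <- function(fs) {
  tibble::tibble(nyquist = fs / 2, conservative = fs / 2.5)
}
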