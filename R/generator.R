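#' Default ground-truth ERD targets for the synthetic generator
#'
#' Target band-power changes (ERD %, negative = desynchronisation; positive
#' = synchronisation) imposed on the oscillators of specific channel groups
#' during the stimulation window. The default profile follows the
#' tonic-pain EEG literature: theta power increases over frontal/central
#' sites, alpha and lower-beta desynchronise over central/parietal sites,
#' and gamma increases over central (somatosensory) sites -- each effect
#' stronger for high than for low pain, so the classes are separable in
#' exactly the band-power features the pipeline extracts.
#'
#' @return A tibble with columns `intensity`, `group`, `band`, `erd`.
#' @export
erd_targets_default <- function() {
  dplyr::bind_rows(
    tibble::tibble(intensity = "low",
                   group = c("frontal", "central", "central", "parietal",
                             "central", "parietal", "central"),
                   band = c("theta", "theta", "alpha", "alpha",
                            "lower_beta", "lower_beta", "gamma"),
                   erd = c(10, 10, -15, -15, -10, -10, 8)),
    tibble::tibble(intensity = "high",
                   group = c("frontal", "central", "central", "parietal",
                             "central", "parietal", "central"),
                   band = c("theta", "theta", "alpha", "alpha",
                            "lower_beta", "lower_beta", "gamma"),
                   erd = c(25, 25, -40, -40, -25, -25, 25))
  )
}

#' Synthetic-EEG generator configuration
#'
#' The generator emits peri-stimulus epochs as 1/f^beta background noise
#' plus independent band-limited Gaussian oscillators per canonical band.
#' During the stimulation window (rise ramp then 3 s hold) the variance of
#' targeted oscillators is scaled multiplicatively by `1 + erd/100`, so the
#' baseline-relative power change recovered by the spectral stage equals the
#' target in expectation (up to the small dilution by in-band background
#' power). Ratings follow a condition-mean model on the 0-100 scale.
#'
#' @param n_channels Number of channels (desk-scale default 8; the full
#'   recording montage had 128 analysed channels).
#' @param fs_raw Raw sampling rate in Hz (1000).
#' @param epoch_span Two-element numeric, seconds relative to stimulus onset
#'   (`c(-4, 6)`).
#' @param background_exponent Spectral slope beta of the 1/f^beta background.
#' @param noise_sd Background RMS amplitude (a.u.).
#' @param band_amplitudes Named per-band oscillator RMS amplitudes (a.u.).
#' @param erd_targets Tibble `(intensity, group, band, erd)`; see
#'   [erd_targets_default()]. Values must be >= -100.
#' @param recover_time Seconds over which band power returns smoothly
#'   (half-cosine) to baseline after stimulus offset.
#' @param slow_rise_atten Multiplier applied to ERD targets for slow-rise
#'   (3 s) conditions; < 1 attenuates the class contrast in the second
#'   external-validation set.
#' @param participant_sdlog Log-normal SD of per-participant band-amplitude
#'   scaling factors.
#' @param n_participants Participants per simulated study (round-robin
#'   assignment over trials).
#' @param rating_model List with `low_mean`, `high_mean`, `touch_mean`,
#'   `rise_effect` (subtracted for slow rise), `study_shift` (added for
#'   study two), `sd`; all on the 0-100 rating scale.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_channels = 8, fs_raw = 1000,
                             epoch_span = c(-4, 6),
                             background_exponent = 1,
                             noise_sd = 1,
                             band_amplitudes = c(theta = 1.5, alpha = 2,
                                                 lower_beta = 1.2,
                                                 upper_beta = 0.8,
                                                 gamma = 1.0),
                             erd_targets = erd_targets_default(),
                             recover_time = 1,
                             slow_rise_atten = 0.5,
                             participant_sdlog = 0.1,
                             n_participants = 5,
                             rating_model = list(low_mean = 36.87,
                                                 high_mean = 62.65,
                                                 touch_mean = 8,
                                                 rise_effect = 4,
                                                 study_shift = 12.3,
                                                 sd = 14)) {
  stopifnot(is_count(n_channels), fs_raw > 0, length(epoch_span) == 2,
            epoch_span[1] < 0, epoch_span[2] > 0)
  if (any(band_amplitudes < 0)) {
    stop_painerd("Band amplitudes must be non-negative.", "painerd_config_error")
  }
  if (any(erd_targets$erd < -100)) {
    stop_painerd("ERD targets below -100% are impossible (power cannot be negative).",
                 "painerd_config_error")
  }
  means <- unlist(rating_model[c("low_mean", "high_mean", "touch_mean")])
  if (any(means < 0 | means > 100)) {
    stop_painerd("Rating-model means must lie in [0, 100].", "painerd_config_error")
  }
  cfg <- list(
    n_channels = as.integer(n_channels), fs_raw = fs_raw,
    epoch_span = epoch_span, background_exponent = background_exponent,
    noise_sd = noise_sd, band_amplitudes = band_amplitudes,
    erd_targets = erd_targets, recover_time = recover_time,
    slow_rise_atten = slow_rise_atten,
    participant_sdlog = participant_sdlog,
    n_participants = as.integer(n_participants),
    rating_model = rating_model,
    channel_groups = default_channel_groups(n_channels)
  )
  class(cfg) <- "generator_config"
  cfg
}

# scalp-region stand-ins: channels split into three contiguous groups
default_channel_groups <- function(n_channels) {
  idx <- seq_len(n_channels)
  cut3 <- split(idx, cut(idx, 3, labels = c("frontal", "central", "parietal")))
  lapply(cut3, as.integer)
}

# colored / band-limited Gaussian noise, synthesised in the frequency
# domain: complex white spectrum shaped by a symmetric amplitude weight;
# the real part of one inverse FFT per column is a stationary Gaussian
# process with the target power spectrum. `shape_fun` maps (two-sided
# folded) frequency in Hz to an amplitude weight.
shaped_noise <- function(n, n_cols, fs, shape_fun) {
  f <- fs * (seq_len(n) - 1) / n
  f_fold <- pmin(f, fs - f)
  a <- shape_fun(f_fold)
  a[1] <- 0  # no DC
  z <- matrix(complex(real = rnorm(n * n_cols),
                      imaginary = rnorm(n * n_cols)), n, n_cols)
  Re(stats::mvfft(z * a, inverse = TRUE)) / n
}

rms_cols <- function(x) sqrt(colMeans(x^2))

#' Simulate one peri-stimulus epoch
#'
#' Produces a channels x samples array: 1/f background plus per-band
#' oscillators, with targeted oscillators' variance ramped to `1 + erd/100`
#' over the condition's rise time, held through the 3 s plateau, and back at
#' baseline outside the stimulation window.
#'
#' @param cond One-row tibble from [condition_spec()] (or a schedule row).
#' @param gen A [generator_config()].
#' @param seed Integer seed (bit-identical output for identical seeds).
#' @param participant_scale Optional named per-band amplitude multipliers
#'   (inter-participant variability); default all 1.
#' @return An object of class `eeg_epoch`: list with `data`
#'   (channels x samples matrix), `fs`, `t0`, `meta`.
#' @export
#' @examples
#' ep <- simulate_epoch(condition_spec("high"), generator_config(), seed = 1)
#' dim(ep$data)
simulate_epoch <- function(cond, gen, seed = 1L, participant_scale = NULL) {
  stopifnot(inherits(gen, "generator_config"))
  fs <- gen$fs_raw
  span <- gen$epoch_span
  n <- round((span[2] - span[1]) * fs)
  t <- span[1] + (seq_len(n) - 1) / fs
  nch <- gen$n_channels
  bands <- band_scheme()
  beta <- gen$background_exponent
  if (is.null(participant_scale)) {
    participant_scale <- stats::setNames(rep(1, nrow(bands)), bands$band)
  }

  # per (channel, band) variance gain during stimulation
  erd <- gen$erd_targets
  if (!is.na(cond$intensity) && cond$intensity %in% erd$intensity) {
    erd <- erd[erd$intensity == cond$intensity, , drop = FALSE]
  } else {
    erd <- erd[0, , drop = FALSE]
  }
  atten <- if (isTRUE(cond$rise_time == 3)) gen$slow_rise_atten else 1
  rise <- cond$rise_time
  hold <- cond$hold_time

  with_seed(seed, {
    bg <- shaped_noise(n, nch, fs, function(f) ifelse(f > 0, 1 / pmax(f, 1)^(beta / 2), 0))
    bg <- sweep(bg, 2, rms_cols(bg) / gen$noise_sd, "/")
    data <- t(bg)

    for (bi in seq_len(nrow(bands))) {
      bname <- bands$band[bi]
      lo <- bands$lo[bi]; hi <- bands$hi[bi]
      osc <- shaped_noise(n, nch, fs, function(f) as.numeric(f >= lo & f <= hi))
      amp <- gen$band_amplitudes[[bname]] * participant_scale[[bname]]
      if (amp == 0) next
      osc <- sweep(osc, 2, rms_cols(osc) / amp, "/")
      # amplitude envelope sqrt(variance gain) per channel
      for (grp in names(gen$channel_groups)) {
        chans <- gen$channel_groups[[grp]]
        row <- erd[erd$group == grp & erd$band == bname, , drop = FALSE]
        if (nrow(row) == 1 && row$erd != 0) {
          g <- row$erd / 100 * atten
          rec <- gen$recover_time
          vgain <- rep(1, n)
          in_rise <- t >= 0 & t < rise
          in_hold <- t >= rise & t <= rise + hold
          in_rec <- t > rise + hold & t <= rise + hold + rec
          vgain[in_rise] <- 1 + g * t[in_rise] / rise
          vgain[in_hold] <- 1 + g
          # smooth post-offset recovery: an abrupt gain step would smear
          # broadband transient power into every band
          vgain[in_rec] <- 1 + g * (1 + cos(pi * (t[in_rec] - rise - hold) / rec)) / 2
          osc[, chans] <- osc[, chans] * sqrt(vgain)
        }
      }
      data <- data + t(osc)
    }
    structure(list(data = data, fs = fs, t0 = span[1],
                   meta = list(condition = cond$condition,
                               intensity = cond$intensity,
                               rise_time = cond$rise_time,
                               label = cond$label)),
              class = "eeg_epoch")
  })
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %d channels x %d samples @ %g Hz, t0 = %g s\n",
              nrow(x$data), ncol(x$data), x$fs, x$t0))
  invisible(x)
}

#' Simulate a full study: one epoch per scheduled trial
#'
#' Draws the trial schedule for `design`, assigns participants round-robin,
#' applies per-participant log-normal band-amplitude factors, and simulates
#' every epoch with a per-trial derived seed (the whole set is reproducible
#' from `seed` alone).
#'
#' @param design A [study_design()].
#' @param gen A [generator_config()].
#' @param seed Integer master seed.
#' @return An object of class `epoch_set`: list with `epochs` (list of
#'   `eeg_epoch`), `meta` (tibble: one row per trial, schedule columns plus
#'   `participant` and `study`), `fs`, `t0`.
#' @export
simulate_study <- function(design, gen, seed = 1L) {
  sched <- make_schedule(design, seed = derive_seed(seed, 1))
  n_trials <- nrow(sched)
  participants <- rep_len(seq_len(gen$n_participants), n_trials)
  bands <- band_scheme()$band
  pfac <- with_seed(derive_seed(seed, 2), {
    matrix(stats::rlnorm(gen$n_participants * length(bands),
                         meanlog = 0, sdlog = gen$participant_sdlog),
           gen$n_participants, length(bands),
           dimnames = list(NULL, bands))
  })
  epochs <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    epochs[[i]] <- simulate_epoch(
      sched[i, ], gen, seed = derive_seed(seed, 2 + i),
      participant_scale = pfac[participants[i], ]
    )
  }
  meta <- dplyr::mutate(sched,
                        participant = participants,
                        study = design$study_id)
  structure(list(epochs = epochs, meta = meta, fs = gen$fs_raw,
                 t0 = gen$epoch_span[1]),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs, %d channels @ %g Hz\n",
              length(x$epochs), nrow(x$epochs[[1]]$data), x$fs))
  print(dplyr::count(x$meta, .data$condition))
  invisible(x)
}

#' Subset an epoch set by trial index or predicate
#'
#' @param set An `epoch_set`.
#' @param idx Integer or logical index into trials.
#' @return A new `epoch_set` with the selected trials.
#' @export
subset_epochs <- function(set, idx) {
  if (is.logical(idx)) idx <- which(idx)
  structure(list(epochs = set$epochs[idx],
                 meta = set$meta[idx, , drop = FALSE],
                 fs = set$fs, t0 = set$t0),
            class = "epoch_set")
}

#' Simulate behavioural pain ratings for a schedule
#'
#' Rating = condition mean (low/high/touch), minus the rise-time effect for
#' slow-rise trials, plus a between-study shift for study two, plus Gaussian
#' noise; clipped to the 0-100 visual-analogue scale.
#'
#' @param schedule Schedule tibble from [make_schedule()] (needs columns
#'   `intensity`, `rise_time`; a `study` column is used when present).
#' @param gen A [generator_config()] supplying the rating model.
#' @param seed Integer seed.
#' @return The schedule with a `rating` column appended.
#' @export
simulate_ratings <- function(schedule, gen, seed = 1L) {
  rm_ <- gen$rating_model
  mu <- dplyr::case_when(
    schedule$intensity == "low" ~ rm_$low_mean,
    schedule$intensity == "high" ~ rm_$high_mean,
    TRUE ~ rm_$touch_mean
  )
  mu <- mu - rm_$rise_effect * (schedule$rise_time == 3)
  if ("study" %in% names(schedule)) {
    mu <- mu + rm_$study_shift * (schedule$study == "two")
  }
  noise <- with_seed(seed, rnorm(nrow(schedule), 0, rm_$sd))
  schedule$rating <- pmin(100, pmax(0, mu + noise))
  schedule
}
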