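# shared fixture builders (all generated in code; nothing on disk)

# single-channel epoch holding a pure sinusoid (or DC) at 1000 Hz
sine_epoch <- function(freq, fs = 1000, span = c(-4, 6), amp = 1) {
  t <- seq(span[1], span[2] - 1 / fs, by = 1 / fs)
  x <- if (freq == 0) rep(amp, length(t)) else amp * sin(2 * pi * freq * t)
  structure(list(data = matrix(x, 1), fs = fs, t0 = span[1], meta = list()),
            class = "eeg_epoch")
}

epoch_rms <- function(ep) sqrt(mean(ep$data^2))

# bare feature table around a numeric matrix
toy_table <- function(x, label, intensity = NULL, study = NULL) {
  stopifnot(!is.null(colnames(x)))
  meta <- tibble::tibble(.trial = seq_len(nrow(x)), .label = label)
  if (!is.null(intensity)) meta$.intensity <- intensity
  if (!is.null(study)) meta$.study <- study
  dplyr::bind_cols(meta, tibble::as_tibble(x))
}

# balanced two-condition design (low/high only) for compact studies
small_design <- function(n_blocks = 2, per_cond_per_block = 5) {
  conds <- dplyr::bind_rows(condition_spec("low", 1), condition_spec("high", 1))
  quota <- matrix(per_cond_per_block, n_blocks, 2,
                  dimnames = list(NULL, conds$condition))
  structure(list(study_id = "one", n_blocks = n_blocks,
                 trials_per_block = 2 * per_cond_per_block,
                 conditions = conds, per_block_quota = quota,
                 min_isi = 16, constraint_no_repeat = TRUE),
            class = "study_design")
}

# feature table straight from the generator + full signal path
small_feature_table <- function(n_blocks = 2, per_cond_per_block = 5,
                                seed = 7, gen = generator_config()) {
  set <- simulate_study(small_design(n_blocks, per_cond_per_block), gen, seed)
  set <- preprocess_epochs(set)
  trial_features(band_erd_from_epochs(set))
}

# crafted tf_map with constant baseline power r and active power a
flat_tf <- function(r, a, n_trials = 1, n_ch = 1,
                    freqs = 1:70, times = seq(-3.5, 5.5, by = 0.5)) {
  vals <- array(r, c(n_trials, n_ch, length(freqs), length(times)))
  vals[, , , times > 0] <- a
  structure(list(values = vals, freqs = freqs, times = times),
            class = "tf_map")
}
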