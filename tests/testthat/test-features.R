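test_that("the statistic catalogue matches hand-computed oracles", {
  x <- c(1, 2, 3)
  expect_equal(compute_statistic(x, "mean"), 2)
  expect_equal(compute_statistic(x, "median"), 2)
  expect_equal(compute_statistic(x, "range"), 2)
  expect_equal(compute_statistic(x, "variance"), 1)
  expect_equal(compute_statistic(x, "rms"), sqrt(14 / 3))
  expect_equal(compute_statistic(x, "sd"), 1)
  expect_equal(compute_statistic(x, "min"), 1)
  expect_equal(compute_statistic(x, "max"), 3)
  expect_equal(compute_statistic(x, "abs_mean"), 2)
  expect_equal(compute_statistic(x, "squared_mean"), 4)
  expect_equal(compute_statistic(x, "skewness"), 0)
  # raw (uncorrected) kurtosis: m4/m2^2 = (2/3)/(2/3)^2
  expect_equal(compute_statistic(x, "kurtosis"), 1.5)
  # energy entropies with the 0 log 0 := 0 convention
  expect_equal(compute_statistic(1, "shannon_entropy"), 0)
  expect_equal(compute_statistic(c(0.5, 0.5), "shannon_entropy"),
               -2 * 0.25 * log(0.25))
  expect_equal(compute_statistic(x, "log_energy_entropy"), log(4) + log(9))
  expect_equal(compute_statistic(c(0, 2), "log_energy_entropy"), log(4))
  # mode ties break toward the smallest value
  expect_equal(compute_statistic(c(3, 1, 3, 1, 2), "mode"), 1)
  expect_equal(compute_statistic(c(5, 5, 2), "mode"), 5)
  expect_error(compute_statistic(x, "nope"), class = "painerd_config_error")
  expect_error(compute_statistic(1, "sd"), class = "painerd_config_error")
})

test_that("constant time courses give the closed-form feature values", {
  c0 <- -7
  vals <- array(c0, c(2, 1, 5, 11))
  be <- structure(list(values = vals, bands = band_scheme(),
                       times = seq(0, 1, 0.1),
                       meta = tibble::tibble(trial_global = 1:2, label = c(0L, 1L))),
                  class = "band_erd")
  ft <- trial_features(be)
  expect_equal(ft$ch01_alpha_mean, c(c0, c0))
  expect_equal(ft$ch01_alpha_median, c(c0, c0))
  expect_equal(ft$ch01_theta_min, ft$ch01_theta_max)
  expect_equal(ft$ch01_gamma_range, c(0, 0))
  expect_equal(ft$ch01_gamma_sd, c(0, 0))
  expect_equal(ft$ch01_lower_beta_variance, c(0, 0))
  expect_equal(ft$ch01_upper_beta_rms, c(abs(c0), abs(c0)))
  expect_equal(ft$ch01_alpha_squared_mean, c(c0^2, c0^2))
})

test_that("feature count law: channels x 5 bands x 15 statistics", {
  for (nch in c(1, 8)) {
    vals <- array(rnorm(3 * nch * 5 * 7), c(3, nch, 5, 7))
    be <- structure(list(values = vals, bands = band_scheme(),
                         times = seq_len(7), meta = tibble::tibble(x = 1:3)),
                    class = "band_erd")
    ft <- trial_features(be)
    expect_length(feature_cols(ft), nch * 5 * 15)
  }
})

test_that("MAD outliers are interpolated from their neighbours", {
  x <- matrix(c(1, 2, 100, 4, 5), ncol = 1, dimnames = list(NULL, "f1"))
  tab <- toy_table(x, label = rep(0L, 5))
  out <- suppressWarnings(fill_outliers(tab))
  # median 4, scaled MAD 2.9652, threshold 8.8956: only 100 is flagged
  expect_equal(out$f1, c(1, 2, 3, 4, 5))
  expect_equal(sum(attr(out, "outlier_mask")), 1)

  # boundary flags take the nearest surviving value
  xb <- matrix(c(100, 2, 3, 4, 5), ncol = 1, dimnames = list(NULL, "f1"))
  outb <- suppressWarnings(fill_outliers(toy_table(xb, label = rep(0L, 5))))
  expect_equal(outb$f1, c(2, 2, 3, 4, 5))

  # missing values are treated like flags
  xm <- matrix(c(1, NA, 3, 4, 5), ncol = 1, dimnames = list(NULL, "f1"))
  outm <- suppressWarnings(fill_outliers(toy_table(xm, label = rep(0L, 5))))
  expect_equal(outm$f1, c(1, 2, 3, 4, 5))
})

test_that("outlier handling is grouped per condition and idempotent", {
  x <- matrix(c(1, 2, 100, 4, 5, 50, 52, 54, 300, 56), ncol = 1,
              dimnames = list(NULL, "f1"))
  tab <- toy_table(x, label = rep(c(0L, 1L), each = 5),
                   intensity = rep(c("low", "high"), each = 5))
  out <- suppressWarnings(fill_outliers(tab))
  expect_equal(out$f1[1:5], c(1, 2, 3, 4, 5))
  expect_equal(out$f1[9], (54 + 56) / 2)
  twice <- fill_outliers(out)
  expect_equal(twice$f1, out$f1)
  expect_equal(sum(attr(twice, "outlier_mask")), 0)

  # identical values never flag; untouched tables report an empty mask
  const <- toy_table(matrix(3, 4, 1, dimnames = list(NULL, "f1")), rep(0L, 4))
  outc <- fill_outliers(const)
  expect_equal(outc$f1, rep(3, 4))
  expect_equal(sum(attr(outc, "outlier_mask")), 0)

  # an all-flagged group is an explicit error
  allbad <- toy_table(matrix(c(0, 1e6), 2, 1, dimnames = list(NULL, "f1")),
                      label = c(0L, 1L), intensity = c("low", "low"))
  allbad$f1 <- c(NA_real_, NA_real_)
  expect_error(fill_outliers(allbad), class = "painerd_outlier_error")
})

test_that("min-max scaling maps fit columns onto [0, 1] exactly", {
  x <- matrix(c(2, 4, 6, 5, 5, 5), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  tab <- toy_table(x, label = c(0L, 1L, 0L))
  sc <- scale_minmax(tab)
  expect_equal(sc$table$a, c(0, 0.5, 1))
  expect_equal(sc$table$b, c(0, 0, 0))  # constant column rule
  # transform-only mode extrapolates without clipping
  new <- toy_table(matrix(c(8, 5), ncol = 2, dimnames = list(NULL, c("a", "b"))),
                   label = 0L)
  tr <- scale_minmax(new, sc$params)
  expect_equal(tr$table$a, 1.5, ignore_attr = TRUE)
  # fitted ranges are exactly [0,1] for non-constant columns
  set.seed(1)
  big <- toy_table(matrix(rnorm(200), 20, 10,
                          dimnames = list(NULL, paste0("f", 1:10))),
                   label = rep(0:1, 10))
  sb <- scale_minmax(big)
  rng <- sapply(feature_cols(sb$table), function(f) range(sb$table[[f]]))
  expect_equal(unname(rng[1, ]), rep(0, 10))
  expect_equal(unname(rng[2, ]), rep(1, 10))
})

test_that("interpolated fraction on generator data stays small", {
  ft <- small_feature_table(n_blocks = 2, per_cond_per_block = 6, seed = 21)
  out <- fill_outliers(ft)
  expect_lt(attr(out, "outlier_fraction"), 0.15)
})
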