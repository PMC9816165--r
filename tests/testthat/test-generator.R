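test_that("epoch shape follows span and sampling rate", {
  gen <- generator_config(n_channels = 8, fs_raw = 1000)
  ep <- simulate_epoch(condition_spec("low"), gen, seed = 1)
  expect_equal(dim(ep$data), c(8, 10000))
  expect_true(all(is.finite(ep$data)))
  expect_equal(ep$fs, 1000)
  expect_equal(ep$t0, -4)
})

test_that("identical seeds give bit-identical epochs, different seeds differ", {
  gen <- generator_config(n_channels = 4)
  a <- simulate_epoch(condition_spec("high"), gen, seed = 99)
  b <- simulate_epoch(condition_spec("high"), gen, seed = 99)
  expect_identical(a$data, b$data)
  c <- simulate_epoch(condition_spec("high"), gen, seed = 100)
  expect_false(identical(a$data, c$data))
})

test_that("null modulation leaves baseline and active band power equal", {
  null_targets <- erd_targets_default()
  null_targets$erd <- 0
  gen <- generator_config(n_channels = 4, erd_targets = null_targets)
  # pool several epochs; compare raw alpha-band variance before/after onset
  ratio <- sapply(1:12, function(i) {
    ep <- simulate_epoch(condition_spec("high"), gen, seed = i)
    t <- ep$t0 + (seq_len(ncol(ep$data)) - 1) / ep$fs
    base <- ep$data[, t >= -3.5 & t <= -0.5]
    act <- ep$data[, t >= 1 & t <= 4]
    mean(apply(act, 1, var)) / mean(apply(base, 1, var))
  })
  expect_lt(abs(mean(ratio) - 1), 0.1)
})

test_that("simulate_study emits one epoch per trial with study-one counts", {
  gen <- generator_config(n_channels = 2)
  set <- simulate_study(study_design("one"), gen, seed = 3)
  expect_length(set$epochs, 120)
  expect_true(all(table(set$meta$condition) == 40))
  expect_equal(sort(unique(set$meta$participant)), 1:5)
  set2 <- simulate_study(study_design("one"), gen, seed = 3)
  expect_identical(set$epochs[[17]]$data, set2$epochs[[17]]$data)
})

test_that("study-two sets split into two 72-trial validation subsets", {
  gen <- generator_config(n_channels = 2)
  set <- simulate_study(study_design("two"), gen, seed = 4)
  expect_length(set$epochs, 144)
  ev1 <- subset_epochs(set, set$meta$rise_time == 1)
  ev2 <- subset_epochs(set, set$meta$rise_time == 3)
  expect_length(ev1$epochs, 72)
  expect_length(ev2$epochs, 72)
  expect_true(all(table(ev1$meta$intensity) == 36))
  expect_true(all(table(ev2$meta$intensity) == 36))
})

test_that("ratings follow the condition-mean model and stay on the 0-100 scale", {
  gen0 <- generator_config()
  gen0$rating_model$sd <- 0
  sched <- make_schedule(study_design("one"), seed = 1)
  r <- simulate_ratings(sched, gen0, seed = 1)
  expect_equal(unique(r$rating[r$intensity == "low"]), 36.87)
  expect_equal(unique(r$rating[r$intensity == "high"]), 62.65)

  # slow rise subtracts the rise effect; study two adds the study shift
  sched2 <- make_schedule(study_design("two"), seed = 1)
  sched2$study <- "two"
  r2 <- simulate_ratings(sched2, gen0, seed = 1)
  fast_high <- unique(r2$rating[r2$intensity == "high" & r2$rise_time == 1])
  slow_high <- unique(r2$rating[r2$intensity == "high" & r2$rise_time == 3])
  expect_equal(fast_high - slow_high, gen0$rating_model$rise_effect)
  expect_equal(fast_high, 62.65 + gen0$rating_model$study_shift)

  # clipping contract under extreme noise
  genx <- generator_config()
  genx$rating_model$sd <- 200
  rx <- simulate_ratings(sched, genx, seed = 2)
  expect_true(all(rx$rating >= 0 & rx$rating <= 100))

  # CLT: large-n sample means reproduce configured means within 2 SE
  genc <- generator_config()
  big <- dplyr::bind_rows(replicate(40, sched, simplify = FALSE))
  rc <- simulate_ratings(big, genc, seed = 3)
  for (lev in c("low", "high")) {
    v <- rc$rating[rc$intensity == lev]
    target <- if (lev == "low") 36.87 else 62.65
    expect_lt(abs(mean(v) - target), 2 * sd(v) / sqrt(length(v)))
  }
})

test_that("generator config rejects impossible targets and amplitudes", {
  bad <- erd_targets_default()
  bad$erd[1] <- -150
  expect_error(generator_config(erd_targets = bad), class = "painerd_config_error")
  expect_error(generator_config(band_amplitudes = c(theta = -1)),
               class = "painerd_config_error")
  expect_error(generator_config(rating_model = list(low_mean = 120,
                                                    high_mean = 60,
                                                    touch_mean = 5,
                                                    rise_effect = 4,
                                                    study_shift = 0, sd = 10)),
               class = "painerd_config_error")
})
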