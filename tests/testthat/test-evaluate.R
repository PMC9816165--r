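test_that("stratified folds balance both classes to within one trial", {
  f <- stratified_folds(rep(c(0, 1), each = 10), cv_config(k = 10, seed = 1))
  counts <- table(f, rep(c(0, 1), each = 10))
  expect_true(all(counts == 1))

  y <- c(rep(0, 9), rep(1, 11))
  for (seed in 1:5) {
    f2 <- suppressWarnings(stratified_folds(y, cv_config(k = 10, seed = seed)))
    tab <- table(factor(f2, levels = 1:10), y)
    expect_true(all(abs(tab[, 1] - 0.9) <= 1))
    expect_true(all(abs(tab[, 2] - 1.1) <= 1))
    expect_equal(sum(tab), 20)
  }

  expect_error(stratified_folds(c(0, 1), cv_config(k = 10)),
               class = "painerd_config_error")
  expect_identical(stratified_folds(y, cv_config(k = 5, seed = 3)),
                   stratified_folds(y, cv_config(k = 5, seed = 3)))
})

test_that("confusion counts match their definitions", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 0))
  expect_equal(as.list(cm), list(tp = 1L, fp = 0L, fn = 1L, tn = 2L))
  perfect <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$fp + perfect$fn, 0)
  all1 <- confusion(c(1, 1, 0, 0), c(1, 1, 1, 1))
  expect_equal(as.list(all1), list(tp = 2L, fp = 2L, fn = 0L, tn = 0L))
  expect_error(confusion(c(1, 0), 1), class = "painerd_config_error")
})

test_that("discrimination metrics reproduce hand-worked values", {
  # tp 3, fp 1, fn 2, tn 4
  y <- c(rep(1, 5), rep(0, 5))
  p <- c(0.9, 0.9, 0.9, 0.1, 0.1, 0.9, 0.1, 0.1, 0.1, 0.1)
  m <- discrimination_metrics(p, y)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)
  expect_equal(m$brier, mean((p - y)^2))

  # no-skill constants
  m2 <- suppressWarnings(
    discrimination_metrics(rep(0.5, 10), rep(c(0, 1), 5)))
  expect_equal(m2$auc, 0.5)
  expect_equal(m2$brier, 0.25)

  # pairwise oracle example
  m3 <- discrimination_metrics(c(0.7, 0.3, 0.6, 0.4), c(1, 1, 0, 0))
  expect_equal(m3$auc, 0.5)

  # zero-denominator convention: all-negative predictions
  expect_warning(
    m4 <- discrimination_metrics(rep(0.1, 4), c(1, 1, 0, 0)),
    "undefined")
  expect_equal(m4$precision, 0)
  expect_equal(m4$recall, 0)
  expect_equal(m4$f1, 0)
})

test_that("rank AUC, ROC trapezoid and the brute-force pairwise statistic agree", {
  pairwise_auc <- function(p, y) {
    pos <- p[y == 1]; neg <- p[y == 0]
    s <- 0
    for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
    s / (length(pos) * length(neg))
  }
  set.seed(12)
  for (rep_i in 1:20) {
    n <- sample(4:50, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    p <- round(runif(n), sample(c(1, 2, 6), 1))  # coarse rounding forces ties
    roc <- roc_points(p, y)
    area <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
    bf <- pairwise_auc(p, y)
    m <- suppressWarnings(discrimination_metrics(p, y))
    expect_equal(m$auc, bf, tolerance = 1e-12)
    expect_equal(area, bf, tolerance = 1e-12)
    # independent library cross-check
    ref <- as.numeric(suppressMessages(pROC::auc(y, p, direction = "<")))
    expect_equal(m$auc, ref, tolerance = 1e-12)
  }
})

test_that("ROC curves span (0,0) to (1,1) and flag degenerate input", {
  roc <- roc_points(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
  expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))  # perfect ranking corner
  const <- roc_points(rep(0.5, 6), rep(c(0, 1), 3))
  expect_equal(nrow(const), 2)
  expect_error(roc_points(c(0.1, 0.9), c(1, 1)), class = "painerd_config_error")
})

test_that("calibration bins summarise predictions as stated", {
  cc <- calibration_curve(rep(0.5, 8), rep(c(0, 1), 4))
  occ <- cc[cc$n > 0, ]
  expect_equal(nrow(occ), 1)
  expect_equal(occ$mean_pred, 0.5)
  expect_equal(occ$obs_freq, 0.5)
  expect_equal(sum(cc$n), 8)

  over <- calibration_curve(rep(0.9, 5), rep(0, 5))
  occ2 <- over[over$n > 0, ]
  expect_equal(occ2$mean_pred, 0.9)
  expect_equal(occ2$obs_freq, 0)

  # simulated known calibration: curve hugs the diagonal
  set.seed(13)
  p <- runif(4000)
  y <- rbinom(4000, 1, p)
  cc3 <- calibration_curve(p, y)
  occ3 <- cc3[cc3$n > 0, ]
  expect_lt(max(abs(occ3$mean_pred - occ3$obs_freq)), 0.08)

  expect_error(calibration_curve(0.5, 1, n_bins = 1),
               class = "painerd_config_error")
})

test_that("cross-validation is exact on separable data and at chance on permuted labels", {
  set.seed(14)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(f1 = y + rnorm(n, 0, 0.05), f2 = rnorm(n))
  tab <- toy_table(x, y)
  res <- cross_validate(model_spec("lda"), tab, cv_config(k = 5, seed = 1))
  expect_equal(res$metrics$mean[res$metrics$metric == "accuracy"], 1)
  expect_equal(res$metrics$sd[res$metrics$metric == "accuracy"], 0)
  expect_equal(nrow(res$predictions), n)

  tabp <- tab
  set.seed(15)
  tabp$.label <- sample(tabp$.label)
  resp <- cross_validate(model_spec("lda"), tabp, cv_config(k = 5, seed = 1))
  accp <- resp$metrics$mean[resp$metrics$metric == "accuracy"]
  expect_lt(abs(accp - 0.5), 0.2)
})

test_that("external validation freezes the model and checks its inputs", {
  set.seed(16)
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(f1 = y + rnorm(n, 0, 0.1), f2 = rnorm(n))
  tab <- toy_table(x, y)
  fit <- fit_model(model_spec("lda"), tab)
  # smoke: identical ev set reproduces training metrics
  train_metrics <- discrimination_metrics(predict(fit, tab), y)
  ev <- external_validate(list(lda = fit), list(ev1 = tab))
  expect_equal(ev$metrics$accuracy, train_metrics$accuracy)
  expect_equal(ev$metrics$auc, train_metrics$auc)
  expect_equal(sum(ev$calibration$n), n)

  expect_error(external_validate(list(lda = fit), list(ev1 = tab[0, ])),
               class = "painerd_config_error")
  bad <- tab
  names(bad)[names(bad) == "f1"] <- "other"
  expect_error(external_validate(list(lda = fit), list(ev1 = bad)),
               class = "painerd_feature_mismatch_error")
})

test_that("nested selection sees only its training fold", {
  set.seed(17)
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  tab <- toy_table(x, y)
  folds <- stratified_folds(y, cv_config(k = 4, seed = 2))
  select_fun <- function(tr) {
    sc <- scale_minmax(tr)
    rk <- rank_features(sc$table)
    list(features = head(rk$feature, 3), scaler = sc$params)
  }
  tr1 <- tab[folds != 1, ]
  sel_a <- select_fun(tr1)
  # perturbing held-out rows must not change the fitted transforms
  tab2 <- tab
  tab2[folds == 1, paste0("f", 1:6)] <-
    tab2[folds == 1, paste0("f", 1:6)] * 5 + 7
  sel_b <- select_fun(tab2[folds != 1, ])
  expect_identical(sel_a, sel_b)
})
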