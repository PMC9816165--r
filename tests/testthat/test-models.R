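make_noise_table <- function(n = 60, p = 8, seed = 1, informative = 0) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  if (informative > 0) {
    for (j in seq_len(informative)) x[, j] <- x[, j] + y * 2
  }
  toy_table(x, label = sample(y))
}

test_that("a perfect separator outranks noise and constants rank last", {
  set.seed(3)
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  x[, 3] <- y                 # perfect separator
  x[, 5] <- 1                 # constant
  rk <- rank_features(toy_table(x, y))
  expect_equal(rk$feature[1], "f3")
  expect_equal(rk$feature[5], "f5")
  expect_equal(rk$score[rk$feature == "f5"], 0, ignore_attr = TRUE)
  expect_true(all(diff(rk$score) <= 0))
})

test_that("the vectorised F-statistic matches aov and duplicates tie stably", {
  set.seed(4)
  n <- 30
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "a_copy")))
  x[, 3] <- x[, 1]
  rk <- rank_features(toy_table(x, y))
  for (f in c("a", "b")) {
    fit <- stats::aov(x[, f] ~ factor(y))
    f_aov <- summary(fit)[[1]][["F value"]][1]
    expect_equal(rk$score[rk$feature == f], f_aov, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  dup <- rk[rk$feature %in% c("a", "a_copy"), ]
  expect_equal(unname(dup$score[1]), unname(dup$score[2]))
  expect_equal(dup$feature, c("a", "a_copy"))  # tie kept in column order
  expect_error(rank_features(toy_table(x, rep(0L, n))),
               class = "painerd_config_error")
  # mutual information also finds the separator
  x2 <- x; x2[, 2] <- y + rnorm(n, 0, 0.01)
  rk2 <- rank_features(toy_table(x2, y), method = "mutual_info")
  expect_equal(rk2$feature[1], "b")
})

test_that("sequential selection honours the fixed-k override and plateaus", {
  tab <- make_noise_table(n = 100, p = 100, seed = 5)
  rk <- rank_features(tab)
  fixed <- sequential_select(tab, rk, fixed_k = 50)
  expect_length(fixed$selected, 50)
  expect_identical(fixed$selected, rk$feature[1:50])

  # one strong informative feature among noise: the curve plateaus early
  set.seed(6)
  n <- 100
  y <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rnorm(n * 40), n, 40, dimnames = list(NULL, sprintf("g%02d", 1:40)))
  x[, 1] <- y + rnorm(n, 0, 0.1)
  tab2 <- toy_table(x, y)
  sel <- sequential_select(tab2, rank_features(tab2),
                           cv = cv_config(k = 5, seed = 2),
                           k_max = 10, epsilon = 0.01)
  expect_lte(sel$k, 5)
  expect_equal(nrow(sel$curve), 10)
  expect_gt(sel$curve$accuracy[1], 0.9)

  one <- sequential_select(tab2, rank_features(tab2),
                           cv = cv_config(k = 5, seed = 2), k_max = 1)
  expect_length(one$selected, 1)
  expect_equal(nrow(one$curve), 1)
})

test_that("grid search is exhaustive, deterministic and nb-exempt", {
  tab <- make_noise_table(n = 60, p = 6, seed = 7, informative = 2)
  tab$.label <- rep(c(0L, 1L), each = 30)  # keep the informative signal
  single <- grid_search(model_spec("lda", grid = list(shrinkage = 0.3)), tab,
                        cv = cv_config(k = 5, seed = 1))
  expect_equal(single$best$shrinkage, 0.3)
  expect_equal(nrow(single$results), 1)

  nbres <- grid_search(model_spec("nb"), tab)
  expect_equal(nbres$best, list())
  expect_equal(nrow(nbres$results), 0)

  # degenerate vs sensible setting: the sensible one must win
  rfspec <- model_spec("rf", grid = list(num_trees = c(1, 350)), seed = 3)
  gs <- grid_search(rfspec, tab, cv = cv_config(k = 5, seed = 1))
  expect_equal(gs$best$num_trees, 350)
  expect_equal(gs$results$accuracy,
               grid_search(rfspec, tab, cv = cv_config(k = 5, seed = 1))$results$accuracy)

  expect_error(model_spec("rf", grid = list(bogus = 1)),
               class = "painerd_config_error")
  expect_error(fit_model(model_spec("svm"), tab, hyper = list(bogus = 1)),
               class = "painerd_config_error")
})

test_that("tree and kernel models separate a linearly separable toy set", {
  set.seed(5)
  n <- 40
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(f1 = c(runif(n / 2, 0, 0.4), runif(n / 2, 0.6, 1)),
             f2 = runif(n))
  tab <- toy_table(x, y)
  for (alg in c("rf", "svm", "xgboost")) {
    hp <- if (alg == "xgboost") list(nrounds = 60) else NULL
    fit <- fit_model(model_spec(alg, seed = 2), tab, hyper = hp)
    expect_equal(mean(predict(fit, tab, type = "class") == y), 1,
                 info = alg)
  }
})

test_that("naive Bayes reduces to the class prior when classes are identical", {
  set.seed(8)
  base <- rnorm(20)
  x <- cbind(g1 = rep(base, 2), g2 = rep(rev(base), 2))
  tab <- toy_table(x, rep(c(0L, 1L), each = 20))
  fit <- fit_model(model_spec("nb"), tab)
  expect_true(all(abs(predict(fit, tab, type = "prob") - 0.5) < 1e-9))
})

test_that("every family emits valid, complementary class probabilities", {
  tab <- make_noise_table(n = 50, p = 6, seed = 9, informative = 1)
  for (alg in c("adaboost", "lda", "logreg", "nb", "rf", "svm", "xgboost")) {
    hp <- switch(alg, adaboost = list(n_estimators = 30),
                 xgboost = list(nrounds = 30), NULL)
    fit <- fit_model(model_spec(alg, seed = 4), tab, hyper = hp)
    pr <- predict_proba(fit, tab)
    expect_true(all(pr$p1 >= 0 & pr$p1 <= 1), info = alg)
    expect_true(all(abs(pr$p0 + pr$p1 - 1) < 1e-9), info = alg)
  }
})

test_that("stochastic fitters are reproducible from their seed", {
  tab <- make_noise_table(n = 50, p = 6, seed = 10, informative = 1)
  for (alg in c("adaboost", "rf", "svm", "xgboost")) {
    hp <- switch(alg, adaboost = list(n_estimators = 30),
                 xgboost = list(nrounds = 30), NULL)
    p1 <- predict(fit_model(model_spec(alg, seed = 11), tab, hyper = hp), tab)
    p2 <- predict(fit_model(model_spec(alg, seed = 11), tab, hyper = hp), tab)
    expect_identical(p1, p2, info = alg)
  }
})

test_that("default model specs carry the documented reference optima", {
  expect_equal(model_spec("rf")$hyper[c("num_trees", "max_depth", "mtry")],
               list(num_trees = 350, max_depth = 10, mtry = "log2"))
  expect_equal(model_spec("adaboost")$hyper,
               list(learning_rate = 0.1, n_estimators = 2500))
  expect_equal(model_spec("svm")$hyper[c("C", "gamma")],
               list(C = 1, gamma = 0.1))
  expect_equal(model_spec("nb")$grid, list())
  # default grids contain the default (optimal) point
  for (alg in c("adaboost", "lda", "logreg", "rf", "svm", "xgboost")) {
    spec <- model_spec(alg)
    for (nm in names(spec$grid)) {
      expect_true(spec$hyper[[nm]] %in% spec$grid[[nm]],
                  info = paste(alg, nm))
    }
  }
})
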