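ALGORITHMS <- c("adaboost", "lda", "logreg", "nb", "rf", "svm", "xgboost")

default_hyper <- function(algorithm) {
  switch(algorithm,
    adaboost = list(learning_rate = 0.1, n_estimators = 2500),
    lda = list(shrinkage = 0.4),
    logreg = list(C = 1.0, penalty = "l1"),
    nb = list(),
    rf = list(num_trees = 350, max_depth = 10, mtry = "log2",
              splitrule = "gini"),
    svm = list(C = 1.0, gamma = 0.1, kernel = "radial"),
    xgboost = list(max_depth = 2, gamma = 1.5, min_child_weight = 1,
                   subsample = 1, colsample_bytree = 1, nrounds = 150,
                   eta = 0.1)
  )
}

default_grid <- function(algorithm) {
  switch(algorithm,
    adaboost = list(learning_rate = c(0.05, 0.1, 1), n_estimators = c(500, 2500)),
    lda = list(shrinkage = c(0, 0.2, 0.4, 0.6)),
    logreg = list(C = c(0.1, 1, 10)),
    nb = list(),
    rf = list(num_trees = c(100, 350, 500), max_depth = c(5, 10, 0)),
    svm = list(C = c(0.1, 1, 10), gamma = c(0.01, 0.1, 1)),
    xgboost = list(max_depth = c(2, 4), gamma = c(0, 1.5))
  )
}

hyper_names <- function(algorithm) names(default_hyper(algorithm))

#' Specify one of the seven classifier families
#'
#' Families: AdaBoost (decision stumps with learning-rate shrinkage),
#' shrinkage LDA, L1 logistic regression, Gaussian naive Bayes, random
#' forest, RBF-kernel SVM (with Platt-scaled probabilities) and extreme
#' gradient boosting. Default hyperparameters are the grid-search optima of
#' the reference analysis (naive Bayes needs none); default grids are small
#' neighbourhoods around them.
#'
#' @param algorithm One of `"adaboost"`, `"lda"`, `"logreg"`, `"nb"`,
#'   `"rf"`, `"svm"`, `"xgboost"`.
#' @param grid Named list of candidate hyperparameter values (Cartesian
#'   product is searched); defaults per family.
#' @param hyper Named list of fixed hyperparameters (defaults per family).
#' @param seed Integer seed consumed by stochastic fitters.
#' @return A list of class `model_spec`.
#' @export
#' @examples
#' model_spec("rf")$hyper
model_spec <- function(algorithm, grid = NULL, hyper = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  base <- default_hyper(algorithm)
  if (!is.null(hyper)) {
    bad <- setdiff(names(hyper), names(base))
    if (length(bad) > 0) {
      stop_painerd(sprintf("Unknown hyperparameter(s) for %s: %s",
                           algorithm, paste(bad, collapse = ", ")),
                   "painerd_config_error")
    }
    base[names(hyper)] <- hyper
  }
  g <- if (is.null(grid)) default_grid(algorithm) else grid
  if (length(g) > 0) {
    bad <- setdiff(names(g), names(default_hyper(algorithm)))
    if (length(bad) > 0) {
      stop_painerd(sprintf("Unknown hyperparameter(s) in %s grid: %s",
                           algorithm, paste(bad, collapse = ", ")),
                   "painerd_config_error")
    }
  }
  structure(list(algorithm = algorithm, grid = g, hyper = base,
                 seed = as.integer(seed)),
            class = "model_spec")
}

resolve_xy <- function(table, labels, feature_subset) {
  if (is.null(labels)) labels <- table$.label
  if (is.null(labels) || anyNA(labels)) {
    stop_painerd("Binary labels required (no NAs); drop unlabelled trials first.",
                 "painerd_config_error")
  }
  if (!all(labels %in% c(0, 1))) {
    stop_painerd("Labels must be binary 0/1 (1 = high pain).", "painerd_config_error")
  }
  x <- feature_matrix(table)
  if (!is.null(feature_subset)) {
    missing <- setdiff(feature_subset, colnames(x))
    if (length(missing) > 0) {
      stop_painerd(paste0("Feature subset not present in table: ",
                          paste(head(missing, 5), collapse = ", ")),
                   "painerd_feature_mismatch_error")
    }
    x <- x[, feature_subset, drop = FALSE]
  }
  list(x = x, y = as.integer(labels))
}

#' Fit one classifier
#'
#' Fits the family named by `spec` on the feature table (class 1 = high
#' pain throughout). The returned model predicts classes at the 0.5
#' probability threshold and exposes class-1 probabilities.
#'
#' @param spec A [model_spec()].
#' @param table A (scaled) feature table.
#' @param labels Optional 0/1 vector; defaults to `table$.label`.
#' @param feature_subset Optional character vector of feature columns.
#' @param hyper Optional hyperparameter overrides for this fit.
#' @return A `pain_model`.
#' @export
fit_model <- function(spec, table, labels = NULL, feature_subset = NULL,
                      hyper = NULL) {
  xy <- resolve_xy(table, labels, feature_subset)
  if (length(unique(xy$y)) < 2) {
    stop_painerd("Both classes must be present to fit a classifier.",
                 "painerd_config_error")
  }
  hp <- spec$hyper
  if (!is.null(hyper)) {
    bad <- setdiff(names(hyper), names(default_hyper(spec$algorithm)))
    if (length(bad) > 0) {
      stop_painerd(sprintf("Unknown hyperparameter(s) for %s: %s",
                           spec$algorithm, paste(bad, collapse = ", ")),
                   "painerd_config_error")
    }
    hp[names(hyper)] <- hyper
  }
  fit <- tryCatch(
    switch(spec$algorithm,
      adaboost = fit_adaboost(xy$x, xy$y, hp, spec$seed),
      lda = fit_slda(xy$x, xy$y, hp),
      logreg = fit_logreg(xy$x, xy$y, hp),
      nb = fit_gnb(xy$x, xy$y),
      rf = fit_rf(xy$x, xy$y, hp, spec$seed),
      svm = fit_svm(xy$x, xy$y, hp, spec$seed),
      xgboost = fit_xgb(xy$x, xy$y, hp, spec$seed)
    ),
    error = function(e) {
      stop_painerd(sprintf("Fitting %s failed: %s", spec$algorithm,
                           conditionMessage(e)),
                   "painerd_fit_error")
    }
  )
  structure(list(algorithm = spec$algorithm, hyper = hp, fit = fit,
                 features = colnames(xy$x), seed = spec$seed),
            class = "pain_model")
}

#' @export
print.pain_model <- function(x, ...) {
  cat(sprintf("<pain_model> %s on %d features\n", x$algorithm,
              length(x$features)))
  invisible(x)
}

#' Predict from a fitted pain-intensity classifier
#'
#' @param object A `pain_model`.
#' @param newdata Feature table or numeric matrix containing the model's
#'   feature columns.
#' @param type `"prob"` for the probability of class 1 (high pain),
#'   `"class"` for the 0/1 label at the 0.5 threshold.
#' @param ... Unused.
#' @return Numeric vector of probabilities, or integer 0/1 labels.
#' @export
predict.pain_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  missing <- setdiff(object$features, colnames(x))
  if (length(missing) > 0) {
    stop_painerd(paste0("newdata lacks feature column(s): ",
                        paste(head(missing, 5), collapse = ", ")),
                 "painerd_feature_mismatch_error")
  }
  x <- x[, object$features, drop = FALSE]
  p1 <- switch(object$algorithm,
    adaboost = predict_adaboost(object$fit, x),
    lda = predict_slda(object$fit, x),
    logreg = as.numeric(predict(object$fit, x, type = "response")),
    nb = predict_gnb(object$fit, x),
    rf = {
      pr <- predict(object$fit, data = as.data.frame(x), num.threads = 1)$predictions
      as.numeric(pr[, "1"])
    },
    svm = {
      pr <- attr(predict(object$fit, x, probability = TRUE), "probabilities")
      as.numeric(pr[, "1"])
    },
    xgboost = as.numeric(predict(object$fit, xgboost::xgb.DMatrix(x)))
  )
  p1 <- pmin(1, pmax(0, p1))
  if (type == "prob") p1 else as.integer(p1 > 0.5)
}

#' Class probabilities for both classes
#'
#' @param object A `pain_model`.
#' @param newdata Feature table or matrix.
#' @return Tibble with columns `p0`, `p1` (rows sum to 1).
#' @export
predict_proba <- function(object, newdata) {
  p1 <- predict(object, newdata, type = "prob")
  tibble::tibble(p0 = 1 - p1, p1 = p1)
}

## ---- AdaBoost: discrete boosting of exhaustive-search decision stumps ----

# weighted decision stump: threshold + polarity minimising weighted error
# (weights assumed normalised to sum 1)
fit_stump <- function(x, w, ys, orders) {
  n <- nrow(x); p <- ncol(x)
  best <- list(err = Inf)
  total_pos <- sum(w[ys == 1])
  wy <- w * ys
  for (j in seq_len(p)) {
    o <- orders[[j]]
    v <- x[o, j]
    cs <- cumsum(wy[o])   # sum of w*y among x <= threshold
    csw <- cumsum(w[o])   # total weight among x <= threshold
    pl <- (csw + cs) / 2  # weight of positives left of threshold
    nl <- (csw - cs) / 2
    # rule (left -> +1): errs are negatives left + positives right;
    # the opposite polarity scores 1 - that
    err_pos_left <- nl + (total_pos - pl)
    valid <- c(v[-n] < v[-1], TRUE)
    cand_err <- pmin(err_pos_left, 1 - err_pos_left)
    cand_err[!valid] <- Inf
    i <- which.min(cand_err)
    if (cand_err[i] < best$err) {
      thr <- if (i < n) (v[i] + v[i + 1]) / 2 else v[n] + 1
      pol <- if (err_pos_left[i] <= 1 - err_pos_left[i]) 1 else -1
      best <- list(err = cand_err[i], feature = j, threshold = thr,
                   polarity = pol)
    }
  }
  best
}

stump_predict <- function(st, x) {
  h <- ifelse(x[, st$feature] <= st$threshold, 1, -1)
  st$polarity * h
}

fit_adaboost <- function(x, y, hp, seed) {
  n <- nrow(x)
  ys <- ifelse(y == 1, 1, -1)
  w <- rep(1 / n, n)
  orders <- lapply(seq_len(ncol(x)), function(j) order(x[, j]))
  stumps <- list()
  alphas <- numeric(0)
  nu <- hp$learning_rate
  for (m in seq_len(hp$n_estimators)) {
    st <- fit_stump(x, w, ys, orders)
    err <- min(max(st$err, 1e-10), 1 - 1e-10)
    if (st$err >= 0.5) break
    alpha <- nu * 0.5 * log((1 - err) / err)
    h <- stump_predict(st, x)
    w <- w * exp(-alpha * ys * h)
    w <- w / sum(w)
    stumps[[length(stumps) + 1]] <- st
    alphas <- c(alphas, alpha)
    if (st$err < 1e-10) break
  }
  list(stumps = stumps, alphas = alphas)
}

predict_adaboost <- function(fit, x) {
  f <- rep(0, nrow(x))
  for (m in seq_along(fit$stumps)) {
    f <- f + fit$alphas[m] * stump_predict(fit$stumps[[m]], x)
  }
  1 / (1 + exp(-2 * f))
}

## ---- shrinkage LDA (pooled covariance shrunk toward scaled identity) ----

fit_slda <- function(x, y, hp) {
  a <- hp$shrinkage
  n <- nrow(x); p <- ncol(x)
  i0 <- y == 0; i1 <- y == 1
  mu0 <- colMeans(x[i0, , drop = FALSE])
  mu1 <- colMeans(x[i1, , drop = FALSE])
  xc <- x
  xc[i0, ] <- sweep(x[i0, , drop = FALSE], 2, mu0)
  xc[i1, ] <- sweep(x[i1, , drop = FALSE], 2, mu1)
  s <- crossprod(xc) / (n - 2)
  sh <- (1 - a) * s + a * mean(diag(s)) * diag(p)
  # ridge floor keeps the solve well-posed when shrinkage = 0 and p ~ n
  sh <- sh + 1e-8 * mean(diag(sh)) * diag(p)
  b0 <- solve(sh, mu0)
  b1 <- solve(sh, mu1)
  list(b0 = b0, b1 = b1,
       c0 = -0.5 * sum(mu0 * b0) + log(mean(i0)),
       c1 = -0.5 * sum(mu1 * b1) + log(mean(i1)))
}

predict_slda <- function(fit, x) {
  d0 <- x %*% fit$b0 + fit$c0
  d1 <- x %*% fit$b1 + fit$c1
  as.numeric(1 / (1 + exp(-(d1 - d0))))
}

## ---- L1 logistic regression (liblinear parameterisation) ----

fit_logreg <- function(x, y, hp) {
  if (!identical(hp$penalty, "l1")) {
    stop_painerd("Only the L1 penalty is supported for logistic regression.",
                 "painerd_config_error")
  }
  glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                 lambda = 1 / (nrow(x) * hp$C), standardize = FALSE)
}

## ---- Gaussian naive Bayes with variance smoothing ----

fit_gnb <- function(x, y, var_smoothing = 1e-9) {
  i0 <- y == 0; i1 <- y == 1
  v0 <- apply(x[i0, , drop = FALSE], 2, var)
  v1 <- apply(x[i1, , drop = FALSE], 2, var)
  eps <- var_smoothing * max(apply(x, 2, var), 1e-12)
  list(mu0 = colMeans(x[i0, , drop = FALSE]),
       mu1 = colMeans(x[i1, , drop = FALSE]),
       v0 = v0 + eps, v1 = v1 + eps,
       prior1 = mean(i1))
}

predict_gnb <- function(fit, x) {
  ll0 <- rowSums(sweep(sweep(x, 2, fit$mu0)^2, 2, -2 * fit$v0, "/")) -
    0.5 * sum(log(2 * pi * fit$v0)) + log(1 - fit$prior1)
  ll1 <- rowSums(sweep(sweep(x, 2, fit$mu1)^2, 2, -2 * fit$v1, "/")) -
    0.5 * sum(log(2 * pi * fit$v1)) + log(fit$prior1)
  as.numeric(1 / (1 + exp(ll0 - ll1)))
}

## ---- backends: ranger, e1071, xgboost ----

fit_rf <- function(x, y, hp, seed) {
  df <- as.data.frame(x)
  df$.y <- factor(y, levels = c(0, 1))
  mtry <- if (identical(hp$mtry, "log2")) max(1L, floor(log2(ncol(x)))) else hp$mtry
  ranger::ranger(dependent.variable.name = ".y", data = df,
                 num.trees = hp$num_trees, max.depth = hp$max_depth,
                 mtry = mtry, splitrule = hp$splitrule,
                 probability = TRUE, seed = seed, num.threads = 1)
}

fit_svm <- function(x, y, hp, seed) {
  with_seed(seed, {
    e1071::svm(x, factor(y, levels = c(0, 1)), kernel = hp$kernel,
               cost = hp$C, gamma = hp$gamma, probability = TRUE)
  })
}

fit_xgb <- function(x, y, hp, seed) {
  dm <- xgboost::xgb.DMatrix(x, label = y)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                  gamma = hp$gamma, min_child_weight = hp$min_child_weight,
                  subsample = hp$subsample,
                  colsample_bytree = hp$colsample_bytree, eta = hp$eta,
                  nthread = 1, seed = seed),
    data = dm, nrounds = hp$nrounds, verbose = 0)
}
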