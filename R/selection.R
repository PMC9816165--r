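#' Univariate feature ranking against the binary label
#'
#' Scores every feature independently: `anova_f` uses the one-way ANOVA
#' F-statistic between the two classes (vectorised; identical to
#' per-column `aov`), `mutual_info` a histogram estimate of the mutual
#' information between a 10-bin discretisation of the feature and the
#' label. Constant features score 0. Ties keep column order (stable sort),
#' so duplicated columns receive identical scores and adjacent ranks.
#'
#' @param table A feature table with `.label`.
#' @param method `"anova_f"` (default) or `"mutual_info"`.
#' @param n_bins Bins for the mutual-information estimator.
#' @return A tibble `feature`, `score`, `rank`, ordered by decreasing score.
#' @export
rank_features <- function(table, method = c("anova_f", "mutual_info"),
                          n_bins = 10) {
  method <- match.arg(method)
  y <- table$.label
  if (length(unique(y)) < 2) {
    stop_painerd("Feature ranking needs both classes present.",
                 "painerd_config_error")
  }
  if (min(table(y)) < 2) {
    stop_painerd("Feature ranking needs at least two trials per class.",
                 "painerd_config_error")
  }
  x <- feature_matrix(table)
  scores <- if (method == "anova_f") anova_f_scores(x, y) else
    mi_scores(x, y, n_bins)
  ord <- order(-scores)  # stable: ties keep column index order
  tibble::tibble(feature = colnames(x)[ord], score = unname(scores[ord]),
                 rank = seq_along(ord), method = method)
}

anova_f_scores <- function(x, y) {
  n <- nrow(x)
  i1 <- y == 1
  n1 <- sum(i1); n0 <- n - n1
  m <- colMeans(x)
  m1 <- colMeans(x[i1, , drop = FALSE])
  m0 <- colMeans(x[!i1, , drop = FALSE])
  ss_between <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ss_total <- colSums(sweep(x, 2, m)^2)
  ss_within <- ss_total - ss_between
  f <- (ss_between / 1) / (ss_within / (n - 2))
  f[ss_within == 0 & ss_between > 0] <- Inf
  f[ss_total == 0] <- 0  # constant feature: no between-class variance
  f
}

mi_scores <- function(x, y, n_bins) {
  n <- nrow(x)
  apply(x, 2, function(col) {
    if (max(col) == min(col)) return(0)
    edges <- seq(min(col), max(col), length.out = n_bins + 1)
    b <- findInterval(col, edges, rightmost.closed = TRUE, all.inside = TRUE)
    tab <- table(b, y) / n
    px <- rowSums(tab); py <- colSums(tab)
    mi <- 0
    for (i in seq_along(px)) for (j in seq_along(py)) {
      if (tab[i, j] > 0) mi <- mi + tab[i, j] * log(tab[i, j] / (px[i] * py[j]))
    }
    mi
  })
}

#' Sequential forward selection over a ranking
#'
#' Evaluates cross-validated accuracy with the top-1, top-2, ... top-`k_max`
#' features of `ranking` and returns the performance curve together with
#' the smallest prefix whose accuracy is within `epsilon` of the maximum
#' over the explored range. A fixed-`k` override (the reference analysis
#' fixed k = 50) bypasses the stopping rule and skips the curve sweep.
#'
#' @param table Scaled feature table with `.label`.
#' @param ranking A [rank_features()] tibble.
#' @param spec Model used to score prefixes (default fast shrinkage LDA).
#' @param cv A [cv_config()].
#' @param k_max Largest prefix size to explore.
#' @param epsilon Accuracy tolerance defining "stabilised" (default 0.005).
#' @param fixed_k If non-NULL, return the top `fixed_k` features directly.
#' @return List with `selected` (character), `k`, and `curve`
#'   (tibble `k`, `accuracy`; empty when `fixed_k` is used).
#' @export
sequential_select <- function(table, ranking, spec = model_spec("lda"),
                              cv = cv_config(), k_max = 50, epsilon = 0.005,
                              fixed_k = NULL) {
  feats <- ranking$feature
  if (!is.null(fixed_k)) {
    k <- min(fixed_k, length(feats))
    return(list(selected = feats[seq_len(k)], k = k,
                curve = tibble::tibble(k = integer(), accuracy = numeric())))
  }
  k_max <- min(k_max, length(feats))
  acc <- numeric(k_max)
  for (k in seq_len(k_max)) {
    res <- cross_validate(spec, table, cv, feature_subset = feats[seq_len(k)])
    acc[k] <- res$metrics$mean[res$metrics$metric == "accuracy"]
  }
  k_star <- min(which(acc >= max(acc) - epsilon))
  list(selected = feats[seq_len(k_star)], k = k_star,
       curve = tibble::tibble(k = seq_len(k_max), accuracy = acc))
}

#' Exhaustive grid search by stratified cross-validation
#'
#' Evaluates the Cartesian product of the spec's hyperparameter grid by
#' mean stratified-CV accuracy; ties are broken by grid order. Naive Bayes
#' has nothing to optimise and returns immediately.
#'
#' @param spec A [model_spec()].
#' @param table Scaled feature table.
#' @param labels Optional 0/1 labels (default `table$.label`).
#' @param cv A [cv_config()].
#' @param feature_subset Optional feature columns to use.
#' @return List with `best` (named list of hyperparameters) and `results`
#'   (tibble: one row per grid point with its CV accuracy).
#' @export
grid_search <- function(spec, table, labels = NULL, cv = cv_config(),
                        feature_subset = NULL) {
  if (length(spec$grid) == 0) {
    return(list(best = spec$hyper,
                results = tibble::tibble(accuracy = numeric())))
  }
  pts <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  acc <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    hp <- as.list(pts[i, , drop = FALSE])
    res <- cross_validate(spec, table, cv, labels = labels,
                          feature_subset = feature_subset, hyper = hp)
    acc[i] <- res$metrics$mean[res$metrics$metric == "accuracy"]
  }
  best_i <- which.max(acc)  # first maximum = earliest grid point on ties
  best <- spec$hyper
  best[names(pts)] <- as.list(pts[best_i, , drop = FALSE])
  list(best = best,
       results = dplyr::bind_cols(tibble::as_tibble(pts),
                                  tibble::tibble(accuracy = acc)))
}
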