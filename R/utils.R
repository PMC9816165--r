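#' @importFrom rlang abort warn .data
#' @importFrom stats fft median sd var approx rnorm runif predict quantile coef
#' @importFrom utils head tail
NULL

# Deterministic fan-out of one pipeline seed into per-component seeds.
# Park-Miller style multiplicative step keeps results in [1, 2^31 - 2].
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m) + 1
  for (i in seq_len(k)) s <- (s * 48271) %% m
  as.integer(s)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

stop_painerd <- function(msg, class) {
  abort(msg, class = c(class, "painerd_error"))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == round(x) && x > 0

# metadata columns carried alongside feature columns in a feature table
META_COLS <- c(".trial", ".block", ".condition", ".intensity", ".rise_time",
               ".study", ".participant", ".label")

#' Names of the feature columns of a feature table
#'
#' Feature tables carry per-trial metadata in dot-prefixed columns
#' (`.trial`, `.label`, ...); every other column is a feature.
#'
#' @param table A feature table (tibble) as returned by [trial_features()].
#' @return Character vector of feature column names.
#' @export
feature_cols <- function(table) {
  setdiff(names(table), META_COLS)
}

feature_matrix <- function(table) {
  as.matrix(table[feature_cols(table)])
}
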