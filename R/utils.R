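#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n distinct count across rename pull if_else
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rbinom rpois rnorm rexp runif rmultinom dbinom median mad
#'   fisher.test chisq.test wilcox.test t.test lm cor aov anova p.adjust
#'   quantile setNames complete.cases pchisq sd cor.test rnbinom rgamma
#' @importFrom utils combn
NULL

`%||%` <- rlang::`%||%`

# stop() with a classed condition so callers can test on the class
cc_abort <- function(msg, class = "cohortcompare_error") {
  rlang::abort(msg, class = class)
}

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    cc_abort(sprintf("`%s` must contain probabilities in [0, 1]", name),
             class = "cohortcompare_config_error")
  }
  invisible(x)
}

assert_prob_vector <- function(x, name, tol = 1e-9) {
  assert_prob(x, name)
  if (abs(sum(x) - 1) > tol) {
    cc_abort(sprintf("`%s` must sum to 1 (got %.12f)", name, sum(x)),
             class = "cohortcompare_config_error")
  }
  invisible(x)
}

assert_cols <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    cc_abort(sprintf("`%s` is missing required columns: %s",
                     name, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# deterministic child seeds below 2^31, derived from a user seed
derive_seed <- function(seed, k) {
  (as.integer(seed) * 48271L + as.integer(k) * 1009L) %% 2147483562L
}
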