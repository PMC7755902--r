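#' Expression-level gene filter
#'
#' Retains genes with mean raw count of at least `min_mean_count` AND mean
#' TPM of at least `min_mean_tpm`, the complement of the published removal
#' rule (average count below 10 or average TPM below 0.1).
#'
#' @param counts,tpm Genes x samples matrices aligned on identical gene
#'   and sample identifiers.
#' @param min_mean_count,min_mean_tpm Inclusive retention bounds.
#' @return Character vector of retained genes.
#' @export
filter_genes <- function(counts, tpm, min_mean_count = 10,
                         min_mean_tpm = 0.1) {
  if (!identical(dimnames(counts), dimnames(tpm))) {
    cc_abort("`counts` and `tpm` must share identical gene/sample names")
  }
  rownames(counts)[rowMeans(counts) >= min_mean_count &
                     rowMeans(tpm) >= min_mean_tpm]
}

# single-sample rank-enrichment score: weighted running-sum CDF of the set
# genes (ranks ^ exponent) minus the uniform CDF of non-set genes,
# integrated over the ranking from the most highly expressed gene down
.ssgsea_one <- function(expr, set, weight_exponent) {
  n <- length(expr)
  ord <- order(expr, decreasing = TRUE)
  in_set <- names(expr)[ord] %in% set
  r <- rank(expr, ties.method = "average")[ord]   # high expr -> high rank
  w <- ifelse(in_set, r^weight_exponent, 0)
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_set) / (n - sum(in_set))
  sum(p_in - p_out)
}

#' Single-sample gene-set enrichment scores
#'
#' ssGSEA-form rank-enrichment: within each sample genes are ranked by
#' expression, and the score is the integrated difference between the
#' weighted running-sum CDF of set genes (ranks raised to
#' `weight_exponent`) and the uniform CDF of non-set genes. Depends on the
#' expression values only through ranks, so any monotone transform of a
#' sample's expression leaves its scores unchanged. One documented engine
#' serves both the ESTIMATE-style and immune-cell-set scoring used
#' downstream.
#'
#' @param tpm Genes x samples expression matrix.
#' @param gene_sets Named list of gene identifier vectors.
#' @param weight_exponent Rank weight exponent (default 0.25).
#' @return Tibble: `sample_id`, `set`, `score`.
#' @export
ssgsea_score <- function(tpm, gene_sets, weight_exponent = 0.25) {
  stopifnot(is.matrix(tpm), !is.null(rownames(tpm)))
  absent <- names(gene_sets)[!vapply(gene_sets, function(s)
    any(s %in% rownames(tpm)), logical(1))]
  if (length(absent)) {
    cc_abort(sprintf("no genes of set(s) %s present in the matrix",
                     paste(absent, collapse = ", ")))
  }
  genes <- rownames(tpm)
  out <- lapply(names(gene_sets), function(gs) {
    scores <- vapply(seq_len(ncol(tpm)), function(j) {
      .ssgsea_one(setNames(tpm[, j], genes), gene_sets[[gs]],
                  weight_exponent)
    }, numeric(1))
    tibble::tibble(sample_id = colnames(tpm), set = gs, score = scores)
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(match(.data$sample_id, colnames(tpm)))
}

#' Synthetic IMPRES-style checkpoint feature pairs
#'
#' The IMPRES predictor counts satisfied pairwise inequalities between
#' checkpoint-gene expression values; 14 of the 15 published features are
#' used. The exact published pair list is not redistributable here, so this
#' synthetic 14-pair table over common checkpoint genes stands in; replace
#' it with the published pairs via [read_impres_features()] for real data.
#'
#' @return Tibble: `gene_a`, `gene_b`, `relation` (`"greater"` means the
#'   feature is satisfied when expression of `gene_a` > `gene_b`).
#' @export
synthetic_impres_features <- function() {
  g <- c("PDCD1", "CD274", "CTLA4", "CD28", "CD80", "CD86", "CD27", "CD40",
         "TNFSF4", "TNFRSF9", "LAG3", "HAVCR2", "ICOS", "IDO1", "TIGIT",
         "CD276")
  tibble::tibble(
    gene_a = g[c(1, 3, 5, 7, 9, 11, 13, 15, 2, 4, 6, 8, 10, 12)],
    gene_b = g[c(2, 4, 6, 8, 10, 12, 14, 16, 5, 7, 9, 11, 16, 15)],
    relation = rep(c("greater", "less"), times = c(8, 6))
  )
}

#' Read an IMPRES feature table
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `relation`.
#' @return Feature tibble as in [synthetic_impres_features()].
#' @export
read_impres_features <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  assert_cols(df, c("gene_a", "gene_b", "relation"))
  stopifnot(all(df$relation %in% c("greater", "less")))
  df
}

#' IMPRES checkpoint-feature score
#'
#' Counts, per sample, the features whose pairwise expression relation
#' holds strictly. Features with either gene missing from the matrix are
#' skipped with a warning and the per-sample denominator is reported.
#' The score uses only pairwise order, so it is invariant under monotone
#' transforms of expression.
#'
#' @param tpm Genes x samples expression matrix.
#' @param features Feature tibble (default [synthetic_impres_features()]).
#' @return Tibble: `sample_id`, `impres`, `n_features`.
#' @export
impres_score <- function(tpm, features = synthetic_impres_features()) {
  present <- features$gene_a %in% rownames(tpm) &
    features$gene_b %in% rownames(tpm)
  if (any(!present)) {
    rlang::warn(sprintf("%d feature(s) skipped (gene absent)", sum(!present)))
    features <- features[present, ]
  }
  if (nrow(features) == 0) cc_abort("no usable features")
  a <- tpm[features$gene_a, , drop = FALSE]
  b <- tpm[features$gene_b, , drop = FALSE]
  sat <- ifelse(features$relation == "greater", 1, -1) * (a - b) > 0
  tibble::tibble(sample_id = colnames(tpm),
                 impres = as.integer(colSums(sat)),
                 n_features = nrow(features))
}

#' Dichotomise IMPRES scores
#'
#' High iff the score is 9 or more (the published stratification: "IM
#' High" = 9 or more, "IM Low" = 8 or less).
#'
#' @param score Integer vector of IMPRES scores.
#' @param cutoff High-class lower bound (default 9).
#' @return Factor with levels `"low"`, `"high"`.
#' @export
classify_impres <- function(score, cutoff = 9) {
  factor(ifelse(score >= cutoff, "high", "low"), levels = c("low", "high"))
}

#' ER status from ESR1 expression by two-component Gaussian mixture EM
#'
#' Fits a two-component univariate Gaussian mixture to ESR1 expression
#' (log2(TPM + 1) by default) with an expectation-maximisation algorithm
#' initialised from the sample quantiles. The component with the higher
#' mean is called ER+; samples are labelled by posterior probability
#' above 0.5. The fit is flagged unreliable when the component means are
#' within half a pooled standard deviation.
#'
#' @param esr1_tpm Named numeric vector of ESR1 TPM per sample (>= 10
#'   samples).
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence tolerance on the log-likelihood gain
#'   (default 1e-8).
#' @param log_transform Fit on log2(TPM + 1) (default `TRUE`).
#' @return Object of class `"er_mixfit"`: component `means`, `sds`,
#'   `lambda`, per-sample `posterior` (P(ER+)), `labels`
#'   (`"pos"`/`"neg"`), `loglik` trace, `converged`, `unreliable`.
#' @export
er_status_em <- function(esr1_tpm, max_iter = 500, tol = 1e-8,
                         log_transform = TRUE) {
  if (length(esr1_tpm) < 10) cc_abort("need at least 10 samples")
  x <- if (log_transform) log2(esr1_tpm + 1) else esr1_tpm
  nm <- names(esr1_tpm) %||% as.character(seq_along(esr1_tpm))

  # quantile initialisation: split at the median
  qs <- stats::quantile(x, c(0.25, 0.75))
  mu <- as.numeric(qs)
  sg <- rep(max(stats::sd(x) / 2, 1e-3), 2)
  lam <- c(0.5, 0.5)

  loglik <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- lam[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- lam[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    loglik <- c(loglik, ll)
    if (it > 1 && ll - loglik[it - 1] < tol) { converged <- TRUE; break }
    g2 <- d2 / tot
    g1 <- 1 - g2
    lam <- c(mean(g1), mean(g2))
    mu <- c(sum(g1 * x) / sum(g1), sum(g2 * x) / sum(g2))
    sg <- sqrt(c(sum(g1 * (x - mu[1])^2) / sum(g1),
                 sum(g2 * (x - mu[2])^2) / sum(g2)))
    sg <- pmax(sg, 1e-4)
  }
  if (!converged) rlang::warn("EM did not converge; best fit returned")

  hi <- which.max(mu)                      # higher mean = ER+
  d_hi <- lam[hi] * stats::dnorm(x, mu[hi], sg[hi])
  d_lo <- lam[3 - hi] * stats::dnorm(x, mu[3 - hi], sg[3 - hi])
  post <- d_hi / pmax(d_hi + d_lo, .Machine$double.xmin)
  pooled_sd <- sqrt(mean(sg^2))
  structure(list(
    means = mu, sds = sg, lambda = lam,
    posterior = setNames(post, nm),
    labels = setNames(ifelse(post > 0.5, "pos", "neg"), nm),
    loglik = loglik, converged = converged,
    unreliable = abs(diff(mu)) < 0.5 * pooled_sd,
    data = setNames(x, nm), log_transform = log_transform
  ), class = "er_mixfit")
}

#' @export
print.er_mixfit <- function(x, ...) {
  cat("Two-component Gaussian mixture fit for ER status\n")
  cat(sprintf("  means: %.3f / %.3f  sds: %.3f / %.3f  lambda: %.3f / %.3f\n",
              x$means[1], x$means[2], x$sds[1], x$sds[2],
              x$lambda[1], x$lambda[2]))
  cat(sprintf("  %d ER+ / %d ER- of %d samples; converged: %s%s\n",
              sum(x$labels == "pos"), sum(x$labels == "neg"),
              length(x$labels), x$converged,
              if (x$unreliable) " (UNRELIABLE: components overlap)" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-sample ER mixture assignments
#'
#' @param x An `"er_mixfit"` object.
#' @param ... Unused.
#' @return Tibble: `sample_id`, `esr1`, `posterior_pos`, `er_call`.
#' @export
tidy.er_mixfit <- function(x, ...) {
  tibble::tibble(sample_id = names(x$labels), esr1 = unname(x$data),
                 posterior_pos = unname(x$posterior),
                 er_call = unname(x$labels))
}

#' One-row ER mixture fit summary
#'
#' @param x An `"er_mixfit"` object.
#' @param ... Unused.
#' @return Tibble with component parameters, final log-likelihood,
#'   iteration count and flags.
#' @export
glance.er_mixfit <- function(x, ...) {
  tibble::tibble(mean_neg = min(x$means), mean_pos = max(x$means),
                 sd_neg = x$sds[which.min(x$means)],
                 sd_pos = x$sds[which.max(x$means)],
                 lambda_pos = x$lambda[which.max(x$means)],
                 loglik = x$loglik[length(x$loglik)],
                 n_iter = length(x$loglik),
                 converged = x$converged, unreliable = x$unreliable,
                 n = length(x$labels))
}

#' Linear covariate adjustment of an immune score
#'
#' Ordinary least squares of `response` on the given covariates
#' (categoricals expanded to indicators), with per-coefficient t tests and
#' adjusted R-squared. Errors on rank-deficient designs, naming the
#' collinear columns.
#'
#' @param data Tibble of complete cases.
#' @param response Name of the response column.
#' @param covariates Character vector of covariate column names.
#' @return List with `coefficients` (tibble: `term`, `estimate`,
#'   `std_error`, `statistic`, `p`) and `adj_r_squared`.
#' @export
covariate_regression <- function(data, response, covariates) {
  assert_cols(data, c(response, covariates))
  data <- data[stats::complete.cases(data[, c(response, covariates)]), ]
  if (nrow(data) < length(covariates) + 2) {
    cc_abort("need at least covariates + 2 complete cases")
  }
  f <- stats::as.formula(paste(response, "~",
                               paste(covariates, collapse = " + ")))
  fit <- stats::lm(f, data = data)
  if (anyNA(stats::coef(fit))) {
    cc_abort(sprintf("rank-deficient design; collinear term(s): %s",
                     paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                           collapse = ", ")))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  list(coefficients = tibble::tibble(term = rownames(co),
                                     estimate = unname(co[, 1]),
                                     std_error = unname(co[, 2]),
                                     statistic = unname(co[, 3]),
                                     p = unname(co[, 4])),
       adj_r_squared = sm$adj.r.squared)
}
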