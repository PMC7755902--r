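#' Mutated-allele multiplicity
#'
#' Estimated copies of the mutated allele per tumour cell from the
#' observed VAF, tumour purity and total copy number:
#' `m = max(1, round(vaf / p * (p * CNt + (1 - p) * 2)))`.
#'
#' @param vaf Variant allele frequency in \[0, 1\].
#' @param purity Tumour purity in (0, 1\].
#' @param cn_total Total tumour copy number at the locus.
#' @return Integer multiplicity (vectorised). Records with `cn_total = 0`
#'   and positive VAF are flagged with a warning and return `NA`.
#' @export
multiplicity <- function(vaf, purity, cn_total) {
  stopifnot(all(purity > 0), all(purity <= 1))
  m <- pmax(1, round(vaf / purity * (purity * cn_total + (1 - purity) * 2)))
  bad <- cn_total == 0 & vaf > 0
  if (any(bad)) {
    rlang::warn(sprintf("%d record(s) with cn_total = 0 but vaf > 0 flagged NA",
                        sum(bad)))
    m[bad] <- NA_integer_
  }
  as.integer(m)
}

#' Cancer cell fraction
#'
#' `ccf = vaf * (p * CNt + (1 - p) * 2) / (p * m)`, clipped to `cap`
#' (default 1). Use [clonality_table()] to retain the pre-clip value.
#'
#' @inheritParams multiplicity
#' @param m Multiplicity (default: estimated via [multiplicity()]).
#' @param cap Upper clip (default 1).
#' @return Numeric CCF vector.
#' @export
ccf <- function(vaf, purity, cn_total, m = NULL, cap = 1) {
  if (any(purity <= 0)) cc_abort("`purity` must be positive")
  m <- m %||% multiplicity(vaf, purity, cn_total)
  stopifnot(all(m >= 1, na.rm = TRUE))
  pmin(vaf * (purity * cn_total + (1 - purity) * 2) / (purity * m), cap)
}

#' Per-variant clonality records
#'
#' Joins a mutation table with per-sample purity (and per-variant total
#' copy number when present), then computes multiplicity, the capped CCF
#' and the pre-clip CCF.
#'
#' @param maf Mutation tibble with `sample_id`, `vaf`, `t_depth` and
#'   optionally `cn_total`.
#' @param purity Tibble: `sample_id`, `purity`, optionally a default
#'   `cn_total`.
#' @param cap CCF cap (default 1).
#' @return Tibble with added `purity`, `cn_total`, `m`, `ccf`, `ccf_raw`.
#' @export
clonality_table <- function(maf, purity, cap = 1) {
  assert_cols(maf, c("sample_id", "vaf", "t_depth"))
  assert_cols(purity, c("sample_id", "purity"))
  keep <- c("sample_id", "purity",
            if (!"cn_total" %in% names(maf)) "cn_total")
  d <- dplyr::inner_join(maf, purity[, intersect(keep, names(purity))],
                         by = "sample_id")
  if (!"cn_total" %in% names(d)) d$cn_total <- 2L
  d$m <- multiplicity(d$vaf, d$purity, d$cn_total)
  raw <- d$vaf * (d$purity * d$cn_total + (1 - d$purity) * 2) /
    (d$purity * d$m)
  d$ccf_raw <- raw
  d$ccf <- pmin(raw, cap)
  d
}

#' MATH intratumour heterogeneity score
#'
#' `100 * 1.4826 * MAD(vafs) / median(vafs)` — the scaled median absolute
#' deviation of a sample's VAFs relative to their median. Scale-invariant
#' and order-invariant.
#'
#' @param vafs Numeric vector of at least 3 VAFs.
#' @return The MATH score; `NA` with a warning when the median is zero.
#' @export
math_score <- function(vafs) {
  if (length(vafs) < 3) cc_abort("need at least 3 VAFs")
  med <- stats::median(vafs)
  if (med == 0) {
    rlang::warn("median VAF is zero; MATH undefined")
    return(NA_real_)
  }
  100 * stats::mad(vafs) / med   # mad() already applies the 1.4826 constant
}

# EM for a k-component binomial mixture in CCF space; coef_i maps a
# cluster CCF to the expected VAF of variant i
.binmix_em <- function(alt, depth, coef, k, max_iter = 200, tol = 1e-8) {
  n <- length(alt)
  obs_ccf <- pmin(pmax(alt / depth / coef, 1e-4), 1)
  ccf_k <- as.numeric(stats::quantile(obs_ccf, probs = (seq_len(k) - 0.5) / k))
  ccf_k <- pmin(pmax(ccf_k, 1e-3), 1)
  pi_k <- rep(1 / k, k)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(k), function(j)
      stats::dbinom(alt, depth, pmin(pmax(ccf_k[j] * coef, 1e-9), 1 - 1e-9),
                    log = TRUE) + log(pi_k[j]),
      numeric(n))
    if (n == 1) logd <- matrix(logd, nrow = 1)
    mx <- apply(logd, 1, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    resp <- exp(logd - lse)
    if (is.na(ll)) return(NULL)
    if (ll - ll_old < tol && it > 1) break
    ll_old <- ll
    pi_k <- colMeans(resp)
    # weighted-ratio CCF update (exact MLE when coef is constant)
    ccf_k <- vapply(seq_len(k), function(j)
      sum(resp[, j] * alt) / max(sum(resp[, j] * depth * coef), 1e-12),
      numeric(1))
    ccf_k <- pmin(pmax(ccf_k, 1e-4), 1)
  }
  list(loglik = ll, ccf = ccf_k, pi = pi_k, resp = resp,
       bic = -2 * ll + (2 * k - 1) * log(n))
}

#' Subclone count by BIC-selected binomial mixture
#'
#' A stand-in for Dirichlet-process clustering that retains only what the
#' downstream analysis uses: the number of clusters. Fits binomial mixture
#' models in CCF space for k = 1..`max_k` by EM and returns the k with the
#' lowest BIC.
#'
#' @param alt_counts,depths Integer vectors (>= 10 variants).
#' @param purity Tumour purity (scalar or per-variant).
#' @param cn_total Total copy number (scalar or per-variant).
#' @param max_k Largest cluster count considered (default 8).
#' @param multiplicity Mutated copies per cell (default 1).
#' @return Object of class `"subclone_fit"`: `k`, `ccf` (cluster CCFs),
#'   `pi`, `assignment`, `bic` tibble over k.
#' @export
subclone_count <- function(alt_counts, depths, purity, cn_total = 2,
                           max_k = 8, multiplicity = 1) {
  if (length(alt_counts) < 10) cc_abort("need at least 10 variants")
  stopifnot(length(alt_counts) == length(depths))
  coef <- multiplicity * purity / (purity * cn_total + (1 - purity) * 2)
  coef <- rep_len(coef, length(alt_counts))
  fits <- lapply(seq_len(max_k), function(k) {
    f <- tryCatch(.binmix_em(alt_counts, depths, coef, k),
                  error = function(e) NULL)
    if (is.null(f)) rlang::warn(sprintf("k = %d skipped (non-convergence)", k))
    f
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) cc_abort("no mixture size converged")
  bics <- vapply(fits[ok], `[[`, numeric(1), "bic")
  ks <- which(ok)
  best <- fits[ok][[which.min(bics)]]
  structure(list(
    k = ks[which.min(bics)],
    ccf = best$ccf, pi = best$pi,
    assignment = max.col(best$resp),
    bic = tibble::tibble(k = ks, bic = bics, loglik = vapply(fits[ok], `[[`,
                                                             numeric(1),
                                                             "loglik"))
  ), class = "subclone_fit")
}

#' @export
print.subclone_fit <- function(x, ...) {
  cat(sprintf("Binomial-mixture subclone fit: k = %d (CCFs: %s)\n", x$k,
              paste(sprintf("%.2f", sort(x$ccf, decreasing = TRUE)),
                    collapse = ", ")))
  invisible(x)
}

#' Tidy subclone clusters
#'
#' @param x A `"subclone_fit"`.
#' @param ... Unused.
#' @return Tibble: `cluster`, `ccf`, `weight`, `n_variants`.
#' @export
tidy.subclone_fit <- function(x, ...) {
  tibble::tibble(cluster = seq_along(x$ccf), ccf = x$ccf, weight = x$pi,
                 n_variants = as.integer(tabulate(x$assignment,
                                                  nbins = length(x$ccf))))
}

#' Per-sample heterogeneity summary
#'
#' MATH score and BIC-selected subclone count (with its log2) for every
#' sample with enough variants.
#'
#' @param maf Mutation tibble with `sample_id`, `alt_count`, `t_depth`,
#'   `vaf`.
#' @param purity Tibble: `sample_id`, `purity` and optionally `cn_total`.
#' @param min_variants Minimum variants per sample (default 10).
#' @param max_k Passed to [subclone_count()].
#' @return Tibble: `sample_id`, `n_variants`, `math`, `n_clusters`,
#'   `log2_clusters`.
#' @export
heterogeneity_summary <- function(maf, purity, min_variants = 10, max_k = 8) {
  assert_cols(maf, c("sample_id", "alt_count", "t_depth", "vaf"))
  pur_cols <- c("sample_id", "purity",
                if (!"cn_total" %in% names(maf)) "cn_total")
  d <- dplyr::inner_join(maf, purity[, intersect(pur_cols, names(purity))],
                         by = "sample_id")
  d |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::filter(dplyr::n() >= min_variants) |>
    dplyr::summarise(
      n_variants = dplyr::n(),
      math = math_score(.data$vaf),
      n_clusters = subclone_count(.data$alt_count, .data$t_depth,
                                  .data$purity[1],
                                  if ("cn_total" %in% names(d))
                                    .data$cn_total else 2,
                                  max_k = max_k)$k,
      .groups = "drop") |>
    dplyr::mutate(log2_clusters = log2(.data$n_clusters))
}

#' Binned association between immune score and tumour heterogeneity
#'
#' Samples are split into `n_bins` equal-size groups by immune score; the
#' per-bin mean log2 cluster count is correlated (Spearman) with the bin
#' index.
#'
#' @param immune_scores,log2_clusters Paired per-sample numeric vectors.
#' @param n_bins Number of score bins (default 20).
#' @return List: `rho`, `p`, `bins` tibble.
#' @export
heterogeneity_immune_association <- function(immune_scores, log2_clusters,
                                             n_bins = 20) {
  stopifnot(length(immune_scores) == length(log2_clusters))
  n <- length(immune_scores)
  if (n < 2 * n_bins) cc_abort("need at least 2 * n_bins samples")
  bin <- dplyr::ntile(immune_scores, n_bins)
  bins <- tibble::tibble(bin = bin, h = log2_clusters) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(mean_log2_clusters = mean(.data$h), .groups = "drop")
  ct <- suppressWarnings(
    stats::cor.test(bins$bin, bins$mean_log2_clusters, method = "spearman",
                    exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, bins = bins)
}
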