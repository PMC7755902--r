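#' Binary gene-by-sample mutation matrix
#'
#' Entry is 1 iff the sample carries at least one nonsynonymous mutation in
#' the gene.
#'
#' @param maf Mutation tibble with `sample_id`, `gene` and optionally
#'   `consequence` (used when `classes` is given).
#' @param genes Genes to include (default: all genes in the table).
#' @param samples Samples to include (default: all samples in the table).
#'   Genes or samples absent from the table give all-zero columns/rows.
#' @param classes Optional consequence classes to restrict to.
#' @return Integer matrix, samples x genes.
#' @export
gene_sample_matrix <- function(maf, genes = NULL, samples = NULL,
                               classes = NULL) {
  assert_cols(maf, c("sample_id", "gene"))
  if (!is.null(classes)) maf <- dplyr::filter(maf, .data$consequence %in% classes)
  genes <- genes %||% sort(unique(maf$gene))
  samples <- samples %||% sort(unique(maf$sample_id))
  m <- matrix(0L, length(samples), length(genes),
              dimnames = list(samples, genes))
  hit <- maf |>
    dplyr::filter(.data$gene %in% genes, .data$sample_id %in% samples) |>
    dplyr::distinct(.data$sample_id, .data$gene)
  m[cbind(hit$sample_id, hit$gene)] <- 1L
  m
}

# sample odds ratio with 0 / Inf at zero cells (no continuity correction)
.sample_or <- function(n11, n10, n01, n00) {
  num <- n11 * n00
  den <- n10 * n01
  dplyr::case_when(num == 0 & den == 0 ~ NA_real_,
                   den == 0 ~ Inf,
                   num == 0 ~ 0,
                   TRUE ~ num / den)
}

#' Pairwise co-occurrence / mutual-exclusivity analysis
#'
#' For every unordered pair among the `top_k` most frequently mutated
#' genes: a two-sided Fisher exact p-value and the sample odds ratio on
#' the 2x2 (both / a-only / b-only / neither) table. Pairs are exclusive
#' when the odds ratio is below 1, co-occurring otherwise.
#'
#' @param mat Binary samples x genes matrix from [gene_sample_matrix()].
#' @param top_k Number of top mutated genes to test (default 15).
#' @return Tibble: `gene_a`, `gene_b`, `n11`, `n10`, `n01`, `n00`, `or`,
#'   `log2_or`, `p`, `direction`.
#' @export
pairwise_association <- function(mat, top_k = 15) {
  freq <- colSums(mat)
  keep <- names(sort(freq, decreasing = TRUE))[seq_len(min(top_k, ncol(mat)))]
  zero <- keep[freq[keep] == 0]
  if (length(zero)) {
    rlang::warn(sprintf("all-zero gene(s) skipped: %s",
                        paste(zero, collapse = ", ")))
    keep <- setdiff(keep, zero)
  }
  if (length(keep) < 2) cc_abort("need at least two non-degenerate genes")
  pairs <- utils::combn(keep, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- mat[, pairs[1, i]]; b <- mat[, pairs[2, i]]
    n11 <- sum(a & b); n10 <- sum(a & !b)
    n01 <- sum(!a & b); n00 <- sum(!a & !b)
    or <- .sample_or(n11, n10, n01, n00)
    p <- stats::fisher.test(matrix(c(n11, n01, n10, n00), 2, 2))$p.value
    tibble::tibble(gene_a = pairs[1, i], gene_b = pairs[2, i],
                   n11 = n11, n10 = n10, n01 = n01, n00 = n00,
                   or = or, log2_or = log2(or), p = p,
                   direction = ifelse(!is.na(or) & or < 1,
                                      "exclusive", "co-occurring"))
  })
}

#' Bonferroni-filter association results
#'
#' Keeps pairs significant at `alpha` after Bonferroni correction over the
#' number of tested pairs, and caps infinite log2 odds ratios at
#' `+/- log_or_cap` for plotting.
#'
#' @param results Tibble from [pairwise_association()].
#' @param alpha Family-wise significance level (default 0.05).
#' @param log_or_cap Cap for infinite `log2_or` values (default 10).
#' @return The significant subset with `p_bonferroni` and capped `log2_or`.
#' @export
bonferroni_filter <- function(results, alpha = 0.05, log_or_cap = 10) {
  if (nrow(results) == 0) {
    return(dplyr::mutate(results, p_bonferroni = double()))
  }
  m <- nrow(results)
  results |>
    dplyr::mutate(p_bonferroni = pmin(1, .data$p * m),
                  log2_or = pmax(pmin(.data$log2_or, log_or_cap),
                                 -log_or_cap)) |>
    dplyr::filter(.data$p * m < alpha)
}
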