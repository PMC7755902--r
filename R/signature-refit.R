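#' Tally mutations into the 96 trinucleotide channels
#'
#' Each SNV must carry `ref`, `alt` and its 3-base reference-strand
#' `context`. Purine-centred mutations are reverse-complemented into the
#' pyrimidine-centred channel. Malformed contexts are skipped with a
#' warning.
#'
#' @param mutations Tibble with `sample_id`, `ref`, `alt`, `context`
#'   (SNVs only; other rows are ignored if `variant_type` is present).
#' @return 96 x n_samples integer matrix with [sbs_channels()] rownames.
#' @export
tally_96 <- function(mutations) {
  assert_cols(mutations, c("sample_id", "ref", "alt", "context"))
  if ("variant_type" %in% names(mutations)) {
    mutations <- dplyr::filter(mutations, .data$variant_type == "SNV")
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  revcomp3 <- function(ctx) {
    paste0(comp[substr(ctx, 3, 3)], comp[substr(ctx, 2, 2)],
           comp[substr(ctx, 1, 1)])
  }
  ref <- mutations$ref; alt <- mutations$alt; ctx <- mutations$context
  ok <- nchar(ctx) == 3 & substr(ctx, 2, 2) == ref & ref != alt &
    ref %in% names(comp) & alt %in% names(comp)
  if (any(!ok)) {
    rlang::warn(sprintf("%d malformed record(s) skipped", sum(!ok)))
    ref <- ref[ok]; alt <- alt[ok]; ctx <- ctx[ok]
    mutations <- mutations[ok, ]
  }
  pur <- ref %in% c("A", "G")
  ref2 <- ifelse(pur, comp[ref], ref)
  alt2 <- ifelse(pur, comp[alt], alt)
  ctx2 <- ifelse(pur, revcomp3(ctx), ctx)
  channel <- paste0(substr(ctx2, 1, 1), "[", ref2, ">", alt2, "]",
                    substr(ctx2, 3, 3))
  samples <- sort(unique(mutations$sample_id))
  tab <- table(factor(channel, levels = sbs_channels()),
               factor(mutations$sample_id, levels = samples))
  m <- matrix(as.integer(tab), nrow = 96,
              dimnames = list(sbs_channels(), samples))
  m
}

# NNLS refit of one normalised spectrum onto the catalogue, with the
# floor-and-renormalise convention
.refit_one <- function(counts, sigs, weight_floor) {
  spec <- counts / sum(counts)
  w <- pracma::lsqnonneg(sigs, spec)$x
  unexplained <- max(0, 1 - sum(w))
  w[w < weight_floor] <- 0
  if (sum(w) > 0) w <- w * (1 - unexplained) / sum(w)
  list(weights = setNames(w, colnames(sigs)), unexplained = unexplained)
}

#' Refit per-sample signature exposures
#'
#' Non-negative least squares fit of each sample's normalised 96-channel
#' spectrum onto the signature catalogue. Samples with fewer than
#' `min_snvs` mutations are ineligible. Weights below `weight_floor` are
#' zeroed and the remainder renormalised so that weights plus the
#' unexplained residual sum to 1.
#'
#' @param catalog96 96 x n_samples count matrix from [tally_96()], or a
#'   single named 96-vector.
#' @param sigs 96 x K signature matrix (default
#'   [synthetic_signature_catalog()]).
#' @param min_snvs Minimum SNV count for eligibility (default 15).
#' @param weight_floor Weights below this are zeroed (default 0.06).
#' @return Tibble with `sample_id`, `total_snvs`, `eligible`,
#'   `unexplained` and one column per signature.
#' @export
refit_exposures <- function(catalog96, sigs = synthetic_signature_catalog(),
                            min_snvs = 15, weight_floor = 0.06) {
  if (is.null(dim(catalog96))) {
    catalog96 <- matrix(catalog96, ncol = 1,
                        dimnames = list(names(catalog96), "sample1"))
  }
  stopifnot(nrow(catalog96) == 96, nrow(sigs) == 96)
  catalog96 <- catalog96[rownames(sigs), , drop = FALSE]
  purrr::map_dfr(seq_len(ncol(catalog96)), function(j) {
    counts <- catalog96[, j]
    total <- sum(counts)
    if (total < min_snvs) {
      w <- setNames(rep(NA_real_, ncol(sigs)), colnames(sigs))
      return(tibble::tibble(sample_id = colnames(catalog96)[j],
                            total_snvs = total, eligible = FALSE,
                            unexplained = NA_real_, !!!as.list(w)))
    }
    fit <- .refit_one(counts, sigs, weight_floor)
    tibble::tibble(sample_id = colnames(catalog96)[j], total_snvs = total,
                   eligible = TRUE, unexplained = fit$unexplained,
                   !!!as.list(fit$weights))
  })
}

#' Pooled-cohort signature refit
#'
#' Combines the spectra of all samples and refits a single exposure vector,
#' the dataset-level alternative to per-sample refitting.
#'
#' @inheritParams refit_exposures
#' @return One-row tibble in the [refit_exposures()] format with
#'   `sample_id = "pooled"`.
#' @export
refit_pooled <- function(catalog96, sigs = synthetic_signature_catalog(),
                         min_snvs = 15, weight_floor = 0.06) {
  pooled <- matrix(rowSums(catalog96), ncol = 1,
                   dimnames = list(rownames(catalog96), "pooled"))
  refit_exposures(pooled, sigs, min_snvs, weight_floor)
}

.signature_cols <- function(exposures) {
  setdiff(names(exposures),
          c("sample_id", "total_snvs", "eligible", "unexplained"))
}

#' Carrier calls from exposures
#'
#' A sample carries a signature when its refitted weight is strictly above
#' `carrier_floor`.
#'
#' @param exposures Tibble from [refit_exposures()].
#' @param carrier_floor Strict carrier threshold (default 0.06).
#' @return Long tibble: `sample_id`, `signature`, `weight`, `carrier`
#'   (eligible samples only).
#' @export
carrier_calls <- function(exposures, carrier_floor = 0.06) {
  sig_cols <- .signature_cols(exposures)
  exposures |>
    dplyr::filter(.data$eligible) |>
    tidyr::pivot_longer(dplyr::all_of(sig_cols), names_to = "signature",
                        values_to = "weight") |>
    dplyr::mutate(carrier = .data$weight > carrier_floor) |>
    dplyr::select("sample_id", "signature", "weight", "carrier")
}

#' Compare per-dataset carrier fractions between two populations
#'
#' Two-sided t-test on per-dataset carrier fractions, per signature.
#' Groups with fewer than two datasets, or zero variance in both groups,
#' are flagged with `NA` p-values.
#'
#' @param fractions Tibble: `dataset`, `population`, `signature`,
#'   `fraction`.
#' @return Tibble: `signature`, `mean_pop1`, `mean_pop2`, `p`, `flag`.
#' @export
compare_carrier_fractions <- function(fractions) {
  assert_cols(fractions, c("dataset", "population", "signature", "fraction"))
  pops <- sort(unique(fractions$population))
  if (length(pops) != 2) cc_abort("exactly two populations required")
  fractions |>
    dplyr::group_by(.data$signature) |>
    dplyr::summarise(
      mean_pop1 = mean(.data$fraction[.data$population == pops[1]]),
      mean_pop2 = mean(.data$fraction[.data$population == pops[2]]),
      p = {
        x <- .data$fraction[.data$population == pops[1]]
        y <- .data$fraction[.data$population == pops[2]]
        if (length(x) < 2 || length(y) < 2) NA_real_
        else if (stats::sd(x) == 0 && stats::sd(y) == 0) {
          if (isTRUE(all.equal(mean(x), mean(y)))) 1 else NA_real_
        } else stats::t.test(x, y)$p.value
      },
      .groups = "drop") |>
    dplyr::mutate(flag = dplyr::if_else(is.na(.data$p),
                                        "degenerate_or_too_few_datasets",
                                        NA_character_))
}

#' One-sided quartile test of signature weights against immune score
#'
#' Samples are ranked by immune score; for each signature a one-sided
#' Wilcoxon rank-sum test (midrank ties) compares weights in the top
#' quartile against the bottom quartile, alternative: top quartile greater.
#'
#' @param exposures Tibble from [refit_exposures()].
#' @param immune_scores Tibble: `sample_id`, `score`.
#' @return Tibble: `signature`, `p`.
#' @export
quartile_signature_test <- function(exposures, immune_scores) {
  assert_cols(immune_scores, c("sample_id", "score"))
  d <- exposures |>
    dplyr::filter(.data$eligible) |>
    dplyr::inner_join(immune_scores, by = "sample_id")
  if (nrow(d) < 8) cc_abort("need at least 8 scored, eligible samples")
  qs <- stats::quantile(d$score, c(0.25, 0.75), type = 7)
  top <- d$score >= qs[2]; bottom <- d$score <= qs[1]
  purrr::map_dfr(.signature_cols(exposures), function(sg) {
    w <- d[[sg]]
    tibble::tibble(
      signature = sg,
      p = suppressWarnings(
        stats::wilcox.test(w[top], w[bottom],
                           alternative = "greater")$p.value))
  })
}

#' Spearman correlation between signature weights and immune scores
#'
#' @param exposures Tibble from [refit_exposures()].
#' @param scores Tibble: `sample_id`, `score_name`, `score` (long form;
#'   one or more score types).
#' @return Tibble: `signature`, `score_name`, `rho` (`NA` for constant
#'   vectors), `p`.
#' @export
signature_immune_correlation <- function(exposures, scores) {
  assert_cols(scores, c("sample_id", "score_name", "score"))
  d <- exposures |> dplyr::filter(.data$eligible)
  purrr::map_dfr(.signature_cols(exposures), function(sg) {
    purrr::map_dfr(unique(scores$score_name), function(sn) {
      s <- scores |> dplyr::filter(.data$score_name == sn)
      m <- dplyr::inner_join(d[, c("sample_id", sg)], s, by = "sample_id")
      w <- m[[sg]]
      if (stats::sd(w) == 0 || stats::sd(m$score) == 0) {
        return(tibble::tibble(signature = sg, score_name = sn,
                              rho = NA_real_, p = NA_real_))
      }
      ct <- suppressWarnings(
        stats::cor.test(w, m$score, method = "spearman", exact = FALSE))
      tibble::tibble(signature = sg, score_name = sn,
                     rho = unname(ct$estimate), p = ct$p.value)
    })
  })
}
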