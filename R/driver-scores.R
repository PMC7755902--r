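#' Gene inclusion by mutated-sample fraction
#'
#' Genes mutated in at least `min_fraction` of samples in at least one
#' stratum are eligible for driver scoring.
#'
#' @param maf Mutation tibble with `sample_id` and `gene`.
#' @param strata Tibble mapping every sample in scope to a stratum:
#'   columns `sample_id`, `stratum`. Samples without mutations must still
#'   appear here, since they enter the denominator.
#' @param min_fraction Minimum mutated-sample fraction (default 0.01).
#' @return Character vector of eligible genes.
#' @export
gene_inclusion <- function(maf, strata, min_fraction = 0.01) {
  assert_cols(strata, c("sample_id", "stratum"))
  sizes <- strata |> dplyr::count(.data$stratum, name = "n_samples")
  if (any(sizes$n_samples == 0) || nrow(sizes) == 0) {
    cc_abort("every stratum must contain at least one sample")
  }
  if (nrow(maf) == 0) return(character())
  assert_cols(maf, c("sample_id", "gene"))
  maf |>
    dplyr::inner_join(strata, by = "sample_id") |>
    dplyr::distinct(.data$gene, .data$stratum, .data$sample_id) |>
    dplyr::count(.data$gene, .data$stratum, name = "n_mutated") |>
    dplyr::left_join(sizes, by = "stratum") |>
    dplyr::filter(.data$n_mutated / .data$n_samples >= min_fraction) |>
    dplyr::distinct(.data$gene) |>
    dplyr::pull("gene")
}

#' Oncogene (ONC) score
#'
#' Percentage of a gene's mutations that are missense mutations at its
#' single most recurrent amino-acid position. Undefined (`NA`) unless the
#' most recurrent position carries at least `min_recurrent` missense
#' mutations.
#'
#' @param consequence Character vector of consequence classes for one
#'   gene's mutations in one stratum.
#' @param protein_pos Integer amino-acid positions (required for missense
#'   records).
#' @param min_recurrent Minimum missense count at the top position
#'   (default 5).
#' @return Score in \[0, 100\], or `NA` when ineligible.
#' @export
onc_score <- function(consequence, protein_pos, min_recurrent = 5) {
  total <- length(consequence)
  if (total == 0) return(NA_real_)
  mis <- consequence == "missense" & !is.na(protein_pos)
  if (!any(mis)) return(NA_real_)
  r <- max(table(protein_pos[mis]))
  if (r < min_recurrent) return(NA_real_)
  100 * r / total
}

#' Tumour-suppressor (TSG) score
#'
#' Percentage of a gene's mutations that are protein-inactivating
#' (nonsense, frameshift or essential splice, the 20/20-rule convention).
#' Undefined (`NA`) with fewer than `min_inactivating` inactivating
#' mutations.
#'
#' @param consequence Character vector of consequence classes.
#' @param min_inactivating Minimum inactivating count (default 5).
#' @return Score in \[0, 100\], or `NA` when ineligible.
#' @export
tsg_score <- function(consequence, min_inactivating = 5) {
  total <- length(consequence)
  if (total == 0) return(NA_real_)
  k <- sum(consequence %in% c("nonsense", "frameshift", "splice"))
  if (k < min_inactivating) return(NA_real_)
  100 * k / total
}

#' Per-stratum driver gene scoring
#'
#' Computes ONC and TSG scores for every eligible gene in every stratum and
#' flags selected candidate drivers (either score strictly above
#' `threshold`).
#'
#' @inheritParams gene_inclusion
#' @param min_recurrent,min_inactivating Eligibility counts for the two
#'   scores.
#' @param threshold Selection threshold on either score, strict (default 20).
#' @return Tibble: `gene`, `stratum`, `n_mutations`, `n_mutated_samples`,
#'   `onc`, `tsg`, `selected`.
#' @export
driver_scores <- function(maf, strata, min_fraction = 0.01,
                          min_recurrent = 5, min_inactivating = 5,
                          threshold = 20) {
  eligible <- gene_inclusion(maf, strata, min_fraction)
  if (!length(eligible)) {
    return(tibble::tibble(gene = character(), stratum = character(),
                          n_mutations = integer(),
                          n_mutated_samples = integer(), onc = double(),
                          tsg = double(), selected = logical()))
  }
  maf |>
    dplyr::inner_join(strata, by = "sample_id") |>
    dplyr::filter(.data$gene %in% eligible) |>
    dplyr::group_by(.data$gene, .data$stratum) |>
    dplyr::summarise(
      n_mutations = dplyr::n(),
      n_mutated_samples = dplyr::n_distinct(.data$sample_id),
      onc = onc_score(.data$consequence, .data$protein_pos, min_recurrent),
      tsg = tsg_score(.data$consequence, min_inactivating),
      .groups = "drop") |>
    dplyr::mutate(selected = (!is.na(.data$onc) & .data$onc > threshold) |
                    (!is.na(.data$tsg) & .data$tsg > threshold))
}

#' Select candidate drivers from a score table
#'
#' @param scores Tibble with `gene`, `onc`, `tsg` (as from
#'   [driver_scores()]).
#' @param threshold Strict selection threshold (default 20).
#' @return Character vector of selected genes (unique).
#' @export
select_drivers <- function(scores, threshold = 20) {
  scores |>
    dplyr::filter((!is.na(.data$onc) & .data$onc > threshold) |
                    (!is.na(.data$tsg) & .data$tsg > threshold)) |>
    dplyr::distinct(.data$gene) |>
    dplyr::pull("gene")
}
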