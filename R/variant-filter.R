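#' Filter cascade configuration
#'
#' Thresholds for the somatic post-calling filter cascade. Defaults follow
#' the published cascade exactly: at least 10 tumour reads and 5 normal
#' reads, OxoG metric strictly below 0.8, VAF of at least 0.075, a
#' strandedness Fisher p of at least 0.05, S_AF strictly above 0.75,
#' removal at gnomAD population frequency of 0.01 or more, at least four
#' alternate reads with at least two per strand, sites recurrent in five
#' or more samples removed unless in COSMIC, and panel-of-normals sites
#' (seen in two or more normals) removed.
#'
#' @param min_t_depth Minimum tumour depth (reads).
#' @param min_n_depth Minimum matched-normal depth (reads).
#' @param max_oxog Exclusive upper bound on the OxoG artefact metric.
#' @param min_vaf Inclusive lower bound on variant allele frequency.
#' @param min_strand_p Inclusive lower bound on the strandedness Fisher p.
#' @param min_s_af Exclusive lower bound on the caller S_AF score.
#' @param recurrence_threshold Sample count at which a position counts as
#'   recurrent.
#' @param max_gnomad_af Records with gnomAD frequency at or above this are
#'   removed.
#' @param min_alt_reads Minimum alternate read count.
#' @param min_alt_per_strand Minimum alternate reads on each strand.
#' @param pon_min_normals Minimum distinct normal samples for a site to
#'   enter the panel of normals.
#' @return A named list of class `"filter_config"`.
#' @export
filter_config <- function(min_t_depth = 10, min_n_depth = 5, max_oxog = 0.8,
                          min_vaf = 0.075, min_strand_p = 0.05,
                          min_s_af = 0.75, recurrence_threshold = 5,
                          max_gnomad_af = 0.01, min_alt_reads = 4,
                          min_alt_per_strand = 2, pon_min_normals = 2) {
  cfg <- list(min_t_depth = min_t_depth, min_n_depth = min_n_depth,
              max_oxog = max_oxog, min_vaf = min_vaf,
              min_strand_p = min_strand_p, min_s_af = min_s_af,
              recurrence_threshold = recurrence_threshold,
              max_gnomad_af = max_gnomad_af, min_alt_reads = min_alt_reads,
              min_alt_per_strand = min_alt_per_strand,
              pon_min_normals = pon_min_normals)
  if (any(unlist(cfg) <= 0)) {
    cc_abort("all filter thresholds must be strictly positive",
             class = "cohortcompare_config_error")
  }
  structure(cfg, class = "filter_config")
}

#' Build a panel of normals from per-normal candidate sites
#'
#' Retains exactly the (chrom, pos, alt) sites observed in at least
#' `min_normals` distinct normal samples.
#'
#' @param normal_calls Tibble with columns `normal_sample_id`, `chrom`,
#'   `pos`, `alt`, de-duplicated per (sample, site, alt).
#' @param min_normals Minimum number of distinct normals (default 2).
#' @return Tibble of blacklisted sites: `chrom`, `pos`, `alt`, `n_normals`.
#' @export
build_panel_of_normals <- function(normal_calls, min_normals = 2) {
  if (nrow(normal_calls) == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          alt = character(), n_normals = integer()))
  }
  assert_cols(normal_calls, c("normal_sample_id", "chrom", "pos", "alt"))
  normal_calls |>
    dplyr::distinct(.data$normal_sample_id, .data$chrom, .data$pos, .data$alt) |>
    dplyr::count(.data$chrom, .data$pos, .data$alt, name = "n_normals") |>
    dplyr::filter(.data$n_normals >= min_normals)
}

#' Strand bias p-value
#'
#' Two-sided Fisher exact test on the 2x2 strandedness table
#' `[[alt_fwd, alt_rev], [ref_fwd, ref_rev]]`. An all-zero table returns 1
#' by convention. Vectorised over records.
#'
#' @param alt_fwd,alt_rev Alternate reads on the forward / reverse strand.
#' @param ref_fwd,ref_rev Reference reads on the forward / reverse strand.
#' @return Numeric vector of p-values in \[0, 1\].
#' @export
strand_bias_p <- function(alt_fwd, alt_rev, ref_fwd, ref_rev) {
  stopifnot(all(c(alt_fwd, alt_rev, ref_fwd, ref_rev) >= 0))
  n <- length(alt_fwd)
  vapply(seq_len(n), function(i) {
    tab <- matrix(c(alt_fwd[i], ref_fwd[i], alt_rev[i], ref_rev[i]), 2, 2)
    if (sum(tab) == 0) return(1)
    stats::fisher.test(tab)$p.value
  }, numeric(1))
}

# ordered rule list; each returns TRUE when the record PASSES
.filter_rules <- function(cfg) {
  list(
    pon            = function(d) !d$in_pon,
    min_t_depth    = function(d) d$t_depth >= cfg$min_t_depth,
    min_n_depth    = function(d) d$n_depth >= cfg$min_n_depth,
    max_oxog       = function(d) d$oxog_metric < cfg$max_oxog,
    min_vaf        = function(d) d$vaf >= cfg$min_vaf,
    strand_bias    = function(d) d$strand_p >= cfg$min_strand_p,
    min_s_af       = function(d) d$s_af > cfg$min_s_af,
    max_gnomad     = function(d) d$gnomad_af < cfg$max_gnomad_af,
    min_alt_reads  = function(d) (d$alt_fwd + d$alt_rev) >= cfg$min_alt_reads,
    min_alt_per_strand = function(d)
      d$alt_fwd >= cfg$min_alt_per_strand & d$alt_rev >= cfg$min_alt_per_strand,
    indel_second_caller = function(d)
      d$variant_type != "indel" | d$second_caller
  )
}

#' Apply the somatic filter cascade
#'
#' A record is retained iff it passes every rule: not in the panel of
#' normals, depth bounds, OxoG, VAF, strand balance, S_AF, gnomAD
#' frequency, alternate-read support (total and per strand), and -- for
#' indels -- confirmation by a second caller. Whitelisted sites bypass the
#' cascade (the mechanism used for manually salvaged variants).
#'
#' @param records Tibble of variant calls with the MAF-like columns
#'   (`sample_id`, `chrom`, `pos`, `ref`, `alt`, `variant_type`, `t_depth`,
#'   `n_depth`, `alt_fwd`, `alt_rev`, `ref_fwd`, `ref_rev`, `vaf`,
#'   `oxog_metric`, `s_af`, `gnomad_af`, `second_caller`).
#' @param pon Panel-of-normals tibble from [build_panel_of_normals()]
#'   (may be empty).
#' @param config A [filter_config()].
#' @param whitelist Optional tibble of `chrom`, `pos`, `alt` sites that are
#'   always retained.
#' @return A list with `retained` (the passing records) and `audit`
#'   (one row per record x rule: `row_id`, `sample_id`, `chrom`, `pos`,
#'   `rule`, `pass`, plus a per-record `verdict` column).
#' @export
apply_snv_filters <- function(records, pon = NULL, config = filter_config(),
                              whitelist = NULL) {
  req <- c("sample_id", "chrom", "pos", "ref", "alt", "variant_type",
           "t_depth", "n_depth", "alt_fwd", "alt_rev", "ref_fwd", "ref_rev",
           "vaf", "oxog_metric", "s_af", "gnomad_af", "second_caller")
  if (nrow(records) == 0) {
    return(list(retained = records,
                audit = tibble::tibble(row_id = integer(), sample_id = character(),
                                       chrom = character(), pos = integer(),
                                       rule = character(), pass = logical(),
                                       verdict = logical())))
  }
  # records with missing required fields are dropped with a record-level error
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    cc_abort(sprintf("records are missing required columns: %s",
                     paste(missing_cols, collapse = ", ")))
  }
  bad <- !stats::complete.cases(records[, req])
  if (any(bad)) {
    rlang::warn(sprintf("%d record(s) with missing fields excluded", sum(bad)))
    records <- records[!bad, , drop = FALSE]
  }

  d <- records
  d$row_id <- seq_len(nrow(d))
  pon_key <- if (!is.null(pon) && nrow(pon)) {
    paste(pon$chrom, pon$pos, pon$alt, sep = ":")
  } else character()
  d$in_pon <- paste(d$chrom, d$pos, d$alt, sep = ":") %in% pon_key
  d$strand_p <- strand_bias_p(d$alt_fwd, d$alt_rev, d$ref_fwd, d$ref_rev)

  rules <- .filter_rules(config)
  pass_mat <- vapply(rules, function(f) f(d), logical(nrow(d)))
  if (nrow(d) == 1) pass_mat <- matrix(pass_mat, nrow = 1,
                                       dimnames = list(NULL, names(rules)))
  verdict <- rowSums(!pass_mat) == 0

  if (!is.null(whitelist) && nrow(whitelist)) {
    wl <- paste(whitelist$chrom, whitelist$pos, whitelist$alt, sep = ":")
    verdict <- verdict | paste(d$chrom, d$pos, d$alt, sep = ":") %in% wl
  }

  audit <- tibble::tibble(
    row_id = rep(d$row_id, times = length(rules)),
    sample_id = rep(d$sample_id, times = length(rules)),
    chrom = rep(d$chrom, times = length(rules)),
    pos = rep(d$pos, times = length(rules)),
    rule = rep(names(rules), each = nrow(d)),
    pass = as.vector(pass_mat),
    verdict = rep(verdict, times = length(rules))
  ) |>
    dplyr::arrange(.data$row_id, match(.data$rule, names(rules)))

  list(retained = records[verdict, , drop = FALSE], audit = audit)
}

#' Cohort recurrence filter
#'
#' Positions carried by `threshold` or more samples are removed unless the
#' site is in COSMIC (`in_cosmic` is `TRUE`), the default reading of the
#' published exception for recurrent artefact positions. Removed positions
#' are attached as the `"removed_positions"` attribute.
#'
#' @param retained Filtered mutation tibble with `sample_id`, `chrom`,
#'   `pos`, `in_cosmic`.
#' @param threshold Recurrence sample count (default 5).
#' @param rescue_cosmic Keep recurrent positions that are in COSMIC
#'   (default `TRUE`).
#' @return The mutation tibble with recurrent artefact positions removed.
#' @export
recurrence_filter <- function(retained, threshold = 5, rescue_cosmic = TRUE) {
  if (nrow(retained) == 0) return(retained)
  assert_cols(retained, c("sample_id", "chrom", "pos", "in_cosmic"))
  rec <- retained |>
    dplyr::distinct(.data$sample_id, .data$chrom, .data$pos) |>
    dplyr::count(.data$chrom, .data$pos, name = "n_samples") |>
    dplyr::filter(.data$n_samples >= threshold)
  key <- paste(retained$chrom, retained$pos)
  is_rec <- key %in% paste(rec$chrom, rec$pos)
  drop <- is_rec & if (rescue_cosmic) !retained$in_cosmic else TRUE
  removed <- retained[drop, , drop = FALSE] |>
    dplyr::count(.data$chrom, .data$pos, name = "n_samples")
  out <- retained[!drop, , drop = FALSE]
  attr(out, "removed_positions") <- removed
  if (nrow(removed)) {
    message(sprintf("recurrence_filter: removed %d position(s) recurrent in >= %d samples",
                    nrow(removed), threshold))
  }
  out
}
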