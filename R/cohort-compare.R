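#' Subtype prevalence per cohort
#'
#' Counts and fractions per cohort x subtype, optionally within age strata
#' (strictly below the cutoff versus at-or-above).
#'
#' @param cohort_table Tibble with `patient_id`, `cohort`, `subtype` and,
#'   if stratifying, `age`.
#' @param stratify_age Split by age stratum (default `FALSE`).
#' @param age_cutoff Stratum boundary in years (default 50).
#' @return Tibble: `cohort`, (`age_stratum`,) `subtype`, `n`, `fraction`;
#'   fractions sum to 1 within each cohort (x stratum).
#' @export
subtype_prevalence <- function(cohort_table, stratify_age = FALSE,
                               age_cutoff = 50) {
  assert_cols(cohort_table, c("patient_id", "cohort", "subtype"))
  d <- cohort_table
  grp <- c("cohort", "subtype")
  if (stratify_age) {
    assert_cols(d, "age")
    d$age_stratum <- ifelse(d$age < age_cutoff,
                            sprintf("<%d", age_cutoff),
                            sprintf(">=%d", age_cutoff))
    grp <- c("cohort", "age_stratum", "subtype")
  }
  d |>
    dplyr::count(dplyr::across(dplyr::all_of(grp)), name = "n") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(setdiff(grp, "subtype")))) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction. A zero margin gives an `NA` p-value with
#' a warning.
#'
#' @param counts Integer matrix (e.g. 2x2 subtype-vs-rest by cohort).
#' @return Tibble: `statistic`, `df`, `p`.
#' @export
prevalence_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    rlang::warn("zero margin; p undefined")
    return(tibble::tibble(statistic = NA_real_, df = NA_integer_,
                          p = NA_real_))
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic),
                 df = as.integer(unname(ct$parameter)),
                 p = ct$p.value)
}

#' Per-subtype prevalence comparison between two cohorts
#'
#' Subtype-versus-rest 2x2 chi-square per subtype (matching per-bar p
#' values), plus the omnibus K x 2 test, both without continuity
#' correction and with raw and Bonferroni-adjusted p-values.
#'
#' @param cohort_table Tibble with `cohort` (two levels) and `subtype`.
#' @return Tibble: `subtype` (`"(omnibus)"` for the K x 2 test),
#'   `n_a`, `n_b`, `frac_a`, `frac_b`, `statistic`, `p`, `p_bonferroni`.
#' @export
subtype_prevalence_tests <- function(cohort_table) {
  cohorts <- sort(unique(cohort_table$cohort))
  if (length(cohorts) != 2) cc_abort("exactly two cohorts required")
  tab <- table(cohort_table$subtype, cohort_table$cohort)
  subtypes <- rownames(tab)
  per <- purrr::map_dfr(subtypes, function(st) {
    m <- rbind(tab[st, ], colSums(tab) - tab[st, ])
    tt <- prevalence_test(m)
    tibble::tibble(subtype = st,
                   n_a = tab[st, cohorts[1]], n_b = tab[st, cohorts[2]],
                   frac_a = tab[st, cohorts[1]] / sum(tab[, cohorts[1]]),
                   frac_b = tab[st, cohorts[2]] / sum(tab[, cohorts[2]]),
                   statistic = tt$statistic, p = tt$p)
  })
  per$p_bonferroni <- pmin(1, per$p * nrow(per))
  omni <- prevalence_test(tab)
  dplyr::bind_rows(per,
                   tibble::tibble(subtype = "(omnibus)", n_a = sum(tab[, cohorts[1]]),
                                  n_b = sum(tab[, cohorts[2]]),
                                  frac_a = 1, frac_b = 1,
                                  statistic = omni$statistic, p = omni$p,
                                  p_bonferroni = omni$p))
}

#' Gene mutation prevalence by ER stratum between cohorts
#'
#' Mutated-sample fractions per cohort within ER+ and ER- strata, with a
#' chi-square test (Fisher exact when any expected cell is below 5) per
#' gene x stratum.
#'
#' @param maf Mutation tibble with `sample_id`, `gene`.
#' @param cohort_table Tibble with `patient_id`, `cohort`, `er_status`.
#' @param genes Genes to compare.
#' @return Tibble: `gene`, `er_status`, `n_a`, `n_b`, `frac_a`, `frac_b`,
#'   `test`, `p`.
#' @export
mutation_prevalence_by_er <- function(maf, cohort_table, genes) {
  assert_cols(cohort_table, c("patient_id", "cohort", "er_status"))
  cohorts <- sort(unique(cohort_table$cohort))
  purrr::map_dfr(genes, function(g) {
    carriers <- unique(maf$sample_id[maf$gene == g])
    purrr::map_dfr(c("pos", "neg"), function(er) {
      d <- cohort_table[cohort_table$er_status == er, ]
      if (nrow(d) == 0 || length(unique(d$cohort)) < 2) return(NULL)
      mut <- d$patient_id %in% carriers
      tab <- table(factor(d$cohort, levels = cohorts),
                   factor(mut, levels = c(TRUE, FALSE)))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      use_fisher <- any(expected < 5)
      p <- if (all(colSums(tab) > 0)) {
        if (use_fisher) stats::fisher.test(tab)$p.value
        else suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
      } else NA_real_
      na <- sum(d$cohort == cohorts[1]); nb <- sum(d$cohort == cohorts[2])
      tibble::tibble(gene = g, er_status = er,
                     n_a = na, n_b = nb,
                     frac_a = tab[cohorts[1], "TRUE"] / na,
                     frac_b = tab[cohorts[2], "TRUE"] / nb,
                     test = ifelse(use_fisher, "fisher", "chisq"), p = p)
    })
  })
}

#' Survival-analysis inclusion rule
#'
#' Keeps patients with at least `min_follow_up` years of survival data.
#' By default patients who died before the cutoff are excluded too
#' (symmetric reading of the rule); set `include_early_events = TRUE` to
#' keep deaths before the cutoff.
#'
#' @param cohort_table Tibble with `survival_time`, `event`.
#' @param min_follow_up Minimum years of data (default 2).
#' @param include_early_events Keep deaths before the cutoff
#'   (default `FALSE`).
#' @return Filtered tibble.
#' @export
survival_inclusion <- function(cohort_table, min_follow_up = 2,
                               include_early_events = FALSE) {
  assert_cols(cohort_table, c("survival_time", "event"))
  keep <- cohort_table$survival_time >= min_follow_up
  if (include_early_events) keep <- keep | cohort_table$event
  cohort_table[keep, , drop = FALSE]
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with right censoring, returned as a tidy step
#' function plus the survival probability at a landmark time.
#'
#' @param times Survival times (years).
#' @param events Logical (or 0/1) event indicators.
#' @param landmark Time at which to report survival (default 5 years).
#' @return List: `curve` (tibble `time`, `n_risk`, `n_event`, `surv`) and
#'   `surv_at_landmark`.
#' @export
km_estimate <- function(times, events, landmark = 5) {
  stopifnot(length(times) >= 1)
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  curve <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                          n_event = fit$n.event, surv = fit$surv)
  s5 <- if (any(curve$time <= landmark & curve$n_event > 0)) {
    min(curve$surv[curve$time <= landmark])
  } else 1
  list(curve = curve, surv_at_landmark = s5)
}

#' Log-rank test across groups
#'
#' @param times,events As in [km_estimate()].
#' @param group Group labels (>= 2 groups).
#' @return Tibble: `statistic`, `df`, `p` (`NA` with a warning when there
#'   are no events).
#' @export
logrank_test <- function(times, events, group) {
  if (sum(events) == 0) {
    rlang::warn("no events; log-rank p undefined")
    return(tibble::tibble(statistic = NA_real_, df = NA_integer_,
                          p = NA_real_))
  }
  sd <- survival::survdiff(
    survival::Surv(times, as.integer(events)) ~ g,
    data = data.frame(times = times, events = events, g = group))
  df <- length(sd$n) - 1
  tibble::tibble(statistic = sd$chisq, df = as.integer(df),
                 p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood fit with Efron tie handling, reported as hazard
#' ratios with Wald confidence intervals.
#'
#' @param data Tibble containing the survival and covariate columns.
#' @param time_col,event_col Column names for time and event.
#' @param covariates Character vector of covariate column names.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `"cohort_coxfit"` wrapping the
#'   `survival::coxph` fit; use [tidy.cohort_coxfit()] for the HR table.
#' @export
cox_fit <- function(data, time_col = "survival_time", event_col = "event",
                    covariates, conf_level = 0.95) {
  assert_cols(data, c(time_col, event_col, covariates))
  if (sum(data[[event_col]]) == 0) cc_abort("no events; Cox model undefined")
  for (cv in covariates) {
    if (length(unique(data[[cv]])) < 2) {
      cc_abort(sprintf("covariate `%s` has zero variance", cv))
    }
  }
  f <- stats::as.formula(paste0("survival::Surv(", time_col, ", as.integer(",
                                event_col, ")) ~ ",
                                paste(covariates, collapse = " + ")))
  fit <- survival::coxph(f, data = data, ties = "efron")
  structure(list(fit = fit, conf_level = conf_level,
                 covariates = covariates), class = "cohort_coxfit")
}

#' Tidy Cox hazard ratios
#'
#' @param x A `"cohort_coxfit"`.
#' @param ... Unused.
#' @return Tibble: `term`, `hr`, `conf_low`, `conf_high`, `p`.
#' @export
tidy.cohort_coxfit <- function(x, ...) {
  sm <- summary(x$fit, conf.int = x$conf_level)
  tibble::tibble(term = rownames(sm$coefficients),
                 hr = sm$conf.int[, "exp(coef)"],
                 conf_low = sm$conf.int[, 3],
                 conf_high = sm$conf.int[, 4],
                 p = sm$coefficients[, "Pr(>|z|)"])
}

#' One-row Cox fit summary
#'
#' @param x A `"cohort_coxfit"`.
#' @param ... Unused.
#' @return Tibble: `n`, `n_events`, `loglik`, `concordance`.
#' @export
glance.cohort_coxfit <- function(x, ...) {
  tibble::tibble(n = x$fit$n, n_events = x$fit$nevent,
                 loglik = x$fit$loglik[2],
                 concordance = unname(x$fit$concordance["concordance"]))
}

#' @export
print.cohort_coxfit <- function(x, ...) {
  cat("Cox proportional hazards fit (Efron ties)\n")
  print(tidy.cohort_coxfit(x))
  invisible(x)
}
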