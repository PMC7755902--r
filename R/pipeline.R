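#' Run the full two-cohort comparison on a generated bundle
#'
#' Chains the downstream stages on a synthetic bundle and reports the four
#' headline comparisons: (1) prevalence of a chosen subtype between
#' cohorts (chi-square), (2) TP53 mutation prevalence within ER+ samples,
#' (3) the cohort immune-score difference (one-way ANOVA on mean
#' rank-enrichment immune scores), and (4) survival stratified by TP53
#' status within ER+ patients (log-rank), each with its direction.
#'
#' @param bundle Output of [generate_cohorts()].
#' @param subtype Subtype whose prevalence is compared (default `"IC5"`).
#' @return Tibble: `finding`, `effect_a`, `effect_b`, `p`, `direction_a_vs_b`.
#' @export
run_cohort_comparison <- function(bundle, subtype = "IC5") {
  cohort <- bundle$cohort

  # 1. subtype prevalence
  prev <- subtype_prevalence_tests(cohort)
  p1 <- prev[prev$subtype == subtype, ]

  # 2. TP53 prevalence in ER+
  mut_er <- mutation_prevalence_by_er(bundle$mutations, cohort, "TP53")
  p2 <- mut_er[mut_er$er_status == "pos", ]

  # 3. immune-score cohort difference (combined immune set)
  combined <- list(immune = unlist(bundle$gene_sets, use.names = FALSE))
  imm <- ssgsea_score(bundle$expression$tpm, combined)
  imm <- dplyr::left_join(imm, cohort, by = c(sample_id = "patient_id"))
  fit <- stats::aov(score ~ cohort, data = imm)
  p3 <- summary(fit)[[1]][["Pr(>F)"]][1]
  mean_a <- mean(imm$score[imm$cohort == "A"])
  mean_b <- mean(imm$score[imm$cohort == "B"])

  # 4. survival by TP53 within ER+ (cohort A-style stratification)
  surv <- survival_inclusion(cohort)
  surv <- surv[surv$er_status == "pos", ]
  tp53_carriers <- unique(bundle$mutations$sample_id[
    bundle$mutations$gene == "TP53"])
  surv$tp53 <- surv$patient_id %in% tp53_carriers
  lr <- logrank_test(surv$survival_time, surv$event, surv$tp53)
  km_mut <- km_estimate(surv$survival_time[surv$tp53],
                        surv$event[surv$tp53])$surv_at_landmark
  km_wt <- km_estimate(surv$survival_time[!surv$tp53],
                       surv$event[!surv$tp53])$surv_at_landmark

  tibble::tibble(
    finding = c("subtype_prevalence", "tp53_er_pos", "immune_scores",
                "survival_tp53_er_pos"),
    effect_a = c(p1$frac_a, p2$frac_a, mean_a, km_mut),
    effect_b = c(p1$frac_b, p2$frac_b, mean_b, km_wt),
    p = c(p1$p, p2$p, p3, lr$p),
    direction_a_vs_b = c(
      ifelse(p1$frac_a > p1$frac_b, "higher", "lower"),
      ifelse(p2$frac_a > p2$frac_b, "higher", "lower"),
      ifelse(mean_a > mean_b, "higher", "lower"),
      ifelse(km_mut < km_wt, "worse", "better"))
  )
}
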