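# Independent oracles, deliberately coded without reference to the package
# implementation: plain loops, explicit enumeration, hand formulas.

# two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins
oracle_fisher_p <- function(n11, n12, n21, n22) {
  r1 <- n11 + n12; c1 <- n11 + n21; n <- n11 + n12 + n21 + n22
  if (n == 0) return(1)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  support <- lo:hi
  probs <- vapply(support, function(x) {
    exp(lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1))
  }, numeric(1))
  p_obs <- probs[support == n11]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson chi-square p without continuity correction, hand formula
oracle_chisq_p <- function(tab) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  stats::pchisq(stat, df, lower.tail = FALSE)
}

# rule-by-rule brute-force reimplementation of the filter cascade; loops
# over records, recomputes the strandedness p by enumeration
oracle_filter_verdicts <- function(records, pon_keys = character()) {
  vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    key <- paste(r$chrom, r$pos, r$alt, sep = ":")
    if (key %in% pon_keys) return(FALSE)
    if (r$t_depth < 10) return(FALSE)
    if (r$n_depth < 5) return(FALSE)
    if (!(r$oxog_metric < 0.8)) return(FALSE)
    if (r$vaf < 0.075) return(FALSE)
    sp <- oracle_fisher_p(r$alt_fwd, r$alt_rev, r$ref_fwd, r$ref_rev)
    if (sp < 0.05) return(FALSE)
    if (!(r$s_af > 0.75)) return(FALSE)
    if (r$gnomad_af >= 0.01) return(FALSE)
    if (r$alt_fwd + r$alt_rev < 4) return(FALSE)
    if (r$alt_fwd < 2 || r$alt_rev < 2) return(FALSE)
    if (r$variant_type == "indel" && !r$second_caller) return(FALSE)
    TRUE
  }, logical(1))
}

# exponential survival data with a binary covariate at a planted hazard ratio
simulate_cox_data <- function(n, hr, baseline = 0.1, censor = 10) {
  x <- rep(0:1, length.out = n)
  t_event <- rexp(n, baseline * hr^x)
  data.frame(survival_time = pmin(t_event, censor),
             event = t_event <= censor, x = x)
}
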