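mk_expr <- function(n_genes = 50, n_samples = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(2^rnorm(n_genes * n_samples, 5, 1), n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  m
}

test_that("gene filter retains exactly the complement of the removal rule", {
  counts <- matrix(c(9.9, 10, 10, 0), 4, 1,
                   dimnames = list(c("low_count", "edge", "ok", "zero"), "S1"))
  counts <- cbind(counts, counts)  # two samples, means equal the values
  colnames(counts) <- c("S1", "S2")
  tpm <- counts
  tpm["edge", ] <- 0.1     # exactly at the TPM bound: retained
  tpm["ok", ] <- 5
  kept <- filter_genes(counts, tpm)
  expect_setequal(kept, c("edge", "ok"))
  expect_error(filter_genes(counts, tpm[1:3, , drop = FALSE]), "identical")
})

test_that("rank-enrichment score is maximal for top-ranked sets and rank-invariant", {
  m <- mk_expr()
  expr_sorted <- sort(m[, 1], decreasing = TRUE)
  top_set <- list(top = names(expr_sorted)[1:10])
  s_top <- ssgsea_score(m[, 1, drop = FALSE], top_set)$score
  # any other set of the same size scores strictly less
  set.seed(2)
  for (i in 1:10) {
    other <- list(o = sample(rownames(m), 10))
    if (setequal(other$o, top_set$top)) next
    expect_lt(ssgsea_score(m[, 1, drop = FALSE], other)$score, s_top)
  }
  # monotone transform invariance (rank-based): log2 and affine
  sets <- list(s = rownames(m)[c(3, 9, 27)])
  s0 <- ssgsea_score(m, sets)
  expect_equal(ssgsea_score(log2(m), sets)$score, s0$score, tolerance = 1e-12)
  expect_equal(ssgsea_score(m * 7 + 100, sets)$score, s0$score,
               tolerance = 1e-12)
  expect_error(ssgsea_score(m, list(gone = c("NOPE1", "NOPE2"))), "gone")
})

test_that("random expression centres the enrichment score near zero", {
  set.seed(3)
  scores <- replicate(60, {
    m <- matrix(2^rnorm(200), 200, 1,
                dimnames = list(sprintf("G%03d", 1:200), "S1"))
    ssgsea_score(m, list(s = sprintf("G%03d", 1:20)))$score
  })
  expect_lt(abs(mean(scores)), stats::sd(scores))
})

test_that("IMPRES counts strict inequalities and is bounded and monotone-invariant", {
  # disjoint 14-pair feature set lets all features be satisfied at once
  disjoint <- tibble::tibble(
    gene_a = sprintf("CKA%02d", 1:14),
    gene_b = sprintf("CKB%02d", 1:14),
    relation = rep(c("greater", "less"), 7))
  hi <- ifelse(disjoint$relation == "greater", 10, 1)
  m_all <- matrix(c(hi, 11 - hi), ncol = 1,
                  dimnames = list(c(disjoint$gene_a, disjoint$gene_b), "S1"))
  expect_equal(impres_score(m_all, disjoint)$impres, 14L)
  # inverting every value violates every feature
  m_none <- 11 - m_all
  expect_equal(impres_score(m_none, disjoint)$impres, 0L)
  # ties never satisfy a strict relation
  m_tie <- m_all; m_tie[, 1] <- 5
  expect_equal(impres_score(m_tie, disjoint)$impres, 0L)

  feats <- synthetic_impres_features()
  genes <- unique(c(feats$gene_a, feats$gene_b))
  set.seed(99)
  m <- matrix(2^rnorm(length(genes)), ncol = 1,
              dimnames = list(genes, "S1"))
  sc <- impres_score(m, feats)
  expect_lte(sc$impres, 14)
  expect_gte(sc$impres, 0)
  expect_equal(sc$n_features, 14)
  # monotone transform invariance
  expect_equal(impres_score(m^3, feats)$impres,
               impres_score(m, feats)$impres)
  # swapping the genes of one satisfied 'greater' feature decrements by 1
  set.seed(4)
  m1 <- matrix(2^rnorm(length(genes)), ncol = 1,
               dimnames = list(genes, "S1"))
  base_score <- impres_score(m1, feats)$impres
  gi <- which(feats$relation == "greater" &
                m1[feats$gene_a, 1] > m1[feats$gene_b, 1])[1]
  skip_if(is.na(gi))
  swapped <- feats
  swapped$gene_a[gi] <- feats$gene_b[gi]
  swapped$gene_b[gi] <- feats$gene_a[gi]
  expect_equal(impres_score(m1, swapped)$impres, base_score - 1L)
  # missing gene: feature skipped with warning, denominator reported
  expect_warning(sk <- impres_score(m1[-1, , drop = FALSE], feats),
                 "skipped")
  expect_lt(sk$n_features, 14)
})

test_that("IMPRES dichotomisation is high at 9 or more", {
  expect_equal(as.character(classify_impres(c(9, 8, 0, 14))),
               c("high", "low", "low", "high"))
})

test_that("ER mixture EM separates components and labels reliably", {
  set.seed(5)
  truth <- rep(c("neg", "pos"), each = 250)
  tpm <- 2^c(rnorm(250, 1, 0.7), rnorm(250, 5, 0.7)) - 1
  tpm[tpm < 0] <- 0
  names(tpm) <- sprintf("S%03d", 1:500)
  fit <- er_status_em(tpm)
  expect_gte(mean(fit$labels == truth), 0.95)
  # log-likelihood is non-decreasing every iteration
  expect_true(all(diff(fit$loglik) >= -1e-8))
  expect_false(fit$unreliable)
  # label assignment invariant to sample order
  perm <- sample(500)
  fit2 <- er_status_em(tpm[perm])
  expect_equal(fit2$labels[names(tpm)], fit$labels)
  # tidy/glance wiring
  td <- generics::tidy(fit)
  expect_equal(nrow(td), 500)
  expect_true(all(td$er_call %in% c("pos", "neg")))
  gl <- generics::glance(fit)
  expect_lt(gl$mean_neg, gl$mean_pos)
})

test_that("near-degenerate data is flagged unreliable", {
  # a tight single cluster forces overlapping components
  set.seed(6)
  tpm <- 2^rnorm(300, 3, 0.05)
  fit <- suppressWarnings(er_status_em(tpm))
  pooled_sd <- sqrt(mean(fit$sds^2))
  expect_equal(fit$unreliable, abs(diff(fit$means)) < 0.5 * pooled_sd)
  expect_error(er_status_em(2^rnorm(5)), "10")
})

test_that("EM labels agree with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(7)
  tpm <- 2^c(rnorm(200, 1, 0.8), rnorm(200, 5, 0.8)) - 1
  tpm[tpm < 0] <- 0
  fit <- er_status_em(tpm)
  x <- log2(tpm + 1)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  mc_pos <- mc$classification == which.max(mc$parameters$mean)
  expect_gte(mean((fit$labels == "pos") == mc_pos), 0.97)
})

test_that("covariate regression recovers exact fits and names collinearity", {
  d <- tibble::tibble(age = 1:30, score = 2 * age)
  fit <- suppressWarnings(covariate_regression(d, "score", "age"))
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "age"], 2,
               tolerance = 1e-10)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-10)
  d$age2 <- d$age * 3
  expect_error(covariate_regression(d, "score", c("age", "age2")), "age2")
  # cohort effect retained after adjusting for subtype
  set.seed(8)
  n <- 500
  d2 <- tibble::tibble(
    cohort = rep(c("A", "B"), each = n / 2),
    subtype = sample(c("s1", "s2", "s3"), n, replace = TRUE),
    score = 0.5 * (cohort == "A") + 0.3 * (subtype == "s2") + rnorm(n))
  fit2 <- covariate_regression(d2, "score", c("cohort", "subtype"))
  p_cohort <- fit2$coefficients$p[grepl("cohort", fit2$coefficients$term)]
  expect_lt(p_cohort, 0.01)
})
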