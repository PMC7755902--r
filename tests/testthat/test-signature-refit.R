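sigs <- synthetic_signature_catalog()

test_that("catalogue structure is valid and round-trips through TSV", {
  expect_equal(dim(sigs), c(96, 13))
  expect_equal(unname(colSums(sigs)), rep(1, 13), tolerance = 1e-9)
  expect_true(all(sigs >= 0))
  expect_equal(rownames(sigs), sbs_channels())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature_catalog(sigs, path)
  expect_equal(read_signature_catalog(path), sigs, tolerance = 1e-12)
})

test_that("96-channel tally applies the pyrimidine-centred strand convention", {
  # A[G>T]C on the purine strand lands in the G[C>A]T channel
  mut <- tibble::tibble(sample_id = "S1", ref = "G", alt = "T",
                        context = "AGC")
  tal <- tally_96(mut)
  expect_equal(tal["G[C>A]T", "S1"], 1L)
  expect_equal(sum(tal), 1L)
  # one mutation per channel -> all-ones vector, invariant to input order
  dec <- tibble::tibble(sample_id = "S1",
                        ref = substr(sbs_channels(), 3, 3),
                        alt = substr(sbs_channels(), 5, 5),
                        context = paste0(substr(sbs_channels(), 1, 1),
                                         substr(sbs_channels(), 3, 3),
                                         substr(sbs_channels(), 7, 7)))
  expect_equal(unname(tally_96(dec)[, 1]), rep(1L, 96))
  shuf <- dec[sample(96), ]
  expect_equal(tally_96(shuf), tally_96(dec))
  # malformed context skipped with a warning
  bad <- dplyr::bind_rows(mut, tibble::tibble(sample_id = "S1", ref = "C",
                                              alt = "T", context = "AAT"))
  expect_warning(tal2 <- tally_96(bad), "malformed")
  expect_equal(sum(tal2), 1L)
})

test_that("refit recovers pure and mixed exposures", {
  # spectrum exactly proportional to Signature 2: weight >= 0.94
  pure <- round(sigs[, "Signature.2"] * 1e6)
  e <- refit_exposures(setNames(pure, rownames(sigs)), sigs)
  expect_gte(e$Signature.2, 0.94)
  others <- unlist(e[1, setdiff(colnames(sigs), "Signature.2")])
  expect_true(all(others < 0.06))
  # eligibility: 14 mutations -> ineligible
  few <- c(rep(1L, 14), rep(0L, 82))
  names(few) <- rownames(sigs)
  e14 <- refit_exposures(few, sigs)
  expect_false(e14$eligible)
  expect_true(is.na(e14$Signature.1))
  # 50/50 mixture of Signatures 1 and 3 at 1000 mutations: recovered
  # weights within 0.05 of truth on average over simulation seeds
  errs <- vapply(1:5, function(s) {
    mix <- generate_mutation_catalog(c(0.5, 0, 0, 0.5, rep(0, 9)), 1000,
                                     sigs, seed = 40 + s)
    em1 <- refit_exposures(mix, sigs)
    max(abs(em1$Signature.1 - 0.5), abs(em1$Signature.3 - 0.5))
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
  mix <- generate_mutation_catalog(c(0.5, 0, 0, 0.5, rep(0, 9)), 1000,
                                   sigs, seed = 44)
  em <- refit_exposures(mix, sigs)
  # weights + unexplained sum to 1 for eligible samples
  sig_cols <- setdiff(names(em), c("sample_id", "total_snvs", "eligible",
                                   "unexplained"))
  expect_equal(sum(unlist(em[1, sig_cols])) + em$unexplained, 1,
               tolerance = 1e-6)
})

test_that("residual never increases when a truly present signature is added", {
  mix <- generate_mutation_catalog(c(0.5, 0, 0, 0.5, rep(0, 9)), 2000,
                                   sigs, seed = 45)
  without <- refit_exposures(mix, sigs[, colnames(sigs) != "Signature.3"])
  with_all <- refit_exposures(mix, sigs)
  expect_lte(with_all$unexplained, without$unexplained + 1e-12)
})

test_that("channel-order permutation leaves exposures unchanged", {
  mix <- generate_mutation_catalog(c(0.3, 0.7, rep(0, 11)), 1000, sigs,
                                   seed = 46)
  perm <- sample(96)
  m1 <- refit_exposures(mix, sigs)
  mixm <- matrix(mix[perm], ncol = 1,
                 dimnames = list(rownames(sigs)[perm], "sample1"))
  m2 <- refit_exposures(mixm, sigs[perm, ])
  expect_equal(m1$Signature.2, m2$Signature.2, tolerance = 1e-9)
})

test_that("carrier calls use a strict floor and recover pure signatures", {
  ex <- tibble::tibble(sample_id = c("a", "b", "c"), total_snvs = 100L,
                       eligible = TRUE, unexplained = 0,
                       Signature.1 = c(0, 0.06, 0.3),
                       Signature.2 = c(1, 0.94, 0.7))
  cc <- carrier_calls(ex)
  expect_equal(cc$carrier[cc$sample_id == "a" & cc$signature == "Signature.1"],
               FALSE)
  expect_equal(cc$carrier[cc$sample_id == "b" & cc$signature == "Signature.1"],
               FALSE)   # exactly 0.06 is not a carrier (strict)
  expect_equal(cc$carrier[cc$sample_id == "c" & cc$signature == "Signature.1"],
               TRUE)
  # pure-signature simulation: carrier only for the true signature
  pure <- generate_mutation_catalog(c(0, 1, rep(0, 11)), 2000, sigs, seed = 47)
  cp <- carrier_calls(refit_exposures(pure, sigs))
  expect_true(cp$carrier[cp$signature == "Signature.2"])
  expect_lte(sum(cp$carrier), 2)   # at most one spurious co-carrier
})

test_that("carrier-fraction comparison handles nulls and degenerate groups", {
  fr <- tidyr::expand_grid(dataset = c("d1", "d2", "d3", "d4"),
                           signature = "Signature.1")
  fr$population <- rep(c("P1", "P2"), each = 2)
  fr$fraction <- c(0.5, 0.5, 0.5, 0.5)
  out <- compare_carrier_fractions(fr)
  expect_equal(out$p, 1)               # identical vectors: p = 1
  fr$fraction <- c(0.5, 0.5, 0.9, 0.9) # zero variance, different means
  expect_true(is.na(compare_carrier_fractions(fr)$p))
  expect_equal(compare_carrier_fractions(fr)$flag,
               "degenerate_or_too_few_datasets")
  fr2 <- fr[-1, ]                      # one dataset in P1
  expect_true(is.na(compare_carrier_fractions(fr2)$p))
})

test_that("quartile test detects monotone association and stays calibrated", {
  set.seed(48)
  n <- 80
  ex <- tibble::tibble(sample_id = sprintf("S%03d", 1:n), total_snvs = 100L,
                       eligible = TRUE, unexplained = 0,
                       Signature.1 = runif(n), Signature.3 = runif(n))
  sc <- tibble::tibble(sample_id = ex$sample_id,
                       score = ex$Signature.1 + rnorm(n, 0, 1e-6))
  res <- quartile_signature_test(ex, sc)
  expect_lt(res$p[res$signature == "Signature.1"], 1e-4)
  # independent signature: null p not extreme on average over replicates
  ps <- replicate(50, {
    ex$Signature.3 <- runif(n)
    quartile_signature_test(ex, sc)$p[2]
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_error(quartile_signature_test(ex[1:5, ], sc), "8")
})

test_that("signature-immune Spearman correlations hit the closed cases", {
  n <- 40
  ex <- tibble::tibble(sample_id = sprintf("S%03d", 1:n), total_snvs = 100L,
                       eligible = TRUE, unexplained = 0,
                       Signature.1 = seq_len(n) / n)
  sc <- dplyr::bind_rows(
    tibble::tibble(sample_id = ex$sample_id, score_name = "same",
                   score = ex$Signature.1),
    tibble::tibble(sample_id = ex$sample_id, score_name = "anti",
                   score = -ex$Signature.1),
    tibble::tibble(sample_id = ex$sample_id, score_name = "const",
                   score = 1))
  res <- signature_immune_correlation(ex, sc)
  expect_equal(res$rho[res$score_name == "same"], 1)
  expect_equal(res$rho[res$score_name == "anti"], -1)
  expect_true(is.na(res$rho[res$score_name == "const"]))
})
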