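# one fully-valid record to perturb in boundary tests
valid_record <- function(...) {
  base <- tibble::tibble(
    sample_id = "S1", chrom = "1", pos = 100L, ref = "C", alt = "T",
    variant_type = "SNV", gene = "G1", consequence = "missense",
    protein_pos = 10L, t_depth = 80L, n_depth = 40L, alt_fwd = 10L,
    alt_rev = 10L, ref_fwd = 30L, ref_rev = 30L, vaf = 20 / 80,
    oxog_metric = 0.2, s_af = 0.9, gnomad_af = 0, in_cosmic = FALSE,
    in_str = FALSE, second_caller = TRUE)
  dplyr::mutate(base, ...)
}

test_that("panel of normals keeps exactly sites seen in >= 2 normals", {
  calls <- tibble::tibble(
    normal_sample_id = c("N1", "N1", "N2", "N3", "N3"),
    chrom = c("1", "2", "2", "2", "3"),
    pos = c(10L, 20L, 20L, 20L, 30L),
    alt = c("A", "T", "T", "T", "G"))
  pon <- build_panel_of_normals(calls)
  expect_equal(nrow(pon), 1)          # chr2:20 seen in N1, N2, N3
  expect_equal(pon$n_normals, 3L)
  expect_equal(pon$chrom, "2")
  # single-normal sites excluded; empty input gives empty panel
  expect_false("1" %in% pon$chrom)
  expect_equal(nrow(build_panel_of_normals(calls[0, ])), 0)
})

test_that("strand bias p matches enumeration oracle and conventions", {
  expect_equal(strand_bias_p(5, 5, 50, 50), 1.0)
  expect_equal(strand_bias_p(0, 0, 0, 0), 1.0)
  expect_equal(strand_bias_p(10, 0, 0, 10), oracle_fisher_p(10, 0, 0, 10),
               tolerance = 1e-12)
  # random tables agree with the enumeration oracle
  set.seed(42)
  for (i in 1:25) {
    cnt <- rpois(4, c(5, 5, 40, 40))
    expect_equal(strand_bias_p(cnt[1], cnt[2], cnt[3], cnt[4]),
                 oracle_fisher_p(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-10)
  }
})

test_that("each cascade rule rejects exactly at its boundary", {
  cases <- list(
    list(rec = valid_record(t_depth = 9L), rule = "min_t_depth"),
    list(rec = valid_record(n_depth = 4L), rule = "min_n_depth"),
    list(rec = valid_record(oxog_metric = 0.8), rule = "max_oxog"),
    list(rec = valid_record(alt_fwd = 3L, alt_rev = 2L, vaf = 5 / 80),
         rule = "min_vaf"),
    list(rec = valid_record(alt_fwd = 20L, alt_rev = 0L, vaf = 20 / 80),
         rule = "strand_bias"),
    list(rec = valid_record(s_af = 0.75), rule = "min_s_af"),
    list(rec = valid_record(gnomad_af = 0.01), rule = "max_gnomad"),
    list(rec = valid_record(alt_fwd = 2L, alt_rev = 1L, vaf = 3 / 80),
         rule = "min_alt_reads"),
    list(rec = valid_record(alt_fwd = 19L, alt_rev = 1L, vaf = 20 / 80),
         rule = "min_alt_per_strand"),
    list(rec = valid_record(variant_type = "indel", second_caller = FALSE),
         rule = "indel_second_caller"))
  for (cs in cases) {
    res <- apply_snv_filters(cs$rec)
    expect_equal(nrow(res$retained), 0)
    failed <- res$audit$rule[!res$audit$pass]
    expect_true(cs$rule %in% failed,
                label = sprintf("rule %s among failures", cs$rule))
  }
})

test_that("inclusive and exclusive bounds follow the stated wording", {
  # VAF exactly 0.075 is retained ("0.075 or more")
  r <- valid_record(t_depth = 80L, alt_fwd = 3L, alt_rev = 3L, vaf = 6 / 80)
  expect_equal(nrow(apply_snv_filters(r)$retained), 1)
  # oxog exactly 0.8 rejected (strict "<0.8"); just below retained
  expect_equal(nrow(apply_snv_filters(valid_record(oxog_metric = 0.799))$retained), 1)
  expect_equal(nrow(apply_snv_filters(valid_record(oxog_metric = 0.8))$retained), 0)
  # s_af exactly 0.75 rejected (strict "> 0.75")
  expect_equal(nrow(apply_snv_filters(valid_record(s_af = 0.7501))$retained), 1)
  # gnomad exactly 0.01 removed ("at least 0.01"), just below kept
  expect_equal(nrow(apply_snv_filters(valid_record(gnomad_af = 0.0099))$retained), 1)
  # depth exactly 10 kept, alt reads exactly 4 (2+2) kept
  r2 <- valid_record(t_depth = 10L, n_depth = 5L, alt_fwd = 2L,
                     alt_rev = 2L, ref_fwd = 3L, ref_rev = 3L, vaf = 0.4)
  expect_equal(nrow(apply_snv_filters(r2)$retained), 1)
})

test_that("PoN membership and whitelist override behave as specified", {
  r <- valid_record()
  pon <- tibble::tibble(chrom = "1", pos = 100L, alt = "T", n_normals = 2L)
  expect_equal(nrow(apply_snv_filters(r, pon = pon)$retained), 0)
  # whitelist rescues an otherwise-failing record (manual salvage mechanism)
  bad <- valid_record(t_depth = 9L)
  wl <- tibble::tibble(chrom = "1", pos = 100L, alt = "T")
  expect_equal(nrow(apply_snv_filters(bad, whitelist = wl)$retained), 1)
})

test_that("records with missing fields are excluded and the run continues", {
  recs <- dplyr::bind_rows(valid_record(), valid_record(pos = 200L))
  recs$s_af[2] <- NA
  expect_warning(res <- apply_snv_filters(recs), "missing fields")
  expect_equal(nrow(res$retained), 1)
  expect_equal(res$retained$pos, 100L)
})

test_that("recurrence filter removes recurrent non-COSMIC positions only", {
  mk <- function(pos, samples, cosmic) {
    tibble::tibble(sample_id = samples, chrom = "7", pos = pos,
                   in_cosmic = cosmic)
  }
  maf <- dplyr::bind_rows(
    mk(1000L, sprintf("S%d", 1:5), FALSE),   # recurrent, not COSMIC: drop
    mk(2000L, sprintf("S%d", 1:5), TRUE),    # recurrent, COSMIC: keep
    mk(3000L, sprintf("S%d", 1:4), FALSE))   # below threshold: keep
  suppressMessages(out <- recurrence_filter(maf))
  expect_equal(sort(unique(out$pos)), c(2000L, 3000L))
  removed <- attr(out, "removed_positions")
  expect_equal(removed$pos, 1000L)
  expect_equal(removed$n_samples, 5L)
})

test_that("cascade verdicts are order-independent and monotone in thresholds", {
  rec <- generate_variant_records(150, 150, seed = 11)
  res1 <- apply_snv_filters(rec)
  shuffled <- rec[sample(nrow(rec)), ]
  res2 <- apply_snv_filters(shuffled)
  key <- function(d) sort(paste(d$sample_id, d$chrom, d$pos, d$alt))
  expect_equal(key(res1$retained), key(res2$retained))
  # tightening any threshold never increases the retained count
  n0 <- nrow(res1$retained)
  tighter <- list(filter_config(min_t_depth = 20),
                  filter_config(min_vaf = 0.2),
                  filter_config(min_alt_reads = 8),
                  filter_config(max_oxog = 0.3),
                  filter_config(min_s_af = 0.9))
  for (cfg in tighter) {
    expect_lte(nrow(apply_snv_filters(rec, config = cfg)$retained), n0)
  }
})

test_that("generated truth is recovered: true records pass, artifacts fail", {
  rec <- generate_variant_records(400, 400, seed = 7)
  res <- apply_snv_filters(rec)
  suppressMessages(final <- recurrence_filter(res$retained))
  expect_equal(sum(final$is_somatic), 400)          # sensitivity 1.0
  expect_equal(sum(!final$is_somatic), 0)           # all artifacts rejected
  # low_vaf artifacts all sit strictly below the 0.075 bound
  lv <- generate_variant_records(0, 100, seed = 8,
                                 artifact_tags = "low_vaf")
  expect_true(all(lv$vaf < 0.075))
  # empty call
  expect_equal(nrow(generate_variant_records(0, 0)), 0)
})
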