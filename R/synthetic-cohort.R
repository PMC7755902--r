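#' Configuration for the two-cohort synthetic generator
#'
#' Defines the joint distribution the generator draws from: per-cohort
#' molecular-subtype prevalences, ER-positivity per subtype, TP53 mutation
#' rates conditional on cohort and ER status, a cohort-wide immune
#' infiltration shift on the expression scale, per-subtype Dirichlet priors
#' over the 13-signature catalogue, mutation burden, sequencing depth,
#' purity, and an exponential survival model with hazard ratios for TP53
#' carriers and immune-high patients.
#'
#' Defaults emulate the published two-population structure: an "IC5"-like
#' subtype at 13.1% in cohort A versus 7.9% in cohort B, TP53 enrichment in
#' ER+ cohort-A samples, a 0.5-sd immune shift in cohort A, a median of 45
#' somatic SNVs per sample at 75x depth.
#'
#' @param n_samples_per_cohort Samples per cohort.
#' @param subtype_prevalences Named list with elements `A` and `B`, each a
#'   named probability vector over subtype labels summing to 1.
#' @param er_positive_rate Named vector: P(ER+) per subtype.
#' @param tp53_rate_er_pos,tp53_rate_er_neg Named vectors (`A`, `B`):
#'   P(TP53 mutation) per cohort within each ER stratum.
#' @param immune_shift Mean shift (sd units) of the latent immune
#'   infiltration factor in cohort A.
#' @param signature_exposure_priors Either a single positive 13-vector of
#'   Dirichlet parameters or a named list per subtype.
#' @param mean_mutations_per_sample Negative-binomial mean SNV burden.
#' @param depth_mean Mean tumour sequencing depth.
#' @param purity_range Length-2 interval in (0, 1].
#' @param survival_baseline_hazard Baseline exponential hazard (per year).
#' @param hazard_ratio_tp53 Hazard ratio for TP53-mutant patients.
#' @param hazard_ratio_immune_high Hazard ratio for immune-high patients.
#' @param follow_up_years Administrative censoring time (years).
#' @param seed Integer seed; identical seeds give identical bundles.
#' @return A validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_samples_per_cohort = 500,
                          subtype_prevalences = list(
                            A = c(IC5 = 0.131, IC4 = 0.091, IC8 = 0.140,
                                  IC3 = 0.120, IC10 = 0.090, Other = 0.428),
                            B = c(IC5 = 0.079, IC4 = 0.046, IC8 = 0.140,
                                  IC3 = 0.150, IC10 = 0.090, Other = 0.495)),
                          er_positive_rate = c(IC5 = 0.50, IC4 = 0.50,
                                               IC8 = 0.90, IC3 = 0.90,
                                               IC10 = 0.10, Other = 0.75),
                          tp53_rate_er_pos = c(A = 0.25, B = 0.15),
                          tp53_rate_er_neg = c(A = 0.60, B = 0.60),
                          immune_shift = 0.5,
                          signature_exposure_priors = c(8, 3, 3, 4, 1, 0.5,
                                                        0.5, 0.5, 0.5, 4,
                                                        0.5, 1, 0.5),
                          mean_mutations_per_sample = 45,
                          depth_mean = 75,
                          purity_range = c(0.3, 0.9),
                          survival_baseline_hazard = 0.04,
                          hazard_ratio_tp53 = 2.5,
                          hazard_ratio_immune_high = 0.45,
                          follow_up_years = 10,
                          seed = 17) {
  if (n_samples_per_cohort < 1) {
    cc_abort("`n_samples_per_cohort` must be positive",
             class = "cohortcompare_config_error")
  }
  if (!setequal(names(subtype_prevalences), c("A", "B"))) {
    cc_abort("`subtype_prevalences` must have elements \"A\" and \"B\"",
             class = "cohortcompare_config_error")
  }
  for (co in c("A", "B")) {
    assert_prob_vector(subtype_prevalences[[co]],
                       paste0("subtype_prevalences$", co))
  }
  if (!setequal(names(subtype_prevalences$A), names(subtype_prevalences$B))) {
    cc_abort("cohorts must share subtype labels",
             class = "cohortcompare_config_error")
  }
  assert_prob(er_positive_rate, "er_positive_rate")
  missing_er <- setdiff(names(subtype_prevalences$A), names(er_positive_rate))
  if (length(missing_er)) {
    cc_abort(sprintf("`er_positive_rate` missing subtype(s): %s",
                     paste(missing_er, collapse = ", ")),
             class = "cohortcompare_config_error")
  }
  assert_prob(tp53_rate_er_pos, "tp53_rate_er_pos")
  assert_prob(tp53_rate_er_neg, "tp53_rate_er_neg")
  if (is.list(signature_exposure_priors)) {
    lapply(signature_exposure_priors, function(a)
      stopifnot(length(a) == 13, all(a > 0)))
  } else {
    stopifnot(length(signature_exposure_priors) == 13,
              all(signature_exposure_priors > 0))
  }
  stopifnot(length(purity_range) == 2, purity_range[1] > 0,
            purity_range[2] <= 1, purity_range[1] <= purity_range[2],
            mean_mutations_per_sample > 0, depth_mean > 0,
            survival_baseline_hazard > 0, hazard_ratio_tp53 > 0,
            hazard_ratio_immune_high > 0)
  structure(as.list(environment()), class = "cohort_config")
}

# Dirichlet draws via gamma normalisation
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  g / rowSums(g)
}

#' Default synthetic immune gene sets
#'
#' Three disjoint synthetic immune-cell gene sets (T cell, B cell, NK-like)
#' used by the expression generator and as inputs to the single-sample
#' enrichment scorer. Gene identifiers are synthetic placeholders.
#'
#' @param genes_per_set Number of genes per set.
#' @return Named list of character vectors.
#' @export
default_immune_gene_sets <- function(genes_per_set = 30) {
  ids <- sprintf("IMM%03d", seq_len(3 * genes_per_set))
  split(ids, rep(c("T_cells", "B_cells", "NK_cells"), each = genes_per_set))
}

# map 96-channel index -> ref, alt, trinucleotide context
.channel_decode <- function(channels) {
  ref <- substr(channels, 3, 3)
  alt <- substr(channels, 5, 5)
  ctx <- paste0(substr(channels, 1, 1), ref, substr(channels, 7, 7))
  tibble::tibble(channel = channels, ref = ref, alt = alt, context = ctx)
}

#' Simulate a 96-channel mutation catalogue from signature exposures
#'
#' Counts are multinomially sampled from the exposure-weighted mixture of
#' signature profiles.
#'
#' @param exposures Non-negative 13-vector summing to 1.
#' @param n_mutations Number of mutations to draw.
#' @param catalog 96 x 13 signature matrix
#'   (default [synthetic_signature_catalog()]).
#' @param seed Integer seed.
#' @return Named integer vector of 96 channel counts.
#' @export
generate_mutation_catalog <- function(exposures, n_mutations,
                                      catalog = synthetic_signature_catalog(),
                                      seed = 17) {
  if (any(exposures < 0) || abs(sum(exposures) - 1) > 1e-6) {
    cc_abort("`exposures` must be non-negative and sum to 1",
             class = "cohortcompare_config_error")
  }
  stopifnot(n_mutations >= 0)
  probs <- as.vector(catalog %*% exposures)
  set.seed(seed)
  counts <- if (n_mutations == 0) rep(0L, 96) else
    as.integer(stats::rmultinom(1, n_mutations, probs))
  setNames(counts, rownames(catalog))
}

#' Simulate clonal variant read counts
#'
#' Variants are assigned to clones by `clone_weights`; the expected VAF of
#' a clone with cancer cell fraction `ccf` is
#' `ccf * m * purity / (purity * cn_total + (1 - purity) * 2)` with
#' multiplicity `m = 1` unless configured, and alternate read counts are
#' binomially sampled at the given depth.
#'
#' @param clone_ccfs Clone cancer cell fractions in (0, 1].
#' @param clone_weights Probability vector over clones.
#' @param purity Tumour purity in (0, 1].
#' @param cn_total Total copy number at the loci (>= 1).
#' @param depth Read depth per variant.
#' @param n_variants Number of variants.
#' @param seed Integer seed.
#' @param multiplicity Mutated copies per cell (default 1).
#' @return Tibble: `alt_count`, `depth`, `clone`, `true_ccf`, `expected_vaf`.
#' @export
generate_clonal_vafs <- function(clone_ccfs, clone_weights, purity, cn_total,
                                 depth, n_variants, seed = 17,
                                 multiplicity = 1) {
  stopifnot(purity > 0, purity <= 1, cn_total >= 1, depth >= 1,
            all(clone_ccfs > 0), all(clone_ccfs <= 1))
  assert_prob_vector(clone_weights, "clone_weights", tol = 1e-9)
  evaf <- clone_ccfs * multiplicity * purity /
    (purity * cn_total + (1 - purity) * 2)
  if (any(evaf > 1)) {
    cc_abort("configured expected VAF exceeds 1",
             class = "cohortcompare_config_error")
  }
  set.seed(seed)
  clone <- sample.int(length(clone_ccfs), n_variants, replace = TRUE,
                      prob = clone_weights)
  tibble::tibble(
    alt_count = stats::rbinom(n_variants, depth, evaf[clone]),
    depth = as.integer(depth),
    clone = clone,
    true_ccf = clone_ccfs[clone],
    expected_vaf = evaf[clone]
  )
}

# one valid passing record template, vectorised over n
.true_record_fields <- function(n, depth_mean) {
  t_depth <- 10L + stats::rpois(n, max(depth_mean - 10, 1))
  vaf_target <- stats::runif(n, 0.15, 0.5)
  alt <- pmax(4L, as.integer(ceiling(0.075 * t_depth)),
              as.integer(round(vaf_target * t_depth)))
  alt <- pmin(alt, t_depth)
  ref <- t_depth - alt
  tibble::tibble(
    t_depth = t_depth,
    n_depth = 5L + stats::rpois(n, 35),
    alt_fwd = as.integer(ceiling(alt / 2)),
    alt_rev = as.integer(floor(alt / 2)),
    ref_fwd = as.integer(ceiling(ref / 2)),
    ref_rev = as.integer(floor(ref / 2)),
    vaf = alt / t_depth,
    oxog_metric = stats::runif(n, 0, 0.7),
    s_af = stats::runif(n, 0.8, 1),
    gnomad_af = ifelse(stats::runif(n) < 0.9, 0, stats::runif(n, 0, 0.009)),
    in_cosmic = stats::runif(n) < 0.15,
    in_str = FALSE,
    second_caller = TRUE
  )
}

.artifact_tags <- c("low_t_depth", "low_n_depth", "high_oxog", "low_vaf",
                    "strand_bias", "low_s_af", "high_gnomad", "few_alt_reads",
                    "single_strand", "indel_single_caller",
                    "recurrent_position")

#' Simulate variant call records with truth labels
#'
#' True somatic records are constructed to pass the full filter cascade;
#' artifact records each violate at least one named rule (the injected
#' violation is recorded in `violation`). The `"recurrent_position"` tag
#' produces groups of five or more otherwise-valid records sharing a
#' non-COSMIC position, which only the cohort recurrence stage removes.
#'
#' @param n_true,n_artifact Record counts (>= 0).
#' @param depth_mean Mean tumour depth.
#' @param seed Integer seed.
#' @param artifact_tags Tags to draw artifact violations from (default: all
#'   of `low_t_depth`, `low_n_depth`, `high_oxog`, `low_vaf`, `strand_bias`,
#'   `low_s_af`, `high_gnomad`, `few_alt_reads`, `single_strand`,
#'   `indel_single_caller`, `recurrent_position`).
#' @return Tibble of variant call records with `is_somatic` and `violation`
#'   truth columns.
#' @export
generate_variant_records <- function(n_true, n_artifact, depth_mean = 75,
                                     seed = 17,
                                     artifact_tags = .artifact_tags) {
  stopifnot(n_true >= 0, n_artifact >= 0)
  bad_tags <- setdiff(artifact_tags, .artifact_tags)
  if (length(bad_tags)) {
    cc_abort(sprintf("unknown artifact tag(s): %s",
                     paste(bad_tags, collapse = ", ")))
  }
  set.seed(seed)
  n <- n_true + n_artifact
  if (n == 0) {
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          pos = integer(), ref = character(),
                          alt = character(), variant_type = character(),
                          gene = character(), consequence = character(),
                          protein_pos = integer(), t_depth = integer(),
                          n_depth = integer(), alt_fwd = integer(),
                          alt_rev = integer(), ref_fwd = integer(),
                          ref_rev = integer(), vaf = double(),
                          oxog_metric = double(), s_af = double(),
                          gnomad_af = double(), in_cosmic = logical(),
                          in_str = logical(), second_caller = logical(),
                          is_somatic = logical(), violation = character()))
  }

  base <- .true_record_fields(n, depth_mean)
  bases <- c("A", "C", "G", "T")
  ref_nt <- sample(bases, n, replace = TRUE)
  alt_nt <- vapply(ref_nt, function(r) sample(setdiff(bases, r), 1), "")
  rec <- dplyr::bind_cols(
    tibble::tibble(
      sample_id = sprintf("S%04d", sample.int(5000, n, replace = TRUE)),
      chrom = as.character(sample.int(22, n, replace = TRUE)),
      pos = sample.int(2^28, n),          # unique: never recurrent by chance
      ref = ref_nt, alt = alt_nt,
      variant_type = ifelse(stats::runif(n) < 0.05, "indel", "SNV"),
      gene = sprintf("GENE%03d", sample.int(300, n, replace = TRUE)),
      consequence = sample(c("missense", "nonsense", "frameshift", "splice",
                             "inframe"), n, replace = TRUE,
                           prob = c(0.75, 0.1, 0.08, 0.05, 0.02)),
      protein_pos = sample.int(1000, n, replace = TRUE)
    ),
    base)
  rec$is_somatic <- rep(c(TRUE, FALSE), c(n_true, n_artifact))
  rec$violation <- NA_character_

  if (n_artifact > 0) {
    idx <- which(!rec$is_somatic)
    tag <- sample(artifact_tags, n_artifact, replace = TRUE)
    rec$violation[idx] <- tag
    for (i in seq_along(idx)) {
      j <- idx[i]
      switch(tag[i],
        low_t_depth = {
          td <- sample(1:9, 1)
          a <- min(td, 4L)
          rec$t_depth[j] <- td
          rec$alt_fwd[j] <- as.integer(ceiling(a / 2))
          rec$alt_rev[j] <- as.integer(floor(a / 2))
          rec$ref_fwd[j] <- as.integer(ceiling((td - a) / 2))
          rec$ref_rev[j] <- as.integer(floor((td - a) / 2))
          rec$vaf[j] <- a / td
        },
        low_n_depth = rec$n_depth[j] <- sample(0:4, 1),
        high_oxog = rec$oxog_metric[j] <- stats::runif(1, 0.8, 1),
        low_vaf = {
          td <- rec$t_depth[j]
          a <- max(1L, as.integer(floor(0.074 * td)))
          while (a / td >= 0.075) a <- a - 1L
          rec$alt_fwd[j] <- as.integer(ceiling(a / 2))
          rec$alt_rev[j] <- as.integer(floor(a / 2))
          rec$ref_fwd[j] <- as.integer(ceiling((td - a) / 2))
          rec$ref_rev[j] <- as.integer(floor((td - a) / 2))
          rec$vaf[j] <- a / td
        },
        strand_bias = {
          td <- rec$t_depth[j]
          a <- min(12L, td)
          rec$alt_fwd[j] <- a; rec$alt_rev[j] <- 0L
          rec$ref_fwd[j] <- as.integer(ceiling((td - a) / 2))
          rec$ref_rev[j] <- as.integer(floor((td - a) / 2))
          rec$vaf[j] <- a / td
        },
        low_s_af = rec$s_af[j] <- stats::runif(1, 0.2, 0.75),
        high_gnomad = rec$gnomad_af[j] <- stats::runif(1, 0.01, 0.5),
        few_alt_reads = {
          td <- rec$t_depth[j]
          a <- sample(2:3, 1)
          rec$alt_fwd[j] <- a - 1L; rec$alt_rev[j] <- 1L
          rec$ref_fwd[j] <- as.integer(ceiling((td - a) / 2))
          rec$ref_rev[j] <- as.integer(floor((td - a) / 2))
          rec$vaf[j] <- a / td
        },
        single_strand = {
          td <- rec$t_depth[j]
          rec$alt_fwd[j] <- 5L; rec$alt_rev[j] <- 1L
          rec$ref_fwd[j] <- as.integer(ceiling((td - 6L) / 2))
          rec$ref_rev[j] <- as.integer(floor((td - 6L) / 2))
          rec$vaf[j] <- 6 / td
        },
        indel_single_caller = {
          rec$variant_type[j] <- "indel"
          rec$second_caller[j] <- FALSE
        },
        recurrent_position = NULL   # handled as groups below
      )
    }
    # recurrent_position: regroup those records into shared positions,
    # >= 5 distinct samples each, not in COSMIC, otherwise valid
    ridx <- idx[tag == "recurrent_position"]
    if (length(ridx)) {
      n_groups <- max(1L, length(ridx) %/% 5L)
      grp <- rep(seq_len(n_groups), length.out = length(ridx))
      for (g in seq_len(n_groups)) {
        gi <- ridx[grp == g]
        if (length(gi) < 5) {        # too few for recurrence: re-tag
          rec$violation[gi] <- "high_gnomad"
          rec$gnomad_af[gi] <- stats::runif(length(gi), 0.01, 0.5)
          next
        }
        rec$chrom[gi] <- rec$chrom[gi[1]]
        rec$pos[gi] <- rec$pos[gi[1]]
        rec$ref[gi] <- rec$ref[gi[1]]
        rec$alt[gi] <- rec$alt[gi[1]]
        rec$sample_id[gi] <- sprintf("S%04d_r%d_%d", g, g, seq_along(gi))
        rec$in_cosmic[gi] <- FALSE
      }
    }
  }
  rec
}

#' Simulate a gene-by-sample expression matrix
#'
#' Log2-scale Gaussian background per gene; genes in the immune sets share
#' a per-sample latent infiltration factor whose mean is `immune_shift`
#' higher in cohort A; ESR1 is drawn from the mixture component matching
#' each sample's true ER label. Returned in TPM-like positive units with a
#' matching Poisson pseudo-count matrix.
#'
#' @param cohort_table Tibble with `patient_id`, `cohort`, `er_truth`
#'   (`"pos"`/`"neg"`), and optionally `immune_latent` (reused when
#'   present so expression agrees with survival truth).
#' @param immune_gene_sets Named list of disjoint gene sets (must not
#'   contain `"ESR1"`).
#' @param immune_shift Cohort-A mean shift of the latent immune factor.
#' @param esr1_params List with `means` and `sds`, each length-2 `(neg,
#'   pos)` on the log2 scale.
#' @param seed Integer seed.
#' @param n_background_genes Number of non-immune background genes.
#' @return List with `tpm` and `counts` (genes x samples matrices) and
#'   `immune_latent` (named per-sample vector).
#' @export
generate_expression <- function(cohort_table,
                                immune_gene_sets = default_immune_gene_sets(),
                                immune_shift = 0.5,
                                esr1_params = list(means = c(neg = 1, pos = 5),
                                                   sds = c(neg = 0.7, pos = 0.7)),
                                seed = 17, n_background_genes = 400) {
  assert_cols(cohort_table, c("patient_id", "cohort", "er_truth"))
  imm_genes <- unlist(immune_gene_sets, use.names = FALSE)
  if (!length(imm_genes) || anyDuplicated(imm_genes) || "ESR1" %in% imm_genes) {
    cc_abort("immune gene sets must be non-empty, disjoint and exclude ESR1")
  }
  set.seed(seed)
  samples <- cohort_table$patient_id
  ns <- length(samples)
  bg_genes <- sprintf("BG%04d", seq_len(n_background_genes))
  genes <- c(bg_genes, imm_genes, "ESR1")

  latent <- if ("immune_latent" %in% names(cohort_table)) {
    cohort_table$immune_latent
  } else {
    stats::rnorm(ns, ifelse(cohort_table$cohort == "A", immune_shift, 0), 1)
  }
  baseline <- stats::runif(length(genes), 2, 8)
  logx <- matrix(stats::rnorm(length(genes) * ns, 0, 1),
                 nrow = length(genes),
                 dimnames = list(genes, samples)) + baseline
  logx[imm_genes, ] <- sweep(logx[imm_genes, , drop = FALSE], 2, latent, `+`)
  er_i <- ifelse(cohort_table$er_truth == "pos", 2L, 1L)
  logx["ESR1", ] <- stats::rnorm(ns, esr1_params$means[er_i],
                                 esr1_params$sds[er_i])
  tpm <- 2^logx
  counts <- matrix(stats::rpois(length(tpm), lambda = tpm),
                   nrow = nrow(tpm), dimnames = dimnames(tpm))
  list(tpm = tpm, counts = counts,
       immune_latent = setNames(latent, samples))
}

# whole-cohort somatic mutation records with clonal VAF structure and
# driver-gene lesions, vectorised across samples; channels drawn from the
# exposure-weighted catalogue by inverse-CDF sampling
.cohort_mutations <- function(sample_ids, n_mut, exposures, catalog,
                              purity, depth_mean, tp53_mutant) {
  N <- length(sample_ids)
  M <- sum(n_mut)
  idx <- rep.int(seq_len(N), n_mut)

  # per-mutation signature, then channel within the signature
  ecum <- t(apply(exposures, 1, cumsum))
  sig <- 1L + as.integer(rowSums(stats::runif(M) > ecum[idx, , drop = FALSE]))
  sig[sig > ncol(exposures)] <- ncol(exposures)
  ccum <- t(apply(catalog, 2, cumsum))
  ch <- 1L + as.integer(rowSums(stats::runif(M) > ccum[sig, , drop = FALSE]))
  ch[ch > 96L] <- 96L

  # clone architecture per sample: 1-3 clones, truncal clone at CCF 1
  k <- sample(1:3, N, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  extra <- matrix(stats::runif(2 * N, 0.2, 0.7), N, 2)
  ccf_mat <- cbind(1, pmax(extra[, 1], extra[, 2]),
                   pmin(extra[, 1], extra[, 2]))
  w <- rdirichlet(N, rep(2, 3))
  w[k < 3, 3] <- 0
  w[k < 2, 2] <- 0
  w <- w / rowSums(w)
  wcum <- t(apply(w, 1, cumsum))
  clone <- 1L + as.integer(rowSums(stats::runif(M) > wcum[idx, , drop = FALSE]))
  clone[clone > 3L] <- 3L
  ccf <- ccf_mat[cbind(idx, clone)]

  dp <- pmax(10L, stats::rpois(M, depth_mean))
  altc <- pmax(1L, stats::rbinom(M, dp, pmin(1, ccf * purity[idx] / 2)))
  cons <- sample(c("missense", "nonsense", "frameshift", "splice", "inframe"),
                 M, replace = TRUE, prob = c(0.75, 0.1, 0.08, 0.05, 0.02))
  gene <- sprintf("GENE%03d", sample.int(250, M, replace = TRUE))
  ppos <- sample.int(800, M, replace = TRUE)

  # driver lesions overwrite the first free slot of each carrier's block,
  # so the per-sample burden stays n_mut; drivers are truncal
  start <- cumsum(c(0L, n_mut[-N]))
  slot_used <- integer(N)
  place <- function(sel, g, cs_pool, pp_max, hot = NULL) {
    sel <- sel & (slot_used < n_mut)
    n <- sum(sel)
    if (n == 0) return(invisible())
    rows <- start[sel] + slot_used[sel] + 1L
    gene[rows] <<- g
    cons[rows] <<- sample(cs_pool, n, replace = TRUE)
    ppos[rows] <<- if (is.null(hot)) sample.int(pp_max, n, replace = TRUE)
      else sample(hot, n, replace = TRUE)
    clone[rows] <<- 1L
    ccf[rows] <<- 1
    altc[rows] <<- pmax(1L, stats::rbinom(n, dp[rows],
                                          pmin(1, purity[sel] / 2)))
    slot_used[sel] <<- slot_used[sel] + 1L
    invisible()
  }
  hot53 <- tp53_mutant & stats::runif(N) < 0.6
  place(hot53, "TP53", "missense", NA, hot = c(175L, 248L, 273L))
  place(tp53_mutant & !hot53, "TP53", c("nonsense", "frameshift"), 390L)
  place(stats::runif(N) < 0.28, "PIK3CA", "missense", NA,
        hot = c(545L, 1047L))
  place(stats::runif(N) < 0.10, "GATA3", "frameshift", 440L)
  place(stats::runif(N) < 0.055, "MAP3K1", c("nonsense", "frameshift"), 1500L)
  place(stats::runif(N) < 0.04, "CDH1", c("nonsense", "frameshift"), 880L)

  d <- .channel_decode(rownames(catalog))[ch, ]
  tibble::tibble(
    sample_id = sample_ids[idx],
    gene = gene,
    chrom = as.character(sample.int(22, M, replace = TRUE)),
    pos = sample.int(2^28, M),
    ref = d$ref, alt = d$alt, context = d$context,
    variant_type = "SNV",
    consequence = cons,
    protein_pos = ppos,
    t_depth = dp,
    alt_count = altc,
    vaf = altc / dp,
    n_depth = 5L + stats::rpois(M, 35),
    alt_fwd = as.integer(ceiling(altc / 2)),
    alt_rev = as.integer(floor(altc / 2)),
    ref_fwd = as.integer(ceiling((dp - altc) / 2)),
    ref_rev = as.integer(floor((dp - altc) / 2)),
    oxog_metric = stats::runif(M, 0, 0.7),
    s_af = stats::runif(M, 0.8, 1),
    gnomad_af = 0,
    in_cosmic = gene %in% c("TP53", "PIK3CA", "GATA3", "MAP3K1", "CDH1"),
    in_str = FALSE,
    second_caller = TRUE,
    true_clone = clone,
    true_ccf = ccf,
    cn_total = 2L
  )
}

#' Generate a two-cohort synthetic bundle
#'
#' Draws two cohorts labelled `"A"` and `"B"` with the configured subtype
#' prevalences, ER rates, TP53 rates, signature exposures, clonal VAF
#' structure, immune-shifted expression and exponential survival with
#' administrative censoring, plus full ground truth.
#'
#' @param config A [cohort_config()].
#' @return List with `cohort` (clinical tibble), `mutations` (MAF-like
#'   tibble with truth columns), `expression` (list of `tpm`, `counts`),
#'   `purity` (tibble), `gene_sets`, `catalog`, and `truth` (per-sample
#'   truth tibble and `exposures` matrix).
#' @export
generate_cohorts <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  subtypes <- names(config$subtype_prevalences$A)
  n <- config$n_samples_per_cohort
  catalog <- synthetic_signature_catalog()

  per_cohort <- lapply(c("A", "B"), function(co) {
    prev <- config$subtype_prevalences[[co]]
    subtype <- sample(subtypes, n, replace = TRUE, prob = prev)
    er <- ifelse(stats::runif(n) < config$er_positive_rate[subtype],
                 "pos", "neg")
    tp53_rate <- ifelse(er == "pos", config$tp53_rate_er_pos[co],
                        config$tp53_rate_er_neg[co])
    tp53 <- stats::runif(n) < tp53_rate
    latent <- stats::rnorm(n, if (co == "A") config$immune_shift else 0, 1)
    age <- round(pmin(88, pmax(25,
      stats::rnorm(n, if (co == "A") 50 else 58, 11))))
    tibble::tibble(
      patient_id = sprintf("%s%04d", co, seq_len(n)),
      cohort = co, subtype = subtype, er_truth = er, age = age,
      tp53_truth = tp53, immune_latent = latent,
      purity = stats::runif(n, config$purity_range[1], config$purity_range[2])
    )
  })
  cohort <- dplyr::bind_rows(per_cohort)

  # survival: exponential with HRs for TP53 and immune-high (latent above
  # the pooled median), administrative censoring
  immune_high <- cohort$immune_latent > stats::median(cohort$immune_latent)
  hazard <- config$survival_baseline_hazard *
    config$hazard_ratio_tp53^cohort$tp53_truth *
    config$hazard_ratio_immune_high^immune_high
  t_event <- stats::rexp(nrow(cohort), hazard)
  cohort$immune_high_truth <- immune_high
  cohort$survival_time <- pmin(t_event, config$follow_up_years)
  cohort$event <- t_event <= config$follow_up_years
  cohort$follow_up_years <- cohort$survival_time
  cohort$er_status <- cohort$er_truth

  # per-sample signature exposures and mutation tables
  priors <- config$signature_exposure_priors
  alpha_for <- function(st) if (is.list(priors)) priors[[st]] else priors
  exposures <- t(vapply(cohort$subtype,
                        function(st) rdirichlet(1, alpha_for(st))[1, ],
                        numeric(13)))
  rownames(exposures) <- cohort$patient_id
  colnames(exposures) <- colnames(catalog)

  n_mut <- pmax(1L, stats::rnbinom(nrow(cohort), mu = config$mean_mutations_per_sample,
                                   size = 5))
  mutations <- .cohort_mutations(cohort$patient_id, n_mut, exposures,
                                 catalog, cohort$purity, config$depth_mean,
                                 cohort$tp53_truth)

  expression <- generate_expression(cohort,
                                    immune_gene_sets = default_immune_gene_sets(),
                                    immune_shift = config$immune_shift,
                                    seed = derive_seed(config$seed, 2))

  purity_tab <- cohort |>
    dplyr::transmute(sample_id = .data$patient_id, purity = .data$purity,
                     cn_total = 2L)

  list(
    cohort = cohort |>
      dplyr::select("patient_id", "cohort", "subtype", "age", "er_status",
                    "survival_time", "event", "follow_up_years"),
    mutations = mutations,
    expression = expression,
    purity = purity_tab,
    gene_sets = default_immune_gene_sets(),
    catalog = catalog,
    truth = list(samples = cohort, exposures = exposures)
  )
}
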