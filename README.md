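# cohortcompare

Tools for comparing the somatic, immune and clonal landscape of two
breast-cancer cohorts, built as a tested, reusable pipeline around the
analysis stages such studies chain together:

- **Variant post-filtering** — a somatic SNV/indel filter cascade with a
  panel of normals (sites in ≥ 2 normals), read-evidence rules (depth
  ≥ 10/5, OxoG < 0.8, VAF ≥ 0.075, strand Fisher p ≥ 0.05, S_AF > 0.75,
  gnomAD < 0.01, ≥ 4 alt reads with ≥ 2 per strand, second-caller
  confirmation for indels) and cohort-recurrence removal with COSMIC
  rescue, with a full per-record audit trail.
- **Driver scoring** — 20/20-style scores per gene and stratum:
  ONC = 100·(missense at the most recurrent codon)/(all mutations),
  TSG = 100·(nonsense + frameshift + splice)/(all mutations), each
  needing ≥ 5 qualifying mutations; candidates have either score > 20.
- **Mutual exclusivity** — pairwise Fisher exact tests and sample odds
  ratios over the top mutated genes, Bonferroni-filtered.
- **Signature refitting** — per-sample non-negative least-squares
  exposures over a 13-signature breast catalogue with the 0.06
  floor-and-renormalise convention, carrier calls, and the associated
  cohort and immune-score statistics.
- **Immune scoring** — a single-sample rank-enrichment (ssGSEA-form)
  engine, an IMPRES-style checkpoint-pair score (14 features, high at
  ≥ 9), and OLS covariate adjustment.
- **ER calling** — a two-component Gaussian mixture EM on ESR1
  expression, with `tidy()`/`glance()`/`autoplot()` methods.
- **Clonality** — multiplicity m = max(1, round(vaf/p·(p·CNt+(1−p)·2))),
  CCF = vaf·(p·CNt+(1−p)·2)/(p·m) capped at 1, MATH
  (100·1.4826·MAD/median of VAFs), and a BIC-selected binomial-mixture
  subclone counter.
- **Cohort statistics** — subtype prevalence with Pearson chi-square
  (no continuity correction), gene-by-ER comparisons, Kaplan–Meier,
  log-rank and Efron-tie Cox models.

Because the patient data such comparisons run on are controlled-access,
the package ships a **synthetic two-cohort generator** with full ground
truth (subtype prevalences, ER- and cohort-conditional TP53 rates, a
latent immune shift shared between expression and survival, Dirichlet
signature exposures, clonal VAFs, exponential survival). Every stage is
validated against that truth and against independent oracles.

All user-facing functions take data frames first and return tibbles, so
stages chain with the pipe.

## A worked example

```r
library(cohortcompare)

bundle <- generate_cohorts(cohort_config(n_samples_per_cohort = 500, seed = 5))
run_cohort_comparison(bundle)
#>   finding              effect_a effect_b        p direction_a_vs_b
#> 1 subtype_prevalence      0.108   0.078  1.02e- 1 higher
#> 2 tp53_er_pos             0.240   0.162  1.13e- 2 higher
#> 3 immune_scores          45.6    14.9    2.69e-18 higher
#> 4 survival_tp53_er_pos    0.828   0.910  1.39e- 5 worse
```

Reading the rows: the "IC5"-like subtype is more prevalent in cohort A
(10.8% vs 7.8% in this draw; the chi-square p of 0.10 reflects limited
power for this effect at n = 500/cohort), TP53 mutations are enriched in
cohort-A ER+ tumours (24.0% vs 16.2%, p = 0.011), immune enrichment
scores are higher in cohort A (ANOVA p ≈ 1e-18), and TP53-mutant ER+
patients have worse 5-year survival (82.8% vs 91.0%, log-rank
p ≈ 1e-5) — each effect matching the structure the generator planted.

Individual stages compose the same way:

```r
rec  <- generate_variant_records(n_true = 500, n_artifact = 500, seed = 1)
flt  <- apply_snv_filters(rec, pon = NULL, config = filter_config())
kept <- recurrence_filter(flt$retained)

spectra   <- tally_96(bundle$mutations)
exposures <- refit_exposures(spectra, synthetic_signature_catalog())
```

## Notes on reference data

The 13-signature catalogue and the IMPRES feature-pair table shipped
here are clearly-labelled synthetic stand-ins (the originals are not
redistributable); `read_signature_catalog()` and
`read_impres_features()` load the real files for production use.
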