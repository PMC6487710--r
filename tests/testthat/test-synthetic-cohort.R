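test_that("empty cohorts and invalid configurations are handled", {
  cfg <- cohort_config(n_patients = 0, seed = 1)
  expect_equal(nrow(sample_cohort(cfg)), 0L)
  expect_error(
    cohort_config(covariate_proportions = list(
      hr_status = c(positive = 0.5, negative = 0.4))),
    "hr_status")
})

test_that("cohort covariates match configured proportions and invariants", {
  cfg <- cohort_config(n_patients = 10000, seed = 11)
  cohort <- sample_cohort(cfg)
  # 3-standard-error binomial bounds per category (exact binomial oracle).
  for (cov in c("hr_status", "n_stage", "tnm_stage", "ki67_group")) {
    p <- cfg$covariate_proportions[[cov]]
    col <- cohort[[cov]]
    for (lv in names(p)) {
      se <- sqrt(p[[lv]] * (1 - p[[lv]]) / nrow(cohort))
      expect_lt(abs(mean(col == lv) - p[[lv]]), 3 * se + 1e-12)
    }
  }
  # Structural invariants.
  expect_true(all((cohort$m_stage == "M1") == (cohort$tnm_stage == "IV")))
  expect_true(all(cohort$tumor_purity > 0 & cohort$tumor_purity <= 1))
  luma <- cohort$subtype == "LuminalA"
  expect_true(all(cohort$hr_status[luma] == "positive" &
                    cohort$her2_ihc[luma] == "negative" &
                    cohort$ki67_group[luma] == "low"))
  expect_true(all(cohort$hr_status[cohort$subtype == "TNBC"] == "negative"))
  # Expected HR-positive count at the study's size (52 of 71).
  expect_equal(71 * cfg$covariate_proportions$hr_status[["positive"]], 52,
               tolerance = 1e-6)
})

test_that("cohort sampling is deterministic given config and seed", {
  cfg <- cohort_config(n_patients = 50, seed = 7)
  expect_identical(sample_cohort(cfg), sample_cohort(cfg))
  mut1 <- sample_cohort_mutations(sample_cohort(cfg), cfg, seed = 8)
  mut2 <- sample_cohort_mutations(sample_cohort(cfg), cfg, seed = 8)
  expect_identical(mut1, mut2)
})

test_that("mutation counts respect the configured law and bounds", {
  # Degenerate law: exactly one mutation, always clonal.
  cfg1 <- cohort_config(n_patients = 40,
                        mutation_count = list(size = 1, mu = 2.4,
                                              min = 1L, max = 1L),
                        seed = 2)
  mut <- sample_cohort_mutations(sample_cohort(cfg1), cfg1)
  expect_equal(nrow(mut), 40L)
  expect_true(all(mut$clonal_true))
  # Default law: counts within [1, 15] for any cohort.
  cfg2 <- cohort_config(n_patients = 3000, seed = 3)
  mut2 <- sample_cohort_mutations(sample_cohort(cfg2), cfg2)
  counts <- table(mut2$patient_id)
  expect_gte(min(counts), 1L)
  expect_lte(max(counts), 15L)
  expect_true(median(counts) %in% c(2, 2.5, 3))
})

test_that("gene prevalence follows the configured frequencies", {
  cfg <- cohort_config(n_patients = 10000, seed = 5)
  cohort <- sample_cohort(cfg)
  mut <- sample_cohort_mutations(cohort, cfg)
  # Closed-form oracle: P(>=1 TP53) = 1 - sum_k P(K = k) (1 - p)^k under the
  # truncated count law.
  mc <- cfg$mutation_count
  pk <- stats::dnbinom(mc$min:mc$max, size = mc$size, mu = mc$mu)
  pk <- pk / sum(pk)
  p_tp53 <- cfg$gene_frequencies[["TP53"]]
  expected <- 1 - sum(pk * (1 - p_tp53)^(mc$min:mc$max))
  observed <- mean(tapply(mut$gene == "TP53", mut$patient_id, any))
  se <- sqrt(expected * (1 - expected) / nrow(cohort))
  expect_lt(abs(observed - expected), 3 * se)
})

test_that("ground-truth clonality closes under the downstream CCF rule", {
  cfg <- cohort_config(n_patients = 200, seed = 13)
  cohort <- sample_cohort(cfg)
  mut <- sample_cohort_mutations(cohort, cfg)
  for (pid in unique(mut$patient_id)) {
    mv <- mut[mut$patient_id == pid, ]
    purity <- cohort$tumor_purity[cohort$patient_id == pid]
    ccf <- compute_ccf(mv$tumor_vaf_true, purity)
    expect_equal(classify_clonality(ccf) == "clonal", mv$clonal_true)
    expect_true(all(mv$ccf_true[mv$clonal_true] >=
                      0.75 * max(mv$ccf_true)))
  }
})

test_that("shedding probability follows the logistic contract", {
  p0 <- shedding_params(intercept = 0, coef_n_stage = 0,
                        coef_hr_negative = 0, coef_m1 = 0, clonal_boost = 1)
  pat <- data.frame(patient_id = "P1", n_stage = "N0",
                    hr_status = "positive", m_stage = "M0")
  mut <- data.frame(patient_id = "P1", clonal_true = FALSE)
  expect_equal(shedding_probability(pat, mut, p0), 0.5)
  # HR-negative raises the probability when its coefficient is positive.
  p1 <- shedding_params(coef_hr_negative = 1.2)
  pat_neg <- pat; pat_neg$hr_status <- "negative"
  expect_gt(shedding_probability(pat_neg, mut, p1),
            shedding_probability(pat, mut, p1))
  # Strictly increasing in ordinal N stage.
  probs <- vapply(c("N0", "N1", "N2", "N3"), function(ns) {
    p <- pat; p$n_stage <- ns
    shedding_probability(p, mut, shedding_params())
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
  # Clonal boost multiplies the odds.
  mutc <- mut; mutc$clonal_true <- TRUE
  sp <- shedding_params(clonal_boost = 4)
  odds <- function(p) p / (1 - p)
  expect_equal(odds(shedding_probability(pat, mutc, sp)) /
                 odds(shedding_probability(pat, mut, sp)), 4,
               tolerance = 1e-9)
})

test_that("plasma simulation honours null and saturated shedding channels", {
  base <- cohort_config(n_patients = 25, seed = 21)
  cohort <- sample_cohort(base)
  mut <- sample_cohort_mutations(cohort, base)
  # Null channel: no shedding, no hematopoietic mutations.
  off <- cohort_config(
    n_patients = 25, seed = 21,
    shedding = shedding_params(intercept = -50, clonal_boost = 1),
    hematopoietic = list(rate = 0, genes = c(DNMT3A = 1),
                         vaf_range = c(0.005, 0.03)))
  expect_equal(nrow(simulate_cohort_plasma(cohort, mut, off, seed = 1)), 0L)
  # Saturated channel at high VAF: every tumor mutation reaches plasma.
  on <- cohort_config(
    n_patients = 25, seed = 21,
    shedding = shedding_params(intercept = 50, clonal_boost = 1,
                               vaf_scale_by_stage = c(I = 0.5, II = 0.5,
                                                      III = 0.5, IV = 0.5)),
    hematopoietic = list(rate = 0, genes = c(DNMT3A = 1),
                         vaf_range = c(0.005, 0.03)),
    purity_range = c(0.8, 0.9))
  mut_hi <- sample_cohort_mutations(cohort, on)
  plasma <- simulate_cohort_plasma(cohort, mut_hi, on, seed = 2)
  expect_equal(nrow(plasma), nrow(mut_hi))
  expect_true(all(plasma$origin == "tumor"))
})

test_that("hematopoietic channel rate matches its binomial expectation", {
  cfg <- cohort_config(
    n_patients = 1000, seed = 31,
    shedding = shedding_params(intercept = -50, clonal_boost = 1))
  cohort <- sample_cohort(cfg)
  mut <- sample_cohort_mutations(cohort, cfg)
  plasma <- simulate_cohort_plasma(cohort, mut, cfg, seed = 32)
  expect_true(all(plasma$origin == "hematopoietic"))
  expect_true(all(plasma$gene %in% c("DNMT3A", "JAK2", "TET2")))
  rate <- cfg$hematopoietic$rate
  se <- sqrt(rate * (1 - rate) / 1000)
  expect_lt(abs(length(unique(plasma$patient_id)) / 1000 - rate), 3 * se)
})
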