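test_that("chi-squared test matches hand computation and handles edge cases", {
  # PIK3CA-by-HR-style 2x2 table.
  tab <- matrix(c(25, 27, 3, 16), nrow = 2, byrow = TRUE)
  res <- chi_square(tab)
  expect_equal(res$statistic, 6.0737, tolerance = 1e-4)
  expect_equal(res$df, 1)
  expect_equal(round(res$p_value, 3), 0.014)
  expect_equal(res$p_value, 0.0137206, tolerance = 1e-6)
  # Identical row distributions: independence exactly.
  flat <- chi_square(matrix(c(10, 20, 10, 20), nrow = 2, byrow = TRUE))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_error(chi_square(matrix(c(1, 2), nrow = 1)), "2x2")
  expect_error(chi_square(matrix(c(0, 0, 3, 4), nrow = 2, byrow = TRUE)),
               "zero marginal")
})

test_that("chi-squared p approximates a fixed-margin permutation null", {
  # Monte-Carlo oracle: random tables with the observed margins via
  # r2dtable; the asymptotic p should sit near the exact conditional p for
  # moderate tables.
  set.seed(12)
  tabs <- list(matrix(c(8, 5, 7, 4, 9, 6), nrow = 2, byrow = TRUE),
               matrix(c(10, 3, 5, 4, 8, 7), nrow = 2, byrow = TRUE))
  for (tab in tabs) {
    res <- chi_square(tab)
    sim <- stats::r2dtable(20000, rowSums(tab), colSums(tab))
    stat_of <- function(m) {
      e <- outer(rowSums(m), colSums(m)) / sum(m)
      sum((m - e)^2 / e)
    }
    p_perm <- mean(vapply(sim, stat_of, numeric(1)) >= res$statistic - 1e-9)
    expect_lt(abs(res$p_value - p_perm), 0.05)
  }
})

test_that("confusion metrics reproduce the ERBB2-style fixtures", {
  tissue <- confusion_metrics(tp = 26, fp = 3, fn = 2, tn = 38)
  expect_equal(round(100 * tissue$overall_consistency, 2), 92.75)
  ctdna <- confusion_metrics(tp = 6, fp = 0, fn = 22, tn = 41)
  expect_equal(round(100 * ctdna$overall_consistency, 2), 68.12)
  expect_equal(ctdna$ppv, 1)
  expect_equal(round(100 * ctdna$npv, 2), 65.08)
  perfect <- confusion_metrics(tp = 5, fp = 0, fn = 0, tn = 9)
  expect_equal(perfect$overall_consistency, 1)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)
  # Zero denominators are flagged, not zeroed.
  noneg <- confusion_metrics(tp = 4, fp = 2, fn = 0, tn = 0)
  expect_true(is.na(noneg$npv))
  expect_true("npv" %in% noneg$undefined)
  # Identities hold.
  m <- confusion_metrics(7, 3, 2, 11)
  expect_equal(m$overall_consistency, (7 + 11) / 23)
  for (f in c("ppv", "npv", "sensitivity", "specificity")) {
    expect_gte(m[[f]], 0); expect_lte(m[[f]], 1)
  }
})

test_that("gene frequencies count mutated patients over the whole cohort", {
  patients <- sprintf("P%02d", 1:70)
  vars <- data.frame(patient_id = rep(patients[1:33], each = 2),
                     gene = "TP53")
  freq <- gene_frequency_table(vars, patients)
  expect_equal(round(freq[["TP53"]], 4), 0.4714)
  empty <- gene_frequency_table(vars[0, ], patients, genes = c("TP53"))
  expect_equal(unname(empty), 0)
  # Brute-force recount on a random fixture.
  set.seed(13)
  rv <- data.frame(patient_id = sample(patients, 200, replace = TRUE),
                   gene = sample(c("TP53", "PIK3CA", "GATA3"), 200,
                                 replace = TRUE))
  freq2 <- gene_frequency_table(rv, patients)
  for (g in names(freq2)) {
    expect_equal(freq2[[g]],
                 length(unique(rv$patient_id[rv$gene == g])) / 70)
  }
})

test_that("squared Pearson correlation matches its closed form", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(pearson_r2(x, x), 1)
  expect_equal(pearson_r2(x, -x), 1)
  a <- c(1, 2, 3, 4); b <- c(2, 4, 5, 9)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r2(a, b), (num / den)^2)
  expect_equal(pearson_r2(a, b), 0.9307692, tolerance = 1e-6)
  expect_error(pearson_r2(a, rep(1, 4)), "variance")
  expect_error(pearson_r2(1:2, 1:2), "length")
})

sim_outcome_cohort <- function(n, beta_n = 0, beta_hr = 0, seed = 1) {
  cfg <- cohort_config(n_patients = n, seed = seed)
  cohort <- sample_cohort(cfg)
  eta <- -0.3 + beta_n * (match(cohort$n_stage,
                                c("N0", "N1", "N2", "N3")) - 1) +
    beta_hr * (cohort$hr_status == "negative")
  cohort$ctdna_positive <- runif(n) < plogis(eta)
  cohort
}

test_that("univariate logistic p-values are calibrated under the null", {
  pvals <- vapply(1:150, function(r) {
    cohort <- sim_outcome_cohort(300, seed = 5000 + r)
    logistic_uva(cohort, "t_stage")$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("univariate logistic detects a planted N-stage effect", {
  hits <- vapply(1:20, function(r) {
    cohort <- sim_outcome_cohort(2000, beta_n = log(2), seed = 6000 + r)
    logistic_uva(cohort, "n_stage")$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # Degenerate covariate errors.
  cohort <- sim_outcome_cohort(50, seed = 1)
  cohort$hr_status <- "positive"
  expect_error(logistic_uva(cohort, "hr_status"), "single observed level")
})

test_that("complete separation falls back to a penalized fit", {
  d <- data.frame(m_stage = rep(c("M0", "M1"), each = 20),
                  ctdna_positive = rep(c(FALSE, TRUE), each = 20))
  res <- logistic_uva(d, "m_stage")
  expect_true(res$separation)
  expect_equal(res$method, "firth")
  expect_lt(res$p_value, 0.001)
  expect_equal(unname(res$direction), 1)
})

test_that("multivariate model matches the univariate one on one covariate", {
  cohort <- sim_outcome_cohort(600, beta_n = 0.5, seed = 17)
  uva <- logistic_uva(cohort, "n_stage")
  mva <- logistic_mva(cohort, covariates = "n_stage")
  expect_equal(mva$p_value, uva$p_value, tolerance = 1e-9)
})

test_that("multivariate model recovers exactly the planted predictors", {
  reps <- 30
  sig <- matrix(NA, reps, 7)
  for (r in seq_len(reps)) {
    cohort <- sim_outcome_cohort(800, beta_n = 0.8, beta_hr = 1.2,
                                 seed = 7000 + r)
    mva <- logistic_mva(cohort)
    sig[r, ] <- mva$p_value < 0.05
    colnames(sig) <- mva$covariate
  }
  expect_gte(mean(sig[, "n_stage"] & sig[, "hr_status"]), 0.9)
  # Noise covariates stay near the nominal false-positive rate.
  noise <- c("age_group", "t_stage", "m_stage", "her2_ihc", "ki67_group")
  expect_lt(mean(sig[, noise]), 0.15)
})

test_that("one-way ANOVA matches the two-group t-test identity", {
  vals <- c(1.2, 1.1, 0.4, 1.9, 2.3, 2.8, 1.7, 2.2)
  grp <- rep(c("a", "b"), each = 4)
  res <- anova_oneway(vals, grp)
  x <- vals[grp == "a"]; y <- vals[grp == "b"]
  sp2 <- (3 * stats::var(x) + 3 * stats::var(y)) / 6
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(res$F, t_stat^2, tolerance = 1e-10)
  # Null structure: identical groups give F = 0, p = 1.
  null <- anova_oneway(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(null$F, 0)
  expect_equal(null$p_value, 1)
  expect_error(anova_oneway(c(1, 2, 3), c("a", "a", "b")),
               "at least two observations")
})

test_that("ANOVA rejection rate tracks the non-central F power curve", {
  set.seed(14)
  n <- 20; delta <- 1
  reject <- vapply(1:200, function(r) {
    x <- c(rnorm(n, 0), rnorm(n, delta))
    anova_oneway(x, rep(c("a", "b"), each = n))$p_value < 0.05
  }, logical(1))
  ncp <- n * delta^2 / 2
  power <- 1 - stats::pf(stats::qf(0.95, 1, 2 * n - 2), 1, 2 * n - 2,
                         ncp = ncp)
  se <- sqrt(power * (1 - power) / 200)
  expect_lt(abs(mean(reject) - power), 3.5 * se)
})
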