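# Cohort-level statistics -----------------------------------------------------
#
# Contingency-table tests, gene-frequency correlation, univariate and
# multivariate logistic models of ctDNA detectability, one-way ANOVA of
# maximal VAF across clinical groups, and confusion-matrix metrics for
# CNV-vs-immunohistochemistry concordance. Standard fits go through base R
# (`chisq.test`, `glm`, `oneway.test`); p-values for the logistic models come
# from likelihood-ratio tests.

#' Pearson chi-squared test on a contingency table
#'
#' Pearson chi-square without continuity correction, df = (r-1)(c-1), upper
#' tail p. Errors on tables with a zero marginal (expected counts undefined).
#'
#' @param table matrix of non-negative counts, at least 2x2.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L) {
    stop("contingency table must be at least 2x2", call. = FALSE)
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("contingency table must contain non-negative integer counts",
         call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("contingency table has a zero marginal", call. = FALSE)
  }
  res <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value), expected = res$expected)
}

#' Confusion-matrix concordance metrics
#'
#' Reference standard in rows (e.g. HER2 immunohistochemistry), test in
#' columns (e.g. ERBB2 amplification call). Metrics with zero denominators
#' are returned as `NA` and listed in `undefined`, never reported as 0.
#'
#' @param tp,fp,fn,tn non-negative integer cell counts.
#' @return list with `overall_consistency`, `ppv`, `npv`, `sensitivity`,
#'   `specificity`, `total`, `undefined`.
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("confusion matrix cells must be non-negative integers",
         call. = FALSE)
  }
  total <- sum(cells)
  if (total == 0L) stop("confusion matrix is empty", call. = FALSE)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(
    overall_consistency = (tp + tn) / total,
    ppv = safe(tp, tp + fp),
    npv = safe(tn, tn + fn),
    sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    total = total
  )
  out$undefined <- names(out)[vapply(out, function(x)
    length(x) == 1L && is.na(x), logical(1))]
  out
}

#' Per-gene mutated-patient fractions
#'
#' Fraction of cohort patients carrying at least one variant in each gene;
#' the denominator is always the full cohort, including patients without
#' variants in the compartment.
#'
#' @param variants data.frame with `patient_id` and `gene` columns (already
#'   restricted to one compartment by the caller, or filtered via `source`).
#' @param patient_ids character vector of all cohort patient ids.
#' @param genes optional gene universe; defaults to genes observed in
#'   `variants`.
#' @return named numeric vector of fractions.
#' @export
gene_frequency_table <- function(variants, patient_ids, genes = NULL) {
  if (length(patient_ids) == 0L) stop("empty cohort", call. = FALSE)
  genes <- genes %||% sort(unique(variants$gene))
  out <- setNames(numeric(length(genes)), genes)
  if (nrow(variants)) {
    hit <- unique(variants[, c("patient_id", "gene")])
    tab <- table(factor(hit$gene, levels = genes))
    out[names(tab)] <- as.numeric(tab) / length(patient_ids)
  }
  out
}

#' Squared Pearson correlation of two frequency vectors
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return r-squared.
#' @export
pearson_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need two equal-length vectors of length >= 3", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance in a frequency vector", call. = FALSE)
  }
  cor(x, y)^2
}

# Ordinal/binary scores for the clinical covariates of the detectability
# models. Multi-level covariates enter as ordered numeric scores so each
# characteristic contributes a single parameter (and a single p-value).
covariate_score <- function(data, covariate) {
  switch(covariate,
    age_group = match(data$age_group, c("<=35", "36-55", ">=56")) - 1L,
    t_stage = match(data$t_stage, c("T1", "T2", "T3", "T4")) - 1L,
    n_stage = n_stage_ordinal(data$n_stage),
    m_stage = as.integer(data$m_stage == "M1"),
    hr_status = as.integer(data$hr_status == "negative"),
    her2_ihc = as.integer(data$her2_ihc == "positive"),
    ki67_group = as.integer(data$ki67_group == "high"),
    tnm_stage = match(data$tnm_stage, c("I", "II", "III", "IV")) - 1L,
    stop(sprintf("unknown covariate '%s'", covariate), call. = FALSE)
  )
}

# Firth-penalized logistic regression (Jeffreys-prior score correction),
# used as fallback under complete separation. Returns coefficients and the
# penalized log-likelihood.
firth_logistic <- function(X, y, max_iter = 50L, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    W <- p * (1 - p)
    XtW <- t(X * W)
    info <- XtW %*% X
    info_inv <- solve(info + diag(1e-10, ncol(X)))
    # hat diagonal of W^(1/2) X (X' W X)^-1 X' W^(1/2)
    h <- rowSums((X %*% info_inv) * X) * W
    U <- drop(t(X) %*% (y - p + h * (0.5 - p)))
    step <- drop(info_inv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  W <- p * (1 - p)
  info <- t(X * W) %*% X
  ll <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300))) +
    0.5 * determinant(info, logarithm = TRUE)$modulus
  list(coefficients = beta, logLik = as.numeric(ll))
}

firth_lrt <- function(data_scores, y, drop_col) {
  X_full <- cbind(1, as.matrix(data_scores))
  fit_full <- firth_logistic(X_full, y)
  X_red <- X_full[, -(drop_col + 1L), drop = FALSE]
  fit_red <- firth_logistic(X_red, y)
  stat <- 2 * (fit_full$logLik - fit_red$logLik)
  list(statistic = max(stat, 0), p_value = pchisq(max(stat, 0), df = 1,
                                                  lower.tail = FALSE),
       coefficients = fit_full$coefficients)
}

#' Univariate logistic model of ctDNA detectability
#'
#' Binary logistic regression of the detectability outcome on one clinical
#' covariate (multi-level covariates as ordered numeric scores); p-value from
#' the likelihood-ratio test against the intercept-only model. Complete
#' separation is detected and handled with a Firth-penalized fit, flagged in
#' the result.
#'
#' @param data per-patient data.frame carrying the covariate columns and the
#'   outcome.
#' @param covariate one of `age_group`, `t_stage`, `n_stage`, `m_stage`,
#'   `hr_status`, `her2_ihc`, `ki67_group` (or `tnm_stage`).
#' @param outcome name of the logical outcome column.
#' @return list (class `association_result`): `covariate`, `statistic`
#'   (likelihood-ratio), `df`, `p_value`, `direction` (sign of the slope),
#'   `method`, `separation`.
#' @export
logistic_uva <- function(data, covariate, outcome = "ctdna_positive") {
  y <- as.integer(data[[outcome]])
  if (is.null(y) || any(is.na(y))) stop("binary outcome required",
                                        call. = FALSE)
  x <- covariate_score(data, covariate)
  keep <- !is.na(x)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2L) {
    stop(sprintf("covariate '%s' has a single observed level", covariate),
         call. = FALSE)
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ x, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated || abs(coef(fit)[2]) > 15) {
    fr <- firth_lrt(matrix(x, ncol = 1), y, 1L)
    return(structure(list(covariate = covariate, statistic = fr$statistic,
                          df = 1L, p_value = fr$p_value,
                          direction = sign(fr$coefficients[2]),
                          method = "firth", separation = TRUE),
                     class = "association_result"))
  }
  null <- glm(y ~ 1, family = binomial())
  lr <- anova(null, fit, test = "Chisq")
  structure(list(covariate = covariate,
                 statistic = lr$Deviance[2], df = lr$Df[2],
                 p_value = lr$`Pr(>Chi)`[2],
                 direction = sign(coef(fit)[[2]]),
                 method = "glm", separation = FALSE),
            class = "association_result")
}

#' Multivariate logistic model of ctDNA detectability
#'
#' One joint binary logistic model over the clinical covariates; each
#' covariate's p-value comes from a drop-one likelihood-ratio test. Patients
#' with unknown HER2 status are excluded when `her2_ihc` is in the model.
#' Rank deficiency raises an error naming the offending covariate; complete
#' separation triggers a Firth-penalized drop-one analysis.
#'
#' @param data per-patient data.frame.
#' @param covariates character vector of covariate names (default: the seven
#'   detectability covariates).
#' @param outcome name of the logical outcome column.
#' @return data.frame with one row per covariate: `covariate`, `statistic`,
#'   `df`, `p_value`, `direction`, `method`.
#' @export
logistic_mva <- function(data,
                         covariates = c("age_group", "t_stage", "n_stage",
                                        "m_stage", "hr_status", "her2_ihc",
                                        "ki67_group"),
                         outcome = "ctdna_positive") {
  if ("her2_ihc" %in% covariates) {
    data <- data[data$her2_ihc != "unknown", , drop = FALSE]
  }
  y <- as.integer(data[[outcome]])
  scores <- as.data.frame(lapply(covariates, function(cv)
    covariate_score(data, cv)))
  names(scores) <- covariates
  if (nrow(scores) <= ncol(scores) + 1L) {
    stop("more parameters than observations", call. = FALSE)
  }
  X <- as.matrix(scores)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1L) {
    di <- qrX$pivot[seq(qrX$rank + 1L, ncol(X) + 1L)] - 1L
    dropped <- covariates[di[di > 0L]]
    stop("rank-deficient design; offending covariate(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  df_fit <- cbind(scores, .y = y)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., family = binomial(), data = df_fit),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated || any(abs(coef(fit)[-1]) > 15)) {
    rows <- lapply(seq_along(covariates), function(j) {
      fr <- firth_lrt(scores, y, j)
      data.frame(covariate = covariates[j], statistic = fr$statistic,
                 df = 1L, p_value = fr$p_value,
                 direction = sign(fr$coefficients[j + 1L]),
                 method = "firth", stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  d1 <- drop1(fit, test = "LRT")
  data.frame(
    covariate = covariates,
    statistic = d1$LRT[-1],
    df = d1$Df[-1],
    p_value = d1$`Pr(>Chi)`[-1],
    direction = sign(coef(fit)[covariates]),
    method = "glm",
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' One-way ANOVA of a continuous response across clinical groups
#'
#' Classical one-way analysis of variance (pooled variance), returning the F
#' statistic and upper-tail p-value. For two groups, F equals the square of
#' the pooled-variance t statistic.
#'
#' @param values numeric response (e.g. per-patient maximal VAF).
#' @param groups group labels, same length as `values`.
#' @return list with `F`, `df1`, `df2`, `p_value`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("every group needs at least two observations", call. = FALSE)
  }
  res <- oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(res$statistic), df1 = unname(res$parameter[1]),
       df2 = unname(res$parameter[2]), p_value = unname(res$p.value))
}
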