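# Synthetic cohort generator -------------------------------------------------
#
# Emulates a primary breast cancer liquid-biopsy study population: clinical
# covariates drawn from configurable category proportions, per-tumor mutation
# profiles with a clonal/subclonal cancer-cell-fraction structure, a
# covariate-dependent logistic shedding model that controls which tumor
# mutations reach plasma, a clonal-hematopoiesis channel producing
# blood-specific mutations, and UID-tagged duplex read families with the
# bimodal cfDNA fragment-length profile.

# Registry of panel genes on the synthetic contigs. Each gene owns a window
# of positions; hematopoiesis-associated genes are included so blood-specific
# variants get coordinates too.
gene_registry <- function() {
  genes <- c("TP53", "PIK3CA", "AKT1", "GATA3", "MAP3K1", "CDH1", "ESR1",
             "ERBB2", "PTEN", "KMT2C", "NF1", "RB1", "ARID1A", "AKT2",
             "SF3B1", "PIK3R1", "DNMT3A", "JAK2", "TET2")
  n <- length(genes)
  data.frame(
    gene = genes,
    chrom = paste0("syn", (seq_len(n) - 1L) %% 4L + 1L),
    start = 100000L * seq_len(n),
    width = 50000L,
    stringsAsFactors = FALSE
  )
}

#' Shedding model parameters
#'
#' Log-odds coefficients of the per-mutation plasma shedding model. The
#' probability that a tumor mutation is shed into plasma at a detectable level
#' is `plogis(intercept + coef_n_stage * n + coef_hr_negative * [HR-] +
#' coef_m1 * [M1] + log(clonal_boost) * [clonal])`, where `n` is the ordinal
#' N stage (N0 = 0 ... N3 = 3). `clonal_boost` multiplies the shedding odds of
#' clonal mutations and must be at least 1. `vaf_scale_by_stage` maps the
#' tumor VAF of a shed mutation onto the plasma scale, one positive factor per
#' TNM stage, encoding higher circulating tumor burden at advanced stage.
#'
#' Defaults were calibrated once by large-cohort simulation so the synthetic
#' study operates at the reference cohort's point: roughly 61% of patients
#' with tumor-derived mutations detectable in plasma (68% with any plasma
#' mutation, including the hematopoietic channel), with N stage and hormone
#' receptor status the dominant covariates.
#'
#' @param intercept baseline log-odds (N0, HR-positive, M0, subclonal).
#' @param coef_n_stage log-odds increment per ordinal N-stage step.
#' @param coef_hr_negative log-odds increment for HR-negative patients.
#' @param coef_m1 log-odds increment for M1 (distant metastasis).
#' @param clonal_boost multiplicative factor (>= 1) on shedding odds of
#'   clonal mutations.
#' @param vaf_scale_by_stage named positive scaling factors for stages I-IV.
#' @return object of class `shedding_params`.
#' @export
shedding_params <- function(intercept = -4.1,
                            coef_n_stage = 0.9,
                            coef_hr_negative = 2.0,
                            coef_m1 = 0.7,
                            clonal_boost = 7,
                            vaf_scale_by_stage = c(I = 0.10, II = 0.12,
                                                   III = 0.18, IV = 0.35)) {
  stopifnot(is.finite(intercept), is.finite(coef_n_stage),
            is.finite(coef_hr_negative), is.finite(coef_m1))
  if (!is.numeric(clonal_boost) || clonal_boost < 1) {
    stop("`clonal_boost` must be >= 1", call. = FALSE)
  }
  if (length(vaf_scale_by_stage) != 4L || any(vaf_scale_by_stage <= 0)) {
    stop("`vaf_scale_by_stage` needs one positive factor per stage I-IV",
         call. = FALSE)
  }
  names(vaf_scale_by_stage) <- c("I", "II", "III", "IV")
  structure(list(intercept = intercept, coef_n_stage = coef_n_stage,
                 coef_hr_negative = coef_hr_negative, coef_m1 = coef_m1,
                 clonal_boost = clonal_boost,
                 vaf_scale_by_stage = vaf_scale_by_stage),
            class = "shedding_params")
}

#' Synthetic cohort configuration
#'
#' Bundles every tunable of the generator. Category proportions default to the
#' reference cohort's clinical table (71 patients); the mutation count per
#' tumor follows a negative binomial truncated to 1..15 whose sample median is
#' 2.5; per-mutation gene labels follow a configurable frequency table.
#'
#' @param n_patients cohort size.
#' @param covariate_proportions named list of per-covariate category
#'   probability vectors (each must sum to 1 within 1e-9).
#' @param mutation_count list with negative binomial `size`, `mu` and the
#'   truncation bounds `min`, `max`.
#' @param gene_frequencies named per-draw gene probabilities (sum to 1).
#' @param shedding [shedding_params()] object.
#' @param hematopoietic list with per-patient Bernoulli `rate`, named gene
#'   probabilities `genes`, and plasma `vaf_range` for clonal-hematopoiesis
#'   mutations.
#' @param purity_range tumor purity is drawn uniformly from this interval.
#' @param n_subclones_max maximal number of subclonal CCF clusters.
#' @param n_subclones_probs sampling weights over 0..`n_subclones_max`
#'   subclones per patient.
#' @param subclone_ccf_range CCF interval subclone clusters are drawn from.
#' @param tumor_depth,plasma_depth sequencing depths used for observed counts.
#' @param tumor_vaf_noise_sd Gaussian noise on observed tumor VAF.
#' @param plasma_vaf_sdlog lognormal spread of observed plasma VAF around its
#'   expected (scaled) value.
#' @param seed default seed used by the sampling functions when they are not
#'   given one explicitly.
#' @return object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_patients = 10, seed = 1)
#' cohort <- sample_cohort(cfg)
#' @export
cohort_config <- function(n_patients = 71,
                          covariate_proportions = NULL,
                          mutation_count = list(size = 1.0, mu = 2.4,
                                                min = 1L, max = 15L),
                          gene_frequencies = NULL,
                          shedding = shedding_params(),
                          hematopoietic = list(
                            rate = 0.20,
                            genes = c(DNMT3A = 0.6, JAK2 = 0.2, TET2 = 0.2),
                            vaf_range = c(0.005, 0.03)),
                          purity_range = c(0.3, 0.9),
                          n_subclones_max = 2L,
                          n_subclones_probs = c(0.15, 0.35, 0.5),
                          subclone_ccf_range = c(0.1, 0.7),
                          tumor_depth = 800L,
                          plasma_depth = 2000L,
                          tumor_vaf_noise_sd = 0.01,
                          plasma_vaf_sdlog = 0.25,
                          seed = NULL) {
  if (is.null(covariate_proportions)) {
    covariate_proportions <- list(
      age_group = c("<=35" = 11, "36-55" = 42, ">=56" = 18) / 71,
      tnm_stage = c(I = 8, II = 18, III = 38, IV = 7) / 71,
      t_stage = c(T1 = 26, T2 = 33, T3 = 9, T4 = 3) / 71,
      n_stage = c(N0 = 19, N1 = 12, N2 = 20, N3 = 20) / 71,
      hr_status = c(positive = 52, negative = 19) / 71,
      her2_ihc = c(positive = 28, negative = 42, unknown = 1) / 71,
      ki67_group = c(high = 60, low = 11) / 71
    )
  }
  if (is.null(gene_frequencies)) {
    gene_frequencies <- c(
      TP53 = 0.19, PIK3CA = 0.16, AKT1 = 0.03, GATA3 = 0.09, MAP3K1 = 0.06,
      CDH1 = 0.06, ESR1 = 0.05, ERBB2 = 0.04, PTEN = 0.06, KMT2C = 0.07,
      NF1 = 0.04, RB1 = 0.03, ARID1A = 0.05, AKT2 = 0.02, SF3B1 = 0.02,
      PIK3R1 = 0.03)
  }
  cfg <- structure(list(
    n_patients = n_patients,
    covariate_proportions = covariate_proportions,
    mutation_count = mutation_count,
    gene_frequencies = gene_frequencies,
    shedding = shedding,
    hematopoietic = hematopoietic,
    purity_range = purity_range,
    n_subclones_max = as.integer(n_subclones_max),
    n_subclones_probs = n_subclones_probs,
    subclone_ccf_range = subclone_ccf_range,
    tumor_depth = as.integer(tumor_depth),
    plasma_depth = as.integer(plasma_depth),
    tumor_vaf_noise_sd = tumor_vaf_noise_sd,
    plasma_vaf_sdlog = plasma_vaf_sdlog,
    seed = seed
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @param config object to validate.
#' @export
validate_cohort_config <- function(config) {
  if (!is.numeric(config$n_patients) || config$n_patients < 0) {
    stop("`n_patients` must be a non-negative integer", call. = FALSE)
  }
  for (cov in names(config$covariate_proportions)) {
    p <- config$covariate_proportions[[cov]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(sprintf(
        "proportions for covariate '%s' must be non-negative and sum to 1 (got %.10f)",
        cov, sum(p)), call. = FALSE)
    }
  }
  mc <- config$mutation_count
  if (mc$min < 1L || mc$max < mc$min) {
    stop("mutation count bounds must satisfy 1 <= min <= max", call. = FALSE)
  }
  gf <- config$gene_frequencies
  if (length(gf) == 0L) stop("gene frequency table is empty", call. = FALSE)
  if (any(gf < 0) || abs(sum(gf) - 1) > 1e-9) {
    stop("proportions for covariate 'gene_frequencies' must sum to 1",
         call. = FALSE)
  }
  unknown <- setdiff(names(gf), gene_registry()$gene)
  if (length(unknown)) {
    stop("genes missing from the synthetic registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  assert_fraction(config$hematopoietic$rate, "hematopoietic$rate")
  stopifnot(inherits(config$shedding, "shedding_params"))
  assert_fraction(config$purity_range, "purity_range", lo = 0, hi = 1,
                  lo_open = TRUE)
  invisible(config)
}

# Molecular subtype from immunohistochemistry, standard surrogate definitions:
# HR+/HER2-/Ki67-low -> Luminal A; HR+ otherwise -> Luminal B;
# HR-/HER2+ -> HER2-enriched; HR-/HER2- -> TNBC; unknown HER2 -> unknown.
derive_subtype <- function(hr, her2, ki67) {
  ifelse(her2 == "unknown", "unknown",
  ifelse(hr == "positive" & her2 == "negative" & ki67 == "low", "LuminalA",
  ifelse(hr == "positive", "LuminalB",
  ifelse(her2 == "positive", "HER2", "TNBC"))))
}

#' Sample a synthetic patient cohort
#'
#' Draws clinical covariates independently from the configured category
#' proportions. M stage is tied to TNM stage (M1 if and only if stage IV) and
#' the molecular subtype is derived from HR/HER2/Ki67, so the recorded fields
#' are always internally consistent.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return data.frame with one row per patient.
#' @export
sample_cohort <- function(config, seed = config$seed) {
  validate_cohort_config(config)
  n <- as.integer(config$n_patients)
  draw <- function(p) {
    if (n == 0L) character(0) else
      sample(names(p), n, replace = TRUE, prob = p)
  }
  with_seed(seed, {
    cp <- config$covariate_proportions
    age_group <- draw(cp$age_group)
    tnm_stage <- draw(cp$tnm_stage)
    t_stage <- draw(cp$t_stage)
    n_stage <- draw(cp$n_stage)
    hr_status <- draw(cp$hr_status)
    her2_ihc <- draw(cp$her2_ihc)
    ki67_group <- draw(cp$ki67_group)
    purity <- runif(n, config$purity_range[1], config$purity_range[2])
    data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      age_group = age_group,
      t_stage = t_stage,
      n_stage = n_stage,
      m_stage = ifelse(tnm_stage == "IV", "M1", "M0"),
      tnm_stage = tnm_stage,
      hr_status = hr_status,
      her2_ihc = her2_ihc,
      ki67_group = ki67_group,
      subtype = derive_subtype(hr_status, her2_ihc, ki67_group),
      tumor_purity = purity,
      stringsAsFactors = FALSE
    )
  })
}

# Truncated negative binomial mutation counts on [min, max].
sample_mutation_counts <- function(n, mc) {
  support <- mc$min:mc$max
  p <- stats::dnbinom(support, size = mc$size, mu = mc$mu)
  sample(support, n, replace = TRUE, prob = p / sum(p))
}

#' Sample tumor mutation profiles for a cohort
#'
#' Each patient receives a truncated-negative-binomial number of somatic
#' mutations (1-15, median 2.5 under the defaults). The cancer cell fraction
#' structure is one clonal cluster at CCF 1 plus 0-`n_subclones_max` subclonal
#' clusters drawn from `subclone_ccf_range`; every mutation is assigned to a
#' cluster (the first always to the clonal one, so a clonal mutation always
#' exists) and flagged `clonal_true` when its CCF is at least 75% of the
#' patient's maximum. True tumor VAF assumes heterozygous mutations at copy
#' number 2: `ccf * purity / 2`.
#'
#' @param cohort data.frame from [sample_cohort()].
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return data.frame of ground-truth mutations (one row per mutation).
#' @export
sample_cohort_mutations <- function(cohort, config, seed = config$seed) {
  validate_cohort_config(config)
  if (nrow(cohort) == 0L) return(empty_mutation_frame())
  reg <- gene_registry()
  with_seed(seed, {
    k <- sample_mutation_counts(nrow(cohort), config$mutation_count)
    m <- sum(k)
    dt <- data.table(
      patient_id = rep(cohort$patient_id, k),
      purity = rep(cohort$tumor_purity, k),
      gene = sample(names(config$gene_frequencies), m, replace = TRUE,
                    prob = config$gene_frequencies)
    )
    dt[, idx := seq_len(.N), by = patient_id]
    # CCF clusters per patient: cluster 1 is clonal (CCF 1).
    sub_probs <- config$n_subclones_probs %||%
      rep(1, config$n_subclones_max + 1L)
    n_sub <- sample(0:config$n_subclones_max, nrow(cohort), replace = TRUE,
                    prob = sub_probs)
    sub_ccf <- matrix(runif(nrow(cohort) * max(1L, config$n_subclones_max),
                            config$subclone_ccf_range[1],
                            config$subclone_ccf_range[2]),
                      nrow = nrow(cohort))
    pt_row <- match(dt$patient_id, cohort$patient_id)
    # Cluster assignment: the first mutation anchors the clonal cluster;
    # subsequent ones fall into the clonal cluster with weight 1 against
    # weight 2 per subclone, reproducing a subclonal-majority mutation mix
    # in multi-cluster tumors.
    ns <- n_sub[pt_row]
    p_clonal <- 1 / (1 + 2 * ns)
    u <- runif(m)
    cluster <- ifelse(dt$idx == 1L | ns == 0L | u < p_clonal, 1L,
                      1L + pmin(ns, 1L + floor((u - p_clonal) /
                                                 (1 - p_clonal) * ns)))
    dt[, ccf_true := ifelse(cluster == 1L, 1,
                            sub_ccf[cbind(pt_row, pmax(cluster - 1L, 1L))])]
    dt[, clonal_true := ccf_true >= 0.75 * max(ccf_true), by = patient_id]
    # Coordinates inside the gene's window on the synthetic reference.
    g <- match(dt$gene, reg$gene)
    dt[, chrom := reg$chrom[g]]
    dt[, pos := reg$start[g] + sample.int(reg$width[g[1]], m, replace = TRUE)]
    dt[, pos := pos + 0:(.N - 1L), by = .(patient_id, chrom, pos)]
    dt[, ref := ref_base(chrom, pos)]
    alt_choices <- c("A", "C", "G", "T")
    dt[, alt := vapply(ref, function(r)
      sample(setdiff(alt_choices, r), 1L), character(1))]
    dt[, tumor_vaf_true := ccf_true * purity / 2]
    dt[, origin := "tumor"]
    out <- as.data.frame(dt[, .(patient_id, gene, chrom, pos, ref, alt,
                                ccf_true, clonal_true, tumor_vaf_true,
                                origin)])
    out
  })
}

empty_mutation_frame <- function() {
  data.frame(patient_id = character(0), gene = character(0),
             chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), ccf_true = numeric(0),
             clonal_true = logical(0), tumor_vaf_true = numeric(0),
             origin = character(0), stringsAsFactors = FALSE)
}

#' @rdname sample_cohort_mutations
#' @param patient single-row data.frame (one patient).
#' @export
sample_tumor_mutations <- function(patient, config, seed = config$seed) {
  sample_cohort_mutations(patient, config, seed = seed)
}

n_stage_ordinal <- function(n_stage) {
  match(n_stage, c("N0", "N1", "N2", "N3")) - 1L
}

#' Per-mutation plasma shedding probability
#'
#' Logistic model of the probability that a tumor mutation is shed into plasma
#' cell-free DNA at a detectable level, as a function of the patient's N
#' stage (ordinal), hormone receptor status, M stage, and the mutation's
#' clonality (clonal mutations get their odds multiplied by `clonal_boost`).
#'
#' @param patient single-row patient data.frame (or a cohort row matched to
#'   each mutation via `mutations$patient_id`).
#' @param mutation data.frame of mutations with a `clonal_true` column.
#' @param params a [shedding_params()].
#' @return numeric vector of probabilities, one per mutation row.
#' @export
shedding_probability <- function(patient, mutation, params) {
  stopifnot(inherits(params, "shedding_params"))
  if (nrow(mutation) == 0L) return(numeric(0))
  if (nrow(patient) > 1L) {
    patient <- patient[match(mutation$patient_id, patient$patient_id), ]
  }
  eta <- params$intercept +
    params$coef_n_stage * n_stage_ordinal(patient$n_stage) +
    params$coef_hr_negative * (patient$hr_status == "negative") +
    params$coef_m1 * (patient$m_stage == "M1") +
    log(params$clonal_boost) * mutation$clonal_true
  plogis(eta)
}

#' Simulate plasma observations for a cohort
#'
#' Each tumor mutation is shed independently with [shedding_probability()];
#' shed mutations acquire a plasma VAF drawn lognormally around the
#' stage-scaled true tumor VAF, observed through binomial sampling at
#' `plasma_depth` consensus families. A clonal-hematopoiesis channel appends,
#' per patient with configurable probability, one blood-only mutation in a
#' hematopoiesis-associated gene (DNMT3A/JAK2/TET2 by default).
#'
#' @param cohort cohort data.frame.
#' @param mutations ground-truth mutations from [sample_cohort_mutations()].
#' @param config a [cohort_config()]; `config$shedding` provides the model.
#' @param seed integer seed.
#' @return data.frame of plasma variant observations with their `origin`
#'   (`tumor` or `hematopoietic`) and the true shed VAF.
#' @export
simulate_cohort_plasma <- function(cohort, mutations, config,
                                   seed = config$seed) {
  params <- config$shedding
  reg <- gene_registry()
  with_seed(seed, {
    shed <- if (nrow(mutations)) {
      p <- shedding_probability(cohort, mutations, params)
      mutations[runif(nrow(mutations)) < p, , drop = FALSE]
    } else mutations
    plasma <- if (nrow(shed)) {
      stage <- cohort$tnm_stage[match(shed$patient_id, cohort$patient_id)]
      scale <- params$vaf_scale_by_stage[stage]
      shed_vaf <- pmin(shed$tumor_vaf_true * scale *
                         rlnorm(nrow(shed), 0, config$plasma_vaf_sdlog), 0.95)
      alt_reads <- rbinom(nrow(shed), config$plasma_depth, shed_vaf)
      keep <- alt_reads >= 1L
      data.frame(
        patient_id = shed$patient_id[keep], gene = shed$gene[keep],
        chrom = shed$chrom[keep], pos = shed$pos[keep],
        ref = shed$ref[keep], alt = shed$alt[keep],
        var_type = "SNV", depth = config$plasma_depth,
        alt_reads = alt_reads[keep],
        vaf = alt_reads[keep] / config$plasma_depth,
        shed_vaf_true = shed_vaf[keep],
        source = "plasma", origin = shed$origin[keep],
        stringsAsFactors = FALSE
      )
    } else empty_plasma_frame()
    # Clonal hematopoiesis channel: blood-only mutations.
    hema <- config$hematopoietic
    if (nrow(cohort) && hema$rate > 0) {
      hit <- runif(nrow(cohort)) < hema$rate
      if (any(hit)) {
        hp <- cohort$patient_id[hit]
        gene <- sample(names(hema$genes), length(hp), replace = TRUE,
                       prob = hema$genes)
        g <- match(gene, reg$gene)
        pos <- reg$start[g] + sample.int(reg$width[1], length(hp),
                                         replace = TRUE)
        ref <- ref_base(reg$chrom[g], pos)
        alt <- vapply(ref, function(r)
          sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
        true_vaf <- runif(length(hp), hema$vaf_range[1], hema$vaf_range[2])
        alt_reads <- pmax(rbinom(length(hp), config$plasma_depth, true_vaf), 1L)
        plasma <- rbind(plasma, data.frame(
          patient_id = hp, gene = gene, chrom = reg$chrom[g], pos = pos,
          ref = ref, alt = alt, var_type = "SNV",
          depth = config$plasma_depth, alt_reads = alt_reads,
          vaf = alt_reads / config$plasma_depth, shed_vaf_true = true_vaf,
          source = "plasma", origin = "hematopoietic",
          stringsAsFactors = FALSE
        ))
      }
    }
    plasma[order(plasma$patient_id, plasma$chrom, plasma$pos), , drop = FALSE]
  })
}

empty_plasma_frame <- function() {
  data.frame(patient_id = character(0), gene = character(0),
             chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), var_type = character(0), depth = integer(0),
             alt_reads = integer(0), vaf = numeric(0),
             shed_vaf_true = numeric(0), source = character(0),
             origin = character(0), stringsAsFactors = FALSE)
}

#' @rdname simulate_cohort_plasma
#' @param patient single-row patient data.frame.
#' @param mutations that patient's mutations.
#' @export
simulate_plasma <- function(patient, mutations, config, seed = config$seed) {
  simulate_cohort_plasma(patient, mutations, config, seed = seed)
}

#' Sample cfDNA fragment lengths
#'
#' Two-component Gaussian mixture rounded to integers, emulating the
#' mononucleosomal cfDNA peak (major mode inside 170-185 bp) and the minor
#' dinucleosomal peak near 322 bp.
#'
#' @param n number of fragments.
#' @param mixture list with `weights`, `means`, `sds` (two components).
#' @param seed integer seed.
#' @return integer vector of fragment lengths (minimum 20).
#' @export
sample_fragment_lengths <- function(n,
                                    mixture = list(weights = c(0.85, 0.15),
                                                   means = c(177, 322),
                                                   sds = c(5, 12)),
                                    seed = NULL) {
  stopifnot(length(mixture$weights) == 2L,
            abs(sum(mixture$weights) - 1) < 1e-9)
  with_seed(seed, {
    comp <- 1L + (runif(n) < mixture$weights[2])
    pmax(20L, as.integer(round(rnorm(n, mixture$means[comp],
                                     mixture$sds[comp]))))
  })
}

#' Simulate UID-tagged duplex read families for one locus
#'
#' Generates `depth` original cfDNA molecules covering a variant position.
#' Each molecule gets a unique UID, a fragment length from the cfDNA mixture,
#' fragment coordinates containing the locus, an allele (alternate with
#' probability `alt_fraction`), and per-strand read families whose sizes come
#' from `family_size_law`. Per-base sequencing/PCR errors are injected
#' independently at `error_rate` (an erroneous base is replaced by a uniform
#' draw from the other three bases).
#'
#' @param variant list or single-row data.frame with `chrom`, `pos`, `ref`,
#'   `alt` and optionally `vaf` (used when `alt_fraction` is `NULL`).
#' @param depth number of original molecules (duplex families).
#' @param alt_fraction probability a molecule carries the alternate allele.
#' @param family_size_law function(n) returning n positive family sizes;
#'   applied independently per strand.
#' @param error_rate per-base error probability in `[0, 1)`.
#' @param fragment_length_mixture see [sample_fragment_lengths()].
#' @param seed integer seed.
#' @return data.frame of tagged reads: `uid`, `chrom`, `fragment_start`,
#'   `fragment_end`, `strand_orientation` (`top`/`bottom`), `bases` (string),
#'   `base_qualities` (Phred+33 string), `mapping_quality`.
#' @export
simulate_read_families <- function(variant, depth,
                                   alt_fraction = NULL,
                                   family_size_law = function(n) 1L + rpois(n, 1),
                                   error_rate = 0.001,
                                   fragment_length_mixture = list(
                                     weights = c(0.85, 0.15),
                                     means = c(177, 322),
                                     sds = c(5, 12)),
                                   seed = NULL) {
  stopifnot(depth > 0)
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 1) {
    stop("`error_rate` must lie in [0, 1)", call. = FALSE)
  }
  v <- as.list(variant)
  alt_fraction <- alt_fraction %||% v$vaf %||% 0
  assert_fraction(alt_fraction, "alt_fraction")
  bases4 <- c("A", "C", "G", "T")
  with_seed(seed, {
    len <- sample_fragment_lengths(depth, fragment_length_mixture)
    offset <- floor(runif(depth) * len)          # 0-based offset of pos
    start <- as.integer(v$pos) - offset
    end <- start + len - 1L
    is_alt <- runif(depth) < alt_fraction
    n_top <- pmax(1L, as.integer(family_size_law(depth)))
    n_bot <- pmax(1L, as.integer(family_size_law(depth)))
    uid <- sprintf("M%06d", seq_len(depth))
    rows <- vector("list", depth)
    for (i in seq_len(depth)) {
      tmpl <- ref_base(v$chrom, start[i]:end[i])
      if (is_alt[i]) tmpl[offset[i] + 1L] <- v$alt
      nr <- n_top[i] + n_bot[i]
      L <- len[i]
      seqs <- character(nr)
      for (r in seq_len(nr)) {
        s <- tmpl
        ne <- rbinom(1L, L, error_rate)
        if (ne > 0L) {
          at <- sample.int(L, ne)
          s[at] <- vapply(s[at], function(b)
            sample(setdiff(bases4, b), 1L), character(1))
        }
        seqs[r] <- paste(s, collapse = "")
      }
      qual <- strrep(intToUtf8(33L + 37L), L)
      rows[[i]] <- data.frame(
        uid = uid[i], chrom = v$chrom,
        fragment_start = start[i], fragment_end = end[i],
        strand_orientation = rep(c("top", "bottom"), c(n_top[i], n_bot[i])),
        bases = seqs, base_qualities = qual, mapping_quality = 60L,
        stringsAsFactors = FALSE
      )
    }
    out <- data.table::rbindlist(rows)
    as.data.frame(out)
  })
}
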