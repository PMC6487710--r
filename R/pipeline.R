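# Pipeline orchestration ------------------------------------------------------
#
# simulate -> (plasma gating) -> tissue filter cascade -> per-patient
# concordance & clonality -> cohort statistics, as one seeded, reproducible
# run. Every threshold of the analysis surfaces as a named configuration key
# with the reference pipeline's value as default. Stage outputs are written
# as TSV when an output directory is given, and a JSON manifest with config
# echo, stage timings and file checksums is written last.

#' Pipeline run configuration
#'
#' @param n_patients synthetic cohort size.
#' @param seed master seed; stage seeds are derived from it.
#' @param outdir output directory (`NULL` for in-memory only).
#' @param stages stages to execute, in dependency order.
#' @param cohort a [cohort_config()]; `n_patients` and `seed` override its
#'   fields.
#' @param lod plasma limit of detection (allele fraction).
#' @param alpha level of the background binomial gate (read-level mode).
#' @param min_members_per_strand duplex consensus membership gate.
#' @param clonality_threshold fraction of maximal CCF defining clonal.
#' @param mvaf_scope `"tumor_derived_only"` or `"all_plasma"`.
#' @param filter filter cascade thresholds, see [filter_thresholds()].
#' @param read_level if `TRUE`, plasma variants are confirmed by simulating
#'   UID read families and re-calling them through the duplex consensus
#'   gates; the default gates on the variant-level observations directly.
#' @param consensus_depth families per variant in read-level mode.
#' @param resume reuse stage outputs already present in `outdir`.
#' @return object of class `run_config`.
#' @export
run_config <- function(n_patients = 71,
                       seed = 1L,
                       outdir = NULL,
                       stages = c("simulate", "filter", "concord", "stats"),
                       cohort = cohort_config(),
                       lod = 0.005,
                       alpha = 0.01,
                       min_members_per_strand = 1L,
                       clonality_threshold = 0.75,
                       mvaf_scope = c("tumor_derived_only", "all_plasma"),
                       filter = filter_thresholds(),
                       read_level = FALSE,
                       consensus_depth = 300L,
                       resume = FALSE) {
  mvaf_scope <- match.arg(mvaf_scope)
  assert_fraction(lod, "lod", lo_open = TRUE, hi_open = TRUE)
  assert_fraction(alpha, "alpha", lo_open = TRUE, hi_open = TRUE)
  assert_fraction(clonality_threshold, "clonality_threshold", lo_open = TRUE)
  stopifnot(all(stages %in% c("simulate", "filter", "concord", "stats")))
  if (is.null(seed)) stop("a seed is mandatory for stochastic stages",
                          call. = FALSE)
  cohort$n_patients <- n_patients
  cohort$seed <- as.integer(seed)
  validate_cohort_config(cohort)
  structure(list(n_patients = n_patients, seed = as.integer(seed),
                 outdir = outdir, stages = stages, cohort = cohort,
                 lod = lod, alpha = alpha,
                 min_members_per_strand = min_members_per_strand,
                 clonality_threshold = clonality_threshold,
                 mvaf_scope = mvaf_scope, filter = filter,
                 read_level = read_level,
                 consensus_depth = as.integer(consensus_depth),
                 resume = resume),
            class = "run_config")
}

write_stage_tsv <- function(obj, outdir, name) {
  if (is.null(outdir)) return(invisible(NULL))
  path <- file.path(outdir, name)
  data.table::fwrite(obj, path, sep = "\t")
  invisible(path)
}

# Read-level confirmation of one plasma variant through the duplex pipeline.
confirm_variant_read_level <- function(v, config, seed) {
  reads <- simulate_read_families(
    list(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt),
    depth = config$consensus_depth, alt_fraction = v$vaf,
    error_rate = 0.001,
    fragment_length_mixture = list(weights = c(1, 0), means = c(40, 40),
                                   sds = c(0, 0)),
    seed = seed)
  fs <- group_families(reads)
  pile <- consensus_pileup(family_consensus(fs, config$min_members_per_strand))
  pile <- annotate_reference(pile)
  calls <- call_plasma_variants(pile, null_background(), germline = NULL,
                                lod = config$lod, alpha = config$alpha)
  any(calls$chrom == v$chrom & calls$pos == v$pos & calls$alt == v$alt)
}

#' Run the full pipeline
#'
#' Executes the configured stages in dependency order and returns the stage
#' outputs plus a run manifest. With an output directory set, each stage's
#' tables are written as TSV and the manifest as JSON (written last); a
#' failed stage is recorded in the manifest before the error propagates.
#'
#' @param config a [run_config()].
#' @return list with `cohort`, `mutations`, `plasma`, `plasma_called`,
#'   `tumor_kept`, `filter_audit`, `results` (per-patient table),
#'   `mutation_status` (per tumor mutation: clonality and detection),
#'   `stats`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  manifest <- list(config = config_echo(config),
                   version = as.character(packageVersion("plasmatrace")),
                   stages = list())
  state <- list()
  written <- character(0)
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(e)
      if (!is.null(outdir)) write_manifest(manifest, written, outdir)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  if ("simulate" %in% config$stages) {
    state <- run_stage("simulate", function() {
      cc <- config$cohort
      if (isTRUE(config$resume) && !is.null(outdir) &&
          file.exists(file.path(outdir, "cohort.tsv"))) {
        cohort <- read_clinical_tsv(file.path(outdir, "cohort.tsv"))
        mutations <- as.data.frame(
          data.table::fread(file.path(outdir, "mutations.tsv")))
        plasma <- as.data.frame(
          data.table::fread(file.path(outdir, "plasma.tsv")))
      } else {
        cohort <- sample_cohort(cc, seed = config$seed)
        mutations <- sample_cohort_mutations(cohort, cc,
                                             seed = config$seed + 1L)
        plasma <- simulate_cohort_plasma(cohort, mutations, cc,
                                         seed = config$seed + 2L)
        written <<- c(written,
                      write_stage_tsv(cohort, outdir, "cohort.tsv"),
                      write_stage_tsv(mutations, outdir, "mutations.tsv"),
                      write_stage_tsv(plasma, outdir, "plasma.tsv"))
      }
      list(cohort = cohort, mutations = mutations, plasma = plasma)
    })
  }

  if ("filter" %in% config$stages) {
    state <- c(state, run_stage("filter", function() {
      cc <- config$cohort
      mut <- state$mutations
      with_seed(config$seed + 3L, {
        vaf_obs <- pmin(pmax(mut$tumor_vaf_true +
                               rnorm(nrow(mut), 0, cc$tumor_vaf_noise_sd),
                             0.001), 1)
        alt_reads <- rbinom(nrow(mut), cc$tumor_depth, vaf_obs)
        candidates <- data.frame(
          patient_id = mut$patient_id, gene = mut$gene, chrom = mut$chrom,
          pos = mut$pos, ref = mut$ref, alt = mut$alt, var_type = "SNV",
          depth = cc$tumor_depth, alt_reads = alt_reads,
          vaf = alt_reads / cc$tumor_depth,
          hq_alt_reads = rbinom(nrow(mut), alt_reads, 0.95),
          in_dbsnp = FALSE, in_cosmic = TRUE,
          source = "tissue", stringsAsFactors = FALSE)
        contexts <- data.frame(
          indel_reads_in_window = 0L, control_alt_fraction = 0,
          control_alt_quality_sum = 0, control_indel_reads_nearby = 0L,
          window_sequence = NA_character_,
          stringsAsFactors = FALSE)[rep(1L, nrow(mut)), , drop = FALSE]
        cascade <- apply_cascade(candidates, contexts, config$filter)
        list(tumor_candidates = candidates, tumor_kept = cascade$kept,
             filter_audit = cbind(candidates[, c("patient_id", "chrom",
                                                 "pos", "ref", "alt")],
                                  cascade$audit))
      })
    }))
    written <- c(written,
                 write_stage_tsv(state$tumor_kept, outdir, "tumor_kept.tsv"),
                 write_stage_tsv(state$filter_audit, outdir,
                                 "filter_audit.tsv"))
  }

  if ("concord" %in% config$stages) {
    state <- c(state, run_stage("concord", function() {
      cohort <- state$cohort
      plasma <- state$plasma
      # Plasma detection gate: allele fraction at or above the LOD, with
      # optional read-level confirmation through the duplex consensus.
      called <- plasma[plasma$vaf >= config$lod, , drop = FALSE]
      if (isTRUE(config$read_level) && nrow(called)) {
        ok <- vapply(seq_len(nrow(called)), function(i)
          confirm_variant_read_level(called[i, ], config,
                                     seed = config$seed + 100L + i),
          logical(1))
        called <- called[ok, , drop = FALSE]
      }
      tumor <- state$tumor_kept
      purity <- cohort$tumor_purity[match(tumor$patient_id,
                                          cohort$patient_id)]
      tumor$ccf <- compute_ccf(tumor$vaf, purity)
      status_rows <- list()
      res_rows <- list()
      for (i in seq_len(nrow(cohort))) {
        pid <- cohort$patient_id[i]
        tv <- tumor[tumor$patient_id == pid, , drop = FALSE]
        pv <- called[called$patient_id == pid, , drop = FALSE]
        part <- partition_variants(tv, pv)
        labels <- if (nrow(tv)) {
          classify_clonality(tv$ccf, config$clonality_threshold)
        } else character(0)
        detected <- if (nrow(tv)) {
          variant_key(tv$chrom, tv$pos, tv$ref, tv$alt) %in%
            c(part$overlapping$key)
        } else logical(0)
        if (nrow(tv)) {
          status_rows[[pid]] <- data.frame(
            patient_id = pid, gene = tv$gene, chrom = tv$chrom,
            pos = tv$pos, ref = tv$ref, alt = tv$alt, ccf = tv$ccf,
            clonal = labels == "clonal", detected = detected,
            stringsAsFactors = FALSE)
        }
        res_rows[[pid]] <- data.frame(
          cohort[i, , drop = FALSE],
          n_tumor = part$n_tumor, n_plasma = part$n_plasma,
          n_overlap = part$n_overlap,
          ctdna_positive = part$ctdna_positive,
          any_plasma_variant = part$n_plasma > 0L,
          tracing_category = if (part$n_tumor > 0L) {
            tracing_category(part)
          } else NA_character_,
          mvaf = mvaf(part, config$mvaf_scope),
          n_clonal = sum(labels == "clonal"),
          n_subclonal = sum(labels == "subclonal"),
          n_clonal_detected = sum(detected[labels == "clonal"]),
          n_subclonal_detected = sum(detected[labels == "subclonal"]),
          stringsAsFactors = FALSE)
      }
      list(plasma_called = called,
           results = do.call(rbind, c(res_rows, make.row.names = FALSE)),
           mutation_status = if (length(status_rows)) {
             do.call(rbind, c(status_rows, make.row.names = FALSE))
           } else NULL)
    }))
    written <- c(written,
                 write_stage_tsv(state$results, outdir, "results.tsv"),
                 write_stage_tsv(state$mutation_status, outdir,
                                 "mutation_status.tsv"))
  }

  if ("stats" %in% config$stages) {
    state <- c(state, run_stage("stats", function() {
      res <- state$results
      covs <- c("age_group", "t_stage", "n_stage", "m_stage", "hr_status",
                "her2_ihc", "ki67_group")
      uva <- lapply(covs, function(cv) {
        tryCatch(logistic_uva(res[res[[cv]] != "unknown", , drop = FALSE],
                              cv),
                 error = function(e) NULL)
      })
      uva_tab <- do.call(rbind, lapply(uva[!vapply(uva, is.null,
                                                   logical(1))],
        function(a) data.frame(covariate = a$covariate,
                               p_uva = a$p_value,
                               direction = a$direction,
                               stringsAsFactors = FALSE)))
      mva_tab <- tryCatch(logistic_mva(res, covs), error = function(e) NULL)
      gene_universe <- sort(unique(c(state$mutations$gene,
                                     state$plasma$gene)))
      freq_tissue <- gene_frequency_table(state$tumor_kept,
                                          res$patient_id,
                                          genes = gene_universe)
      freq_plasma <- gene_frequency_table(state$plasma_called,
                                          res$patient_id,
                                          genes = gene_universe)
      # Correlation over genes mutated in tumor tissue: blood-only
      # (hematopoietic) genes have no tissue frequency by construction and
      # are not part of the tumor-informed comparison.
      in_tissue <- freq_tissue > 0
      r2 <- tryCatch(pearson_r2(freq_tissue[in_tissue],
                                freq_plasma[in_tissue]),
                     error = function(e) NA_real_)
      rates <- if (!is.null(state$mutation_status)) {
        evaluable <- res$patient_id[res$ctdna_positive]
        clonal_tracing_rates(state$mutation_status[
          state$mutation_status$patient_id %in% evaluable, , drop = FALSE])
      } else NULL
      stage_group <- ifelse(res$tnm_stage == "IV", "IV/M1", "I-III/M0")
      mvaf_anova <- tryCatch(
        anova_oneway(res$mvaf, stage_group),
        error = function(e) NULL)
      list(stats = list(
        uva = uva_tab, mva = mva_tab,
        gene_freq = data.frame(gene = gene_universe,
                               tissue = as.numeric(freq_tissue),
                               plasma = as.numeric(freq_plasma),
                               stringsAsFactors = FALSE),
        gene_freq_r2 = r2,
        tracing_rates = rates,
        mvaf_anova = mvaf_anova,
        detection_rate = mean(res$ctdna_positive),
        any_plasma_rate = mean(res$any_plasma_variant)))
    }))
    if (!is.null(outdir)) {
      written <- c(written,
                   write_stage_tsv(state$stats$gene_freq, outdir,
                                   "gene_frequencies.tsv"))
      if (!is.null(state$stats$mva)) {
        written <- c(written, write_stage_tsv(state$stats$mva, outdir,
                                              "mva.tsv"))
      }
    }
  }

  manifest$written <- written
  if (!is.null(outdir)) write_manifest(manifest, written, outdir)
  state$manifest <- manifest
  state
}

config_echo <- function(config) {
  e <- unclass(config)
  e$cohort <- unclass(e$cohort)
  e$cohort$shedding <- unclass(e$cohort$shedding)
  e
}

write_manifest <- function(manifest, written, outdir) {
  written <- written[!vapply(written, is.null, logical(1))]
  manifest$checksums <- as.list(tools::md5sum(unlist(written)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(NULL)
}
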