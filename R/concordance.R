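# Tumor-plasma concordance and clonality -------------------------------------
#
# Per-patient matching of validated tumor-tissue variants against plasma
# variant calls by exact normalized key, yielding the overlapping /
# tissue-specific / blood-specific partition, tracing fraction and category,
# ctDNA positivity (tumor-derived mutations detectable in blood), maximal
# VAF, cancer cell fractions, and the clonal/subclonal split of tracing
# rates.

#' Partition tumor and plasma variant sets
#'
#' Variants are keyed with [variant_key()] (duplicates collapsed); the three
#' output sets are disjoint and exhaustive over the union. `ctdna_positive`
#' is true iff at least one tumor variant is found in plasma.
#'
#' @param tumor data.frame of validated tumor variants (`chrom`, `pos`,
#'   `ref`, `alt`, optionally `vaf` and annotation columns).
#' @param plasma data.frame of plasma variant calls (same key columns; `vaf`
#'   is carried into the partition for MVAF).
#' @return object of class `concordance_partition`: list with `overlapping`,
#'   `tissue_specific`, `blood_specific` data.frames, counts `n_tumor`,
#'   `n_plasma`, `n_overlap`, `tracing_fraction` (NA when `n_tumor` is 0),
#'   `ctdna_positive`.
#' @export
partition_variants <- function(tumor, plasma) {
  tkey <- if (nrow(tumor)) {
    variant_key(tumor$chrom, tumor$pos, tumor$ref, tumor$alt)
  } else character(0)
  pkey <- if (nrow(plasma)) {
    variant_key(plasma$chrom, plasma$pos, plasma$ref, plasma$alt)
  } else character(0)
  tumor <- tumor[!duplicated(tkey), , drop = FALSE]
  tkey <- unique(tkey)
  plasma <- plasma[!duplicated(pkey), , drop = FALSE]
  pkey <- unique(pkey)
  in_plasma <- tkey %in% pkey
  in_tumor <- pkey %in% tkey
  overlapping <- plasma[in_tumor, , drop = FALSE]
  overlapping$key <- pkey[in_tumor]
  tissue_specific <- tumor[!in_plasma, , drop = FALSE]
  if (nrow(tissue_specific)) tissue_specific$key <- tkey[!in_plasma]
  blood_specific <- plasma[!in_tumor, , drop = FALSE]
  if (nrow(blood_specific)) blood_specific$key <- pkey[!in_tumor]
  n_tumor <- length(tkey)
  n_overlap <- nrow(overlapping)
  structure(list(
    overlapping = overlapping,
    tissue_specific = tissue_specific,
    blood_specific = blood_specific,
    tumor_keys = tkey,
    n_tumor = n_tumor,
    n_plasma = length(pkey),
    n_overlap = n_overlap,
    tracing_fraction = if (n_tumor > 0) n_overlap / n_tumor else NA_real_,
    ctdna_positive = n_overlap > 0L
  ), class = "concordance_partition")
}

#' Tracing category of a partition
#'
#' `full` when every tumor variant is traced in plasma, `none` when none is,
#' `partial` otherwise. Undefined (an error) for patients without tumor
#' variants, mirroring their exclusion from concordance denominators.
#'
#' @param partition a `concordance_partition`.
#' @return one of `"full"`, `"partial"`, `"none"`.
#' @export
tracing_category <- function(partition) {
  stopifnot(inherits(partition, "concordance_partition"))
  if (partition$n_tumor == 0L) {
    stop("tracing category is undefined for a patient without tumor variants",
         call. = FALSE)
  }
  f <- partition$tracing_fraction
  if (f == 1) "full" else if (f == 0) "none" else "partial"
}

#' Maximal plasma variant allele frequency
#'
#' The tumor-burden proxy: maximum VAF among the patient's plasma variants.
#' By default only tumor-derived (overlapping) variants are in scope;
#' `"all_plasma"` additionally considers blood-specific variants.
#'
#' @param partition a `concordance_partition` whose plasma variants carry a
#'   `vaf` column.
#' @param scope `"tumor_derived_only"` (default) or `"all_plasma"`.
#' @return maximal VAF, or `NA` when the scope set is empty.
#' @export
mvaf <- function(partition, scope = c("tumor_derived_only", "all_plasma")) {
  stopifnot(inherits(partition, "concordance_partition"))
  scope <- match.arg(scope)
  vafs <- partition$overlapping$vaf
  if (scope == "all_plasma") {
    vafs <- c(vafs, partition$blood_specific$vaf)
  }
  if (length(vafs) == 0L) NA_real_ else max(vafs)
}

#' Cancer cell fraction from VAF
#'
#' Standard purity/copy-number correction for an autosomal heterozygous
#' mutation: `ccf = vaf * (purity * copy_number + (1 - purity) * 2) /
#' purity`, capped at 1. With purity 1 and copy number 2 this reduces to
#' `min(1, 2 * vaf)`.
#'
#' @param vaf variant allele frequency in `[0, 1]` (vectorized).
#' @param purity tumor purity in `(0, 1]`.
#' @param copy_number local total copy number (positive integer).
#' @return CCF in `[0, 1]`.
#' @export
compute_ccf <- function(vaf, purity, copy_number = 2L) {
  assert_fraction(vaf, "vaf")
  if (any(!is.finite(purity)) || any(purity <= 0) || any(purity > 1)) {
    stop("`purity` must lie in (0, 1]", call. = FALSE)
  }
  if (any(copy_number < 1)) stop("`copy_number` must be >= 1", call. = FALSE)
  pmin(1, vaf * (purity * copy_number + (1 - purity) * 2) / purity)
}

#' Clonal/subclonal classification of a patient's mutations
#'
#' A mutation is clonal iff its CCF is at least 75% (configurable) of the
#' patient's maximal CCF; the maximum itself therefore is always clonal and
#' at least one clonal label exists. Labels are invariant under any positive
#' rescaling of all CCFs.
#'
#' @param ccf numeric vector of per-mutation CCFs (one patient).
#' @param threshold fraction of the maximum defining clonality.
#' @return character vector of labels `"clonal"` / `"subclonal"`.
#' @export
classify_clonality <- function(ccf, threshold = 0.75) {
  if (length(ccf) == 0L) {
    stop("cannot classify clonality of an empty mutation list", call. = FALSE)
  }
  assert_fraction(threshold, "threshold", lo_open = TRUE)
  ifelse(ccf >= threshold * max(ccf), "clonal", "subclonal")
}

#' Pooled clonal vs subclonal tracing rates
#'
#' Given one row per tumor mutation of ctDNA-evaluable patients, with its
#' clonality label and whether it was detected in matched plasma, computes
#' pooled detected fractions per class plus the number of patients with at
#' least one detected mutation of each class. A class with zero mutations
#' yields an `NA` fraction and is listed in `undefined_classes`, never
#' reported as 0.
#'
#' @param mutations data.frame with columns `patient_id`, `clonal`
#'   (logical), `detected` (logical).
#' @return list with `clonal_detected_fraction`,
#'   `subclonal_detected_fraction`, `n_clonal`, `n_subclonal`,
#'   `patients_with_clonal_in_blood`, `patients_with_subclonal_in_blood`,
#'   `undefined_classes`.
#' @export
clonal_tracing_rates <- function(mutations) {
  stopifnot(all(c("patient_id", "clonal", "detected") %in% names(mutations)))
  cl <- mutations$clonal
  n_clonal <- sum(cl)
  n_subclonal <- sum(!cl)
  frac <- function(mask) {
    if (sum(mask) == 0L) NA_real_ else mean(mutations$detected[mask])
  }
  undef <- c(if (n_clonal == 0L) "clonal",
             if (n_subclonal == 0L) "subclonal")
  pat_with <- function(mask) {
    length(unique(mutations$patient_id[mask & mutations$detected]))
  }
  list(
    clonal_detected_fraction = frac(cl),
    subclonal_detected_fraction = frac(!cl),
    n_clonal = n_clonal,
    n_subclonal = n_subclonal,
    patients_with_clonal_in_blood = pat_with(cl),
    patients_with_subclonal_in_blood = pat_with(!cl),
    undefined_classes = undef %||% character(0)
  )
}
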