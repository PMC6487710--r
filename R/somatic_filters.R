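# Tissue somatic variant filter cascade --------------------------------------
#
# Post-caller filtering of candidate somatic variants from tumor tissue with
# a matched germline control. SNV rules (each an independent predicate; a
# candidate is kept iff none fires):
#   indel_window     more than 10 indel-bearing reads in the 11-bp window
#                    centered on the site
#   germline_evidence control sample carries >= 3% alternate reads, or >= 2%
#                    with summed alternate base quality above 80
#   dbsnp_not_cosmic present in dbSNP but absent from COSMIC
#   low_hq_support   fewer than 5 high-quality alternate reads (base quality
#                    >= 30 and mapping quality >= 30)
#   low_vaf          allele frequency below 1%
# Indel rules: control_indel (3 or more indel-supporting control reads at the
# site or within 40 bp) and low_complexity (homopolymer or short tandem
# repeat in the +/-40 bp window).

#' Filter thresholds
#'
#' All cascade thresholds as a named list; defaults are the reference
#' pipeline's values. Boundaries are exact as worded: `indel_window` fires
#' strictly above `indel_window_max`; `low_hq_support` fires strictly below
#' `min_hq_alt`; `low_vaf` fires strictly below `min_vaf` (a VAF of exactly
#' 1% is kept); `control_indel` fires at or above `control_indel_min`.
#'
#' @param indel_window_max maximum tolerated indel reads in the 11-bp window.
#' @param germline_af_high control alternate-read fraction that alone vetoes.
#' @param germline_af_low control fraction that vetoes together with quality.
#' @param germline_qual_sum control summed alt base quality threshold.
#' @param min_hq_alt minimum high-quality alternate reads.
#' @param min_vaf minimum allele frequency.
#' @param control_indel_min control indel reads (site +/- 40 bp) that veto.
#' @param homopolymer_min minimal homopolymer run length.
#' @param repeat_unit_max maximal tandem-repeat unit length considered.
#' @param repeat_min_copies minimal contiguous copies of a repeat unit.
#' @export
filter_thresholds <- function(indel_window_max = 10L,
                              germline_af_high = 0.03,
                              germline_af_low = 0.02,
                              germline_qual_sum = 80,
                              min_hq_alt = 5L,
                              min_vaf = 0.01,
                              control_indel_min = 3L,
                              homopolymer_min = 8L,
                              repeat_unit_max = 6L,
                              repeat_min_copies = 4L) {
  as.list(environment())
}

require_ctx <- function(ctx, fields) {
  for (f in fields) {
    if (is.null(ctx[[f]]) || (length(ctx[[f]]) == 1L && is.na(ctx[[f]]))) {
      stop(sprintf("site context field '%s' is missing", f), call. = FALSE)
    }
  }
}

#' Low-complexity / short-tandem-repeat detector
#'
#' Flags a window containing a homopolymer run of at least
#' `homopolymer_min` bases, or a tandem repeat with unit length 2 to
#' `repeat_unit_max` present in at least `repeat_min_copies` contiguous
#' copies. `N` bases are permitted in the sequence but never participate in
#' a repeat.
#'
#' @param window_sequence character string over A/C/G/T/N.
#' @param homopolymer_min,repeat_unit_max,repeat_min_copies thresholds, see
#'   [filter_thresholds()].
#' @return logical scalar.
#' @examples
#' is_low_complexity("ACGTAAAAAAAAGT")   # homopolymer run of 8
#' is_low_complexity("ACGTACGTAC")       # 2.5 copies of ACGT: fine
#' @export
is_low_complexity <- function(window_sequence,
                              homopolymer_min = 8L,
                              repeat_unit_max = 6L,
                              repeat_min_copies = 4L) {
  s <- toupper(window_sequence)
  if (grepl("[^ACGTN]", s)) {
    stop("window sequence contains symbols outside {A,C,G,T,N}",
         call. = FALSE)
  }
  if (grepl(sprintf("([ACGT])\\1{%d,}", homopolymer_min - 1L), s,
            perl = TRUE)) {
    return(TRUE)
  }
  for (u in 2:repeat_unit_max) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", u, repeat_min_copies - 1L)
    if (grepl(pat, s, perl = TRUE)) return(TRUE)
  }
  FALSE
}

#' Filter one candidate somatic SNV
#'
#' Evaluates the five SNV rules as independent predicates; the verdict's
#' `reasons` set contains every rule that fired and the candidate is kept if
#' and only if the set is empty. A missing context field is an explicit
#' error, never a silent pass.
#'
#' @param candidate list or single-row data.frame with at least `vaf` and
#'   `hq_alt_reads`, plus `in_dbsnp`/`in_cosmic` flags (or a `db_flags` list).
#' @param ctx site context: `indel_reads_in_window`, `control_alt_fraction`,
#'   `control_alt_quality_sum`.
#' @param thresholds from [filter_thresholds()].
#' @return list with `kept` (logical) and `reasons` (character vector).
#' @export
filter_snv <- function(candidate, ctx, thresholds = filter_thresholds()) {
  cand <- as.list(candidate)
  if (!is.null(cand$db_flags)) cand <- c(cand, cand$db_flags)
  require_ctx(ctx, c("indel_reads_in_window", "control_alt_fraction",
                     "control_alt_quality_sum"))
  require_ctx(cand, c("vaf", "hq_alt_reads", "in_dbsnp", "in_cosmic"))
  th <- thresholds
  reasons <- character(0)
  if (ctx$indel_reads_in_window > th$indel_window_max) {
    reasons <- c(reasons, "indel_window")
  }
  if (ctx$control_alt_fraction >= th$germline_af_high ||
      (ctx$control_alt_fraction >= th$germline_af_low &&
       ctx$control_alt_quality_sum > th$germline_qual_sum)) {
    reasons <- c(reasons, "germline_evidence")
  }
  if (isTRUE(cand$in_dbsnp) && !isTRUE(cand$in_cosmic)) {
    reasons <- c(reasons, "dbsnp_not_cosmic")
  }
  if (cand$hq_alt_reads < th$min_hq_alt) {
    reasons <- c(reasons, "low_hq_support")
  }
  if (cand$vaf < th$min_vaf) {
    reasons <- c(reasons, "low_vaf")
  }
  list(kept = length(reasons) == 0L, reasons = reasons)
}

#' Filter one candidate somatic indel
#'
#' @param candidate list or single-row data.frame (`var_type` "indel").
#' @param ctx site context: `control_indel_reads_nearby` (maximum
#'   indel-supporting read count in the control at the site or within 40 bp)
#'   and `window_sequence` (reference bases +/- 40 bp).
#' @param thresholds from [filter_thresholds()].
#' @return list with `kept` and `reasons`.
#' @export
filter_indel <- function(candidate, ctx, thresholds = filter_thresholds()) {
  require_ctx(ctx, c("control_indel_reads_nearby", "window_sequence"))
  th <- thresholds
  reasons <- character(0)
  if (ctx$control_indel_reads_nearby >= th$control_indel_min) {
    reasons <- c(reasons, "control_indel")
  }
  if (is_low_complexity(ctx$window_sequence, th$homopolymer_min,
                        th$repeat_unit_max, th$repeat_min_copies)) {
    reasons <- c(reasons, "low_complexity")
  }
  list(kept = length(reasons) == 0L, reasons = reasons)
}

#' Apply the full filter cascade
#'
#' Routes each candidate to [filter_snv()] or [filter_indel()] by its
#' `var_type` and collects one audit row per candidate. The cascade is
#' idempotent: re-filtering the kept set (with its contexts) changes nothing,
#' and since rules are independent predicates, evaluation order never affects
#' a verdict.
#'
#' @param candidates data.frame of candidate variants.
#' @param contexts data.frame of site contexts, row-aligned with
#'   `candidates`.
#' @param thresholds from [filter_thresholds()].
#' @return list with `kept` (data.frame subset of `candidates`) and `audit`
#'   (data.frame with `kept` and comma-joined `reasons` per candidate).
#' @export
apply_cascade <- function(candidates, contexts,
                          thresholds = filter_thresholds()) {
  n <- nrow(candidates)
  if (!is.null(contexts) && nrow(contexts) != n) {
    stop("`contexts` must align row-by-row with `candidates`", call. = FALSE)
  }
  if (n == 0L) {
    return(list(kept = candidates,
                audit = data.frame(kept = logical(0),
                                   reasons = character(0))))
  }
  kept <- logical(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    cand <- candidates[i, , drop = FALSE]
    ctx <- as.list(contexts[i, , drop = FALSE])
    v <- if (identical(cand$var_type, "indel")) {
      filter_indel(cand, ctx, thresholds)
    } else {
      filter_snv(cand, ctx, thresholds)
    }
    kept[i] <- v$kept
    reasons[i] <- paste(v$reasons, collapse = ",")
  }
  list(kept = candidates[kept, , drop = FALSE],
       audit = data.frame(kept = kept, reasons = reasons,
                          stringsAsFactors = FALSE))
}

#' Normalize a variant to its minimal left-aligned representation
#'
#' Trims the shared allele suffix, then the shared prefix (advancing `pos`),
#' so that keys compare equal whenever two records describe the same
#' haplotype change. When `fetch_ref` is supplied (a `function(chrom, pos)`
#' returning one base), indels are additionally shifted left while the
#' haplotype is preserved.
#'
#' @param chrom,pos,ref,alt scalar variant fields (1-based `pos`).
#' @param fetch_ref optional reference-base accessor for full left-shifting.
#' @return list with normalized `chrom`, `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(chrom, pos, ref, alt, fetch_ref = NULL) {
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  # Trim common suffix.
  while (length(r) > 1L && length(a) > 1L &&
         r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  # Trim common prefix (keeping one anchor base for indels).
  while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1L
  }
  if (!is.null(fetch_ref)) {
    # Left-shift pure indels while the flanking base matches.
    while (length(r) != length(a) && r[length(r)] == a[length(a)] &&
           pos > 1L) {
      prev <- fetch_ref(chrom, pos - 1L)
      r <- c(prev, r[-length(r)])
      a <- c(prev, a[-length(a)])
      pos <- pos - 1L
    }
  }
  list(chrom = chrom, pos = as.integer(pos),
       ref = paste(r, collapse = ""), alt = paste(a, collapse = ""))
}

#' Canonical variant key
#'
#' Exact-equality key `chrom:pos:ref:alt` after [normalize_variant()]
#' trimming; vectorized.
#'
#' @param chrom,pos,ref,alt vectors of variant fields.
#' @return character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  n <- length(pos)
  simple <- nchar(ref) == 1L & nchar(alt) == 1L
  if (all(simple)) {
    return(paste(chrom, pos, ref, alt, sep = ":"))
  }
  out <- character(n)
  for (i in seq_len(n)) {
    v <- normalize_variant(chrom[i], pos[i], ref[i], alt[i])
    out[i] <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  }
  out
}
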