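# UMI/duplex consensus variant detection -------------------------------------
#
# Reads sharing a UID and exact fragment coordinates form a family; each
# family derives from one original cfDNA duplex molecule, with `top` and
# `bottom` members coming from its two physical strands. Per-strand majority
# consensus suppresses PCR/sequencing errors; a duplex call additionally
# requires the two strand consensuses to agree. Candidate plasma variants are
# then gated on a limit of detection (default 0.5% allele fraction), a
# one-sided binomial test against a background error model built from control
# plasma, and absence from the matched germline set.

#' Group tagged reads into UID families
#'
#' Families are keyed by exact equality of `(uid, chrom, fragment_start,
#' fragment_end)`; no fuzzy UID matching is attempted. Reads with a missing
#' or empty UID are rejected with a counted warning, never silently dropped.
#'
#' @param reads data.frame of tagged reads (see [simulate_read_families()]).
#' @return object of class `family_set`: list with `reads` (the accepted
#'   reads, annotated with `family_id`), `families` (one row per family with
#'   per-strand member counts), and `n_rejected`.
#' @export
group_families <- function(reads) {
  dt <- as.data.table(reads)
  if (nrow(dt) == 0L) {
    fam <- data.table(family_id = integer(0), uid = character(0),
                      chrom = character(0), fragment_start = integer(0),
                      fragment_end = integer(0), n_top = integer(0),
                      n_bottom = integer(0))
    return(structure(list(reads = dt, families = fam, n_rejected = 0L),
                     class = "family_set"))
  }
  bad <- is.na(dt$uid) | dt$uid == ""
  if (any(bad)) {
    warning(sprintf("%d read(s) without a UID were rejected", sum(bad)),
            call. = FALSE)
    dt <- dt[!bad]
  }
  dt[, family_id := .GRP, by = .(uid, chrom, fragment_start, fragment_end)]
  fam <- dt[, .(uid = uid[1], chrom = chrom[1],
                fragment_start = fragment_start[1],
                fragment_end = fragment_end[1],
                n_top = sum(strand_orientation == "top"),
                n_bottom = sum(strand_orientation == "bottom")),
            by = family_id]
  structure(list(reads = dt, families = fam, n_rejected = sum(bad)),
            class = "family_set")
}

# Long per-base table: one row per (read, position).
reads_to_long <- function(dt) {
  if (nrow(dt) == 0L) {
    return(data.table(family_id = integer(0), strand = character(0),
                      chrom = character(0), pos = integer(0),
                      base = character(0), qual = integer(0)))
  }
  lens <- dt$fragment_end - dt$fragment_start + 1L
  long <- data.table(
    family_id = rep(dt$family_id, lens),
    strand = rep(dt$strand_orientation, lens),
    chrom = rep(dt$chrom, lens),
    pos = unlist(lapply(seq_len(nrow(dt)), function(i)
      dt$fragment_start[i]:dt$fragment_end[i])),
    base = unlist(strsplit(dt$bases, "", fixed = TRUE)),
    qual = unlist(chr_to_phred(dt$base_qualities))
  )
  long
}

#' Per-family strand-aware consensus
#'
#' For each family, strand and position, the consensus allele is the majority
#' base among member reads, with summed base quality breaking ties. A strand
#' with fewer than `min_members_per_strand` members contributes no consensus.
#' The duplex allele at a position is defined only where both strand
#' consensuses exist and agree.
#'
#' @param family_set from [group_families()].
#' @param min_members_per_strand minimum reads per strand (default 1).
#' @return data.table with one row per (family, position): `family_id`,
#'   `chrom`, `pos`, `top_allele`, `bottom_allele` (NA where absent), and
#'   `duplex_allele` (NA unless both strands agree).
#' @export
family_consensus <- function(family_set, min_members_per_strand = 1L) {
  stopifnot(inherits(family_set, "family_set"),
            min_members_per_strand >= 1L)
  long <- reads_to_long(family_set$reads)
  if (nrow(long) == 0L) {
    return(data.table(family_id = integer(0), chrom = character(0),
                      pos = integer(0), top_allele = character(0),
                      bottom_allele = character(0),
                      duplex_allele = character(0)))
  }
  votes <- long[, .(n = .N, q = sum(qual)),
                by = .(family_id, strand, chrom, pos, base)]
  setorder(votes, family_id, strand, pos, -n, -q, base)
  maj <- votes[, .SD[1L], by = .(family_id, strand, chrom, pos)]
  # Apply the per-strand member-count gate.
  fam <- family_set$families
  maj <- merge(maj, fam[, .(family_id, n_top, n_bottom)], by = "family_id")
  maj <- maj[(strand == "top" & n_top >= min_members_per_strand) |
             (strand == "bottom" & n_bottom >= min_members_per_strand)]
  wide <- dcast(maj, family_id + chrom + pos ~ strand, value.var = "base")
  if (!"top" %in% names(wide)) wide[, top := NA_character_]
  if (!"bottom" %in% names(wide)) wide[, bottom := NA_character_]
  setnames(wide, c("top", "bottom"), c("top_allele", "bottom_allele"))
  wide[, duplex_allele := fifelse(!is.na(top_allele) & !is.na(bottom_allele) &
                                    top_allele == bottom_allele,
                                  top_allele, NA_character_)]
  wide[]
}

#' Aggregate family consensuses into per-site consensus calls
#'
#' At each site, `consensus_depth` is the number of families with duplex
#' coverage (a consensus from both strands, agreeing or not); for each allele,
#' `top_support`/`bottom_support` count families whose strand consensus equals
#' the allele, `duplex` flags support from both strands, and
#' `allele_fraction` is the fraction of duplex-covered families whose duplex
#' consensus equals the allele.
#'
#' @param fc family-level consensus from [family_consensus()].
#' @return data.frame of consensus calls, one row per (site, allele).
#' @export
consensus_pileup <- function(fc) {
  fc <- as.data.table(fc)
  if (nrow(fc) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      allele = character(0), top_support = integer(0),
                      bottom_support = integer(0), duplex = logical(0),
                      consensus_depth = integer(0),
                      allele_fraction = numeric(0)))
  }
  depth <- fc[!is.na(top_allele) & !is.na(bottom_allele),
              .(consensus_depth = .N), by = .(chrom, pos)]
  sup_top <- fc[!is.na(top_allele), .(top_support = .N),
                by = .(chrom, pos, allele = top_allele)]
  sup_bot <- fc[!is.na(bottom_allele), .(bottom_support = .N),
                by = .(chrom, pos, allele = bottom_allele)]
  sup_dup <- fc[!is.na(duplex_allele), .(duplex_support = .N),
                by = .(chrom, pos, allele = duplex_allele)]
  out <- merge(sup_top, sup_bot, by = c("chrom", "pos", "allele"),
               all = TRUE)
  out <- merge(out, sup_dup, by = c("chrom", "pos", "allele"), all = TRUE)
  for (cc in c("top_support", "bottom_support", "duplex_support")) {
    out[is.na(get(cc)), (cc) := 0L]
  }
  out <- merge(out, depth, by = c("chrom", "pos"), all.x = TRUE)
  out[is.na(consensus_depth), consensus_depth := 0L]
  out[, duplex := top_support >= 1L & bottom_support >= 1L]
  out[, allele_fraction := fifelse(consensus_depth > 0,
                                   duplex_support / consensus_depth, 0)]
  setorder(out, chrom, pos, -duplex_support)
  as.data.frame(out)
}

#' Annotate a consensus pileup with reference alleles
#'
#' @param pileup from [consensus_pileup()].
#' @param ref_fun function(chrom, pos) returning reference bases; defaults to
#'   the synthetic reference hash [ref_base()].
#' @return pileup with `ref` and `is_alt` columns.
#' @export
annotate_reference <- function(pileup, ref_fun = ref_base) {
  pileup$ref <- ref_fun(pileup$chrom, pileup$pos)
  pileup$is_alt <- pileup$allele != pileup$ref
  pileup
}

#' Background error model from control plasma
#'
#' Pools alternate-allele duplex family counts across control samples into
#' per-site error-fraction estimates `(alt + a) / (depth + 2a)` with
#' pseudocount `a`; a per-substitution-class table (e.g. `C>T`) serves as
#' fallback for sites absent from the controls, and a global floor covers
#' unseen classes.
#'
#' @param controls list of reference-annotated consensus pileups (see
#'   [annotate_reference()]), one per control sample.
#' @param pseudocount pseudocount `a` (default 0.5).
#' @return object of class `background_model`.
#' @export
build_background <- function(controls, pseudocount = 0.5) {
  if (length(controls) == 0L) {
    stop(paste("no control samples supplied; use null_background() for the",
               "packaged null model"), call. = FALSE)
  }
  pooled <- rbindlist(lapply(controls, as.data.table), fill = TRUE)
  if (!"ref" %in% names(pooled)) {
    stop("control pileups must be annotated with annotate_reference()",
         call. = FALSE)
  }
  a <- pseudocount
  site_depth <- pooled[allele == ref, .(depth = sum(consensus_depth)),
                       by = .(chrom, pos, ref)]
  # Also count depth at sites that only appear through alt rows.
  alt <- pooled[is_alt == TRUE,
                .(alt_n = sum(duplex_support),
                  depth_n = sum(consensus_depth)),
                by = .(chrom, pos, ref, alt = allele)]
  site <- alt[, .(chrom, pos, ref, alt, alt_n, depth_n,
                  rate = (alt_n + a) / (depth_n + 2 * a))]
  pooled[, subst_class := paste(ref, allele, sep = ">")]
  cls <- pooled[is_alt == TRUE,
                .(alt_n = sum(duplex_support)),
                by = .(class = subst_class)]
  total_depth <- sum(site_depth$depth)
  cls[, rate := (alt_n + a) / (max(total_depth, 1) + 2 * a)]
  floor_rate <- a / (max(total_depth, mean(pooled$consensus_depth), 1) + 2 * a)
  structure(list(site = site, class = cls, floor = floor_rate,
                 pseudocount = a, total_depth = total_depth),
            class = "background_model")
}

#' @rdname build_background
#' @param assumed_depth notional control depth behind the floor rate.
#' @export
null_background <- function(pseudocount = 0.5, assumed_depth = 1000L) {
  structure(list(
    site = data.table(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      alt_n = integer(0), depth_n = integer(0),
                      rate = numeric(0)),
    class = data.table(class = character(0), alt_n = integer(0),
                       rate = numeric(0)),
    floor = pseudocount / (assumed_depth + 2 * pseudocount),
    pseudocount = pseudocount, total_depth = 0L
  ), class = "background_model")
}

#' Look up background error fractions
#'
#' @param background a `background_model`.
#' @param chrom,pos,ref,alt vectors describing candidate substitutions.
#' @return numeric vector of error fractions (site estimate if available,
#'   else substitution-class estimate, else the model floor).
#' @export
background_rate <- function(background, chrom, pos, ref, alt) {
  stopifnot(inherits(background, "background_model"))
  n <- length(pos)
  out <- rep(background$floor, n)
  cls_key <- paste0(ref, ">", alt)
  m <- match(cls_key, background$class$class)
  out[!is.na(m)] <- background$class$rate[m[!is.na(m)]]
  site_key <- paste(chrom, pos, ref, alt, sep = ":")
  bg_key <- paste(background$site$chrom, background$site$pos,
                  background$site$ref, background$site$alt, sep = ":")
  m2 <- match(site_key, bg_key)
  out[!is.na(m2)] <- background$site$rate[m2[!is.na(m2)]]
  out
}

#' Call plasma variants from consensus calls
#'
#' A candidate (non-reference) allele is emitted if and only if it (a) has
#' duplex support, (b) reaches the limit of detection in allele fraction,
#' (c) significantly exceeds the background error fraction at its site under
#' a one-sided exact binomial test at level `alpha`, and (d) is absent from
#' the matched germline variant set.
#'
#' @param calls reference-annotated consensus pileup
#'   (see [annotate_reference()]).
#' @param background a `background_model`.
#' @param germline data.frame of germline variants with `chrom`, `pos`,
#'   `ref`, `alt` (or `NULL` for none).
#' @param lod minimal reliably detectable allele fraction, in (0, 1).
#' @param alpha one-sided binomial test level.
#' @return data.frame of emitted variant calls (`chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `alt_reads`, `vaf`, `p_background`, `source`), with an `audit`
#'   attribute listing every candidate and its rejection reasons.
#' @export
call_plasma_variants <- function(calls, background, germline = NULL,
                                 lod = 0.005, alpha = 0.01) {
  assert_fraction(lod, "lod", lo_open = TRUE, hi_open = TRUE)
  assert_fraction(alpha, "alpha", lo_open = TRUE, hi_open = TRUE)
  if (!"ref" %in% names(calls)) {
    stop("`calls` must be annotated with annotate_reference()", call. = FALSE)
  }
  cand <- as.data.table(calls)[is_alt == TRUE &
                                 (top_support + bottom_support) > 0L]
  if (nrow(cand) == 0L) {
    empty <- empty_call_frame()
    attr(empty, "audit") <- data.frame(chrom = character(0), pos = integer(0),
                                       ref = character(0), alt = character(0),
                                       reasons = character(0))
    return(empty)
  }
  bg <- background_rate(background, cand$chrom, cand$pos, cand$ref,
                        cand$allele)
  p_bg <- pbinom(cand$duplex_support - 1L, cand$consensus_depth, bg,
                 lower.tail = FALSE)
  gl_key <- if (!is.null(germline) && nrow(germline)) {
    paste(germline$chrom, germline$pos, germline$ref, germline$alt, sep = ":")
  } else character(0)
  key <- paste(cand$chrom, cand$pos, cand$ref, cand$allele, sep = ":")
  reasons <- mapply(function(dup, af, p, in_gl) {
    r <- character(0)
    if (!dup) r <- c(r, "not_duplex")
    if (af < lod) r <- c(r, "below_lod")
    if (p >= alpha) r <- c(r, "background")
    if (in_gl) r <- c(r, "germline")
    paste(r, collapse = ",")
  }, cand$duplex, cand$allele_fraction, p_bg, key %in% gl_key)
  reasons <- as.character(reasons)
  kept <- reasons == ""
  nk <- sum(kept)
  out <- data.frame(
    chrom = cand$chrom[kept], pos = cand$pos[kept], ref = cand$ref[kept],
    alt = cand$allele[kept], var_type = rep("SNV", nk),
    depth = cand$consensus_depth[kept], alt_reads = cand$duplex_support[kept],
    vaf = cand$allele_fraction[kept], p_background = p_bg[kept],
    source = rep("plasma", nk), stringsAsFactors = FALSE
  )
  attr(out, "audit") <- data.frame(
    chrom = cand$chrom, pos = cand$pos, ref = cand$ref, alt = cand$allele,
    vaf = cand$allele_fraction, p_background = p_bg, reasons = reasons,
    stringsAsFactors = FALSE
  )
  out
}

empty_call_frame <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), var_type = character(0), depth = integer(0),
             alt_reads = integer(0), vaf = numeric(0),
             p_background = numeric(0), source = character(0),
             stringsAsFactors = FALSE)
}
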