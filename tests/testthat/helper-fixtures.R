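# Shared fixtures and independent oracles, all built in code.

# A handcrafted duplex read pair (same molecule, both strands).
make_duplex_pair <- function(uid = "U1", chrom = "syn1", start = 101L,
                             seq = NULL) {
  len <- if (is.null(seq)) 10L else nchar(seq)
  seq <- seq %||% paste(ref_base(chrom, start:(start + len - 1L)),
                        collapse = "")
  data.frame(
    uid = uid, chrom = chrom, fragment_start = start,
    fragment_end = start + nchar(seq) - 1L,
    strand_orientation = c("top", "bottom"),
    bases = seq, base_qualities = strrep("F", nchar(seq)),
    mapping_quality = 60L, stringsAsFactors = FALSE
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Build one consensus-pileup row directly (for gate tests).
make_call_row <- function(chrom = "syn1", pos = 500L, ref = "A",
                          allele = "T", depth = 1000L, support = 20L,
                          duplex = TRUE) {
  data.frame(
    chrom = chrom, pos = pos, allele = allele,
    top_support = if (duplex) support else support,
    bottom_support = if (duplex) support else 0L,
    duplex_support = if (duplex) support else 0L,
    consensus_depth = depth, duplex = duplex,
    allele_fraction = if (duplex) support / depth else 0,
    ref = ref, is_alt = allele != ref,
    stringsAsFactors = FALSE
  )
}

# Brute-force low-complexity oracle: scan every substring.
oracle_low_complexity <- function(s, homopolymer_min = 8L,
                                  repeat_unit_max = 6L, min_copies = 4L) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  run <- 1L
  for (i in seq_len(n - 1L)) {
    if (ch[i + 1L] == ch[i] && ch[i] != "N") run <- run + 1L else run <- 1L
    if (run >= homopolymer_min) return(TRUE)
  }
  for (u in 2:repeat_unit_max) {
    need <- u * min_copies
    if (need > n) next
    for (start in 1:(n - need + 1L)) {
      unit <- ch[start:(start + u - 1L)]
      if (any(unit == "N")) next
      ok <- TRUE
      for (cp in 1:(min_copies - 1L)) {
        blk <- ch[(start + cp * u):(start + (cp + 1L) * u - 1L)]
        if (!identical(blk, unit)) { ok <- FALSE; break }
      }
      if (ok) return(TRUE)
    }
  }
  FALSE
}

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# A clean SNV candidate + context that passes every filter rule.
clean_candidate <- function(...) {
  out <- list(chrom = "syn1", pos = 1000L, ref = "A", alt = "T",
              var_type = "SNV", depth = 500L, alt_reads = 50L, vaf = 0.1,
              hq_alt_reads = 45L, in_dbsnp = FALSE, in_cosmic = FALSE)
  utils::modifyList(out, list(...))
}

clean_context <- function(...) {
  out <- list(indel_reads_in_window = 0L, control_alt_fraction = 0,
              control_alt_quality_sum = 0, control_indel_reads_nearby = 0L,
              window_sequence = "ACGTGCTAGCTTGCAACGGATCCGATCGTTAGC")
  utils::modifyList(out, list(...))
}

# Random variant frame for partition / io tests.
random_variants <- function(n, max_pos = 50L, patient_id = NULL) {
  if (n == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      vaf = numeric(0), stringsAsFactors = FALSE))
  }
  pos <- sample.int(max_pos, n, replace = TRUE)
  ref <- ref_base("syn1", pos)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
  out <- data.frame(chrom = "syn1", pos = pos, ref = ref, alt = alt,
                    vaf = runif(n, 0.001, 0.5), stringsAsFactors = FALSE)
  if (!is.null(patient_id)) out$patient_id <- patient_id
  out
}
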