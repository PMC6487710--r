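# File-format I/O -------------------------------------------------------------
#
# Minimal, text-only interchange: a VCF 4.2 subset (CHROM POS ID REF ALT QUAL
# FILTER INFO with DP/AF/GENE/ORIGIN INFO keys), SAM for UID-tagged reads
# (UID in the RX tag, fragment coordinates in POS/TLEN), and TSV for tables.
# Coordinates are 1-based inclusive in memory and on disk for both formats.

vcf_info_keys <- c("DP", "AF", "GENE", "ORIGIN")

#' Write variants to a minimal VCF 4.2 file
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt` and
#'   optionally `depth`, `vaf`, `gene`, `origin`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=plasmatrace-%s", as.character(packageVersion("plasmatrace"))),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Consensus family depth\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"Variant origin\">",
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO"), collapse = "\t"))
  )
  rows <- character(0)
  if (nrow(variants)) {
    info <- vapply(seq_len(nrow(variants)), function(i) {
      parts <- character(0)
      if (!is.null(variants$depth)) {
        parts <- c(parts, sprintf("DP=%d", as.integer(variants$depth[i])))
      }
      if (!is.null(variants$vaf)) {
        parts <- c(parts, sprintf("AF=%s",
                                  format(variants$vaf[i], digits = 10)))
      }
      if (!is.null(variants$gene)) {
        parts <- c(parts, sprintf("GENE=%s", variants$gene[i]))
      }
      if (!is.null(variants$origin)) {
        parts <- c(parts, sprintf("ORIGIN=%s", variants$origin[i]))
      }
      if (length(parts)) paste(parts, collapse = ";") else "."
    }, character(1))
    rows <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                    variants$chrom, as.integer(variants$pos), variants$ref,
                    variants$alt, info)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

parse_info_field <- function(info) {
  out <- list(depth = NA_integer_, vaf = NA_real_, gene = NA_character_,
              origin = NA_character_)
  if (is.na(info) || info == ".") return(out)
  for (kv in strsplit(info, ";", fixed = TRUE)[[1]]) {
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) next
    key <- substr(kv, 1, eq - 1)
    val <- substr(kv, eq + 1, nchar(kv))
    if (key == "DP") out$depth <- as.integer(val)
    if (key == "AF") out$vaf <- as.numeric(val)
    if (key == "GENE") out$gene <- val
    if (key == "ORIGIN") out$origin <- val
  }
  out
}

#' Read variants from a minimal VCF file
#'
#' Supports the subset written by [write_variants_vcf()]; `read(write(x))`
#' is the identity on the supported fields. Multi-allelic rows are split
#' into biallelic records (record count conserved per alternate allele).
#' A malformed data line raises an error naming its line number.
#'
#' @param path VCF path.
#' @return data.frame of variants.
#' @export
read_variants_vcf <- function(path) {
  lines <- readLines(path)
  is_data <- !startsWith(lines, "#") & nzchar(lines)
  out <- list()
  for (i in which(is_data)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8L) {
      stop(sprintf("malformed VCF line %d: expected 8 fields, got %d",
                   i, length(f)), call. = FALSE)
    }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) {
      stop(sprintf("malformed VCF line %d: POS is not an integer", i),
           call. = FALSE)
    }
    info <- parse_info_field(f[8])
    for (alt in strsplit(f[5], ",", fixed = TRUE)[[1]]) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = f[1], pos = pos, ref = f[4], alt = alt,
        depth = info$depth, vaf = info$vaf, gene = info$gene,
        origin = info$origin, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      depth = integer(0), vaf = numeric(0),
                      gene = character(0), origin = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Read or write variants in VCF or TSV form
#'
#' @param path file path.
#' @param format `"vcf"` or `"tsv"`.
#' @param variants data.frame (for writing).
#' @return data.frame (read) or the path invisibly (write).
#' @export
read_variants <- function(path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "vcf") read_variants_vcf(path)
  else as.data.frame(data.table::fread(path, sep = "\t"))
}

#' @rdname read_variants
#' @export
write_variants <- function(variants, path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "vcf") write_variants_vcf(variants, path)
  else {
    data.table::fwrite(variants, path, sep = "\t")
    invisible(path)
  }
}

#' Write UID-tagged reads as SAM
#'
#' Single-end records, one per read: POS is the fragment start, TLEN the
#' signed fragment length (negative for bottom-strand reads, whose FLAG also
#' carries 0x10), CIGAR a full-length match, and the UID in the `RX` tag.
#'
#' @param reads data.frame of tagged reads (see [simulate_read_families()]).
#' @param path output path.
#' @param contig_lengths named integer vector for the `@SQ` header lines;
#'   defaults to the synthetic contigs.
#' @return `path`, invisibly.
#' @export
write_reads_sam <- function(reads, path,
                            contig_lengths = c(syn1 = 5000000L,
                                               syn2 = 5000000L,
                                               syn3 = 5000000L,
                                               syn4 = 5000000L)) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  rows <- character(0)
  if (nrow(reads)) {
    len <- reads$fragment_end - reads$fragment_start + 1L
    bottom <- reads$strand_orientation == "bottom"
    flag <- ifelse(bottom, 16L, 0L)
    tlen <- ifelse(bottom, -len, len)
    qname <- sprintf("%s.%d", reads$uid, seq_len(nrow(reads)))
    rows <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t%d\t%s\t%s\tRX:Z:%s",
                    qname, flag, reads$chrom,
                    as.integer(reads$fragment_start),
                    as.integer(reads$mapping_quality), len, tlen,
                    reads$bases, reads$base_qualities, reads$uid)
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read UID-tagged reads from SAM
#'
#' Parses the single-end convention of [write_reads_sam()]: UID from the
#' `RX` tag, strand orientation from FLAG bit 0x10, fragment end from POS
#' and sequence length. Records without an RX tag get an empty UID (and are
#' later rejected, with a count, by [group_families()]).
#'
#' @param path SAM path.
#' @return data.frame of tagged reads.
#' @export
read_reads_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(uid = character(0), chrom = character(0),
                      fragment_start = integer(0), fragment_end = integer(0),
                      strand_orientation = character(0), bases = character(0),
                      base_qualities = character(0),
                      mapping_quality = integer(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 11L)
  if (length(bad)) {
    stop(sprintf("malformed SAM record at data line %d", bad[1]),
         call. = FALSE)
  }
  get <- function(i) vapply(parts, `[[`, character(1), i)
  flag <- as.integer(get(2))
  seqs <- get(10)
  pos <- as.integer(get(4))
  rx <- vapply(parts, function(p) {
    tag <- p[startsWith(p, "RX:Z:")]
    if (length(tag)) substring(tag[1], 6L) else ""
  }, character(1))
  data.frame(
    uid = rx, chrom = get(3), fragment_start = pos,
    fragment_end = pos + nchar(seqs) - 1L,
    strand_orientation = ifelse(bitwAnd(flag, 16L) > 0L, "bottom", "top"),
    bases = seqs, base_qualities = get(11),
    mapping_quality = as.integer(get(5)), stringsAsFactors = FALSE
  )
}

#' Write / read the per-patient clinical table
#'
#' @param cohort data.frame from [sample_cohort()].
#' @param path TSV path.
#' @return path invisibly (write) or data.frame (read).
#' @export
write_clinical_tsv <- function(cohort, path) {
  data.table::fwrite(cohort, path, sep = "\t")
  invisible(path)
}

#' @rdname write_clinical_tsv
#' @export
read_clinical_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
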