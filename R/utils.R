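#' @importFrom stats rbinom rpois runif rnorm rlnorm plogis pbinom pchisq
#'   chisq.test glm binomial anova drop1 oneway.test cor sd median qnorm
#'   quantile coef vcov as.formula setNames
#' @importFrom utils packageVersion head
#' @import data.table
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's stream afterwards so library calls never clobber user RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

assert_fraction <- function(x, name, lo = 0, hi = 1,
                            lo_open = FALSE, hi_open = FALSE) {
  bad <- !is.numeric(x) | !is.finite(x) |
    (if (lo_open) x <= lo else x < lo) |
    (if (hi_open) x >= hi else x > hi)
  if (any(bad)) {
    stop(sprintf("`%s` must lie in %s%g, %g%s", name,
                 if (lo_open) "(" else "[", lo, hi,
                 if (hi_open) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}

#' Deterministic synthetic reference base
#'
#' The synthetic cohort lives on small made-up contigs; rather than storing a
#' genome, the reference base at any (contig, position) is a deterministic hash
#' of the pair. Every component (read simulation, consensus annotation,
#' variant generation) queries the same function, so reference consistency is
#' guaranteed without I/O.
#'
#' @param chrom character vector of contig names.
#' @param pos integer vector of 1-based positions (recycled against `chrom`).
#' @return character vector of bases in `A`, `C`, `G`, `T`.
#' @examples
#' ref_base("syn1", 101:105)
#' @export
ref_base <- function(chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  csum <- vapply(chrom, function(c) sum(utf8ToInt(c)), numeric(1))
  h <- (csum * 7919 + pos * 104729 + (pos %/% 97) * 131) %% 4
  c("A", "C", "G", "T")[h + 1L]
}

# Phred+33 encoding helpers for quality strings (SAM convention).
phred_to_chr <- function(q) {
  vapply(q, function(v) intToUtf8(as.integer(v) + 33L), character(1))
}

chr_to_phred <- function(s) {
  lapply(s, function(x) utf8ToInt(x) - 33L)
}
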