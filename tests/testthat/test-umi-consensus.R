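test_that("family grouping partitions reads by exact UID and coordinates", {
  expect_equal(nrow(group_families(
    data.frame(uid = character(0), chrom = character(0),
               fragment_start = integer(0), fragment_end = integer(0),
               strand_orientation = character(0), bases = character(0),
               base_qualities = character(0),
               mapping_quality = integer(0)))$families), 0L)
  # A duplex pair lands in one family with both strands populated.
  fs <- group_families(make_duplex_pair())
  expect_equal(nrow(fs$families), 1L)
  expect_equal(fs$families$n_top, 1L)
  expect_equal(fs$families$n_bottom, 1L)
  # Reads without UID are rejected with a counted warning.
  reads <- rbind(make_duplex_pair(), make_duplex_pair(uid = NA))
  expect_warning(fs2 <- group_families(reads), "2 read")
  expect_equal(fs2$n_rejected, 2L)
  expect_equal(nrow(fs2$reads), 2L)
})

test_that("family count and sizes match a brute-force grouping oracle", {
  v <- list(chrom = "syn1", pos = 2000L, ref = ref_base("syn1", 2000L),
            alt = "A")
  reads <- simulate_read_families(
    v, depth = 120, alt_fraction = 0.1, error_rate = 0.005,
    fragment_length_mixture = list(weights = c(1, 0), means = c(25, 25),
                                   sds = c(0, 0)),
    seed = 4)
  expect_gte(nrow(reads), 240L)  # at least a duplex pair per molecule
  fs <- group_families(reads)
  oracle_keys <- unique(paste(reads$uid, reads$chrom, reads$fragment_start,
                              reads$fragment_end))
  expect_equal(nrow(fs$families), length(oracle_keys))
  # Partition property: family sizes sum to the UID-carrying input reads.
  expect_equal(sum(fs$families$n_top + fs$families$n_bottom), nrow(reads))
})

test_that("strand consensus reproduces clean reads and requires membership", {
  seq <- "ACGTACGTAT"
  reads <- do.call(rbind, lapply(1:3, function(i) make_duplex_pair(seq = seq)))
  fc <- family_consensus(group_families(reads))
  expect_equal(nrow(fc), nchar(seq))
  expect_identical(paste(fc$duplex_allele[order(fc$pos)], collapse = ""), seq)
  # min_members_per_strand = 2 removes consensus from a 1+1 family.
  fc2 <- family_consensus(group_families(make_duplex_pair(seq = seq)),
                          min_members_per_strand = 2L)
  expect_equal(nrow(fc2), 0L)
  # 2+2 concordant family yields the duplex call under min = 2.
  reads22 <- do.call(rbind, lapply(1:2, function(i)
    make_duplex_pair(seq = seq)))
  fc3 <- family_consensus(group_families(reads22),
                          min_members_per_strand = 2L)
  expect_true(all(fc3$duplex_allele == strsplit(seq, "")[[1]][order(fc3$pos)]))
})

test_that("duplex consensus suppresses read errors by orders of magnitude", {
  # 2000 families of 3+3 reads at 1% per-base error; majority voting within
  # strands and duplex agreement across strands should leave (at) most a
  # handful of false alleles among 50k family-site calls (~3e-4 squared).
  v <- list(chrom = "syn2", pos = 5000L, ref = ref_base("syn2", 5000L))
  reads <- simulate_read_families(
    v, depth = 2000, alt_fraction = 0, error_rate = 0.01,
    family_size_law = function(n) rep(3L, n),
    fragment_length_mixture = list(weights = c(1, 0), means = c(25, 25),
                                   sds = c(0, 0)),
    seed = 5)
  fc <- family_consensus(group_families(reads))
  dup <- fc[!is.na(fc$duplex_allele), ]
  truth <- ref_base(dup$chrom, dup$pos)
  expect_lt(mean(dup$duplex_allele != truth), 1e-4)
})

test_that("background model matches its closed form and rejects no controls", {
  expect_error(build_background(list()), "null_background")
  # One control: 2 alt families of 1000 at one site.
  ctrl <- rbind(
    make_call_row(pos = 10L, ref = "A", allele = "A", depth = 1000L,
                  support = 998L),
    make_call_row(pos = 10L, ref = "A", allele = "T", depth = 1000L,
                  support = 2L))
  a <- 0.5
  bg <- build_background(list(ctrl), pseudocount = a)
  expect_equal(background_rate(bg, "syn1", 10L, "A", "T"),
               (2 + a) / (1000 + 2 * a))
  # Clean controls: every rate is at the pseudocount floor.
  clean <- make_call_row(pos = 11L, ref = "G", allele = "G", depth = 1000L,
                         support = 1000L)
  bg2 <- build_background(list(clean), pseudocount = a)
  expect_equal(background_rate(bg2, "syn1", 99L, "A", "T"), bg2$floor)
  expect_true(bg2$floor > 0 && bg2$floor < 1)
})

test_that("plasma variant gates follow LOD, background, and germline rules", {
  bg <- null_background()
  # Below the 0.5% limit of detection.
  low <- make_call_row(depth = 10000L, support = 40L)
  expect_equal(nrow(call_plasma_variants(low, bg)), 0L)
  expect_match(attr(call_plasma_variants(low, bg), "audit")$reasons,
               "below_lod")
  # Clear signal passes all gates.
  hit <- make_call_row(depth = 1000L, support = 20L)
  expect_equal(nrow(call_plasma_variants(hit, bg)), 1L)
  # Non-duplex support never passes.
  nodup <- make_call_row(depth = 1000L, support = 20L, duplex = FALSE)
  expect_equal(nrow(call_plasma_variants(nodup, bg)), 0L)
  # Germline membership vetoes.
  germ <- data.frame(chrom = "syn1", pos = 500L, ref = "A", alt = "T")
  expect_equal(nrow(call_plasma_variants(hit, bg, germline = germ)), 0L)
})

test_that("background decision matches the exact binomial tail", {
  # Fraction 0.01 at depth 1000 against background 0.008.
  ctrl <- rbind(
    make_call_row(pos = 20L, ref = "C", allele = "C", depth = 100000L,
                  support = 99200L),
    make_call_row(pos = 20L, ref = "C", allele = "G", depth = 100000L,
                  support = 800L))
  bg <- build_background(list(ctrl), pseudocount = 0)
  rate <- background_rate(bg, "syn1", 20L, "C", "G")
  expect_equal(rate, 0.008)
  cand <- make_call_row(pos = 20L, ref = "C", allele = "G", depth = 1000L,
                        support = 10L)
  p_oracle <- sum(stats::dbinom(10:1000, 1000, rate))
  alpha <- 0.01
  emitted <- nrow(call_plasma_variants(cand, bg, lod = 0.005,
                                       alpha = alpha)) == 1L
  expect_equal(emitted, p_oracle < alpha)
  # And the reported tail probability agrees with the oracle.
  aud <- attr(call_plasma_variants(cand, bg, alpha = 0.5), "audit")
  expect_equal(aud$p_background, p_oracle, tolerance = 1e-12)
})

test_that("raising the LOD or lowering alpha never adds variants", {
  set.seed(6)
  for (rep in 1:20) {
    rows <- do.call(rbind, lapply(1:8, function(i) {
      make_call_row(pos = 100L + i, ref = "A",
                    allele = sample(c("C", "G", "T"), 1),
                    depth = 500L, support = sample(0:30, 1),
                    duplex = sample(c(TRUE, FALSE), 1))
    }))
    bg <- null_background()
    base <- call_plasma_variants(rows, bg, lod = 0.005, alpha = 0.05)
    stricter_lod <- call_plasma_variants(rows, bg, lod = 0.02, alpha = 0.05)
    stricter_alpha <- call_plasma_variants(rows, bg, lod = 0.005,
                                           alpha = 0.001)
    key <- function(x) paste(x$chrom, x$pos, x$alt)
    expect_true(all(key(stricter_lod) %in% key(base)))
    expect_true(all(key(stricter_alpha) %in% key(base)))
  }
})

test_that("duplex calling detects a variant at twice the LOD reliably", {
  # At 2000 duplex families and a 1% true fraction, the expected alt-family
  # count (20) sits well above both the LOD count (10) and the background
  # gate, so detection is near-certain; at the LOD itself the binomial
  # median argument caps detection near 50% by construction.
  v <- list(chrom = "syn3", pos = 700L, ref = ref_base("syn3", 700L))
  v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  hits <- vapply(1:20, function(r) {
    reads <- simulate_read_families(
      v, depth = 2000, alt_fraction = 0.01, error_rate = 0.001,
      family_size_law = function(n) rep(1L, n),
      fragment_length_mixture = list(weights = c(1, 0), means = c(15, 15),
                                     sds = c(0, 0)),
      seed = 600 + r)
    pile <- annotate_reference(
      consensus_pileup(family_consensus(group_families(reads))))
    calls <- call_plasma_variants(pile, null_background())
    any(calls$pos == v$pos & calls$alt == v$alt)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
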