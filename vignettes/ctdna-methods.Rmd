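---
title: "Methods: tumor-informed ctDNA detection and concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-informed ctDNA detection and concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmatrace)
```

`plasmatrace` models a tumor-informed liquid-biopsy study: paired tumor
tissue and plasma from a primary breast cancer cohort, panel sequencing of
both compartments, and the question of when tumor-derived mutations are
recoverable from cell-free DNA (cfDNA). This vignette documents the models,
the tunable parameters, the numerical conventions, and the boundaries of
what the synthetic cohort can and cannot establish.

## Duplex UMI consensus

Plasma libraries carry unique molecular identifiers (UIDs) ligated to both
ends of each cfDNA fragment before PCR. Reads sharing a UID and exact
fragment coordinates descend from one original double-stranded molecule;
the read pairs from its two physical strands form the `top` and `bottom`
members of a *family* (`group_families()`). The family key is exact — no
fuzzy UID matching — which is the simplest defensible contract; UID
sequencing errors therefore fragment families rather than merging them,
a conservative failure mode.

`family_consensus()` takes, per family, strand, and position, the majority
base among members (summed base quality breaks ties); a strand below
`min_members_per_strand` (default 1) contributes nothing. A *duplex* allele
exists only where both strand consensuses agree. With per-base error rate
$e$ and 3 reads per strand, a strand consensus is wrong with probability
about $3e^2(1-e) + e^3$, and a duplex error additionally requires the other
strand to make the *same* error, so the family-level false allele rate is
of order $10^{-7}$ at $e = 10^{-2}$. The test suite measures this on
10,000 simulated 3+3 families (~250,000 family-site calls) and requires
an observed rate below $10^{-4}$.

Candidate variants are emitted by `call_plasma_variants()` iff they

1. have duplex support,
2. reach the limit of detection (`lod`, default 0.005 allele fraction,
   measured in supporting families over duplex-covered families),
3. exceed the background error fraction at their site under a one-sided
   exact binomial test at level `alpha` (default 0.01), and
4. are absent from the matched germline variant set.

The background model (`build_background()`) pools alternate-family counts
across control plasma samples into per-site rates
$(\mathrm{alt} + a)/(\mathrm{depth} + 2a)$ with pseudocount $a$ (default
0.5), falling back to per-substitution-class rates and a global floor;
`null_background()` provides the floor-only model when no controls exist.
Raising `lod` or lowering `alpha` can only remove calls (tested as a
monotonicity property).

**Detection at the LOD boundary.** With the allele-fraction gate set at
exactly the true fraction, the observed supporting-family count is
binomial with its mean *at* the threshold, so detection probability is the
binomial upper-median probability — about 50% at any depth. The LOD is
therefore the fraction at which detection becomes *possible and
specific*, not a fraction detected with high sensitivity; the sensitivity
test instead verifies ≥ 90% detection at twice the LOD (fraction 0.01 at
2,000 families), where the expected count sits ten standard deviations
above the gate.

## Tissue somatic filter cascade

Candidate tumor SNVs (from any upstream caller) are filtered against the
matched germline by five independent predicates, with exact boundaries:

| reason | fires when | default |
|---|---|---|
| `indel_window` | indel-bearing reads in the 11-bp window **> 10** | 10 |
| `germline_evidence` | control alt fraction **≥ 3%**, or **≥ 2%** with summed alt quality **> 80** | 0.03 / 0.02 / 80 |
| `dbsnp_not_cosmic` | in dbSNP and not in COSMIC | — |
| `low_hq_support` | high-quality alt reads (base and mapping quality ≥ 30) **< 5** | 5 |
| `low_vaf` | allele frequency **< 1%** (exactly 1% is kept) | 0.01 |

Indels are vetoed on ≥ 3 indel-supporting control reads at the site or
within 40 bp, or a low-complexity context. Because the rules are
independent predicates whose reasons accumulate, evaluation order cannot
change a verdict and the cascade is idempotent (both tested).

Two genuinely ambiguous readings were fixed as package conventions: the
germline-evidence rule is parsed as (≥ 3%) OR (≥ 2% AND quality sum > 80),
which keeps both thresholds meaningful, and the percentages are fractions
of control depth rather than absolute counts. dbSNP/COSMIC membership is
matched on the exact normalized allele, not positional overlap.

**Low complexity** is defined here (no canonical definition exists) as a
homopolymer run ≥ 8 bp or a tandem repeat of unit length 2–6 in ≥ 4
contiguous copies, all configurable; the implementation is regex-based and
verified against a brute-force substring scanner.

**Indel normalization.** All variant keys are reduced to a minimal
representation by trimming the shared allele suffix then prefix
(advancing the position), so equivalent records compare equal; full
left-shifting across repeat tracts additionally requires a reference
accessor and is applied only when one is supplied.

## Concordance, CCF, and clonality

Per patient, the validated tumor set and the called plasma set are
partitioned by exact normalized key into overlapping, tissue-specific and
blood-specific subsets — disjoint and exhaustive by construction. A
patient is *ctDNA positive* iff at least one tumor variant is found in
plasma; the tracing fraction is |overlapping| / |tumor|, categorized as
`full` (= 1), `none` (= 0) or `partial`. Patients with zero tumor variants
are excluded from concordance denominators (their category is undefined,
and requesting it is an error). MVAF — the maximal plasma VAF, a tumor
burden proxy — defaults to tumor-derived variants only, since
blood-specific (hematopoietic) VAFs do not measure tumor burden; the
`all_plasma` scope is available as an option.

Cancer cell fractions use the standard purity/copy-number correction

$$\mathrm{CCF} = \min\!\left(1,\; \mathrm{VAF} \cdot
  \frac{p \cdot CN + (1 - p) \cdot 2}{p}\right)$$

with tumor purity $p$ and local total copy number $CN$ (default 2, i.e.
heterozygous autosomal), reducing to $\min(1, 2\,\mathrm{VAF})$ at $p = 1$.
A mutation is *clonal* iff its CCF is ≥ 75% of the patient's maximum —
scale-invariant, and guaranteeing at least one clonal mutation per
patient. This deliberately replaces a full Bayesian clustering of
mutations with the simple deterministic rule; the tradeoff is that a
single noisy VAF can move the 75% threshold for the whole patient.

## Cohort statistics

Contingency tests use the Pearson chi-square *without* continuity
correction (`stats::chisq.test(correct = FALSE)`); on the 2×2 tables this
package targets, the uncorrected statistic is the convention that
reproduces the reference results, and a fixed-margin Monte-Carlo oracle
(`r2dtable`) bounds its error in the tests. Detectability models are
binary logistic regressions; multi-level covariates (age group, T, N)
enter as ordered numeric scores so each clinical characteristic yields a
single p-value; p-values come from likelihood-ratio tests (drop-one in the
joint model), which are better behaved than Wald tests at n ≈ 71.
Complete separation is detected and rerouted to a Firth-penalized fit
(Jeffreys-prior score correction, implemented in-package) with a penalized
LRT. One-way ANOVA of MVAF is the classical pooled-variance F test; for
two groups it equals the squared pooled t statistic (tested to 1e-10).
Confusion metrics (overall consistency, PPV, NPV, sensitivity,
specificity) flag zero-denominator cells as undefined rather than zero.

## The synthetic cohort: what it emulates

The generator reproduces, at the study's scale of 71 patients:

- clinical covariate proportions from the reference cohort's table
  (e.g. 73.2% HR-positive, 53.5% stage III), with M stage tied to stage IV
  and molecular subtype derived from HR/HER2/Ki67 so records are always
  internally consistent;
- per-tumor mutation counts from a negative binomial (size 1.0, mean 2.4)
  truncated to 1–15, whose sample median is 2.5 — overdispersion matches
  the long observed tail;
- gene labels from a configurable frequency table calibrated so marginal
  prevalences resemble the reference cohort (TP53 ≈ 0.47, PIK3CA ≈ 0.40);
- a CCF structure of one clonal cluster (CCF 1) plus 0–2 subclones at
  CCF ~ U(0.1, 0.7) (weights 0.15/0.35/0.5), with non-first mutations
  preferring subclones 2:1 so multi-cluster tumors are subclonal-majority.
  CCF is defined purity-free with true tumor VAF = CCF·purity/2, so the
  downstream CCF estimator recovers ground truth exactly on noise-free
  VAFs (the "clonality closure" property test);
- a logistic shedding model on N stage (ordinal), HR status, M stage and
  clonality (odds multiplied by `clonal_boost` ≥ 1 for clonal mutations),
  with stage-dependent plasma VAF scaling. Defaults (intercept −4.1,
  +0.9/N step, +2.0 HR-negative, +0.7 M1, boost 7, VAF scales
  0.10/0.12/0.18/0.35 for stages I–IV) were calibrated once by large-cohort
  simulation so the synthetic study operates where the reference cohort
  does: ≈ 61% of patients ctDNA-positive, ≈ 68% with any plasma mutation,
  N stage and HR status dominant, and clonal mutations traced at a much
  higher rate than subclonal ones;
- a clonal-hematopoiesis channel: with probability 0.2 a patient gains one
  blood-only mutation in DNMT3A/JAK2/TET2 at VAF 0.5–3%;
- duplex read families over a bimodal fragment-length mixture
  (85% N(177, 5), 15% N(322, 12), matching the mononucleosomal and
  dinucleosomal cfDNA peaks), uniform per-base errors, and family sizes
  1 + Poisson(1) per strand.

**What it does not emulate** — and hence what passing tests cannot show
about real data: sequence-context-specific error spectra (e.g. oxidative
C>A damage), UID collisions and errors, GC and fragment-end biases, CNV-
driven VAF distortion, tumor evolution between sampling times, and real
genome coordinates (loci live on small synthetic contigs; the reference
base is a deterministic hash of contig and position, so no genome is
stored). Quantities that depend on unreleased patient data — the exact
cohort percentages and p-values of the reference study — are matched only
as an operating point and as qualitative structure, not reproduced.

## Numerical choices and degenerate inputs

- Coordinates are 1-based inclusive everywhere in memory; SAM/VCF
  conventions apply only at the I/O boundary. Strand orientation is
  recorded explicitly (`top`/`bottom`) and round-trips through SAM FLAG
  bit 0x10.
- Consensus ties break by summed base quality; a remaining exact tie is
  resolved deterministically by base order, keeping runs bit-reproducible.
- Probability vectors must sum to 1 within 1e-9; configuration errors name
  the offending covariate. Thresholds are validated before any stage runs.
- Reads without a UID are rejected with a counted warning — never silently
  dropped. Empty inputs (empty cohort, empty VCF, empty candidate list)
  return empty, well-typed results; undefined quantities (MVAF with no
  tumor-derived variants, tracing rates for an absent clonality class)
  are NA and flagged, never 0.
- Every stochastic function takes an explicit seed and restores the
  caller's RNG state; identical config + seed gives bit-identical output,
  and the pipeline manifest records md5 checksums to prove it.

## Problem sizes in the test suite

Module tests run at small scale (hundreds of families, cohorts of
25–3,000). The property suite uses the sizes the analyses were designed
at: 10,000 duplex families for error suppression, 100 seeded replicates
for control-plasma specificity, 100 replicates × 2,000 patients for
shedding-coefficient recovery (Wald 95% CI coverage ≥ 90% per
coefficient, signs always), 1,000 random patients for partition/clonality
properties, and 20 seeded end-to-end runs at n = 71 for the cohort
operating point (mean any-plasma detection within ±0.05 of 0.676; clonal
tracing exceeding subclonal in ≥ 95% of seeds).

## Known limitations

- The consensus caller supports SNVs at family level; indel consensus
  within read families and CIGAR-level realignment are out of scope
  (tissue indels are filtered, not re-called).
- The background model is per-site/per-class binomial; it does not model
  overdispersion across samples, which real background databases show.
- The Firth fallback reports penalized-LRT p-values but not profile
  confidence intervals.
- CNV calling itself is out of scope; the package evaluates concordance
  *metrics* for amplification calls supplied as inputs.
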