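# plasmatrace

Tumor-informed circulating tumor DNA (ctDNA) analysis for primary breast
cancer cohorts, in R.

When a tumor sheds DNA into blood plasma, its somatic mutations become
detectable in cell-free DNA (cfDNA) at allele fractions well below what
standard variant calling can distinguish from PCR and sequencing error.
`plasmatrace` implements the full analysis chain used in tumor-informed
liquid-biopsy studies, for methods developers and analysts who need a
tested, reproducible reference implementation that runs end to end without
any external data:

- **Duplex UMI consensus calling** — plasma reads are clustered into
  families by unique molecular identifier (UID) and exact fragment
  coordinates; per-strand majority consensus plus duplex (both-strand)
  agreement suppresses the per-base error rate from ~1e-2 to below 1e-4,
  enabling a 0.5% limit of detection. Candidate alleles are gated on the
  LOD, a one-sided exact binomial test against a background error model
  built from control plasma, and a matched germline set.
- **Tissue somatic filter cascade** — the matched-germline post-filters for
  tumor tissue SNVs (indel-window, germline-evidence, dbSNP-not-COSMIC,
  high-quality support, minimum VAF) and indels (control indel support,
  low-complexity/short-tandem-repeat context), each an independent,
  auditable predicate with exact boundaries.
- **Concordance and clonality** — per patient, tumor and plasma variant
  sets are partitioned into overlapping / tissue-specific / blood-specific
  by exact normalized key; tracing fractions, maximal VAF (MVAF), cancer
  cell fractions `CCF = VAF x (p * CN + (1 - p) * 2) / p` (purity `p`,
  local copy number `CN`), and clonal/subclonal labels
  (CCF >= 75% of the patient's maximum) follow.
- **Cohort statistics** — Pearson chi-square (no continuity correction),
  gene-frequency correlation (R^2), univariate/multivariate logistic models
  of ctDNA detectability with likelihood-ratio p-values (Firth fallback
  under separation), one-way ANOVA of MVAF, and confusion-matrix metrics
  for CNV-vs-IHC concordance.
- **Synthetic cohort generator** — a seeded simulator of a 71-patient
  primary breast cancer study: clinical covariates with realistic category
  proportions, 1-15 somatic mutations per tumor (median 2.5) with a
  clonal/subclonal CCF structure, a covariate-dependent logistic shedding
  model, a clonal-hematopoiesis channel (DNMT3A/JAK2/TET2), and UID-tagged
  duplex read families with the bimodal cfDNA fragment-length profile
  (170-185 bp major peak, minor peak near 322 bp).

## Worked example

```r
library(plasmatrace)

out <- run_pipeline(run_config(n_patients = 71, seed = 1))
s <- out$stats
cat(sprintf("ctDNA positive (tumor-derived): %.1f%%\n", 100 * s$detection_rate))
cat(sprintf("any plasma mutation:            %.1f%%\n", 100 * s$any_plasma_rate))
cat(sprintf("clonal tracing rate:            %.1f%%\n",
            100 * s$tracing_rates$clonal_detected_fraction))
cat(sprintf("subclonal tracing rate:         %.1f%%\n",
            100 * s$tracing_rates$subclonal_detected_fraction))
cat(sprintf("gene-frequency R^2:             %.3f\n", s$gene_freq_r2))
```

prints (seed 1):

```
ctDNA positive (tumor-derived): 71.8%
any plasma mutation:            77.5%
clonal tracing rate:            63.4%
subclonal tracing rate:         19.8%
gene-frequency R^2:             0.932
```

One simulated 71-patient cohort was generated, tumor mutations were pushed
through the somatic filter cascade, plasma observations through the
detection gates, and the per-patient concordance table was summarized:
71.8% of patients had at least one tumor mutation traceable in plasma
(77.5% had any plasma mutation once hematopoiesis-derived ones are
counted), clonal mutations were traced at more than three times the
subclonal rate, and per-gene mutation frequencies in tissue and plasma
correlate strongly. A single seed at n = 71 is noisy; averages over seeds
sit near 62% / 69%. The joint logistic model on the same run finds N stage
(p = 0.003) and hormone-receptor status (p = 0.004) as the independent
predictors of detectability, the expected outcome under the generator's
shedding model:

```r
out$stats$mva[, c("covariate", "p_value")]
#    covariate p_value
# 1  age_group 0.40781
# 2    t_stage 0.74244
# 3    n_stage 0.00343
# 4    m_stage 0.89994
# 5  hr_status 0.00403
# 6   her2_ihc 0.14080
# 7 ki67_group 0.77161
```

`out$results` holds the per-patient table (covariates, `n_tumor`,
`n_plasma`, `n_overlap`, `ctdna_positive`, `tracing_category`, `mvaf`,
clonal/subclonal counts); with `outdir` set, every stage writes TSVs plus
a JSON manifest with checksums and timings. A command-line wrapper lives
at `inst/cli/plasmatrace`.

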