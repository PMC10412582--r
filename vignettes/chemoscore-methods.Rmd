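---
title: "Methods: the four-chemokine score pipeline and its synthetic validation cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the four-chemokine score pipeline and its synthetic validation cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoscore)
```

## The model

Tumors responsive to immune checkpoint inhibition (ICI) tend to show
T cell-inflamed microenvironments. The pipeline implemented here scores that
inflammation with a fixed four-chemokine signature — the **c-Score**, the
per-sample arithmetic mean of the stored log2(TPM + 0.001) expression of
*CCL4*, *CCL5*, *CXCL9* and *CXCL10* — and relates it to mutational burden,
genomic instability subtypes, immune gene-set programs and ICI outcomes.
The gene set is fixed; nothing is learned from data.

All expression is stored as log2(TPM + 0.001). The 0.001 pseudo-count means
a TPM of zero maps to log2(0.001) ≈ −9.966, which doubles as the marker the
expressed-gene filter looks for.

### Stratification

Cohorts are split at the first and third quartiles of the c-Score: `hi`
when the score is ≥ Q3, `lo` when ≤ Q1, `med` otherwise, with `hi` tested
first so the degenerate Q1 = Q3 case stays total. Quartiles are computed by
linear interpolation at position (n−1)p + 1 (`stats::quantile` type 7): with
6,987 distinct scores this places exactly 1,747 samples in each tail and
3,493 in the middle, which is the property the convention was chosen for.
Two threshold sources exist: the shipped fixed defaults
(Q1 = 1.940425, Q3 = 4.835088, derived from a 6,987-sample pan-cancer
reference cohort) and cohort-relative quartiles via `derive_thresholds()`
for datasets whose expression scale is not comparable to that reference.
Downstream group comparisons keep only tumor types with at least 5 patients
in each of the three groups, and most analyses pool `lo` and `med` into a
single reference (`lo+med`) against `hi`.

### Mutation metrics

TMB is counted mutations divided by the capture size in megabases (default
35.8 Mb), with `hi` meaning ≥ 10 mutations/Mb (inclusive). The default
counted set is the non-silent MAF classes (Silent, UTR/flank, intron,
intergenic and RNA records excluded); this is declared configuration
recorded on the result, not a claim of bit-equivalence with any upstream
pipeline, because the exact set behind published TMB tables is rarely
printed. Protein-truncating means exactly: frameshift deletion or
insertion, nonsense, splice site, translation start site, nonstop. Pathway
mutation rates over the mismatch-repair (*MLH1, MSH2, MSH6, PMS2*),
homologous-recombination (*BRCA1, BRCA2, PALB2*) and replication
(*POLE, POLD1*) genes are reported both as record counts per patient and as
the fraction of patients carrying any hit.

### Genomic subtyping

MSI is called from MANTIS scores (high when **strictly** > 0.4), HRD from
HRDScore with stratum-specific thresholds — ≥ 46 in BRCA and OV, ≥ 27
elsewhere (inclusive), or cohort-relative stratum third quartiles — and
MSIsensor (high strictly > 0.2). Precedence is MSI first: a sample high on
both MANTIS and HRDScore resolves to `MANTIS_hi`, then `HRDScore_hi`, then
the pooled c-Score label. Missing scores classify low everywhere so every
sample receives exactly one subtype; the number of imputed-low samples is
attached as an attribute so analysts can report it.

A tumor type is **TMB-associated** when a two-sided Wilcoxon rank-sum test
of TMB between `hi` and `lo+med`, Benjamini–Hochberg adjusted across types,
is significant at α = 0.05 *and* the `hi` median exceeds the `lo+med`
median. The direction requirement matters: a type where the pooled group
has higher burden is never associated, however small its P value.

### Enrichment and the AU transform

Before enrichment, genes with zero TPM in strictly more than 50% of samples
are removed (a gene at exactly half is kept), and the four chemokines are
stripped from every gene set so the signature is never scored against
itself; a set emptied by the removal is dropped with a warning.

The single-sample enrichment statistic walks each sample's genes in
descending expression order and sums, position by position, the difference
between the weighted in-set empirical CDF and the uniform out-of-set CDF.
Weights are rank^τ with τ = 0.25 and tie-averaged ascending ranks, so the
most highly expressed genes carry the largest weights; with
`normalize = TRUE` the whole score matrix is divided by its range. τ, the
tie rule and the normalization match the documented defaults of the
standard single-sample GSEA implementation and are recorded as attributes
on the result. The vectorized implementation is tested against an
independent term-by-term oracle to 1e-10 on hundreds of random fixtures.

For display on a positive scale, group medians per gene set are translated
by AU(set, group) = median(group) + 1 − median(reference), reference being
`lo+med`. The reference AU is therefore exactly 1 — the package assigns the
identity directly rather than computing median + 1 − median, which floating
point does not guarantee to be exactly 1 — and between-group median
differences are preserved exactly. All statistics are computed on
untransformed scores; AU is presentation only. (The construction pins the
*reference-group median* at 1; an individual transformed value can still
fall below 1.)

### Outcomes

Durable clinical benefit (DCB) is treatment for strictly more than 183 days
(six months) without progression in that window; the day count is a package
decision since the definition is stated in months. Time to progression and
overall survival are analysed in days with Kaplan–Meier curves (median =
first time the estimate reaches ≤ 0.5, reported as not-reached/NA
otherwise), log-rank tests across groups, and Cox proportional-hazards
models with the Efron tie approximation. Per-term hazard ratios carry Wald
95% CIs; the model-level P is the score (log-rank) test. When tumor type is
a covariate, types with fewer than 3 patients are dropped before the fit.
The covariate-controlled DCB comparison is an ordinary linear model of the
(binary) benefit indicator on group plus histology indicators; a logistic variant is exposed as an option for analysts who
prefer a generative binary model.

## The synthetic cohort generator

No public expression/MAF/outcome cohort ships with the package, so every
stage is exercised on seeded synthetic cohorts whose structure mirrors what
the analysis assumes:

* **Expression** is Gaussian on the log2 scale (log-normal TPM). Each
  sample carries a latent inflammation factor, standard normal within its
  tumor type; chemokine and immune-gene-set genes shift by
  `inflammation_effect` (default 2) log2 units per unit factor, background
  genes do not. A tenth of the background panel is given heavy zero-TPM
  dropout to exercise the expressed-gene filter.
* **Cold types** (default 6 of 31) have the latent factor shifted down by
  `cold_shift` (default −2 SD), so they lack score-high samples and are
  removed by the 5-per-group filter — the planted truth behind the
  31 → 25 type-filtering test.
* **Mutations** are negative binomial (size 2) with a per-type log-normal
  mean (default 80 counts ≈ 2.2 mut/Mb); MSI samples are inflated 10-fold.
  In planted TMB-associated types the mean of score-high samples is shifted
  by `tmb_assoc_log2fc` (default 1.5). Variant classes follow a fixed
  categorical over the MAF vocabulary; MSI/HRD minorities receive extra
  repair-pathway lesions, and KRAS carriers are planted as an exact rounded
  per-type count so prevalence checks are deterministic.
* **Genomic scores** are drawn from disjoint ranges on either side of the
  classification thresholds, so planted MSI/HRD membership is recoverable
  exactly; a small fraction of MANTIS values is set missing to exercise the
  missing-maps-low rule.
* **Outcomes** are exponential with the planted hazard multiplied by
  `hazard_ratio_hi` (default 0.5) for score-high samples, under independent
  uniform censoring whose window is solved numerically so the baseline
  censoring fraction equals `censoring_rate`. The hazard is planted on the
  *realized* cohort-relative c-Score group rather than the latent factor:
  the recovery experiment then estimates exactly the planted log-HR, with
  no attenuation from boundary misclassification, which keeps the CI
  coverage check a clean test of the survival machinery. DCB labels are
  drawn per group (defaults 0.36 / 0.16 / 0.02) and the treatment duration
  and progression flag are generated consistently with the label.

Identical configurations (including the seed) give bit-identical cohorts,
and the generator restores the caller's RNG state.

What the generator does **not** emulate: copy-number and subclonal
structure, read-level noise, batch effects, correlated gene-gene noise
beyond the single latent factor, non-proportional hazards, and informative
censoring. Passing recovery tests therefore show the pipeline is correct
and well-calibrated under its own assumptions, not that those assumptions
hold in any real cohort.

## Problem sizes and numerical choices

Validation runs use cohorts of roughly 500–4,650 samples and a few hundred
genes — large enough for the planted effects to dominate sampling noise
(e.g. the Cox recovery uses 100 replicates of n = 500, where the planted
log-HR of −0.69 has a CI half-width around 0.2) while keeping the whole
suite quick on a laptop. The TMB-association recovery isolates its planted
mechanism by switching the MSI/HRD minorities off; with them on, MSI's
10-fold burden and elevated inflammation would plant a genuine, if
unintended, association in types meant to be null.

Tolerances: enrichment scores match their oracle to 1e-10; Cox and OLS
estimates match closed-form/1-D-optimisation oracles to 1e-6; exact-test P
values match enumeration to 1e-12. Tie-breaks: average ranks in enrichment
and rank tests; first-in-file order wins dedup median ties; `hi` wins the
degenerate Q1 = Q3 stratification.

## Interface

The package's interface is its functions, used from R as shown in the
README; results are plain data frames ready for `write_tsv()`. No shell
entry point is shipped.

## Known limitations

* The fixed thresholds are only meaningful for data processed onto the same
  log2(TPM + 0.001) scale as the reference cohort; use cohort-relative mode
  otherwise.
* The default counted-class set for TMB, and hence TMB^hi calls near the
  10 mut/Mb boundary, is configuration; published burdens computed with
  other sets will differ.
* The linear DCB adjustment is the primary analysis but treats a binary
  response with OLS; the logistic option is provided for sensitivity
  analysis.
* MANTIS, HRDScore, MSIsensor and HRDetect values are consumed as
  precomputed inputs; the package does not derive them from sequence data.
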