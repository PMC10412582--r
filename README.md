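# chemoscore

Tumors with a T cell-inflamed microenvironment respond to immune checkpoint
inhibitors (ICI) far more often than "cold" tumors, and tumor mutational
burden (TMB) alone misses many of them. `chemoscore` implements a pan-cancer
analysis pipeline around a fixed four-chemokine expression signature, the
**c-Score**:

> c-Score(sample) = mean of log2(TPM + 0.001) over {CCL4, CCL5, CXCL9, CXCL10}

and everything needed to relate it to genomics and outcomes:

* **Stratification** — hi / med / lo groups at the global score quartiles
  (fixed reference thresholds Q1 = 1.940425, Q3 = 4.835088, or
  cohort-relative), a ≥5-patients-per-group tumor-type filter, and lo+med
  pooling.
* **Mutation metrics** — per-sample TMB (counted mutations / 35.8 Mb;
  TMB-high at ≥10 mut/Mb), protein-truncating classification, DNA-repair
  pathway mutation rates, KRAS status.
* **Genomic subtyping** — MSI from MANTIS (> 0.4) or MSIsensor (> 0.2), HRD
  from HRDScore (≥46 in BRCA/OV, ≥27 elsewhere), resolved with
  MSI-over-HRD precedence; Wilcoxon + BH-FDR classification of tumor types
  as "TMB-associated".
* **Immune enrichment** — single-sample gene-set enrichment (rank-weighted
  ECDF statistic, τ = 0.25), the >50%-zeros gene filter, chemokine removal
  from gene sets, and the arbitrary-unit (AU) transform that pins the
  reference-group median at exactly 1.
* **Outcomes** — durable clinical benefit (>183 days without progression),
  per-group response rates, Kaplan–Meier / log-rank, Cox models with Efron
  ties, covariate-controlled linear comparisons, Spearman correlation of
  per-type medians.
* **Synthetic cohorts** — a seeded generator (`sim_config()`,
  `simulate_cohort()`) that plants a latent inflammation factor, MSI/HRD
  minorities, TMB-associated types and group-dependent hazards, so every
  stage is testable without controlled-access data.

It is intended for computational oncologists analysing bulk RNA-seq + MAF +
clinical cohorts, and for anyone who needs a tested reference implementation
of these scoring and stratification rules.

## Worked example

```r
library(chemoscore)

cfg    <- sim_config(n_tumor_types = 6, samples_per_type = 80,
                     n_cold_types = 1, n_tmb_assoc_types = 2, seed = 11)
cohort <- simulate_cohort(cfg)

cscore <- compute_cscore(cohort$expression)
strat  <- stratify(cscore, derive_thresholds(cscore),
                   tumor_type = cohort$clinical$tumor_type)
table(strat$group)
#>  hi med  lo
#> 120 240 120
filter_tumor_types(strat)
#> [1] "BRCA" "OV"   "TT03" "TT04" "TT05"
```

The cohort-relative quartiles put exactly a quarter of the 480 samples in
each tail, and the one planted "cold" type (TT06, no score-high samples) is
dropped by the five-per-group filter.

```r
tmb   <- compute_tmb(cohort$mutations, samples = cohort$clinical$sample_id)
assoc <- classify_tmb_association(tmb, strat)
assoc[assoc$associated, c("tumor_type", "median_hi", "median_lo_med", "p_adj")]
#>   tumor_type median_hi median_lo_med        p_adj
#> 1       BRCA  3.030726      1.075419 3.151520e-04
#> 2         OV  5.293296      1.438547 1.177838e-07
```

Exactly the two types planted with score-linked mutation loads are flagged
TMB-associated: their score-high patients carry roughly 3-fold higher
median TMB (mutations/Mb), significant after BH adjustment across types.

```r
es <- ssgsea(filter_expressed_genes(cohort$expression),
             prepare_genesets(cohort$genesets))
au <- au_transform(es, pool_groups(strat$group))
head(au[au$group == "hi", ], 3)
#>    geneset group median_score       au
#> 2 IMMSET01    hi    0.1179552 1.395997
#> 4 IMMSET02    hi    0.2053739 1.380820
#> 6 IMMSET03    hi    0.3189053 1.420526
```

Immune gene-set enrichment is higher in score-high tumors: AU values around
1.4 against the lo+med reference, which sits at exactly 1 by construction.

```r
pooled <- pool_groups(strat$group)
km  <- km_logrank(cohort$clinical$ttp_days, cohort$clinical$ttp_event, pooled)
km$medians
#>        hi    lo+med
#> 177.78601  73.71273
km$p_value
#> [1] 6.079422e-08
fit <- cox_ph(data.frame(time  = cohort$clinical$ttp_days,
                         event = cohort$clinical$ttp_event,
                         group = pooled,
                         tumor_type = cohort$clinical$tumor_type),
              terms = c("group", "tumor_type"))
fit$terms[1, ]
#>          term       hr    ci_lo    ci_hi       p_wald
#> 1 grouplo+med 2.128894 1.623396 2.791795 4.678491e-08
```

Score-high patients progress later (median time to progression 178 vs 74
days, log-rank P = 6e-08); the histology-adjusted Cox model estimates a
lo+med hazard of 2.13 relative to high — i.e. a hazard ratio of about 0.47
for score-high patients, recovering the planted 0.5.

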