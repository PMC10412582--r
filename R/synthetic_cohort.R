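# Seeded synthetic multi-tumor-type cohort generator.  Produces an
# expression matrix, MAF-style mutation table and clinical table carrying
# the statistical structure the downstream analyses assume: a latent
# inflammation factor co-driving the four chemokines and immune-geneset
# genes, per-type negative-binomial mutation loads, minority MSI/HRD
# subpopulations with elevated burden and inflammation, and survival / DCB
# outcomes with group-dependent hazards.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the emulated study conditions: 31 tumor types of 100
#' samples (two named BRCA and OV so the stratified HRD thresholds have
#' their stratum), six "cold" types with a depressed latent inflammation
#' factor (so they lack score-high samples and are dropped by the
#' five-per-group filter), eight types whose mutation load is shifted in the
#' score-high group (the planted TMB-associated types), a 5% MSI and 15% HRD
#' minority, and a planted treatment hazard ratio of 0.5 for score-high
#' patients.
#'
#' @param n_tumor_types Number of tumor types.
#' @param samples_per_type Samples per type; scalar or vector of length
#'   `n_tumor_types`.
#' @param n_background_genes Background (non-signature) genes.
#' @param inflammation_effect log2-scale expression shift of chemokine and
#'   immune-geneset genes per unit of the latent factor.
#' @param msi_fraction,hrd_fraction Fractions of samples planted MSI / HRD.
#' @param tmb_base_mean Mean raw mutation count per sample (negative
#'   binomial).
#' @param tmb_msi_multiplier Multiplier of the mutation mean in MSI samples.
#' @param hazard_ratio_hi Planted hazard of score-high versus the rest for
#'   both endpoints.
#' @param dcb_prob_by_group Durable-clinical-benefit probabilities for the
#'   hi, med and lo groups.
#' @param censoring_rate Probability a survival time is uniformly censored.
#' @param seed RNG seed; identical configurations give identical cohorts.
#' @param n_cold_types Types planted with a depressed latent factor.
#' @param cold_shift Latent-factor shift (in SD units) of cold types.
#' @param n_tmb_assoc_types Types planted TMB-associated.
#' @param tmb_assoc_log2fc log2 fold-change of the mutation mean in
#'   score-high samples of associated types.
#' @param kras_fraction Fraction of samples per type planted KRAS-mutant;
#'   scalar or per-type vector.  Counts are exact (rounded per type).
#' @param n_genesets,geneset_size Immune genesets emitted alongside the
#'   cohort.
#' @param noise_sd Per-gene Gaussian noise SD on the log2 scale.
#' @param ttp_median_days,os_median_days Baseline (non-high) median survival
#'   times of the two endpoints.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_tumor_types = 31L, samples_per_type = 100L,
                       n_background_genes = 200L, inflammation_effect = 2,
                       msi_fraction = 0.05, hrd_fraction = 0.15,
                       tmb_base_mean = 80, tmb_msi_multiplier = 10,
                       hazard_ratio_hi = 0.5,
                       dcb_prob_by_group = c(hi = 0.36, med = 0.16, lo = 0.02),
                       censoring_rate = 0.2, seed = 1L,
                       n_cold_types = 6L, cold_shift = -2,
                       n_tmb_assoc_types = 8L, tmb_assoc_log2fc = 1.5,
                       kras_fraction = 0.15,
                       n_genesets = 8L, geneset_size = 15L, noise_sd = 1,
                       ttp_median_days = 72, os_median_days = 196) {
  cfg <- list(n_tumor_types = as.integer(n_tumor_types),
              samples_per_type = as.integer(samples_per_type),
              n_background_genes = as.integer(n_background_genes),
              inflammation_effect = inflammation_effect,
              msi_fraction = msi_fraction, hrd_fraction = hrd_fraction,
              tmb_base_mean = tmb_base_mean,
              tmb_msi_multiplier = tmb_msi_multiplier,
              hazard_ratio_hi = hazard_ratio_hi,
              dcb_prob_by_group = dcb_prob_by_group,
              censoring_rate = censoring_rate, seed = as.integer(seed),
              n_cold_types = as.integer(n_cold_types),
              cold_shift = cold_shift,
              n_tmb_assoc_types = as.integer(n_tmb_assoc_types),
              tmb_assoc_log2fc = tmb_assoc_log2fc,
              kras_fraction = kras_fraction,
              n_genesets = as.integer(n_genesets),
              geneset_size = as.integer(geneset_size), noise_sd = noise_sd,
              ttp_median_days = ttp_median_days,
              os_median_days = os_median_days)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- c("n_tumor_types", "n_background_genes", "tmb_base_mean",
           "tmb_msi_multiplier", "hazard_ratio_hi", "n_genesets",
           "geneset_size", "noise_sd", "ttp_median_days", "os_median_days")
  for (f in pos) {
    if (any(is.na(cfg[[f]])) || any(cfg[[f]] <= 0))
      stop(sprintf("'%s' must be positive", f))
  }
  if (any(cfg$samples_per_type <= 0))
    stop("'samples_per_type' must be positive")
  if (!length(cfg$samples_per_type) %in% c(1L, cfg$n_tumor_types))
    stop("'samples_per_type' must be a scalar or one value per tumor type")
  frac <- c("msi_fraction", "hrd_fraction", "censoring_rate")
  for (f in frac) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("'%s' must lie in [0, 1]", f))
  }
  if (length(cfg$dcb_prob_by_group) != 3L ||
      any(cfg$dcb_prob_by_group < 0 | cfg$dcb_prob_by_group > 1))
    stop("'dcb_prob_by_group' must be three probabilities in [0, 1]")
  if (any(cfg$kras_fraction < 0 | cfg$kras_fraction > 1))
    stop("'kras_fraction' must lie in [0, 1]")
  if (cfg$n_cold_types < 0 || cfg$n_cold_types >= cfg$n_tumor_types)
    stop("'n_cold_types' must be in [0, n_tumor_types)")
  if (cfg$n_tmb_assoc_types < 0 ||
      cfg$n_tmb_assoc_types > cfg$n_tumor_types - cfg$n_cold_types)
    stop("'n_tmb_assoc_types' must not exceed the number of non-cold types")
  invisible(cfg)
}

# Fixed categorical over MAF classes for simulated variant records.
.variant_class_probs <- c(
  Missense_Mutation = 0.55, Silent = 0.12, Nonsense_Mutation = 0.05,
  Frame_Shift_Del = 0.04, Frame_Shift_Ins = 0.03, Splice_Site = 0.04,
  In_Frame_Del = 0.02, "3'UTR" = 0.05, Intron = 0.05, RNA = 0.02,
  Nonstop_Mutation = 0.01, Translation_Start_Site = 0.01, "5'UTR" = 0.01)

#' Simulate a synthetic multi-tumor-type cohort
#'
#' Generates an expression matrix (stored log2(TPM + 0.001)), a MAF-style
#' mutation table, a clinical table and the accompanying immune genesets,
#' together with the planted ground truth, under the model described in the
#' package vignette: log-normal TPMs whose chemokine / immune-gene means
#' shift by `inflammation_effect` per unit of a standard-normal latent
#' factor; negative-binomial mutation counts with per-type means, inflated
#' in MSI samples and (for planted TMB-associated types) in score-high
#' samples; exponential survival times with group-specific hazards and
#' independent uniform censoring.
#'
#' @param config A `sim_config` object.
#' @return List of class `chemo_cohort` with elements `expression`
#'   (matrix), `mutations` (data frame), `clinical` (data frame),
#'   `genesets` (named list) and `truth` (planted ground truth: latent
#'   factor, realized groups, MSI/HRD membership, cold and associated types,
#'   KRAS carriers, thresholds used).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(config$seed, .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(cfg) {
  n_types <- cfg$n_tumor_types
  type_names <- c("BRCA", "OV", sprintf("TT%02d", seq_len(max(0, n_types - 2L)) + 2L))
  type_names <- type_names[seq_len(n_types)]
  n_per <- rep_len(cfg$samples_per_type, n_types)
  tumor_type <- rep(type_names, times = n_per)
  n <- length(tumor_type)
  sample_id <- sprintf("S%05d", seq_len(n))

  cold_types <- if (cfg$n_cold_types > 0L)
    type_names[seq.int(n_types - cfg$n_cold_types + 1L, n_types)] else character()
  warm_types <- setdiff(type_names, cold_types)
  assoc_types <- warm_types[seq_len(cfg$n_tmb_assoc_types)]

  # latent inflammation factor: standard normal, shifted down in cold types,
  # up in MSI samples
  z <- stats::rnorm(n)
  msi <- .plant_exact(tumor_type, rep_len(cfg$msi_fraction, n_types), type_names)
  hrd <- .plant_exact(tumor_type, rep_len(cfg$hrd_fraction, n_types), type_names)
  inflam <- z + ifelse(tumor_type %in% cold_types, cfg$cold_shift, 0) +
    0.5 * msi

  # gene panel
  imm_genes <- lapply(seq_len(cfg$n_genesets), function(j)
    sprintf("IMM%02d_G%02d", j, seq_len(cfg$geneset_size)))
  bg_genes <- sprintf("BG%04d", seq_len(cfg$n_background_genes))
  genes <- c(CHEMOKINE_GENES, unlist(imm_genes), bg_genes)
  n_genes <- length(genes)
  is_signal <- genes %in% c(CHEMOKINE_GENES, unlist(imm_genes))

  mu <- c(rep(3.4, 4L),
          stats::runif(length(unlist(imm_genes)), 1, 4),
          stats::runif(cfg$n_background_genes, 0.5, 5))
  beta <- ifelse(is_signal, cfg$inflammation_effect, 0)

  expr <- matrix(stats::rnorm(n_genes * n, sd = cfg$noise_sd), n_genes, n,
                 dimnames = list(genes, sample_id))
  expr <- expr + mu + outer(beta, inflam)

  # dropout genes: first tenth of the background panel is zero-TPM in ~60%
  # of samples, exercising the expressed-gene filter
  n_drop <- max(1L, cfg$n_background_genes %/% 10L)
  drop_rows <- match(bg_genes[seq_len(n_drop)], genes)
  zero_mask <- matrix(stats::runif(n_drop * n) < 0.6, n_drop, n)
  expr[drop_rows, ][zero_mask] <- log_zero_tpm()

  # genesets: the immune blocks; the first two also carry chemokines so the
  # preparation step has something to strip
  genesets <- stats::setNames(imm_genes,
                              sprintf("IMMSET%02d", seq_len(cfg$n_genesets)))
  if (cfg$n_genesets >= 1L) genesets[[1L]] <- c(genesets[[1L]], "CCL5", "CXCL9")
  if (cfg$n_genesets >= 2L) genesets[[2L]] <- c(genesets[[2L]], "CCL4", "CXCL10")

  # realized stratification: cohort-relative quartiles of the c-Score
  cscore <- compute_cscore(expr)
  thresholds <- derive_thresholds(cscore)
  strat <- stratify(cscore, thresholds, tumor_type = tumor_type)
  group <- as.character(strat$group)
  hi <- group == "hi"

  # mutation loads: negative binomial, per-type mean, MSI and planted
  # association multipliers
  type_mult <- stats::setNames(exp(stats::rnorm(n_types, 0, 0.4)), type_names)
  mu_mut <- cfg$tmb_base_mean * type_mult[tumor_type] *
    ifelse(msi, cfg$tmb_msi_multiplier, 1) *
    ifelse(tumor_type %in% assoc_types & hi, 2^cfg$tmb_assoc_log2fc, 1)
  counts <- stats::rnbinom(n, size = 2, mu = mu_mut)

  mut_pool <- c(bg_genes, unlist(pathway_genes(), use.names = FALSE))
  rec_sample <- rep(sample_id, times = counts)
  rec_gene <- sample(mut_pool, sum(counts), replace = TRUE)
  rec_class <- sample(names(.variant_class_probs), sum(counts),
                      replace = TRUE, prob = .variant_class_probs)

  # planted repair-pathway lesions in the MSI / HRD minorities
  pg <- pathway_genes()
  extra <- function(flag, gene_set, p_carry) {
    idx <- which(flag & stats::runif(n) < p_carry)
    if (!length(idx)) return(NULL)
    data.frame(Tumor_Sample_Barcode = sample_id[idx],
               Hugo_Symbol = sample(gene_set, length(idx), replace = TRUE),
               Variant_Classification = sample(
                 c("Frame_Shift_Del", "Nonsense_Mutation", "Missense_Mutation"),
                 length(idx), replace = TRUE, prob = c(0.4, 0.3, 0.3)),
               stringsAsFactors = FALSE)
  }
  kras_frac <- rep_len(cfg$kras_fraction, n_types)
  kras_mut <- .plant_exact(tumor_type, kras_frac, type_names)
  kras_rec <- if (any(kras_mut)) {
    data.frame(Tumor_Sample_Barcode = sample_id[kras_mut],
               Hugo_Symbol = "KRAS",
               Variant_Classification = sample(
                 c("Missense_Mutation", "Nonsense_Mutation"), sum(kras_mut),
                 replace = TRUE, prob = c(0.85, 0.15)),
               stringsAsFactors = FALSE)
  } else NULL
  mutations <- rbind(
    data.frame(Tumor_Sample_Barcode = rec_sample, Hugo_Symbol = rec_gene,
               Variant_Classification = rec_class, stringsAsFactors = FALSE),
    extra(msi, pg$mmr, 0.7), extra(hrd, pg$hr, 0.5), kras_rec)
  rownames(mutations) <- NULL

  # genomic scores consistent with planted membership
  in_brca_ov <- tumor_type %in% c("BRCA", "OV")
  mantis <- ifelse(msi, stats::runif(n, 0.45, 0.85), stats::runif(n, 0, 0.38))
  mantis[!msi & stats::runif(n) < 0.02] <- NA  # sporadic missingness
  hrd_score <- ifelse(hrd,
                      ifelse(in_brca_ov, stats::runif(n, 46, 90),
                             stats::runif(n, 27, 70)),
                      ifelse(in_brca_ov, stats::runif(n, 0, 44),
                             stats::runif(n, 0, 25)))
  msisensor <- ifelse(msi, stats::runif(n, 0.25, 1.5), stats::runif(n, 0, 0.18))

  # outcomes: exponential survival with the planted hazard for score-high
  # independent uniform censoring C ~ U(0, M), with M solved so the
  # baseline-group censoring fraction P(C < T) equals censoring_rate
  draw_surv <- function(median_days) {
    base_rate <- log(2) / median_days
    rate <- base_rate * ifelse(hi, cfg$hazard_ratio_hi, 1)
    t <- stats::rexp(n, rate)
    if (cfg$censoring_rate > 0) {
      x <- stats::uniroot(function(x) (1 - exp(-x)) / x - cfg$censoring_rate,
                          c(1e-8, 1e6), tol = 1e-10)$root
      cens_time <- stats::runif(n, 0, x / base_rate)
      list(time = pmax(pmin(t, cens_time), 0.51),
           event = as.integer(t <= cens_time))
    } else {
      list(time = pmax(t, 0.51), event = rep(1L, n))
    }
  }
  ttp <- draw_surv(cfg$ttp_median_days)
  os <- draw_surv(cfg$os_median_days)

  dcb_p <- cfg$dcb_prob_by_group[match(group, c("hi", "med", "lo"))]
  dcb <- stats::runif(n) < dcb_p
  progressed <- ifelse(dcb, FALSE, stats::runif(n) < 0.8)
  duration <- ifelse(dcb, stats::runif(n, 190, 700),
                     ifelse(progressed, stats::runif(n, 5, 400),
                            stats::runif(n, 5, 182)))

  clinical <- data.frame(
    sample_id = sample_id, patient_id = sample_id, tumor_type = tumor_type,
    ttp_days = ttp$time, ttp_event = ttp$event,
    os_days = os$time, os_event = os$event,
    treatment_duration_days = duration, progressed = as.integer(progressed),
    dcb = ifelse(dcb, "DCB", "NCB"),
    mantis = mantis, hrd_score = hrd_score, msisensor = msisensor,
    stringsAsFactors = FALSE)

  structure(list(
    expression = expr, mutations = mutations, clinical = clinical,
    genesets = genesets,
    truth = list(latent = stats::setNames(inflam, sample_id),
                 group = stats::setNames(group, sample_id),
                 msi = stats::setNames(msi, sample_id),
                 hrd = stats::setNames(hrd, sample_id),
                 kras_mutant = stats::setNames(kras_mut, sample_id),
                 cold_types = cold_types, assoc_types = assoc_types,
                 thresholds = thresholds, config = cfg)
  ), class = "chemo_cohort")
}

# Plant an exact (rounded) per-type number of flagged samples, positions
# chosen at random within each type.
.plant_exact <- function(tumor_type, frac_by_type, type_names) {
  flag <- logical(length(tumor_type))
  for (i in seq_along(type_names)) {
    idx <- which(tumor_type == type_names[i])
    k <- round(frac_by_type[i] * length(idx))
    if (k > 0L) flag[sample(idx, k)] <- TRUE
  }
  flag
}

#' @export
print.chemo_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d samples, %d tumor types, %d genes, %d mutation records\n",
              ncol(x$expression), length(unique(x$clinical$tumor_type)),
              nrow(x$expression), nrow(x$mutations)))
  invisible(x)
}

#' Write a simulated cohort to disk in the standard input formats
#'
#' Emits `expression.tsv` (TPM scale, genes x samples), `mutations.tsv`
#' (MAF-style columns), `clinical.tsv` and `genesets.gmt` into `dir`, so
#' that simulated data exercise the same readers as real data.
#'
#' @param cohort A `chemo_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "chemo_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             mutations = file.path(dir, "mutations.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             genesets = file.path(dir, "genesets.gmt"))
  write_expression(cohort$expression, paths[["expression"]], scale = "tpm")
  write_tsv(cohort$mutations, paths[["mutations"]])
  write_tsv(cohort$clinical, paths[["clinical"]])
  write_genesets(cohort$genesets, paths[["genesets"]])
  invisible(paths)
}
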