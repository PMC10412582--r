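# MSI / HRD genomic subtyping, TMB-association classification of tumor
# types, and contingency-table summaries.

#' Classify MANTIS microsatellite-instability scores
#'
#' High when the score is strictly greater than 0.4; missing scores are
#' classified low so that every sample receives a label (the number of
#' missing scores imputed low is attached as attribute `"n_missing"`).
#'
#' @param score Numeric vector of MANTIS scores (NA allowed).
#' @param cutoff Strict threshold, default 0.4.
#' @return Factor hi/lo.
#' @export
classify_mantis <- function(score, cutoff = 0.4) {
  cls <- factor(ifelse(!is.na(score) & score > cutoff, "hi", "lo"),
                levels = c("hi", "lo"))
  attr(cls, "n_missing") <- sum(is.na(score))
  cls
}

#' Classify MSIsensor scores
#'
#' High when strictly above 0.2; missing scores are low.
#'
#' @param score Numeric vector (NA allowed).
#' @param cutoff Strict threshold, default 0.2.
#' @return Factor hi/lo.
#' @export
classify_msisensor <- function(score, cutoff = 0.2) {
  cls <- factor(ifelse(!is.na(score) & score > cutoff, "hi", "lo"),
                levels = c("hi", "lo"))
  attr(cls, "n_missing") <- sum(is.na(score))
  cls
}

#' Fixed HRDScore thresholds
#'
#' The shipped defaults: HRD-high at a score of at least 46 in BRCA and OV
#' and at least 27 in all other tumor types.
#'
#' @return List with `brca_ov`, `other` and `source`.
#' @export
hrd_fixed_thresholds <- function() {
  list(brca_ov = 46, other = 27, source = "fixed")
}

#' Cohort-relative HRDScore thresholds
#'
#' BRCA and OV show far more homologous-recombination deficiency than other
#' tumor types, so the third quartile is computed separately within the
#' BRCA/OV stratum and within the remainder (same type-7 interpolation
#' convention as [derive_thresholds()]).
#'
#' @param scores Numeric HRDScore vector (NA dropped per stratum).
#' @param tumor_type Tumor-type codes aligned with `scores`.
#' @param brca_ov_types Types forming the high-prevalence stratum.
#' @return List with `brca_ov`, `other` and `source = "cohort"`.
#' @export
hrd_thresholds <- function(scores, tumor_type,
                           brca_ov_types = c("BRCA", "OV")) {
  stopifnot(length(scores) == length(tumor_type))
  in_stratum <- tumor_type %in% brca_ov_types
  q3 <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    stats::quantile(x, 0.75, type = 7, names = FALSE)
  }
  list(brca_ov = q3(scores[in_stratum]), other = q3(scores[!in_stratum]),
       source = "cohort")
}

#' Classify HRDScores against stratum thresholds
#'
#' High when the score is at least the threshold of the sample's stratum
#' (inclusive); missing scores are low.
#'
#' @param scores Numeric HRDScore vector.
#' @param tumor_type Tumor-type codes aligned with `scores`.
#' @param thresholds From [hrd_fixed_thresholds()] or [hrd_thresholds()].
#' @param brca_ov_types Types using the `brca_ov` threshold.
#' @return Factor hi/lo.
#' @export
classify_hrd <- function(scores, tumor_type,
                         thresholds = hrd_fixed_thresholds(),
                         brca_ov_types = c("BRCA", "OV")) {
  cut <- ifelse(tumor_type %in% brca_ov_types,
                thresholds$brca_ov, thresholds$other)
  cls <- factor(ifelse(!is.na(scores) & scores >= cut, "hi", "lo"),
                levels = c("hi", "lo"))
  attr(cls, "n_missing") <- sum(is.na(scores))
  cls
}

#' Resolve the final genomic subtype
#'
#' After c-Score stratification, MSI takes precedence over HRD: a sample is
#' `MANTIS_hi` whenever its MANTIS class is high (regardless of HRD), else
#' `HRDScore_hi` when its HRD class is high, else it keeps its pooled c-Score
#' label (`cScore_hi` or `cScore_lo_med`).  Every sample receives exactly one
#' subtype.
#'
#' @param cscore_group hi/med/lo or pooled hi/"lo+med" labels.
#' @param mantis_class hi/lo from [classify_mantis()].
#' @param hrd_class hi/lo from [classify_hrd()].
#' @return Factor with levels MANTIS_hi, HRDScore_hi, cScore_hi,
#'   cScore_lo_med.
#' @export
resolve_subtype <- function(cscore_group, mantis_class, hrd_class) {
  pooled <- as.character(cscore_group)
  pooled[pooled %in% c("med", "lo", "lo+med")] <- "lo+med"
  if (!all(pooled %in% c("hi", "lo+med")))
    stop("cscore_group must contain hi/med/lo or hi/'lo+med' labels")
  out <- ifelse(as.character(mantis_class) == "hi", "MANTIS_hi",
         ifelse(as.character(hrd_class) == "hi", "HRDScore_hi",
         ifelse(pooled == "hi", "cScore_hi", "cScore_lo_med")))
  factor(out, levels = c("MANTIS_hi", "HRDScore_hi", "cScore_hi",
                         "cScore_lo_med"))
}

#' Classify tumor types as TMB-associated
#'
#' Per tumor type, compares TMB between the c-Score-high and pooled lo+med
#' groups with a two-sided Wilcoxon rank-sum test; P values are
#' Benjamini-Hochberg adjusted across types.  A type is associated when the
#' adjusted P is below `alpha` and the high group's median TMB exceeds the
#' pooled group's.  Types with an empty group are unassociated (with a
#' warning) and excluded from the adjustment.
#'
#' @param tmb Data frame from [compute_tmb()] (columns `sample_id`, `tmb`).
#' @param cohort Stratified cohort with `sample_id`, `group`, `tumor_type`.
#' @param alpha Significance level on the adjusted P, default 0.05.
#' @return Data frame, one row per tumor type: group sizes, medians,
#'   Wilcoxon statistic, raw and adjusted P, direction and `associated`.
#' @export
classify_tmb_association <- function(tmb, cohort, alpha = 0.05) {
  stopifnot(all(c("sample_id", "tmb") %in% names(tmb)),
            all(c("sample_id", "group", "tumor_type") %in% names(cohort)))
  d <- merge(cohort, tmb[, c("sample_id", "tmb")], by = "sample_id")
  d$pooled <- pool_groups(d$group)
  types <- sort(unique(d$tumor_type))
  rows <- lapply(types, function(tt) {
    hi <- d$tmb[d$tumor_type == tt & d$pooled == "hi"]
    lm <- d$tmb[d$tumor_type == tt & d$pooled == "lo+med"]
    if (!length(hi) || !length(lm)) {
      warning(sprintf("tumor type '%s' has an empty c-Score group; unassociated", tt))
      return(data.frame(tumor_type = tt, n_hi = length(hi),
                        n_lo_med = length(lm), median_hi = NA_real_,
                        median_lo_med = NA_real_, statistic = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    wt <- suppressWarnings(stats::wilcox.test(hi, lm, exact = FALSE))
    data.frame(tumor_type = tt, n_hi = length(hi), n_lo_med = length(lm),
               median_hi = stats::median(hi), median_lo_med = stats::median(lm),
               statistic = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- adjust_fdr(out$p[ok])
  out$direction <- ifelse(!is.na(out$median_hi) &
                            out$median_hi > out$median_lo_med, "hi>lo+med",
                          "not_higher")
  out$associated <- ok & !is.na(out$p_adj) & out$p_adj < alpha &
    out$direction == "hi>lo+med"
  out
}

#' Cross-tabulate two labellings with an association test
#'
#' Builds the contingency table of `labels_a` (rows) by `labels_b` (columns)
#' and tests association with Fisher's exact test or a chi-squared test
#' without continuity correction.
#'
#' @param labels_a,labels_b Vectors of equal length, or `table` may be given
#'   directly via `tab`.
#' @param test `"fisher"` or `"chisq"`.
#' @param tab Optional pre-built contingency table (matrix); overrides the
#'   label vectors.
#' @return List with `table`, row-wise `proportions`, `method`, `statistic`
#'   (chi-squared only) and `p_value`.
#' @export
cross_tabulate <- function(labels_a = NULL, labels_b = NULL,
                           test = c("fisher", "chisq"), tab = NULL) {
  test <- match.arg(test)
  if (is.null(tab)) {
    stopifnot(length(labels_a) == length(labels_b))
    tab <- table(labels_a, labels_b)
  }
  tab <- as.matrix(tab)
  if (test == "fisher") {
    ft <- stats::fisher.test(tab)
    res <- list(table = tab, proportions = prop.table(tab, 1L),
                method = "fisher", statistic = NA_real_, p_value = ft$p.value)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    res <- list(table = tab, proportions = prop.table(tab, 1L),
                method = "chisq", statistic = unname(ct$statistic),
                p_value = ct$p.value)
  }
  res
}
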