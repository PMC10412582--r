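# Clinical-benefit labels, Kaplan-Meier / log-rank survival comparisons,
# Cox proportional-hazards models, and the covariate-controlled and
# rank-based group comparisons used throughout the analyses.

#' Durable clinical benefit label
#'
#' DCB requires treatment for strictly more than six months (183 days)
#' without disease progression within that time; everything else is NCB.
#'
#' @param treatment_duration_days Numeric vector of days on treatment.
#' @param progressed_within Logical vector: progression during treatment.
#' @param min_days Strict duration cutoff in days; default 183 (six months).
#' @return Factor DCB/NCB.
#' @export
derive_dcb <- function(treatment_duration_days, progressed_within,
                       min_days = 183) {
  stopifnot(length(treatment_duration_days) == length(progressed_within))
  dcb <- treatment_duration_days > min_days & !progressed_within
  factor(ifelse(dcb, "DCB", "NCB"), levels = c("DCB", "NCB"))
}

#' Per-group response rates with a chi-squared test
#'
#' Tabulates DCB / NCB counts per group, reports the percentage with benefit,
#' and tests the group-by-benefit table with a chi-squared test without
#' continuity correction.
#'
#' @param dcb Factor/character of DCB/NCB labels.
#' @param groups Group labels aligned with `dcb`.
#' @return List: `rates` (data frame group, n, n_dcb, rate_pct), `table`,
#'   `p_value`.
#' @export
response_rates <- function(dcb, groups) {
  stopifnot(length(dcb) == length(groups))
  dcb <- factor(as.character(dcb), levels = c("DCB", "NCB"))
  tab <- table(groups, dcb)
  rates <- data.frame(
    group = rownames(tab),
    n = as.integer(rowSums(tab)),
    n_dcb = as.integer(tab[, "DCB"]),
    rate_pct = 100 * tab[, "DCB"] / rowSums(tab),
    stringsAsFactors = FALSE, row.names = NULL
  )
  p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
  list(rates = rates, table = tab, p_value = p)
}

#' Kaplan-Meier curves, medians and a log-rank test
#'
#' Fits the product-limit estimator per group, reports the median survival
#' (first time the estimate drops to 0.5 or below; NA when never reached)
#' and the log-rank P across groups.
#'
#' @param time Follow-up times (days, positive).
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Group labels.
#' @return List: `fit` (a [survival::survfit] object), `medians` (named
#'   vector, NA = not reached), `p_value` (log-rank; NA if a single group).
#' @export
km_logrank <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  if (any(time <= 0)) stop("survival times must be positive")
  d <- data.frame(time = time, event = event, group = factor(group))
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  st <- summary(fit)$table
  if (is.null(dim(st))) {  # single group
    medians <- stats::setNames(st[["median"]], levels(d$group))
    p <- NA_real_
  } else {
    medians <- stats::setNames(st[, "median"],
                               sub("^group=", "", rownames(st)))
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
    p <- stats::pchisq(sd_$chisq, df = length(sd_$n) - 1L, lower.tail = FALSE)
  }
  list(fit = fit, medians = medians, p_value = p)
}

#' Cox proportional-hazards model with Efron tie handling
#'
#' Fits a partial-likelihood Cox model of the requested terms, using the
#' Efron approximation for tied event times.  Per-term hazard ratios carry
#' Wald 95% confidence intervals and P values; the model-level P is the
#' score (log-rank) test.  When `tumor_type` is among the terms, tumor types
#' with fewer than `min_type_n` samples are dropped before fitting.
#' Constant covariates are an error; convergence problems are flagged on the
#' result rather than silently ignored.
#'
#' @param data Data frame holding times, events and covariates.
#' @param time,event Column names of the follow-up time and event indicator.
#' @param terms Character vector of covariate column names.
#' @param min_type_n Minimum samples per tumor type kept, default 3.
#' @return List: `terms` (data frame term, hr, ci_lo, ci_hi, p_wald),
#'   `score_p` (log-rank model P), `n`, `flagged` (TRUE on
#'   convergence/separation warnings), `fit`.
#' @export
cox_ph <- function(data, time = "time", event = "event", terms,
                   min_type_n = 3L) {
  stopifnot(is.data.frame(data), all(c(time, event, terms) %in% names(data)))
  if ("tumor_type" %in% terms) {
    counts <- table(data$tumor_type)
    keep <- names(counts)[counts >= min_type_n]
    data <- data[data$tumor_type %in% keep, , drop = FALSE]
    data$tumor_type <- droplevels(factor(data$tumor_type))
  }
  for (tm in terms) {
    if (length(unique(data[[tm]])) < 2L)
      stop(sprintf("covariate '%s' is constant; no information", tm))
  }
  fml <- stats::as.formula(sprintf("survival::Surv(%s, %s) ~ %s", time, event,
                                   paste(terms, collapse = " + ")))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  s <- summary(fit)
  ci <- s$conf.int
  out <- data.frame(
    term = rownames(s$coefficients),
    hr = unname(s$coefficients[, "exp(coef)"]),
    ci_lo = unname(ci[, "lower .95"]),
    ci_hi = unname(ci[, "upper .95"]),
    p_wald = unname(s$coefficients[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(terms = out, score_p = unname(s$sctest["pvalue"]), n = s$n,
       flagged = flagged, fit = fit)
}

#' Two-sided Wilcoxon rank-sum comparison of two groups
#'
#' @param values Numeric vector.
#' @param groups Two-level grouping aligned with `values`.
#' @return List: `statistic` (rank-sum W for the first level), `p_value`,
#'   `medians` (named), `direction` (level with the larger median, or
#'   `"none"`).
#' @export
group_compare <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("group_compare requires exactly two groups")
  x <- values[g == levels(g)[1L]]
  y <- values[g == levels(g)[2L]]
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  med <- c(stats::median(x), stats::median(y))
  names(med) <- levels(g)
  dir <- if (med[1L] > med[2L]) levels(g)[1L]
         else if (med[2L] > med[1L]) levels(g)[2L] else "none"
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       medians = med, direction = dir)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' @param raw_ps Numeric vector of raw P values.
#' @return Adjusted P values (same order as the input).
#' @export
adjust_fdr <- function(raw_ps) {
  stats::p.adjust(raw_ps, method = "BH")
}

#' Group effect controlled for covariates
#'
#' Regresses the response on a group indicator plus covariate indicators and
#' reports the group coefficient and its P value.  The default is the
#' ordinary-least-squares linear model; `family = "logistic"` fits a
#' binomial GLM instead for binary responses.
#'
#' @param response Numeric (or 0/1) response vector.
#' @param group Two-level grouping.
#' @param covariates Data frame of covariates (each coerced to factor when
#'   non-numeric), or NULL.
#' @param family `"linear"` (default) or `"logistic"`.
#' @return List: `estimate` (group coefficient, effect of the second level
#'   relative to the first), `p_value`, `fit`.
#' @export
controlled_compare <- function(response, group, covariates = NULL,
                               family = c("linear", "logistic")) {
  family <- match.arg(family)
  g <- factor(group)
  if (nlevels(g) != 2L) stop("controlled_compare requires exactly two groups")
  d <- data.frame(.y = response, .g = g)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(response))
    d <- cbind(d, covariates)
  }
  fml <- stats::as.formula(paste(".y ~ .g +",
                                 paste(c("1", names(covariates)),
                                       collapse = " + ")))
  fit <- if (family == "linear") stats::lm(fml, data = d)
         else stats::glm(fml, data = d, family = stats::binomial())
  cf <- summary(fit)$coefficients
  row <- grep("^\\.g", rownames(cf))
  list(estimate = unname(cf[row, 1L]), p_value = unname(cf[row, 4L]),
       fit = fit)
}

#' Spearman correlation of paired per-type medians
#'
#' @param x,y Numeric vectors of equal length (e.g. per-tumor-type median
#'   TMB and median c-Score).
#' @return List: `rho`, `p_value`, `n`.
#' @export
correlate_medians <- function(x, y) {
  stopifnot(length(x) == length(y))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
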