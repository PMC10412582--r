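# c-Score computation and quartile stratification.

#' Fixed pan-cancer stratification thresholds
#'
#' The first- and third-quartile c-Score cutoffs derived from the 6,987-sample
#' pan-cancer reference cohort, shipped as named defaults.  Use
#' [derive_thresholds()] for cohort-relative stratification instead.
#'
#' @return A `strat_thresholds` object with elements `q1`, `q3` and `source`.
#' @export
#' @examples
#' fixed_thresholds()
fixed_thresholds <- function() {
  new_thresholds(q1 = 1.940425, q3 = 4.835088, source = "fixed")
}

new_thresholds <- function(q1, q3, source) {
  stopifnot(is.numeric(q1), is.numeric(q3), length(q1) == 1L, length(q3) == 1L)
  if (is.na(q1) || is.na(q3)) stop("thresholds must not be NA")
  if (q1 > q3) stop("q1 must not exceed q3")
  structure(list(q1 = q1, q3 = q3, source = source),
            class = "strat_thresholds")
}

#' @export
print.strat_thresholds <- function(x, ...) {
  cat(sprintf("c-Score stratification thresholds (%s): q1 = %g, q3 = %g\n",
              x$source, x$q1, x$q3))
  invisible(x)
}

#' Compute the per-sample c-Score
#'
#' The c-Score of a sample is the arithmetic mean of the stored
#' log2(TPM + 0.001) expression of CCL4, CCL5, CXCL9 and CXCL10.
#'
#' @param mat Expression matrix on the stored log2(TPM + 0.001) scale,
#'   genes in rows (rownames are gene symbols), samples in columns.
#' @return Named numeric vector of c-Scores, one per sample.
#' @export
#' @examples
#' m <- matrix(log2(1 + 0.001), 4, 2,
#'             dimnames = list(CHEMOKINE_GENES, c("s1", "s2")))
#' compute_cscore(m)  # log2(1.001) for both samples
compute_cscore <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  missing <- setdiff(CHEMOKINE_GENES, rownames(mat))
  if (length(missing))
    stop("chemokine gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  colMeans(mat[CHEMOKINE_GENES, , drop = FALSE])
}

#' Derive quartile stratification thresholds from a score vector
#'
#' Computes the first and third quartiles of the supplied c-Scores by linear
#' interpolation between order statistics at position (n - 1) * p + 1 (the
#' convention of [stats::quantile()] type 7).  With 6,987 distinct scores this
#' convention places exactly one quarter of the cohort at or above q3 and one
#' quarter at or below q1.
#'
#' @param scores Numeric vector of c-Scores; at least 4 values.
#' @return A `strat_thresholds` object with `source = "cohort"`.
#' @export
derive_thresholds <- function(scores) {
  scores <- as.numeric(scores)
  if (anyNA(scores)) stop("scores must not contain NA")
  if (length(scores) < 4L) stop("at least 4 scores are required")
  q <- stats::quantile(scores, probs = c(0.25, 0.75), type = 7, names = FALSE)
  new_thresholds(q1 = q[1], q3 = q[2], source = "cohort")
}

#' Assign hi / med / lo groups from c-Scores and thresholds
#'
#' A sample is `hi` if its score is greater than or equal to q3, otherwise
#' `lo` if less than or equal to q1, otherwise `med`.  In the degenerate case
#' q1 == q3 the hi rule is tested first, so a score equal to both thresholds
#' is `hi`; every sample receives exactly one group.
#'
#' @param scores Named numeric vector of c-Scores (names are sample ids).
#' @param thresholds A `strat_thresholds` object, e.g. from
#'   [fixed_thresholds()] or [derive_thresholds()].
#' @param tumor_type Optional vector of tumor-type codes, recycled against
#'   `scores`.
#' @return Data frame with columns `sample_id`, `c_score`, `group`
#'   (factor hi/med/lo) and, if given, `tumor_type`; the thresholds used are
#'   attached as attribute `"thresholds"`.
#' @export
stratify <- function(scores, thresholds = fixed_thresholds(),
                     tumor_type = NULL) {
  stopifnot(inherits(thresholds, "strat_thresholds"))
  scores <- stats::setNames(as.numeric(scores), names(scores))
  if (anyNA(scores)) stop("scores must not contain NA")
  group <- ifelse(scores >= thresholds$q3, "hi",
                  ifelse(scores <= thresholds$q1, "lo", "med"))
  out <- data.frame(
    sample_id = if (is.null(names(scores))) seq_along(scores) else names(scores),
    c_score = unname(scores),
    group = factor(group, levels = c("hi", "med", "lo")),
    stringsAsFactors = FALSE
  )
  if (!is.null(tumor_type)) out$tumor_type <- rep_len(tumor_type, nrow(out))
  attr(out, "thresholds") <- thresholds
  out
}

#' Tumor types eligible for group comparisons
#'
#' A tumor type is included only when each of the hi, med and lo groups
#' contains at least `min_per_group` samples.
#'
#' @param cohort Stratified cohort from [stratify()]; must carry a
#'   `tumor_type` column.
#' @param min_per_group Minimum samples per group (default 5).
#' @return Character vector of included tumor types (sorted).
#' @export
filter_tumor_types <- function(cohort, min_per_group = 5L) {
  stopifnot(is.data.frame(cohort), "tumor_type" %in% names(cohort))
  tab <- table(cohort$tumor_type, factor(cohort$group,
                                         levels = c("hi", "med", "lo")))
  keep <- rownames(tab)[apply(tab >= min_per_group, 1L, all)]
  sort(keep)
}

#' Pool med and lo into a single reference group
#'
#' Collapses the three-level stratification to the binary comparison used for
#' enrichment, TMB and outcome analyses: hi versus lo+med.
#'
#' @param group Factor or character vector with values hi/med/lo.
#' @return Factor with levels `"hi"` and `"lo+med"`.
#' @export
pool_groups <- function(group) {
  group <- as.character(group)
  bad <- setdiff(unique(group), c("hi", "med", "lo", NA))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  factor(ifelse(group == "hi", "hi", "lo+med"), levels = c("hi", "lo+med"))
}
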