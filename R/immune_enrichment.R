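# Gene filtering, geneset preparation, single-sample gene-set enrichment
# (ssGSEA) and the arbitrary-unit (AU) rescaling of group medians.

#' Remove genes with zero TPM in more than half the samples
#'
#' A stored value equal to log2(0.001) marks a TPM of zero.  A gene is
#' removed when its fraction of zero-TPM samples is strictly greater than
#' `max_zero_fraction`; a gene at exactly the boundary is retained.
#'
#' @param mat Expression matrix on the log2(TPM + 0.001) scale.
#' @param max_zero_fraction Maximum tolerated zero fraction, default 0.5.
#' @return The filtered matrix.
#' @export
filter_expressed_genes <- function(mat, max_zero_fraction = 0.5) {
  stopifnot(is.matrix(mat), ncol(mat) > 0L)
  zero <- abs(mat - log_zero_tpm()) < 1e-9
  keep <- rowMeans(zero) <= max_zero_fraction
  mat[keep, , drop = FALSE]
}

#' Strip the c-Score chemokines from genesets
#'
#' CCL4, CCL5, CXCL9 and CXCL10 define the stratification itself, so they are
#' removed from every geneset before enrichment to avoid scoring the
#' signature against itself.  A geneset emptied by the removal is dropped
#' with a warning.
#'
#' @param genesets Named list of character vectors.
#' @return The prepared list.
#' @export
prepare_genesets <- function(genesets) {
  out <- lapply(genesets, setdiff, y = CHEMOKINE_GENES)
  empty <- vapply(out, length, integer(1L)) == 0L
  if (any(empty)) {
    warning("geneset(s) emptied by chemokine removal and dropped: ",
            paste(names(out)[empty], collapse = ", "))
    out <- out[!empty]
  }
  out
}

# Single-sample enrichment score for one sample's rank vector and one
# in-set indicator, both in descending-expression order.
# rnk_desc: tie-averaged expression ranks (largest expression = largest
# rank), reordered so position 1 is the most highly expressed gene.
.ssgsea_sample <- function(rnk_desc, inset_desc, tau) {
  m <- sum(inset_desc)
  w <- ifelse(inset_desc, rnk_desc^tau, 0)
  step_in <- cumsum(w) / sum(w)
  step_out <- cumsum(!inset_desc) / (length(inset_desc) - m)
  sum(step_in - step_out)
}

#' Single-sample gene-set enrichment (ssGSEA)
#'
#' For each sample, genes are ranked by expression (ties by average rank) and
#' walked in descending order; the enrichment score is the sum over positions
#' of the difference between the weighted in-set empirical CDF (weights equal
#' to rank^tau) and the uniform out-of-set empirical CDF.  With
#' `normalize = TRUE` all scores of the run are divided by the range
#' (max - min) of the whole geneset-by-sample score matrix, the documented
#' behaviour of the standard implementation.
#'
#' @param mat Expression matrix (genes x samples), any monotone scale.
#' @param genesets Named list of character vectors, or a single character
#'   vector (treated as one geneset called `"set"`).
#' @param tau Rank-weighting exponent, default 0.25.
#' @param normalize Divide by the overall score range, default TRUE.
#' @return Matrix of scores, genesets x samples, with attributes `tau` and
#'   `normalized`.
#' @export
ssgsea <- function(mat, genesets, tau = 0.25, normalize = TRUE) {
  stopifnot(is.matrix(mat), is.numeric(mat), nrow(mat) >= 2L)
  if (!is.list(genesets)) genesets <- list(set = genesets)
  if (is.null(names(genesets))) stop("genesets must be named")
  genes <- rownames(mat)
  inset <- lapply(names(genesets), function(nm) {
    hit <- genes %in% genesets[[nm]]
    if (!any(hit)) stop(sprintf("geneset '%s' shares no genes with the matrix", nm))
    if (all(hit)) stop(sprintf("geneset '%s' covers every gene; empty out-set", nm))
    hit
  })
  rnk <- apply(mat, 2L, rank)  # ties: average rank
  es <- matrix(NA_real_, length(genesets), ncol(mat),
               dimnames = list(names(genesets), colnames(mat)))
  for (s in seq_len(ncol(mat))) {
    ord <- order(rnk[, s], decreasing = TRUE)
    r_desc <- rnk[ord, s]
    for (g in seq_along(inset)) {
      es[g, s] <- .ssgsea_sample(r_desc, inset[[g]][ord], tau)
    }
  }
  if (normalize) {
    rng <- max(es) - min(es)
    if (rng > 0) es <- es / rng
  }
  attr(es, "tau") <- tau
  attr(es, "normalized") <- normalize
  es
}

#' Arbitrary-unit (AU) rescaling of group enrichment medians
#'
#' Translates per-geneset group medians onto a positive scale by adding a
#' pseudo-value of one minus the reference-group (lo+med) median:
#' AU(geneset, group) = median(group) + 1 - median(lo+med).  The reference
#' group's AU is therefore exactly 1 for every geneset, and between-group
#' median differences are preserved.  This is a display transform; tests are
#' run on the untransformed scores.
#'
#' @param scores Enrichment matrix from [ssgsea()] (genesets x samples).
#' @param pooled_groups Vector of pooled labels ("hi" / "lo+med") aligned
#'   with the columns of `scores`; see [pool_groups()].
#' @param reference Reference group label, default `"lo+med"`.
#' @return Data frame with one row per geneset x group: `geneset`, `group`,
#'   `median_score`, `au`.
#' @export
au_transform <- function(scores, pooled_groups, reference = "lo+med") {
  stopifnot(is.matrix(scores), length(pooled_groups) == ncol(scores))
  pooled_groups <- as.character(pooled_groups)
  groups <- unique(pooled_groups)
  if (!reference %in% groups)
    stop(sprintf("reference group '%s' is empty", reference))
  if (any(!table(pooled_groups) > 0L)) stop("empty group")
  rows <- lapply(rownames(scores), function(gs) {
    med <- vapply(groups, function(g)
      stats::median(scores[gs, pooled_groups == g]), numeric(1L))
    au <- unname(med) + 1 - med[[reference]]
    au[groups == reference] <- 1  # the identity holds exactly by definition
    data.frame(geneset = gs, group = groups,
               median_score = unname(med), au = au,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
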