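# Independent oracles used to validate the package's implementations.
# Each is written as a direct, scalar transcription of the defining
# formula or an exhaustive enumeration, never sharing code with the
# functions it checks.

# Term-by-term single-sample enrichment score: walk the descending-
# expression list one gene at a time, accumulating the weighted in-set and
# uniform out-of-set empirical CDFs.
oracle_ssgsea_one <- function(expr_vec, set_genes, tau) {
  genes <- names(expr_vec)
  r <- rank(expr_vec)
  ord <- order(r, decreasing = TRUE)
  in_set <- genes %in% set_genes
  total_w <- 0
  for (g in which(in_set)) total_w <- total_w + r[[g]]^tau
  n_out <- sum(!in_set)
  es <- 0; cum_in <- 0; cum_out <- 0
  for (i in ord) {
    if (in_set[[i]]) cum_in <- cum_in + r[[i]]^tau else cum_out <- cum_out + 1
    es <- es + cum_in / total_w - cum_out / n_out
  }
  es
}

# Two-sided Fisher exact P for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables with the observed margins whose
# probability does not exceed the observed table's (with the customary
# relative slack for floating point).
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n_ <- c_ + d; k <- a + c_
  support <- max(0, k - n_):min(k, m)
  probs <- dhyper(support, m, n_, k)
  p_obs <- dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Wilcoxon rank-sum P by full enumeration of all
# assignments of the pooled ranks to the first group (no ties assumed).
oracle_wilcoxon <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- rank(c(x, y))
  w_obs <- sum(pooled[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  ranks <- seq_len(n1 + n2)
  w_all <- apply(combos, 2, function(idx) sum(ranks[idx])) - n1 * (n1 + 1) / 2
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Benjamini-Hochberg step-up by direct arithmetic on the sorted P values.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- numeric(n)
  running_min <- Inf
  for (i in seq_len(n)) {
    idx <- o[i]
    rank_i <- n - i + 1
    running_min <- min(running_min, p[idx] * n / rank_i)
    adj[idx] <- min(1, running_min)
  }
  adj
}

# Maximum-partial-likelihood log hazard for a single binary covariate with
# no ties and no censoring, found by direct 1-D optimisation of the Cox
# partial log-likelihood written out term by term.
oracle_cox_binary <- function(time, x) {
  ord <- order(time)
  time <- time[ord]; x <- x[ord]
  n <- length(time)
  pll <- function(b) {
    ll <- 0
    for (i in seq_len(n)) {
      risk <- i:n
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }
  stats::optimize(pll, c(-10, 10), maximum = TRUE, tol = 1e-10)$maximum
}

# Small deterministic expression fixture on the stored log scale.
make_expr <- function(tpm, genes, samples) {
  matrix(log2(tpm + 0.001), nrow = length(genes),
         dimnames = list(genes, samples))
}
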