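test_that("durable clinical benefit needs >183 days without progression", {
  expect_equal(as.character(derive_dcb(c(200, 200, 183, 184),
                                       c(FALSE, TRUE, FALSE, FALSE))),
               c("DCB", "NCB", "NCB", "DCB"))
})

test_that("response rates reproduce the per-group percentages", {
  dcb <- c(rep(c("DCB", "NCB"), c(10, 18)),   # hi 10/28
           rep(c("DCB", "NCB"), c(7, 37)),    # med 7/44
           rep("NCB", 10))                    # lo 0/10
  groups <- rep(c("hi", "med", "lo"), c(28, 44, 10))
  rr <- response_rates(dcb, groups)
  rates <- setNames(rr$rates$rate_pct, rr$rates$group)
  expect_equal(round(unname(rates["hi"])), 36)
  expect_equal(round(unname(rates["med"])), 16)
  expect_equal(unname(rates["lo"]), 0)
  expect_lt(abs(rr$p_value - 0.029), 5e-4)
})

test_that("KM medians equal empirical medians without censoring", {
  km <- km_logrank(c(1, 2, 3, 4, 5, 6), rep(1, 6),
                   rep(c("A", "B"), each = 3))
  expect_equal(unname(km$medians["A"]), 2)
  expect_equal(unname(km$medians["B"]), 5)
  expect_lt(km$p_value, 0.05 + 1)  # defined

  # identical groups: log-rank P of 1 and equal medians
  km2 <- km_logrank(rep(c(3, 5, 8), 2), rep(1, 6), rep(c("A", "B"), each = 3))
  expect_equal(km2$p_value, 1)
  expect_equal(unname(km2$medians["A"]), unname(km2$medians["B"]))
})

test_that("KM estimate is nonincreasing from 1 and flags unreached medians", {
  set.seed(12)
  time <- rexp(40, 1 / 50)
  km <- km_logrank(time, rbinom(40, 1, 0.7), rep(c("A", "B"), 20))
  idx <- rep(seq_along(km$fit$strata), km$fit$strata)
  for (s in unique(idx)) {
    expect_true(all(diff(km$fit$surv[idx == s]) <= 1e-12))
    expect_lte(max(km$fit$surv[idx == s]), 1)
  }
  # heavy censoring: median never reached
  km3 <- km_logrank(c(10, 20, 30, 40), c(1, 0, 0, 0), rep("A", 4))
  expect_true(is.na(km3$medians["A"]))
})

test_that("Cox with a binary covariate matches the 1-D partial-likelihood oracle", {
  set.seed(8)
  d <- data.frame(time = c(2.1, 3.7, 1.2, 5.5, 4.4, 0.9, 7.3, 6.1),
                  event = 1,
                  x = c(1, 0, 1, 0, 1, 1, 0, 0))
  fit <- cox_ph(d, "time", "event", "x")
  expect_equal(log(fit$terms$hr), oracle_cox_binary(d$time, d$x),
               tolerance = 1e-6)
})

test_that("constant covariates are rejected and planted HRs recovered", {
  d <- data.frame(time = rexp(20) + 0.1, event = 1, x = 1)
  expect_error(cox_ph(d, "time", "event", "x"), "constant")

  set.seed(99)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.01 * ifelse(x == 1, 0.5, 1))
  fit <- cox_ph(data.frame(time = t, event = 1, x = x), "time", "event", "x")
  expect_true(fit$terms$ci_lo <= 0.5 && 0.5 <= fit$terms$ci_hi)
  expect_false(fit$flagged)
  expect_lt(fit$score_p, 0.001)
})

test_that("small tumor types are dropped before multivariate Cox fits", {
  set.seed(5)
  d <- data.frame(time = rexp(43) + 0.1, event = 1,
                  group = rbinom(43, 1, 0.5),
                  tumor_type = c(rep("A", 20), rep("B", 19), rep("C", 3),
                                 "D"))  # D has a single sample
  fit <- cox_ph(d, "time", "event", c("group", "tumor_type"))
  expect_equal(fit$n, 42L)  # D dropped, C (n = 3) kept
})

test_that("Wilcoxon comparison matches full permutation enumeration", {
  gc <- group_compare(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(gc$p_value, 0.1)
  expect_equal(gc$p_value, oracle_wilcoxon(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(gc$direction, "b")

  same <- group_compare(rep(c(5, 7, 9), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$p_value, 1)
  expect_equal(same$direction, "none")
})

test_that("Wilcoxon has power against a 1-SD shift at n = 200 per group", {
  set.seed(14)
  x <- rnorm(200); y <- rnorm(200, 1)
  gc <- group_compare(c(x, y), rep(c("a", "b"), each = 200))
  expect_lt(gc$p_value, 0.001)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.037), 0.037)
  set.seed(2)
  p <- runif(6)
  adj <- adjust_fdr(p)
  expect_true(all(adj >= p))
  expect_equal(adj, oracle_bh(p))
  # monotone in input ranks
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
})

test_that("covariate-controlled comparison recovers planted effects exactly", {
  g <- rep(c("ctrl", "case"), each = 20)
  cov <- rep(rep(c("u", "v"), each = 10), 2)  # balanced, orthogonal
  y <- ifelse(g == "case", 1, 0) * 1.0 + ifelse(cov == "v", 1, 0) * 2.0
  res <- suppressWarnings(  # noiseless fixture: perfect fit is the point
    controlled_compare(y, factor(g, levels = c("ctrl", "case")),
                       data.frame(cov = cov)))
  expect_equal(res$estimate, 1.0, tolerance = 1e-6)
  cf <- coef(res$fit)
  expect_equal(unname(cf[grep("cov", names(cf))]), 2.0, tolerance = 1e-6)

  # orthogonality: estimate equals the unadjusted mean difference
  set.seed(10)
  y2 <- rnorm(40)
  res2 <- controlled_compare(y2, factor(g, levels = c("ctrl", "case")),
                             data.frame(cov = cov))
  expect_equal(res2$estimate,
               mean(y2[g == "case"]) - mean(y2[g == "ctrl"]),
               tolerance = 1e-10)

  # logistic option runs and reports a finite estimate
  yb <- rbinom(40, 1, 0.5)
  res3 <- controlled_compare(yb, g, data.frame(cov = cov),
                             family = "logistic")
  expect_true(is.finite(res3$estimate))
})

test_that("Spearman correlation of medians behaves at the extremes", {
  expect_equal(correlate_medians(1:5, c(2, 4, 6, 9, 20))$rho, 1)
  expect_equal(correlate_medians(1:5, -(1:5))$rho, -1)
  x <- c(3, 1, 4, 1.5, 9)
  y <- c(2, 7, 1, 8, 3)
  # rank-Pearson by hand
  expect_equal(correlate_medians(x, y)$rho,
               cor(rank(x), rank(y)))
})

test_that("the planted hazard advantage shows in downstream KM medians", {
  cfg <- sim_config(n_tumor_types = 5, samples_per_type = 100,
                    n_cold_types = 0, n_tmb_assoc_types = 0,
                    hazard_ratio_hi = 0.5, seed = 121)
  co <- simulate_cohort(cfg)
  cs <- compute_cscore(co$expression)
  st <- stratify(cs, derive_thresholds(cs))
  pooled <- pool_groups(st$group)
  km <- km_logrank(co$clinical$ttp_days, co$clinical$ttp_event, pooled)
  expect_gt(unname(km$medians["hi"]), unname(km$medians["lo+med"]))
  expect_lt(km$p_value, 0.05)
})
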