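test_that("MANTIS and MSIsensor cutoffs are strict and missing maps low", {
  expect_equal(as.character(classify_mantis(c(0.41, 0.4, NA))),
               c("hi", "lo", "lo"))
  expect_equal(attr(classify_mantis(c(0.5, NA, NA)), "n_missing"), 2L)
  expect_equal(as.character(classify_msisensor(c(0.21, 0.2, NA))),
               c("hi", "lo", "lo"))
})

test_that("HRD thresholds are stratum-wise third quartiles with fixed defaults", {
  th <- hrd_thresholds(c(10, 20, 46, 80, 1, 2, 3, 4),
                       c(rep("BRCA", 4), rep("LUAD", 4)))
  expect_equal(th$brca_ov, 54.5)
  expect_equal(th$other, 3.25)

  # fixed defaults: >= 46 in BRCA/OV, >= 27 elsewhere (inclusive)
  cls <- classify_hrd(c(46, 45.9, 27, 26.9, NA),
                      c("BRCA", "OV", "LUAD", "LUAD", "LUAD"))
  expect_equal(as.character(cls), c("hi", "lo", "hi", "lo", "lo"))
})

test_that("subtype precedence is MSI, then HRD, then the pooled c-Score label", {
  expect_equal(as.character(resolve_subtype("hi", "hi", "hi")), "MANTIS_hi")
  expect_equal(as.character(resolve_subtype("lo", "lo", "hi")), "HRDScore_hi")
  expect_equal(as.character(resolve_subtype("hi", "lo", "lo")), "cScore_hi")
  expect_equal(as.character(resolve_subtype("med", "lo", "lo")), "cScore_lo_med")
  expect_error(resolve_subtype("weird", "lo", "lo"), "labels")
})

test_that("every sample receives exactly one resolved subtype", {
  combos <- expand.grid(g = c("hi", "med", "lo"), m = c("hi", "lo"),
                        h = c("hi", "lo"), stringsAsFactors = FALSE)
  out <- resolve_subtype(combos$g, combos$m, combos$h)
  expect_false(anyNA(out))
  expect_length(out, nrow(combos))
})

test_that("TMB association needs both direction and adjusted significance", {
  set.seed(42)
  n <- 60
  cohort <- data.frame(
    sample_id = paste0("S", 1:(3 * n)),
    group = rep(rep(c("hi", "med", "lo"), each = n / 3), 3),
    tumor_type = rep(c("null", "up", "down"), each = n))
  tmb <- data.frame(sample_id = cohort$sample_id, tmb = rnorm(3 * n, 10))
  hi <- cohort$group == "hi"
  tmb$tmb[cohort$tumor_type == "up" & hi] <- tmb$tmb[cohort$tumor_type == "up" & hi] + 15
  tmb$tmb[cohort$tumor_type == "down" & hi] <- tmb$tmb[cohort$tumor_type == "down" & hi] - 15

  res <- classify_tmb_association(tmb, cohort)
  expect_true(res$associated[res$tumor_type == "up"])
  expect_false(res$associated[res$tumor_type == "null"])
  # higher median in the pooled group with a significant P is still unassociated
  expect_false(res$associated[res$tumor_type == "down"])
  expect_true(res$p_adj[res$tumor_type == "down"] < 0.05)
})

test_that("TMB association is invariant to monotone transforms and sample order", {
  set.seed(7)
  cohort <- data.frame(sample_id = paste0("S", 1:80),
                       group = rep(c("hi", "med"), 40),
                       tumor_type = rep(c("A", "B"), each = 40))
  tmb <- data.frame(sample_id = cohort$sample_id,
                    tmb = rexp(80) + ifelse(cohort$group == "hi", 1, 0))
  r1 <- classify_tmb_association(tmb, cohort)
  tmb2 <- transform(tmb, tmb = log1p(tmb)^3)
  r2 <- classify_tmb_association(tmb2, cohort)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$associated, r2$associated)
  shuf <- sample(nrow(tmb))
  r3 <- classify_tmb_association(tmb[shuf, ], cohort[shuf, ])
  expect_equal(r1$p, r3$p)
})

test_that("a type with an empty group is unassociated with a warning", {
  cohort <- data.frame(sample_id = paste0("S", 1:10),
                       group = "med", tumor_type = "A")
  tmb <- data.frame(sample_id = cohort$sample_id, tmb = 1:10)
  expect_warning(res <- classify_tmb_association(tmb, cohort), "empty")
  expect_false(res$associated)
})

test_that("chi-squared cross-tabulation reproduces the 3x2 benefit table P", {
  tab <- matrix(c(10, 18, 7, 37, 0, 10), nrow = 3, byrow = TRUE,
                dimnames = list(c("hi", "med", "lo"), c("DCB", "NCB")))
  res <- cross_tabulate(tab = tab, test = "chisq")
  expect_lt(abs(res$p_value - 0.029), 5e-4)
})

test_that("Fisher cross-tabulation matches the hypergeometric oracle", {
  t_null <- matrix(c(5, 5, 5, 5), 2)
  expect_equal(cross_tabulate(tab = t_null)$p_value, 1)
  t_assoc <- matrix(c(1, 9, 11, 3), 2, byrow = TRUE)
  expect_equal(cross_tabulate(tab = t_assoc)$p_value,
               oracle_fisher_2x2(t_assoc))
})

test_that("planted MSI and HRD membership is recovered through the classifiers", {
  cfg <- sim_config(n_tumor_types = 4, samples_per_type = 50, n_cold_types = 0,
                    n_tmb_assoc_types = 0, msi_fraction = 0.1,
                    hrd_fraction = 0.2, seed = 77)
  co <- simulate_cohort(cfg)
  cl <- co$clinical
  mantis_cls <- classify_mantis(cl$mantis)
  hrd_cls <- classify_hrd(cl$hrd_score, cl$tumor_type)
  expect_equal(as.character(mantis_cls) == "hi", unname(co$truth$msi))
  expect_equal(as.character(hrd_cls) == "hi", unname(co$truth$hrd))
})
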