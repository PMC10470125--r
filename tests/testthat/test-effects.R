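# Pooled effect models, spline LR checks, interaction models and the
# sensitivity suite.

test_that("OR per IQR is exp(beta x IQR) and scale equivariant", {
  d <- make_complete_table(seed = 1, n_cases = 80, n_controls = 400,
                           n_source = 10000)
  imp <- list(d, d)
  iqr <- sapply(metal_names(), function(m) iqr_ln(d[[m]]))
  eff <- fit_effects(imp, "cu", iqr = iqr, variants = "single")
  expect_equal(eff$OR, exp(eff$beta * eff$iqr))
  expect_true(eff$ci_low < eff$OR & eff$OR < eff$ci_high)
  # multiplying concentrations by a constant leaves OR per IQR unchanged
  d2 <- d; d2$cu <- d2$cu + log(1000)  # x1000 on the raw scale
  iqr2 <- iqr; iqr2["cu"] <- iqr_ln(d2$cu)
  eff2 <- fit_effects(list(d2, d2), "cu", iqr = iqr2, variants = "single")
  expect_equal(eff2$OR, eff$OR, tolerance = 1e-8)
  # co-adjusted variant contains all exposures simultaneously
  effc <- fit_effects(imp, c("cu", "mn", "hg"), iqr = iqr,
                      variants = "co_adjusted")
  expect_equal(nrow(effc), 3)
  expect_true(all(effc$variant == "co_adjusted"))
})

test_that("single and co-adjusted estimates agree for independent exposures", {
  d <- make_complete_table(seed = 2, betas = c(cu = 0.4),
                           n_cases = 400, n_controls = 2000,
                           n_source = 60000)
  iqr <- sapply(metal_names(), function(m) iqr_ln(d[[m]]))
  both <- fit_effects(list(d, d), c("cu", "se"), iqr = iqr)
  bs <- both[both$term == "cu" & both$variant == "single", ]
  bc <- both[both$term == "cu" & both$variant == "co_adjusted", ]
  expect_equal(bc$beta, bs$beta, tolerance = 0.05)
  expect_gt(bs$OR, 1)
})

test_that("spline LR statistics are non-negative and calibrated under linear truth", {
  d <- make_complete_table(seed = 3, betas = c(mn = 0.5),
                           n_cases = 144, n_controls = 700,
                           n_source = 15000)
  sp <- spline_lr(list(d, d), "mn")
  expect_s3_class(sp, "cp_spline_comparison")
  expect_true(all(sp$lr >= 0))
  expect_equal(unname(sp$knots),
               unname(quantile(c(d$mn, d$mn), c(0.1, 0.5, 0.9), type = 7)))
  expect_true(sp$verdict %in% c("linear", "nonlinear"))
})

test_that("spline LR detects a strong quadratic dose-response", {
  hits <- 0L
  for (r in 1:10) {
    d <- make_complete_table(seed = 300 + r, n_cases = 150,
                             n_controls = 750, n_source = 12000)
    # rebuild the outcome with a quadratic log-odds in standardized ln Mn
    set.seed(r)
    z <- scale(d$mn)[, 1]
    eta <- qlogis(0.15) + log(2) * z^2
    d$case <- rbinom(nrow(d), 1, plogis(eta))
    sp <- spline_lr(list(d, d), "mn")
    hits <- hits + (sp$p <= 0.05)
  }
  expect_gte(hits, 8)
})

test_that("interaction curves are parallel iff the interaction is null", {
  d <- make_complete_table(seed = 4, n_cases = 100, n_controls = 500,
                           n_source = 10000)
  res <- interaction_effects(list(d, d), c("cu:pb"))
  cv <- res$curves
  lo <- cv$logodds[cv$partner_level == "low"]
  hi <- cv$logodds[cv$partner_level == "high"]
  b_int <- res$coefficients$beta[grepl("cu:pb", res$coefficients$term)]
  # slope difference between strata equals 2 x interaction coefficient
  expect_equal(coef(lm(hi ~ cv$z[cv$partner_level == "high"]))[[2]] -
               coef(lm(lo ~ cv$z[cv$partner_level == "low"]))[[2]],
               2 * b_int, tolerance = 1e-8)
})

test_that("an injected interaction is recovered within 3 pooled SE", {
  d <- make_complete_table(seed = 5, n_cases = 300, n_controls = 1500,
                           n_source = 40000)
  set.seed(5)
  zcu <- scale(d$cu)[, 1]; zed <- scale(d$education)[, 1]
  eta <- qlogis(0.15) + 0.3 * zcu + 0.6 * zcu * zed
  d$case <- rbinom(nrow(d), 1, plogis(eta))
  res <- interaction_effects(list(d, d), c("cu:education"))
  row <- res$coefficients[grepl("cu:education", res$coefficients$term), ]
  expect_lt(abs(row$beta - 0.6), 3 * row$se)
})

test_that("sensitivity suite applies each restriction as defined", {
  co <- make_small_cohort(seed = 6, n_cases = 80, n_controls = 400)
  res <- sensitivity_suite(co, c("cu", "hg"),
                           scenarios = c("full", "term", "non_smoking",
                                         "no_winsorize", "complete_case"),
                           M = 2, seed = 2)
  expect_setequal(unique(res$scenario),
                  c("full", "term", "non_smoking", "no_winsorize",
                    "complete_case"))
  expect_true(all(res$variant == "co_adjusted"))
  # a restriction matching the full sample gives identical estimates
  co2 <- co
  co2$observed$gest_age[is.na(co2$observed$gest_age)] <- 280
  co2$observed$gest_age <- pmax(co2$observed$gest_age, 260)
  r2 <- sensitivity_suite(co2, c("cu"), scenarios = c("full", "term"),
                          M = 2, seed = 3)
  expect_equal(r2$OR[r2$scenario == "term"], r2$OR[r2$scenario == "full"],
               tolerance = 1e-10)
  # estimates across scenarios remain mutually compatible on null data
  ors <- res$OR[res$term == "cu"]
  expect_true(all(ors > res$ci_low[res$term == "cu"][1] - 1 &
                  ors < res$ci_high[res$term == "cu"][1] + 1))
})
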