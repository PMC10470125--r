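# Synthetic cohort generator: marginal calibration, copula dependence,
# outcome construction, batch effects and censoring.

test_that("log-normal moment calibration matches closed form and Monte Carlo", {
  # degenerate point mass
  p0 <- lognormal_params_from_moments(1.4, 0)
  expect_equal(p0$mu, log(1.4))
  expect_equal(p0$sigma, 0)
  # values verified by Monte-Carlo moments of 1e6 draws (mean 1.3995,
  # sd 0.8998)
  p <- lognormal_params_from_moments(1.4, 0.9)
  expect_equal(p$sigma, 0.588135, tolerance = 1e-5)
  expect_equal(p$mu, 0.163521, tolerance = 1e-5)
  # closed-form inversion: mean e^1.5 with sd = mean*sqrt(e-1) gives
  # sigma = 1, mu = 1
  p2 <- lognormal_params_from_moments(exp(1.5), exp(1.5) * sqrt(exp(1) - 1))
  expect_equal(p2$sigma, 1, tolerance = 1e-12)
  expect_equal(p2$mu, 1, tolerance = 1e-12)
  expect_error(lognormal_params_from_moments(-1, 1), "positive")
  expect_error(lognormal_params_from_moments(1, -0.1), "non-negative")
})

test_that("moment calibration round-trips through simulation", {
  m <- default_marginals()
  x <- simulate_metals(50000, seed = 11)
  for (i in seq_len(nrow(m))) {
    se <- m$sd[i] / sqrt(50000)
    expect_lt(abs(mean(x[[m$metal[i]]]) - m$mean[i]), 4 * se)
  }
})

test_that("Spearman-Pearson conversion is exact at the anchors and verified by simulation", {
  expect_equal(spearman_to_pearson(0), 0)
  expect_equal(spearman_to_pearson(1), 1)
  expect_equal(spearman_to_pearson(-1), -1)
  # 2*sin(pi*0.59/6) = 0.6081; bivariate-normal simulation at that
  # Pearson value returned Spearman 0.5905 (2e6 draws)
  expect_equal(spearman_to_pearson(0.59), 0.6080661, tolerance = 1e-6)
  expect_true(all(abs(spearman_to_pearson(c(0.3, -0.7))) >= c(0.3, 0.7)))
  expect_error(spearman_to_pearson(1.2), "\\[-1, 1\\]")
})

test_that("simulated Spearman correlations converge to the specified values", {
  x <- simulate_metals(100000, seed = 5)
  expect_equal(cor(x$as, x$hg, method = "spearman"), 0.59, tolerance = 0.02)
  expect_equal(cor(x$mg, x$zn, method = "spearman"), 0.53, tolerance = 0.02)
  # an unlisted pair stays near zero
  expect_lt(abs(cor(x$cd, x$se, method = "spearman")), 0.02)
})

test_that("identical seed and config give a bit-identical cohort", {
  a <- simulate_cohort(seed = 42, outcome_spec = default_outcome_spec(
    n_cases = 30, n_controls = 120), n_source = 8000)
  b <- simulate_cohort(seed = 42, outcome_spec = default_outcome_spec(
    n_cases = 30, n_controls = 120), n_source = 8000)
  expect_identical(a$truth, b$truth)
  expect_identical(a$observed, b$observed)
  expect_identical(a$qc, b$qc)
})

test_that("null outcome model yields exposure distributions identical in law", {
  d <- make_complete_table(seed = 3, n_cases = 100, n_controls = 500,
                           n_source = 15000)
  p <- suppressWarnings(
    ks.test(d$hg[d$case == 1], d$hg[d$case == 0])$p.value)
  expect_gt(p, 0.001)
})

test_that("logistic refit on the latent truth recovers the generating odds ratio", {
  # beta chosen so the true OR per IQR of ln(Cu) is 1.4
  m <- default_marginals()
  pcu <- lognormal_params_from_moments(m$mean[m$metal == "cu"],
                                       m$sd[m$metal == "cu"])
  big <- simulate_population(150000, seed = 8,
    outcome_spec = default_outcome_spec(betas = c(cu = 0.5)))
  zcu <- (log(big$cu) - pcu$mu) / pcu$sigma
  fit <- glm(case ~ zcu + sex + mat_age, binomial(), data = big)
  # 3 asymptotic SE at this sample size
  expect_lt(abs(unname(coef(fit)["zcu"]) - 0.5), 0.055)
})

test_that("batch effects are multiplicative and QC-recoverable", {
  co <- generate_cohort(outcome_spec = default_outcome_spec(
    n_cases = 30, n_controls = 150), seed = 2, n_source = 8000)
  # zero noise, unit multipliers: raw equals truth
  bs <- default_batch_spec()
  bs$qc_noise_cv <- 0; bs$meas_noise_cv <- 0
  bs$multipliers[] <- 1
  ident <- apply_batch_effects(co, bs, seed = 1)
  expect_equal(ident$observed$hg, co$truth$hg)
  # multiplier 2 in round 2, zero noise: raw = 2 x truth there
  bs$multipliers["hg", "2"] <- 2
  pert <- apply_batch_effects(co, bs, seed = 1)
  in2 <- pert$observed$round == "2"
  expect_equal(pert$observed$hg[in2], 2 * co$truth$hg[in2])
  expect_equal(pert$observed$hg[!in2], co$truth$hg[!in2])
})

test_that("censoring applies the configured limits and the external-lab subset", {
  m <- default_marginals()
  co <- make_small_cohort(seed = 9, n_cases = 100, n_controls = 900)
  r <- co$reasons
  expect_true(all(r$reason[r$variable == "as"] == "below_lod"))
  expect_true(all(r$reason[r$variable %in% c("cd", "co")] == "below_loq"))
  # every censored As cell is missing in the observed table
  expect_true(all(is.na(co$observed$as[match(
    r$subject_id[r$variable == "as"], co$observed$subject_id)])))
  # Lund subset: Mg and Cs not analysed, same subjects
  mg_ids <- sort(r$subject_id[r$variable == "mg"])
  cs_ids <- sort(r$subject_id[r$variable == "cs"])
  expect_identical(mg_ids, cs_ids)
  expect_identical(mg_ids, sort(co$observed$subject_id[co$observed$lund == 1]))
  # censored fraction near the calibrated rate (binomial bound)
  n <- nrow(co$observed)
  rate <- 12 / 1226
  expect_lt(abs(sum(r$variable == "as") / n - rate),
            4 * sqrt(rate * (1 - rate) / n) + 1 / n)
  # no LOD configured: no censoring
  m2 <- m; m2$lod[] <- NA; m2$loq[] <- NA
  co2 <- censor_and_missing(co, m2, missing_spec = NULL, seed = 1)
  expect_false(any(co2$reasons$reason %in% c("below_lod", "below_loq")))
})
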