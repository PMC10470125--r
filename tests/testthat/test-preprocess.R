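# Batch adjustment, winsorization, ln transform, IQR.

mini_exposures <- function(values, rounds) {
  data.frame(subject_id = seq_along(values), case = 0,
             hg = values, round = as.character(rounds),
             stringsAsFactors = FALSE)
}

test_that("batch adjustment implements the pooled/round geometric-mean ratio", {
  # single round: output equals input
  qc1 <- data.frame(round = "1", metal = "hg", qc_value = c(2, 3))
  e1 <- mini_exposures(c(1.5, 2.5), c(1, 1))
  expect_equal(batch_adjust(e1, qc1)$hg, e1$hg)

  # pooled geomean 2, round geomean 4: 10 -> 5
  qc2 <- data.frame(round = c("1", "2"), metal = "hg", qc_value = c(1, 4))
  e2 <- mini_exposures(10, 2)
  expect_equal(batch_adjust(e2, qc2)$hg, 10 * 2 / 4)

  # hand-computed worked example: QC round1 {2,8}, round2 {1,4};
  # sample in round 2 with M = 3 -> 3 * (64^(1/4) / 2) = 4.2426
  qc3 <- data.frame(round = c("1", "1", "2", "2"), metal = "hg",
                    qc_value = c(2, 8, 1, 4))
  e3 <- mini_exposures(3, 2)
  expect_equal(batch_adjust(e3, qc3)$hg, 3 * (64^(1 / 4) / 2),
               tolerance = 1e-12)
  expect_equal(batch_adjust(e3, qc3)$hg, 4.242641, tolerance = 1e-6)

  # missing cells stay missing
  e4 <- mini_exposures(c(3, NA), c(2, 2))
  expect_true(is.na(batch_adjust(e4, qc3)$hg[2]))

  # errors: missing QC coverage, nonpositive QC
  expect_error(batch_adjust(mini_exposures(1, 3), qc3), "round\\(s\\) 3")
  qc_bad <- data.frame(round = "1", metal = "hg", qc_value = c(2, -1))
  expect_error(batch_adjust(mini_exposures(1, 1), qc_bad), "positive")
})

test_that("repeated adjustment with unbiased QC leaves values unchanged up to QC noise", {
  co <- make_small_cohort(seed = 4)
  pp1 <- batch_adjust(co$observed, co$qc)
  # re-measured QC with no round bias: all factors 1, values unchanged
  qc2 <- co$qc
  qc2$qc_value <- ave(qc2$qc_value, qc2$metal, FUN = mean)
  pp2 <- batch_adjust(pp1, qc2)
  expect_equal(pp2$hg, pp1$hg, tolerance = 1e-12)
})

test_that("batch adjustment recovers the latent truth on perturbed data", {
  co <- make_small_cohort(seed = 6, n_cases = 100, n_controls = 900)
  adj <- batch_adjust(co$observed, co$qc)
  for (met in c("hg", "cu", "pb")) {
    ok <- !is.na(adj[[met]])
    rel_rmse <- sqrt(mean((adj[[met]][ok] / co$truth[[met]][ok] - 1)^2))
    expect_lt(rel_rmse, default_batch_spec()$qc_noise_cv)
    # adjusted correlates with truth better than raw
    expect_gt(cor(log(adj[[met]][ok]), log(co$truth[[met]][ok])),
              cor(log(co$observed[[met]][ok]), log(co$truth[[met]][ok])))
  }
})

test_that("winsorization caps at the interpolated 1st/99th percentiles", {
  expect_equal(as.numeric(winsorize(rep(7, 10))), rep(7, 10))
  w <- winsorize(as.numeric(1:100))
  expect_equal(min(w), 1.99)
  expect_equal(max(w), 99.01)
  expect_equal(attr(w, "limits"), c(1.99, 99.01))
  # order statistics preserved in the interior; at most ceil(2% n) + ties
  # altered
  expect_equal(sum(w != 1:100), 2L)
  expect_equal(order(w[3:98]), order(3:98))
  # post-winsorization extremes equal the pre-winsorization percentiles
  set.seed(1)
  x <- rlnorm(500)
  wx <- winsorize(x)
  expect_equal(min(wx), unname(quantile(x, 0.01, type = 7)))
  expect_equal(max(wx), unname(quantile(x, 0.99, type = 7)))
  # missing passes through
  expect_true(is.na(winsorize(c(1, NA, 3))[2]))
  expect_error(winsorize(c(NA_real_, NA_real_)), "2 observed")
})

test_that("log transform and winsorization agree on the log scale", {
  expect_equal(log_transform(c(1, exp(1))), c(0, 1))
  expect_error(log_transform(c(1, -2)), "positive")
  # interior (uncapped) values commute exactly; the caps use percentile
  # interpolation, which is linear on the working scale, so they agree
  # only to first order between the bracketing order statistics
  set.seed(2)
  x <- rlnorm(300, 1, 0.8)
  wl <- as.numeric(winsorize(log(x)))
  lw <- log(as.numeric(winsorize(x)))
  interior <- x > quantile(x, 0.02) & x < quantile(x, 0.98)
  expect_equal(wl[interior], lw[interior], tolerance = 1e-12)
  expect_equal(wl, lw, tolerance = 1e-3)
})

test_that("ln-scale IQR follows the percentile rule and is scale invariant", {
  set.seed(3)
  u <- runif(200000)
  expect_equal(iqr_ln(u), 0.5, tolerance = 0.01)
  expect_error(iqr_ln(rep(2, 10)), "degenerate")
  x <- rlnorm(100)
  expect_equal(iqr_ln(log(x)), iqr_ln(log(37.5 * x)), tolerance = 1e-12)
})

test_that("preprocess chains adjust, winsorize and log with per-cell bounds", {
  co <- make_small_cohort(seed = 5)
  pp <- preprocess(co$observed, co$qc, default_marginals(), co$reasons)
  expect_s3_class(pp, "cp_preprocessed")
  # metals are on the ln scale: IQR of exp() matches raw-scale quartiles
  expect_true(all(pp$iqr > 0))
  # winsorization limits recorded per metal on the adjusted scale
  expect_equal(rownames(pp$limits), intersect(metal_names(),
                                              names(co$observed)))
  # every censored cell has a bound with lower < upper = ln(limit*factor)
  expect_true(all(pp$bounds$lower < pp$bounds$upper))
  expect_setequal(unique(pp$bounds$variable), c("as", "cd", "co"))
  # the no-winsorize variant leaves tails longer
  pp0 <- preprocess(co$observed, co$qc, default_marginals(), co$reasons,
                    winsorize = FALSE)
  expect_gte(max(pp0$data$hg, na.rm = TRUE), max(pp$data$hg, na.rm = TRUE))
})
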