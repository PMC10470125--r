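# Design construction, elastic net, stability selection, permutation
# p-values and BH thresholds.

test_that("design matrix has the documented term structure", {
  d <- make_complete_table(seed = 1, n_cases = 50, n_controls = 250,
                           n_source = 8000)
  des <- build_design(d)
  expect_equal(ncol(des$x), 18)
  expect_equal(sum(des$penalized), 11)
  expect_equal(sum(!des$penalized), 7)
  expect_true(all(abs(colMeans(des$x)) < 1e-10))
  expect_equal(unname(apply(des$x, 2, sd)), rep(1, 18))
  # interaction run: 55 metal-metal + 11 metal-sex + 11 metal-education
  di <- build_design(d, include_interactions = TRUE)
  expect_equal(ncol(di$x), 18 + 77)
  expect_equal(sum(di$penalized), 11 + 77)
  # interaction columns are products of their standardized parents
  expect_equal(di$x[, "pb:cu"], di$x[, "pb"] * di$x[, "cu"])
  expect_equal(di$x[, "hg:education"], di$x[, "hg"] * di$x[, "education"])
  # missing cells are rejected
  d2 <- d; d2$hg[1] <- NA
  expect_error(build_design(d2), "impute")
})

test_that("elastic net honors the penalty structure in both limits", {
  d <- make_complete_table(seed = 2, n_cases = 144, n_controls = 600,
                           n_source = 10000)
  des <- build_design(d)
  # penalty limit: all penalized coefficients zero, unpenalized match
  # the covariate-only MLE
  hi <- elastic_net_logistic(des, lambda = 5)
  expect_true(all(hi$coef[metal_names()] == 0))
  cov_mle <- glm(reformulate(adjustment_covariates(), "case"),
                 binomial(), data = cbind(as.data.frame(des$x),
                                          case = des$y))
  expect_equal(hi$coef[adjustment_covariates()],
               coef(cov_mle)[adjustment_covariates()], tolerance = 1e-4)
  # lambda = 0: matches the unpenalized IRLS fit
  lo <- elastic_net_logistic(des, lambda = 0)
  full_mle <- glm(des$y ~ des$x, binomial())
  expect_equal(unname(lo$coef), unname(coef(full_mle)), tolerance = 1e-4)
})

test_that("a strong signal is selected at the CV-chosen lambda", {
  hits <- 0L
  for (r in 1:10) {
    d <- make_complete_table(seed = 100 + r, betas = c(cu = log(2)),
                             n_cases = 144, n_controls = 1082,
                             n_source = 20000)
    des <- build_design(d)
    fit <- elastic_net_logistic(des, nfolds = 5, nlambda = 20, seed = r)
    hits <- hits + fit$selected[["cu"]]
  }
  expect_gte(hits, 9)
})

test_that("stability selection brackets the extremes", {
  d <- make_complete_table(seed = 3, n_cases = 60, n_controls = 300,
                           n_source = 9000)
  # a deterministic perfect predictor is selected in every resample
  d$hg <- d$case * 2 + rnorm(nrow(d), 0, 1e-3)
  psel <- stability_selection(d, B = 5, M = 2, seed = 1,
                              nfolds = 3, nlambda = 10)
  expect_equal(unname(psel["hg"]), 1)
  expect_true(all(psel >= 0 & psel <= 1))
  expect_equal(names(psel), metal_names())
})

test_that("permutation p-values follow the counting formula and monotonicity", {
  obs <- c(a = 0.9, b = 0.1)
  null_mat <- rbind(a = seq(0, 0.98, length.out = 50),
                    b = seq(0, 0.98, length.out = 50))
  p <- (1 + rowSums(null_mat >= obs)) / (1 + 50)
  # null values 0.90, 0.92, ..., 0.98 tie or exceed the observed 0.9
  expect_equal(unname(p["a"]), 6 / 51)
  # observed above every null value gives the minimum attainable p
  p_top <- (1 + sum(null_mat["a", ] >= 0.99)) / 51
  expect_equal(p_top, 1 / 51)
  # p is monotone non-increasing in the observed statistic
  expect_gt(p[["b"]], p[["a"]])
  expect_error(permutation_pvalues(data.frame(), obs, K = 5), "19")
})

test_that("BH step-up matches the hand-computed worked example", {
  r <- bh_thresholds(c(0.01, 0.02, 0.2), 0.05)
  expect_equal(r$bh_threshold, c(0.05 / 3, 0.1 / 3, 0.05), tolerance = 1e-12)
  expect_equal(r$pass, c(TRUE, TRUE, FALSE))
  # none pass when all p = 1
  expect_false(any(bh_thresholds(rep(1, 5), 0.05)$pass))
  # m = 1 reduces to p <= alpha
  expect_true(bh_thresholds(0.04, 0.05)$pass)
  expect_false(bh_thresholds(0.06, 0.05)$pass)
  # agreement with the standard step-up implementation on random input
  set.seed(6)
  for (i in 1:50) {
    p <- runif(sample(3:30, 1))^2
    expect_equal(bh_thresholds(p, 0.05)$pass,
                 p.adjust(p, "BH") <= 0.05)
  }
  expect_error(bh_thresholds(c(0, 0.5)), "\\(0, 1\\]")
})
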