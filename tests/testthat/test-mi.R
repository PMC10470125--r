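# EM for the multivariate normal, bounded bootstrap-EM imputation, and
# Rubin / D2 pooling.

test_that("EM with no missing data returns the ML sample moments", {
  set.seed(1)
  X <- matrix(rnorm(600), 200, 3)
  fit <- em_mvn(X)
  expect_equal(fit$mu, colMeans(X))
  expect_equal(fit$sigma, cov(X) * 199 / 200)
})

test_that("EM log-likelihood is non-decreasing and recovers MVN parameters under MCAR", {
  set.seed(2)
  n <- 2000
  S <- matrix(0.5, 4, 4); diag(S) <- 1
  X <- matrix(rnorm(n * 4), n) %*% chol(S) + rep(1:4, each = n)
  Xm <- X
  Xm[matrix(runif(n * 4) < 0.10, n)] <- NA
  fit <- em_mvn(Xm)
  expect_true(all(diff(fit$loglik) > -1e-6))
  # complete-data ML oracle: parameters within 3 SE of the truth
  se_mu <- 1 / sqrt(n)
  expect_true(all(abs(fit$mu - 1:4) < 3.5 * se_mu / sqrt(0.9)))
  expect_true(all(abs(fit$sigma - S) < 0.1))
})

test_that("imputation honors bounds and leaves observed cells untouched", {
  co <- make_small_cohort(seed = 7)
  pp <- preprocess(co$observed, co$qc, default_marginals(), co$reasons)
  imp <- impute(pp$data, M = 3, bounds = pp$bounds, seed = 11)
  expect_s3_class(imp, "cp_imputation_set")
  expect_length(imp$datasets, 3)
  # no remaining missing values in the model variables
  vars <- imp$vars
  for (d in imp$datasets) expect_false(anyNA(d[, vars]))
  # observed cells identical across datasets
  obs_mask <- !is.na(pp$data$hg)
  for (d in imp$datasets)
    expect_identical(d$hg[obs_mask], pp$data$hg[obs_mask])
  # every bounded cell inside its bounds in every dataset
  b <- pp$bounds
  for (d in imp$datasets) {
    v <- mapply(function(id, var) d[[var]][match(id, d$subject_id)],
                b$subject_id, b$variable)
    expect_true(all(v >= b$lower - 1e-9 & v <= b$upper + 1e-9))
  }
  # imputed values fall within the observed range +/- 3 SD
  for (var in c("mg", "cs", "folate")) {
    obs_v <- pp$data[[var]][!is.na(pp$data[[var]])]
    lim <- range(obs_v) + c(-3, 3) * sd(obs_v)
    for (d in imp$datasets) {
      miss_i <- which(is.na(pp$data[[var]]))
      expect_true(all(d[[var]][miss_i] >= lim[1] & d[[var]][miss_i] <= lim[2]))
    }
  }
  # binary imputed covariates stay 0/1
  for (d in imp$datasets)
    expect_true(all(d$education %in% c(0, 1)))
  # bit-for-bit seed determinism
  imp2 <- impute(pp$data, M = 3, bounds = pp$bounds, seed = 11)
  expect_identical(imp$datasets, imp2$datasets)
  # a complete table passes through unchanged
  cc <- pp$data[complete.cases(pp$data[, vars]), ]
  imp3 <- impute(cc, M = 2, seed = 1)
  expect_identical(imp3$datasets[[1]], cc)
  expect_identical(imp3$datasets[[2]], cc)
})

test_that("Rubin pooling matches hand arithmetic and its variance contract", {
  # B = 0 case
  p0 <- rubin_pool(c(0.5, 0.5, 0.5), c(0.04, 0.04, 0.04))
  expect_equal(p0$point, 0.5)
  expect_equal(p0$T, 0.04)
  expect_equal(p0$df, Inf)
  # hand-computed: W = 0.04, B = 0.02, T = 0.04 + 1.5*0.02 = 0.07
  p <- rubin_pool(c(0.4, 0.6), c(0.04, 0.04))
  expect_equal(p$point, 0.5)
  expect_equal(p$W, 0.04)
  expect_equal(p$B, 0.02)
  expect_equal(p$T, 0.07)
  expect_lt(p$ci[1], 0.5); expect_gt(p$ci[2], 0.5)
  expect_error(rubin_pool(0.5, 0.1), "M >= 2")
  # T >= W and T = W + (1+1/M)B on random instances
  set.seed(4)
  for (i in 1:2000) {
    M <- sample(2:10, 1)
    pts <- rnorm(M); vs <- rexp(M)
    r <- rubin_pool(pts, vs)
    expect_gte(r$T, r$W)
    expect_equal(r$T, r$W + (1 + 1 / M) * r$B)
  }
  # CI width grows with between-imputation variance
  narrow <- rubin_pool(c(0.49, 0.51), c(0.04, 0.04))
  wide <- rubin_pool(c(0.3, 0.7), c(0.04, 0.04))
  expect_gt(diff(wide$ci), diff(narrow$ci))
})

test_that("D2 pooling of LR statistics reduces to chi-square for equal statistics", {
  # statistic 0 -> p = 1
  expect_equal(pool_lr_pvalues(c(0, 0, 0), 1)$p, 1)
  # equal statistics -> single-dataset chi-square p
  expect_equal(pool_lr_pvalues(rep(3.84, 5), 1)$p,
               pchisq(3.84, 1, lower.tail = FALSE))
  # under H0, pooled p approximately uniform (chi-square draws as the
  # per-imputation statistics)
  set.seed(5)
  ps <- replicate(1000, {
    d0 <- rchisq(1, 1)
    pool_lr_pvalues((sqrt(d0) + rnorm(5, 0, 0.05))^2, 1)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  expect_error(pool_lr_pvalues(c(1, 2), 0), "positive")
})
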