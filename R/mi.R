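# Multiple imputation: EM for the multivariate normal with arbitrary
# missingness patterns, bootstrap-EM imputation with per-cell bounds for
# left-censored exposures, and Rubin's-rules pooling utilities.

# group rows by missingness pattern; returns list of (rows, obs, mis)
missing_patterns <- function(miss) {
  key <- apply(miss, 1L, function(r) paste(which(r), collapse = ","))
  lapply(split(seq_len(nrow(miss)), key), function(rows) {
    m <- which(miss[rows[1], ])
    list(rows = rows, mis = m, obs = setdiff(seq_len(ncol(miss)), m))
  })
}

#' EM estimation of a multivariate normal with missing data
#'
#' Maximum-likelihood mean and covariance under an MVN model via
#' expectation-maximization, grouping rows by missingness pattern. The
#' observed-data log-likelihood is monitored and must be non-decreasing;
#' a near-singular covariance is ridge-stabilized with a warning.
#'
#' @param X Numeric matrix, `NA` for missing cells.
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Iteration cap; non-convergence is an error carrying
#'   the log-likelihood trace.
#' @param ridge Ridge added to the covariance diagonal when it becomes
#'   numerically singular.
#' @return List: `mu`, `sigma`, `loglik` (trace), `iterations`.
#' @export
em_mvn <- function(X, tol = 1e-6, max_iter = 500L, ridge = 1e-8) {
  X <- as.matrix(X)
  if (!is.numeric(X)) abort("em_mvn requires a numeric matrix")
  n <- nrow(X); p <- ncol(X)
  miss <- is.na(X)
  if (any(rowSums(!miss) == 0)) abort("rows with no observed cells")
  mu <- colMeans(X, na.rm = TRUE)
  v <- apply(X, 2L, stats::var, na.rm = TRUE)
  v[!is.finite(v) | v <= 0] <- 1
  sigma <- diag(v, p)
  if (!anyNA(X)) {
    sigma <- stats::cov(X) * (n - 1) / n
    ll <- mvn_loglik_patterns(X, list(list(rows = seq_len(n),
                                           mis = integer(0),
                                           obs = seq_len(p))), mu, sigma)
    return(list(mu = mu, sigma = sigma, loglik = ll, iterations = 0L))
  }
  pats <- missing_patterns(miss)
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    S1 <- numeric(p)
    S2 <- matrix(0, p, p)
    ll <- 0
    for (pat in pats) {
      o <- pat$obs; m <- pat$mis; rows <- pat$rows
      Xo <- X[rows, o, drop = FALSE]
      So <- sigma[o, o, drop = FALSE]
      ch <- tryCatch(chol(So), error = function(e) NULL)
      if (is.null(ch)) {
        So <- So + diag(ridge * max(diag(So)), length(o))
        ch <- chol(So)
      }
      dev <- sweep(Xo, 2L, mu[o])
      z <- backsolve(ch, t(dev), transpose = TRUE)
      ll <- ll - 0.5 * (length(rows) * (2 * sum(log(diag(ch))) +
                        length(o) * log(2 * pi)) + sum(z^2))
      if (length(m)) {
        B <- t(backsolve(ch, backsolve(ch, sigma[o, m, drop = FALSE],
                                       transpose = TRUE)))
        Xm <- matrix(mu[m], length(rows), length(m), byrow = TRUE) +
          dev %*% t(B)
        C <- sigma[m, m, drop = FALSE] - B %*% sigma[o, m, drop = FALSE]
        Xfull <- matrix(0, length(rows), p)
        Xfull[, o] <- Xo; Xfull[, m] <- Xm
        S1 <- S1 + colSums(Xfull)
        S2 <- S2 + crossprod(Xfull)
        S2[m, m] <- S2[m, m] + length(rows) * C
      } else {
        S1 <- S1 + colSums(Xo)
        S2 <- S2 + crossprod(Xo)
      }
    }
    trace <- c(trace, ll)
    mu_new <- S1 / n
    sigma_new <- S2 / n - tcrossprod(mu_new)
    sigma_new <- (sigma_new + t(sigma_new)) / 2
    if (inherits(tryCatch(chol(sigma_new), error = function(e) e), "error")) {
      warning("singular covariance in EM; ridge-stabilized", call. = FALSE)
      sigma_new <- sigma_new + diag(ridge * max(diag(sigma_new)), p)
    }
    mu <- mu_new; sigma <- sigma_new
    if (iter > 1 &&
        abs(trace[iter] - trace[iter - 1]) <
          tol * (abs(trace[iter - 1]) + 0.1)) {
      dimnames(sigma) <- list(colnames(X), colnames(X))
      names(mu) <- colnames(X)
      return(list(mu = mu, sigma = sigma, loglik = trace, iterations = iter))
    }
  }
  err <- simpleError(sprintf("EM did not converge in %d iterations", max_iter))
  err$trace <- trace
  stop(err)
}

mvn_loglik_patterns <- function(X, pats, mu, sigma) {
  ll <- 0
  for (pat in pats) {
    o <- pat$obs
    ch <- chol(sigma[o, o, drop = FALSE])
    dev <- sweep(X[pat$rows, o, drop = FALSE], 2L, mu[o])
    z <- backsolve(ch, t(dev), transpose = TRUE)
    ll <- ll - 0.5 * (length(pat$rows) * (2 * sum(log(diag(ch))) +
                      length(o) * log(2 * pi)) + sum(z^2))
  }
  ll
}

# scalar truncated-normal draw by inverse CDF; a numerically degenerate
# interval collapses to its midpoint
rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  if (!is.finite(plo) || !is.finite(phi) || phi - plo < 1e-12)
    return(rep((lower + upper) / 2, n))
  out <- stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
  pmin(pmax(out, lower), upper)
}

#' Variables entering the default imputation model
#'
#' Case status (never imputed; design-fixed), the 11 ln-scale metals, the
#' adjustment covariates, and the auxiliary variables gestational age,
#' folate and BMI.
#'
#' @return Character vector of column names.
#' @export
imputation_variables <- function() {
  c("case", METALS, ADJUST_COVARIATES, AUX_COVARIATES)
}

#' Bounded multiple imputation via bootstrap EM
#'
#' Amelia-style scheme: for each of `M` imputations the rows are
#' resampled with replacement, EM fits the MVN parameters on the
#' resample, and each missing cell of the original table is drawn from
#' its conditional normal given the row's observed cells. Cells with
#' censoring bounds (ln-scale lower/upper, e.g. `ln(LOD/10)` to
#' `ln(LOD)`) are drawn by joint rejection with a retry cap, falling back
#' to truncated univariate Gibbs updates, so every bounded cell respects
#' its bounds in every dataset. Binary variables are drawn continuous and
#' thresholded at 0.5.
#'
#' @param data Data.frame (metals already on the ln scale).
#' @param M Number of imputations (>= 2).
#' @param bounds Per-cell bounds: data.frame `subject_id`, `variable`,
#'   `lower`, `upper` (ln scale); `NULL` for none.
#' @param seed Integer seed; the whole procedure is bit-reproducible.
#' @param vars Columns entering the imputation model
#'   (default [imputation_variables()], intersected with `data`).
#' @param tol,max_iter EM controls.
#' @param reject_cap Joint-rejection retries before the Gibbs fallback.
#' @return Object of class `cp_imputation_set`: list with `M`,
#'   `datasets` (M completed copies of `data`), `bounds`, `seed`, `em`
#'   (per-imputation iteration counts).
#' @export
impute <- function(data, M = 20L, bounds = NULL, seed = 1L,
                   vars = intersect(imputation_variables(), names(data)),
                   tol = 1e-6, max_iter = 500L, reject_cap = 50L) {
  if (M < 2) abort("M must be at least 2")
  if (anyNA(data$case)) abort("case status is design-fixed and cannot be missing")
  X <- as.matrix(data[, vars, drop = FALSE])
  if (!is.numeric(X)) abort("imputation variables must be numeric")
  miss <- is.na(X)
  binary <- vapply(vars, function(v) {
    u <- unique(X[!miss[, match(v, vars)], match(v, vars)])
    all(u %in% c(0, 1))
  }, logical(1))

  bmat <- NULL
  if (!is.null(bounds) && nrow(bounds)) {
    rows <- match(bounds$subject_id, data$subject_id)
    cols <- match(bounds$variable, vars)
    if (anyNA(rows) || anyNA(cols))
      abort("bounds refer to unknown subjects or variables")
    if (any(bounds$lower >= bounds$upper)) abort("empty bounds interval")
    if (any(!miss[cbind(rows, cols)]))
      abort("bounds supplied for non-missing cells")
    bmat <- cbind(row = rows, col = cols,
                  lower = bounds$lower, upper = bounds$upper)
  }

  pats <- missing_patterns(miss)
  seeds <- derive_seeds(seed, M)
  datasets <- vector("list", M)
  iters <- integer(M)
  n <- nrow(X)

  for (m in seq_len(M)) {
    if (!anyNA(X)) { datasets[[m]] <- data; next }
    set.seed(seeds[m])
    fit <- em_mvn(X[sample.int(n, n, replace = TRUE), , drop = FALSE],
                  tol = tol, max_iter = max_iter)
    Xc <- impute_from_fit(X, pats, fit, bmat, reject_cap)
    iters[m] <- fit$iterations
    out <- data
    for (j in seq_along(vars)) {
      was_missing <- miss[, j]
      v <- out[[vars[j]]]
      newv <- Xc[was_missing, j]
      if (binary[j]) newv <- as.numeric(newv >= 0.5)
      v[was_missing] <- newv
      out[[vars[j]]] <- v
    }
    datasets[[m]] <- out
  }
  structure(list(M = M, datasets = datasets, bounds = bounds, seed = seed,
                 vars = vars, em = iters),
            class = "cp_imputation_set")
}

# draw missing cells of X from the conditional normal under fit,
# respecting per-cell bounds
impute_from_fit <- function(X, pats, fit, bmat, reject_cap) {
  mu <- fit$mu; sigma <- fit$sigma
  Xc <- X
  for (pat in pats) {
    m <- pat$mis
    if (!length(m)) next
    o <- pat$obs; rows <- pat$rows
    So <- sigma[o, o, drop = FALSE]
    ch <- chol(So + diag(1e-10 * max(diag(So)), length(o)))
    B <- t(backsolve(ch, backsolve(ch, sigma[o, m, drop = FALSE],
                                   transpose = TRUE)))
    C <- sigma[m, m, drop = FALSE] - B %*% sigma[o, m, drop = FALSE]
    C <- (C + t(C)) / 2
    cm <- matrix(mu[m], length(rows), length(m), byrow = TRUE) +
      sweep(X[rows, o, drop = FALSE], 2L, mu[o]) %*% t(B)
    chC <- tryCatch(chol(C), error = function(e)
      chol(C + diag(1e-8 * max(diag(C), 1e-12), nrow(C))))
    draw <- cm + matrix(stats::rnorm(length(rows) * length(m)),
                        length(rows)) %*% chC
    if (!is.null(bmat)) {
      brows <- bmat[bmat[, "row"] %in% rows, , drop = FALSE]
      if (nrow(brows)) {
        for (ri in unique(brows[, "row"])) {
          k <- match(ri, rows)
          rb <- brows[brows[, "row"] == ri, , drop = FALSE]
          jb <- match(rb[, "col"], m)
          ok <- all(draw[k, jb] >= rb[, "lower"] & draw[k, jb] <= rb[, "upper"])
          tries <- 0L
          while (!ok && tries < reject_cap) {
            draw[k, ] <- cm[k, ] + drop(stats::rnorm(length(m)) %*% chC)
            ok <- all(draw[k, jb] >= rb[, "lower"] &
                        draw[k, jb] <= rb[, "upper"])
            tries <- tries + 1L
          }
          if (!ok) {
            # Gibbs fallback with truncated univariate conditionals
            cur <- cm[k, ]
            for (sweep_i in 1:5) for (jj in seq_along(m)) {
              others <- setdiff(seq_along(m), jj)
              if (length(others)) {
                cj <- C[jj, others, drop = FALSE] %*%
                  solve(C[others, others, drop = FALSE])
                mj <- cm[k, jj] + drop(cj %*% (cur[others] - cm[k, others]))
                sj <- sqrt(max(C[jj, jj] - drop(cj %*% C[others, jj]), 1e-12))
              } else { mj <- cm[k, jj]; sj <- sqrt(max(C[jj, jj], 1e-12)) }
              hit <- match(jj, jb)
              cur[jj] <- if (!is.na(hit))
                rtruncnorm1(1L, mj, sj, rb[hit, "lower"], rb[hit, "upper"])
              else stats::rnorm(1L, mj, sj)
            }
            draw[k, ] <- cur
            if (any(cur[jb] < rb[, "lower"] | cur[jb] > rb[, "upper"]))
              abort("bounded cell violated its bounds after fallback")
          }
        }
      }
    }
    Xc[rows, m] <- draw
  }
  Xc
}

#' Rubin's-rules pooling of a scalar estimate
#'
#' Pools M point estimates and their variances: pooled point = mean;
#' within-imputation variance W = mean variance; between-imputation
#' variance B = sample variance of the points; total T = W + (1 + 1/M) B.
#' Degrees of freedom by the Barnard-Rubin small-sample formula when a
#' complete-data df is supplied, otherwise the classic large-sample
#' formula. Pool log-odds, then exponentiate for OR reporting.
#'
#' @param points Numeric vector of M estimates (M >= 2).
#' @param variances Numeric vector of M non-negative variances.
#' @param dfcom Complete-data degrees of freedom (default `Inf`).
#' @param conf Confidence level for the interval.
#' @return List of class `pooled_estimate`: `point`, `W`, `B`, `T`,
#'   `df`, `se`, `ci` (length-2), `M`.
#' @export
rubin_pool <- function(points, variances, dfcom = Inf, conf = 0.95) {
  M <- length(points)
  if (M < 2) abort("Rubin pooling needs M >= 2 estimates")
  if (length(variances) != M || any(variances < 0))
    abort("variances must be M non-negative values")
  point <- mean(points)
  W <- mean(variances)
  B <- stats::var(points)
  Tv <- W + (1 + 1 / M) * B
  if (B <= 0 || Tv <= 0) {
    df <- Inf
  } else {
    r <- (1 + 1 / M) * B / W
    df <- (M - 1) * (1 + 1 / r)^2
    if (is.finite(dfcom)) {
      lambda <- (1 + 1 / M) * B / Tv
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df <- 1 / (1 / df + 1 / df_obs)
    }
  }
  se <- sqrt(Tv)
  q <- stats::qt(1 - (1 - conf) / 2, df)
  structure(list(point = point, W = W, B = B, T = Tv, df = df, se = se,
                 ci = c(point - q * se, point + q * se), M = M),
            class = "pooled_estimate")
}

#' Pool likelihood-ratio statistics across imputations (D2)
#'
#' Combines M chi-square likelihood-ratio statistics with common df into
#' one p-value by the D2 rule: an F reference built from the mean
#' statistic with a between-imputation correction based on the variance
#' of the root statistics. With no between-imputation variance it
#' reduces to the single-dataset chi-square p.
#'
#' @param stats Numeric vector of M non-negative LR statistics.
#' @param df Common degrees of freedom (> 0).
#' @return List: `p`, `D` (pooled test statistic), `df1`, `df2`, `r`.
#' @export
pool_lr_pvalues <- function(stats, df) {
  if (df <= 0) abort("df must be positive")
  if (any(stats < -1e-8)) abort("LR statistics must be non-negative")
  stats <- pmax(stats, 0)
  M <- length(stats)
  dbar <- mean(stats)
  if (M == 1 || stats::var(sqrt(stats)) < 1e-12) {
    return(list(p = stats::pchisq(dbar, df, lower.tail = FALSE),
                D = dbar / df, df1 = df, df2 = Inf, r = 0))
  }
  r <- (1 + 1 / M) * stats::var(sqrt(stats))
  D <- max((dbar / df - (M + 1) / (M - 1) * r) / (1 + r), 0)
  df2 <- df^(-3 / M) * (M - 1) * (1 + 1 / r)^2
  list(p = stats::pf(D, df, df2, lower.tail = FALSE),
       D = D, df1 = df, df2 = df2, r = r)
}
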