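# Quantile g-computation of joint mixture effects with signed weights,
# MI pooling, and a bootstrap marginal-structural variant.

#' Mixture membership
#'
#' The three analyzed mixtures: all 11 metals/elements (`all`), the five
#' toxic metals As, Hg, Cd, Cs, Pb (`tox`), and the six essential
#' elements Mn, Cu, Co, Se, Mg, Zn (`essential`). A character vector of
#' metal names defines a custom mixture.
#'
#' @param mixture `"all"`, `"tox"`, `"essential"`, or metal names.
#' @return Character vector of members.
#' @export
mixture_members <- function(mixture) {
  if (length(mixture) == 1L && mixture %in% c("all", "tox", "essential"))
    switch(mixture,
           all = METALS,
           tox = c("as", "hg", "cd", "cs", "pb"),
           essential = c("mn", "cu", "co", "se", "mg", "zn"))
  else {
    bad <- setdiff(mixture, METALS)
    if (length(bad)) abort("unknown mixture members: %s",
                           paste(bad, collapse = ", "))
    if (length(mixture) < 1) abort("empty mixture")
    mixture
  }
}

#' Quantile scores
#'
#' Scores values into `q` quantile categories 0..q-1 using cut-points at
#' the `1/q, ..., (q-1)/q` percentiles (linear-interpolation rule).
#' Monotone in the input and invariant to strictly increasing
#' transforms.
#'
#' @param x Numeric vector with at least `q` distinct values.
#' @param q Number of quantiles (default 4, quartiles).
#' @param name Label used in error messages.
#' @return Integer scores with attribute `cutpoints`.
#' @export
quantize <- function(x, q = 4L, name = deparse(substitute(x))) {
  if (q < 2) abort("q must be at least 2")
  if (length(unique(x[!is.na(x)])) < q)
    abort("too few distinct values to form %d quantiles for %s", q, name)
  br <- quantile7(x, seq(0, 1, length.out = q + 1))
  if (any(duplicated(br)))
    abort("duplicate quantile cut-points for %s", name)
  scores <- as.integer(cut(x, breaks = br, include.lowest = TRUE)) - 1L
  attr(scores, "cutpoints") <- br[2:q]
  scores
}

# weights from sign-partitioned coefficients, each partition normalized
partition_weights <- function(coefs) {
  pos <- coefs[coefs > 0]; neg <- coefs[coefs < 0]
  rbind(
    if (length(pos)) data.frame(member = names(pos), sign = "positive",
                                weight = pos / sum(pos),
                                stringsAsFactors = FALSE),
    if (length(neg)) data.frame(member = names(neg), sign = "negative",
                                weight = neg / sum(neg),
                                stringsAsFactors = FALSE))
}

fit_member_glm <- function(d, members, covariates, q) {
  Q <- vapply(members, function(m) as.numeric(quantize(d[[m]], q, m)),
              numeric(nrow(d)))
  colnames(Q) <- members
  dd <- as.data.frame(Q)
  for (cv in covariates) dd[[cv]] <- d[[cv]]
  dd$case <- d$case
  f <- stats::as.formula(paste("case ~",
    paste(c(members, covariates), collapse = " + ")))
  fit <- stats::glm(f, stats::binomial(), data = dd)
  co <- stats::coef(fit)
  if (anyNA(co)) {
    warning("collinear quantized members; ridge-stabilized fit",
            call. = FALSE)
    X <- stats::model.matrix(f, dd)[, -1, drop = FALSE]
    rg <- glmnet::glmnet(X, dd$case, family = "binomial", alpha = 0,
                         lambda = 1e-3, standardize = FALSE)
    co2 <- c(as.numeric(rg$a0), as.numeric(rg$beta))
    names(co2) <- c("(Intercept)", rownames(rg$beta))
    co[is.na(co)] <- 0
    co[names(co2)] <- co2
    vc <- matrix(0, length(co), length(co),
                 dimnames = list(names(co), names(co)))
  } else vc <- stats::vcov(fit)
  list(coef = co, vcov = vc, dfcom = fit$df.residual, data = dd, fit = fit)
}

#' Quantile g-computation, core variant
#'
#' In every imputed dataset the mixture members are scored into
#' quantiles and entered jointly (with covariates) into a logistic
#' model; the joint mixture effect psi per one-quantile increase in all
#' members is the sum of the member coefficients, with variance the sum
#' of the member block of the coefficient covariance. Psi is pooled
#' across imputations by Rubin's rules and reported as an OR. Member
#' weights come from the imputation-averaged coefficients, partitioned
#' by sign with each partition normalized to 1.
#'
#' @param imp Imputation set (or list of completed data.frames).
#' @param mixture Mixture id or member vector (see [mixture_members()]).
#' @param q Number of quantiles (default 4).
#' @param covariates Adjustment covariates.
#' @return List of class `cp_mixture_result`: `mixture`, `members`,
#'   `psi` (pooled estimate), `OR`, `ci`, `weights`, `per_imputation`,
#'   `variant = "core"`.
#' @export
qgcomp_core <- function(imp, mixture = "all", q = 4L,
                        covariates = adjustment_covariates()) {
  members <- mixture_members(mixture)
  datasets <- as_datasets(imp)
  M <- length(datasets)
  psi_m <- var_m <- numeric(M)
  coef_mat <- matrix(NA_real_, length(members), M,
                     dimnames = list(members, NULL))
  dfcom <- Inf
  for (m in seq_len(M)) {
    fm <- fit_member_glm(datasets[[m]], members, covariates, q)
    b <- fm$coef[members]
    psi_m[m] <- sum(b)
    var_m[m] <- sum(fm$vcov[members, members])
    coef_mat[, m] <- b
    dfcom <- fm$dfcom
  }
  pooled <- if (M >= 2) rubin_pool(psi_m, var_m, dfcom = dfcom)
  else {
    se <- sqrt(var_m)
    list(point = psi_m, se = se, T = var_m,
         ci = psi_m + c(-1, 1) * stats::qnorm(0.975) * se, M = 1L)
  }
  avg <- rowMeans(coef_mat)
  structure(list(mixture = if (length(mixture) == 1L) mixture else "custom",
                 members = members, psi = pooled,
                 OR = exp(pooled$point), ci = exp(pooled$ci),
                 weights = partition_weights(avg),
                 per_imputation = list(psi = psi_m, var = var_m,
                                       coef = coef_mat),
                 q = q, variant = "core"),
            class = "cp_mixture_result")
}

# counterfactual design: members (and derived terms) set to score s
counterfactual_eta <- function(co, dd, members, covariates, s, degree,
                               interactions) {
  eta <- rep(co[["(Intercept)"]], nrow(dd))
  for (m in members) eta <- eta + co[[m]] * s
  if (degree >= 2)
    for (m in members) eta <- eta + co[[paste0(m, "_sq")]] * s^2
  for (tm in interactions %||% character(0)) {
    pr <- parse_interaction(tm)
    key <- paste0(pr[1], "_x_", pr[2])
    both <- all(pr %in% members)
    eta <- eta + if (both) co[[key]] * s^2
                 else co[[key]] * s * dd[[setdiff(pr, members)[1]]]
  }
  for (cv in covariates) eta <- eta + co[[cv]] * dd[[cv]]
  eta
}

#' Quantile g-computation, bootstrap marginal-structural variant
#'
#' Fits the conditional logistic model with quantized members plus
#' optional per-member quadratic terms (`degree = 2`) and supplied
#' interaction terms, then estimates the marginal joint effect by
#' g-computation: the population-averaged log-odds is computed at each
#' counterfactual joint quantile setting 0..q-1 and a polynomial of the
#' stated degree is fitted to the grid by least squares; psi is its
#' linear coefficient. Confidence intervals come from a subject-level
#' bootstrap, pooled across imputations. With `degree = 1` and no
#' interactions this reproduces the core variant's psi exactly.
#'
#' @inheritParams qgcomp_core
#' @param degree Polynomial degree of the marginal model (1 or 2).
#' @param interactions Interaction terms (e.g. `"cu:pb"`, `"hg:education"`)
#'   to include in the conditional model; `NULL` for none.
#' @param n_boot Bootstrap resamples per imputation (>= 2).
#' @param seed Integer seed.
#' @return `cp_mixture_result` with `variant = "boot"` and, for
#'   `degree = 2`, a `psi_quadratic` pooled estimate.
#' @export
qgcomp_boot <- function(imp, mixture = "all", q = 4L, degree = 1L,
                        interactions = NULL, n_boot = 200L, seed = 1L,
                        covariates = adjustment_covariates()) {
  if (degree < 1 || degree > 2) abort("degree must be 1 or 2")
  members <- mixture_members(mixture)
  datasets <- as_datasets(imp)
  M <- length(datasets)
  seeds <- derive_seeds(seed, M)

  fit_cond <- function(d) {
    Q <- vapply(members, function(m) as.numeric(quantize(d[[m]], q, m)),
                numeric(nrow(d)))
    colnames(Q) <- members
    dd <- as.data.frame(Q)
    terms <- members
    if (degree >= 2) for (m in members) {
      dd[[paste0(m, "_sq")]] <- dd[[m]]^2
      terms <- c(terms, paste0(m, "_sq"))
    }
    for (tm in interactions %||% character(0)) {
      pr <- parse_interaction(tm)
      key <- paste0(pr[1], "_x_", pr[2])
      v1 <- if (pr[1] %in% members) dd[[pr[1]]] else d[[pr[1]]]
      v2 <- if (pr[2] %in% members) dd[[pr[2]]] else d[[pr[2]]]
      dd[[key]] <- v1 * v2
      terms <- c(terms, key)
      for (p_ in setdiff(pr, c(members, covariates)))
        if (!p_ %in% names(dd)) { dd[[p_]] <- d[[p_]]; terms <- c(terms, p_) }
    }
    for (cv in covariates) dd[[cv]] <- d[[cv]]
    dd$case <- d$case
    f <- stats::as.formula(paste("case ~",
      paste(c(terms, covariates), collapse = " + ")))
    fit <- suppressWarnings(stats::glm(f, stats::binomial(), data = dd))
    co <- stats::coef(fit)
    co[is.na(co)] <- 0
    list(coef = as.list(co), data = dd)
  }

  msm_psi <- function(co, dd) {
    s_grid <- 0:(q - 1)
    mbar <- vapply(s_grid, function(s)
      mean(counterfactual_eta(co, dd, members, covariates, s, degree,
                              interactions)), numeric(1))
    if (degree == 1) {
      fit <- stats::lm(mbar ~ s_grid)
      c(psi = unname(stats::coef(fit)[2]), psi2 = NA_real_)
    } else {
      fit <- stats::lm(mbar ~ s_grid + I(s_grid^2))
      c(psi = unname(stats::coef(fit)[2]), psi2 = unname(stats::coef(fit)[3]))
    }
  }

  psi_m <- var_m <- psi2_m <- var2_m <- numeric(M)
  coef_mat <- matrix(NA_real_, length(members), M,
                     dimnames = list(members, NULL))
  redrawn <- 0L
  for (m in seq_len(M)) {
    d <- datasets[[m]]
    full <- fit_cond(d)
    est <- msm_psi(full$coef, full$data)
    psi_m[m] <- est["psi"]; psi2_m[m] <- est["psi2"]
    coef_mat[, m] <- unlist(full$coef[members])
    set.seed(seeds[m])
    bs <- matrix(NA_real_, n_boot, 2L)
    n <- nrow(d)
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (sum(d$case[idx]) > 0 && sum(d$case[idx]) < n) break
        redrawn <- redrawn + 1L
      }
      fb <- tryCatch(fit_cond(d[idx, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(fb)) next
      bs[b, ] <- msm_psi(fb$coef, fb$data)
    }
    var_m[m] <- stats::var(bs[, 1], na.rm = TRUE)
    var2_m[m] <- stats::var(bs[, 2], na.rm = TRUE)
  }
  pooled <- if (M >= 2) rubin_pool(psi_m, var_m)
  else {
    se <- sqrt(var_m)
    list(point = psi_m, se = se, T = var_m,
         ci = psi_m + c(-1, 1) * stats::qnorm(0.975) * se, M = 1L)
  }
  psi2 <- if (degree >= 2) {
    if (M >= 2) rubin_pool(psi2_m, var2_m)
    else list(point = psi2_m, se = sqrt(var2_m),
              ci = psi2_m + c(-1, 1) * stats::qnorm(0.975) * sqrt(var2_m))
  } else NULL
  avg <- rowMeans(coef_mat)
  structure(list(mixture = if (length(mixture) == 1L) mixture else "custom",
                 members = members, psi = pooled,
                 OR = exp(pooled$point), ci = exp(pooled$ci),
                 psi_quadratic = psi2,
                 weights = partition_weights(avg),
                 per_imputation = list(psi = psi_m, var = var_m),
                 q = q, degree = degree, n_boot = n_boot,
                 redrawn = redrawn, variant = "boot"),
            class = "cp_mixture_result")
}

#' Leave-one-out mixture estimate
#'
#' Re-runs the core quantile g-computation on the mixture with one named
#' member removed (e.g. MixTox without Hg).
#'
#' @inheritParams qgcomp_core
#' @param member Member to drop.
#' @return `cp_mixture_result` for the reduced mixture.
#' @export
leave_one_out <- function(imp, mixture, member, q = 4L,
                          covariates = adjustment_covariates()) {
  members <- mixture_members(mixture)
  if (!member %in% members) abort("'%s' is not in the mixture", member)
  if (length(members) <= 1) abort("cannot drop the only member")
  qgcomp_core(imp, setdiff(members, member), q = q, covariates = covariates)
}
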