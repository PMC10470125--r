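# Pooled logistic effect estimation, spline nonlinearity checks,
# interaction models, and the sensitivity-analysis suite.

as_datasets <- function(imp) {
  if (inherits(imp, "cp_imputation_set")) imp$datasets
  else if (is.data.frame(imp)) list(imp)
  else if (is.list(imp)) imp
  else abort("expected an imputation set, data.frame, or list of data.frames")
}

pool_glm_term <- function(datasets, formula_terms, target, dfcom_hint = NULL) {
  # fit case ~ terms in each dataset, pool the target coefficient
  M <- length(datasets)
  pts <- vars <- rep(NA_real_, M)
  failed <- 0L
  dfcom <- Inf
  for (m in seq_len(M)) {
    f <- stats::as.formula(paste("case ~", paste(formula_terms, collapse = " + ")))
    fit <- tryCatch(
      stats::glm(f, family = stats::binomial(), data = datasets[[m]]),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(stats::glm(f, family = stats::binomial(),
                                    data = datasets[[m]]))
      })
    if (is.null(fit) || !fit$converged || is.na(stats::coef(fit)[target])) {
      failed <- failed + 1L
      next
    }
    pts[m] <- stats::coef(fit)[target]
    vars[m] <- stats::vcov(fit)[target, target]
    dfcom <- fit$df.residual
  }
  ok <- !is.na(pts)
  if (sum(ok) < 2) abort("fewer than 2 usable imputation fits for '%s'", target)
  pooled <- rubin_pool(pts[ok], vars[ok], dfcom = dfcom)
  list(pooled = pooled, failed = failed, M = M)
}

#' Pooled odds ratios per IQR for selected exposures
#'
#' Fits multivariable adjusted logistic models in every imputed dataset
#' and pools the ln-scale coefficients by Rubin's rules. Both variants
#' are produced: single-exposure models (one metal at a time plus
#' covariates) and the co-adjusted model containing all supplied
#' exposures simultaneously. Estimates are reported as OR per
#' interquartile-range increase of the ln-scale exposure:
#' `OR = exp(beta * IQR)`.
#'
#' @param imp Imputation set (or list of completed data.frames).
#' @param exposures Metal names to estimate.
#' @param covariates Adjustment covariates.
#' @param iqr Named ln-scale IQR vector (from [preprocess()]).
#' @param variants Any of `"single"`, `"co_adjusted"`.
#' @return Data.frame: `term`, `variant`, `OR`, `ci_low`, `ci_high`,
#'   `beta`, `se`, `iqr`, `unreliable`.
#' @export
fit_effects <- function(imp, exposures, covariates = adjustment_covariates(),
                        iqr, variants = c("single", "co_adjusted")) {
  datasets <- as_datasets(imp)
  if (!all(exposures %in% names(iqr)))
    abort("IQR missing for: %s",
          paste(setdiff(exposures, names(iqr)), collapse = ", "))
  rows <- list()
  add_row <- function(term, variant, res) {
    p <- res$pooled
    scale <- iqr[[term]]
    rows[[length(rows) + 1L]] <<- data.frame(
      term = term, variant = variant,
      OR = exp(p$point * scale),
      ci_low = exp(p$ci[1] * scale), ci_high = exp(p$ci[2] * scale),
      beta = p$point, se = p$se, iqr = scale,
      unreliable = res$failed > 0.1 * res$M,
      stringsAsFactors = FALSE)
  }
  if ("single" %in% variants)
    for (e in exposures)
      add_row(e, "single", pool_glm_term(datasets, c(e, covariates), e))
  if ("co_adjusted" %in% variants && length(exposures))
    for (e in exposures)
      add_row(e, "co_adjusted",
              pool_glm_term(datasets, c(exposures, covariates), e))
  do.call(rbind, rows)
}

#' Spline likelihood-ratio check for nonlinearity
#'
#' Tests a linear ln-exposure term against a natural cubic spline with
#' knots at the 10th, 50th and 90th percentiles (internal knot at the
#' median, boundary knots at the outer two) in multivariable adjusted
#' logistic models. The LR statistic is computed in every imputed
#' dataset and pooled with a between-imputation correction.
#'
#' @param imp Imputation set.
#' @param exposure Metal name (ln scale in the data).
#' @param covariates Adjustment covariates.
#' @param alpha Verdict level.
#' @param internal_knots `"median"` (default: one internal knot at the
#'   50th percentile) or `"all"` (internal knots at all three stated
#'   percentiles).
#' @return List of class `cp_spline_comparison`: `exposure`, `knots`,
#'   `lr` (per-imputation statistics), `df`, `p`, `verdict`.
#' @export
spline_lr <- function(imp, exposure, covariates = adjustment_covariates(),
                      alpha = 0.05, internal_knots = c("median", "all")) {
  internal_knots <- match.arg(internal_knots)
  datasets <- as_datasets(imp)
  pooled_x <- unlist(lapply(datasets, `[[`, exposure))
  kn <- quantile7(pooled_x, c(0.1, 0.5, 0.9))
  if (any(duplicated(kn))) abort("coincident spline knots for '%s'", exposure)
  lr <- numeric(length(datasets))
  spline_df <- NA_integer_
  for (m in seq_along(datasets)) {
    d <- datasets[[m]]
    basis <- if (internal_knots == "median")
      splines::ns(d[[exposure]], knots = kn[2], Boundary.knots = kn[c(1, 3)])
    else splines::ns(d[[exposure]], knots = kn)
    spline_df <- ncol(basis)
    d$.spl <- basis
    f0 <- stats::as.formula(paste("case ~", exposure, "+",
                                  paste(covariates, collapse = " + ")))
    f1 <- stats::as.formula(paste("case ~ .spl +",
                                  paste(covariates, collapse = " + ")))
    fit0 <- stats::glm(f0, stats::binomial(), data = d)
    fit1 <- stats::glm(f1, stats::binomial(), data = d)
    lr[m] <- max(fit0$deviance - fit1$deviance, 0)
  }
  df <- spline_df - 1L
  pooled <- if (length(lr) >= 2) pool_lr_pvalues(lr, df)
            else list(p = stats::pchisq(lr, df, lower.tail = FALSE))
  structure(list(exposure = exposure, knots = kn, lr = lr, df = df,
                 p = pooled$p,
                 verdict = if (pooled$p <= alpha) "nonlinear" else "linear"),
            class = "cp_spline_comparison")
}

parse_interaction <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

#' Pooled interaction model with stratified prediction curves
#'
#' Fits one multivariable logistic model containing all selected
#' interaction terms, their (standardized) main effects, and the
#' adjustment covariates, pooled across imputations. For visualization it
#' exports predicted log-odds curves of each metal over a +/-2 SD grid at
#' low/high (-1/+1 SD) levels of its partner, with all other terms at
#' their means.
#'
#' @param imp Imputation set.
#' @param terms Interaction terms like `"cu:pb"` or `"hg:education"`.
#' @param covariates Adjustment covariates.
#' @return List of class `cp_interaction_result`: `coefficients`
#'   (data.frame term/beta/se/ci), `curves` (plot-ready data.frame).
#' @export
interaction_effects <- function(imp, terms,
                                covariates = adjustment_covariates()) {
  datasets <- as_datasets(imp)
  parents <- unique(unlist(lapply(terms, parse_interaction)))
  model_terms <- c(parents, paste0("`", terms, "`"))
  M <- length(datasets)
  all_names <- NULL
  pts <- vars <- NULL
  for (m in seq_len(M)) {
    d <- datasets[[m]]
    need <- unique(c(parents, covariates))
    Z <- scale(as.matrix(d[, need, drop = FALSE]))
    dd <- as.data.frame(Z)
    for (tm in terms) {
      pr <- parse_interaction(tm)
      dd[[tm]] <- dd[[pr[1]]] * dd[[pr[2]]]
    }
    dd$case <- d$case
    f <- stats::as.formula(paste("case ~",
      paste(c(covariates, model_terms), collapse = " + ")))
    fit <- stats::glm(f, stats::binomial(), data = dd)
    co <- stats::coef(fit)
    vc <- diag(stats::vcov(fit))
    drop_na <- is.na(co)
    if (any(drop_na)) {
      warning("rank-deficient interaction model; dropped: ",
              paste(names(co)[drop_na], collapse = ", "), call. = FALSE)
      co[drop_na] <- 0; vc[drop_na] <- 0
    }
    if (is.null(all_names)) {
      all_names <- names(co)
      pts <- vars <- matrix(NA_real_, length(co), M,
                            dimnames = list(all_names, NULL))
    }
    pts[, m] <- co[all_names]
    vars[, m] <- vc[all_names]
  }
  coefs <- do.call(rbind, lapply(all_names, function(nm) {
    p <- if (M >= 2) rubin_pool(pts[nm, ], vars[nm, ])
         else list(point = pts[nm, 1], se = sqrt(vars[nm, 1]),
                   ci = pts[nm, 1] + c(-1.96, 1.96) * sqrt(vars[nm, 1]))
    data.frame(term = nm, beta = p$point, se = p$se,
               ci_low = p$ci[1], ci_high = p$ci[2], stringsAsFactors = FALSE)
  }))
  beta <- stats::setNames(coefs$beta, coefs$term)

  grid <- seq(-2, 2, length.out = 41)
  curves <- list()
  for (tm in terms) {
    pr <- parse_interaction(tm)
    met <- if (pr[1] %in% METALS) pr[1] else pr[2]
    partner <- setdiff(pr, met)[1]
    itm <- paste0("`", tm, "`")
    bi <- if (itm %in% names(beta)) beta[[itm]] else beta[[tm]]
    for (lev in c(-1, 1)) {
      eta <- beta[["(Intercept)"]] + beta[[met]] * grid +
        (if (partner %in% names(beta)) beta[[partner]] * lev else 0) +
        bi * grid * lev
      curves[[length(curves) + 1L]] <- data.frame(
        term = tm, metal = met, partner = partner,
        partner_level = ifelse(lev < 0, "low", "high"),
        z = grid, logodds = eta, stringsAsFactors = FALSE)
    }
  }
  structure(list(coefficients = coefs, curves = do.call(rbind, curves)),
            class = "cp_interaction_result")
}

#' Sensitivity-analysis suite
#'
#' Re-estimates the co-adjusted effect models for the selected exposures
#' under each scenario: restriction to term births (gestational age >=
#' 259 days), to children not born small for gestational age, to
#' non-smoking mothers; the no-winsorization variant; complete cases
#' (no imputation); and stratification by median maternal folate intake
#' (computed per imputed dataset). Underpowered scenarios (< 20 cases)
#' are flagged but still run.
#'
#' @param cohort A `cp_cohort` with `observed`, `qc`, `reasons`.
#' @param exposures Metals to estimate (co-adjusted).
#' @param scenarios Character subset of the defaults.
#' @param marginals Marginal spec (for censoring bounds).
#' @param M Imputations per scenario.
#' @param seed Integer seed.
#' @param covariates Adjustment covariates.
#' @return Long data.frame of effect rows with `scenario` and
#'   `underpowered` columns.
#' @export
sensitivity_suite <- function(cohort, exposures,
                              scenarios = c("full", "term", "non_sga",
                                            "non_smoking", "no_winsorize",
                                            "complete_case", "folate_low",
                                            "folate_high"),
                              marginals = default_marginals(), M = 5L,
                              seed = 1L,
                              covariates = adjustment_covariates()) {
  obs <- cohort$observed
  out <- list()
  for (i in seq_along(scenarios)) {
    sc <- scenarios[i]
    keep <- switch(sc,
      full = , no_winsorize = , complete_case = ,
      folate_low = , folate_high = rep(TRUE, nrow(obs)),
      term = !is.na(obs$gest_age) & obs$gest_age >= 259,
      non_sga = if ("sga" %in% names(obs)) obs$sga == 0
                else rep(TRUE, nrow(obs)),
      non_smoking = !is.na(obs$smoking) & obs$smoking == 0,
      abort("unknown scenario '%s'", sc))
    sub <- obs[keep, , drop = FALSE]
    reasons <- cohort$reasons[cohort$reasons$subject_id %in% sub$subject_id, ,
                              drop = FALSE]
    pp <- preprocess(sub, cohort$qc, marginals, reasons,
                     winsorize = sc != "no_winsorize")
    eff <- if (sc == "complete_case") {
      used <- intersect(imputation_variables(), names(pp$data))
      cc <- pp$data[stats::complete.cases(pp$data[, used]), , drop = FALSE]
      fit_effects(list(cc, cc), exposures, covariates, pp$iqr,
                  variants = "co_adjusted")
    } else {
      # seed depends on the data content only, so a restriction that
      # keeps the full sample reproduces the full-sample estimates
      imp <- impute(pp$data, M = max(M, 2L), bounds = pp$bounds,
                    seed = seed)
      dsets <- imp$datasets
      if (sc %in% c("folate_low", "folate_high")) {
        dsets <- lapply(dsets, function(d) {
          med <- stats::median(d$folate)
          if (sc == "folate_low") d[d$folate <= med, , drop = FALSE]
          else d[d$folate > med, , drop = FALSE]
        })
      }
      fit_effects(dsets, exposures, covariates, pp$iqr,
                  variants = "co_adjusted")
    }
    n_cases_sc <- if (sc %in% c("folate_low", "folate_high"))
      round(sum(sub$case) / 2) else sum(sub$case)
    eff$scenario <- sc
    eff$underpowered <- n_cases_sc < 20
    out[[sc]] <- eff
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
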