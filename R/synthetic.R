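# Synthetic cohort generator: Gaussian-copula log-normal exposures,
# margin-matched covariates, logistic case-control outcome, analytical
# round batch effects with QC replicates, and below-LOD/LOQ censoring.

#' Log-normal parameters from arithmetic moments
#'
#' Method-of-moments calibration: returns the ln-scale location and scale
#' of the log-normal distribution whose arithmetic mean and SD equal the
#' supplied values: `sigma^2 = ln(1 + (sd/mean)^2)`,
#' `mu = ln(mean) - sigma^2/2`.
#'
#' @param mean Arithmetic mean (> 0).
#' @param sd Arithmetic SD (>= 0); `sd = 0` yields a point mass.
#' @return List with elements `mu` and `sigma`.
#' @examples
#' lognormal_params_from_moments(1.4, 0.9)
#' @export
lognormal_params_from_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0)
    abort("mean must be a positive finite number, got %s", format(mean))
  if (!is.finite(sd) || sd < 0)
    abort("sd must be a non-negative finite number, got %s", format(sd))
  sigma2 <- log1p((sd / mean)^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Spearman to Pearson correlation under a Gaussian copula
#'
#' Converts a target Spearman rank correlation into the Pearson
#' correlation of the underlying bivariate normal so that the simulated
#' ranks reproduce the target: `rho_p = 2 sin(pi rho_s / 6)`.
#'
#' @param rho_s Spearman correlation in `[-1, 1]` (vectorized).
#' @return Pearson correlation(s) of the latent normal.
#' @export
spearman_to_pearson <- function(rho_s) {
  if (any(!is.finite(rho_s)) || any(abs(rho_s) > 1))
    abort("Spearman correlation must lie in [-1, 1]")
  2 * sin(pi * rho_s / 6)
}

# Build the latent Pearson correlation matrix from a Spearman pair spec.
# Non-positive-definite results are repaired to the nearest PSD matrix
# (with a warning) unless repair = FALSE.
copula_correlation <- function(correlations, metals = METALS, repair = TRUE) {
  R <- diag(length(metals))
  dimnames(R) <- list(metals, metals)
  if (!is.null(correlations) && nrow(correlations)) {
    for (r in seq_len(nrow(correlations))) {
      i <- match(correlations$metal_i[r], metals)
      j <- match(correlations$metal_j[r], metals)
      if (is.na(i) || is.na(j))
        abort("unknown metal in correlation spec: %s-%s",
              correlations$metal_i[r], correlations$metal_j[r])
      R[i, j] <- R[j, i] <- spearman_to_pearson(correlations$rho[r])
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    if (!repair)
      abort("implied latent correlation matrix is not positive semi-definite")
    warning("latent correlation matrix repaired to nearest PSD", call. = FALSE)
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    dimnames(R) <- list(metals, metals)
  }
  R
}

#' Simulate latent metal concentrations
#'
#' Draws `n` subjects' uncensored concentrations from a Gaussian copula
#' with log-normal marginals calibrated to the supplied arithmetic
#' moments.
#'
#' @param n Number of subjects.
#' @param marginals Marginal spec ([default_marginals()]).
#' @param correlations Spearman pair spec ([default_correlations()]).
#' @param seed Integer seed.
#' @return A data.frame of `n` rows, one column per metal.
#' @export
simulate_metals <- function(n, marginals = default_marginals(),
                            correlations = default_correlations(),
                            seed = 1L) {
  validate_marginals(marginals)
  metals <- marginals$metal
  R <- copula_correlation(correlations, metals)
  set.seed(as.integer(seed))
  Z <- matrix(stats::rnorm(n * length(metals)), n) %*% chol(R)
  out <- matrix(NA_real_, n, length(metals), dimnames = list(NULL, metals))
  for (i in seq_along(metals)) {
    p <- lognormal_params_from_moments(marginals$mean[i], marginals$sd[i])
    out[, i] <- if (p$sigma == 0) rep(marginals$mean[i], n)
                else stats::qlnorm(stats::pnorm(Z[, i]), p$mu, p$sigma)
  }
  as.data.frame(out)
}

simulate_covariates <- function(n, covariate_spec = default_covariate_spec(),
                                seed = 1L) {
  set.seed(as.integer(seed))
  out <- data.frame(row.names = seq_len(n))
  cc <- covariate_spec$continuous
  for (i in seq_len(nrow(cc))) {
    out[[cc$name[i]]] <- switch(cc$family[i],
      normal = stats::rnorm(n, cc$mean[i], cc$sd[i]),
      lognormal = {
        p <- lognormal_params_from_moments(cc$mean[i], cc$sd[i])
        stats::rlnorm(n, p$mu, p$sigma)
      },
      abort("unknown covariate family %s", cc$family[i]))
  }
  bb <- covariate_spec$binary
  for (i in seq_len(nrow(bb)))
    out[[bb$name[i]]] <- stats::rbinom(n, 1L, bb$prob[i])
  out
}

#' Simulate the source population
#'
#' Generates a full source population (exposures, covariates, case
#' probability and case indicator) before any case-control subsampling,
#' batch perturbation or censoring. Metal effect sizes in the outcome
#' spec are log-odds per 1 SD of the ln-scale concentration.
#'
#' @inheritParams simulate_metals
#' @param covariate_spec Covariate spec ([default_covariate_spec()]).
#' @param outcome_spec Outcome spec ([default_outcome_spec()]).
#' @return A data.frame with `subject_id`, the 11 metals, covariates,
#'   `eta` (true log-odds) and `case`.
#' @export
simulate_population <- function(n, marginals = default_marginals(),
                                correlations = default_correlations(),
                                covariate_spec = default_covariate_spec(),
                                outcome_spec = default_outcome_spec(),
                                seed = 1L) {
  seeds <- derive_seeds(seed, 3L)
  metals <- simulate_metals(n, marginals, correlations, seeds[1])
  covs <- simulate_covariates(n, covariate_spec, seeds[2])
  pop <- cbind(subject_id = seq_len(n), metals, covs)

  eta <- rep(outcome_spec$intercept, n)
  betas <- outcome_spec$betas
  for (term in names(betas)) {
    if (term %in% marginals$metal) {
      p <- lognormal_params_from_moments(
        marginals$mean[marginals$metal == term],
        marginals$sd[marginals$metal == term])
      z <- if (p$sigma == 0) rep(0, n) else (log(pop[[term]]) - p$mu) / p$sigma
      eta <- eta + betas[[term]] * z
    } else if (term %in% names(covs)) {
      eta <- eta + betas[[term]] * covs[[term]]
    } else abort("outcome beta refers to unknown term '%s'", term)
  }
  set.seed(seeds[3])
  pop$eta <- eta
  pop$case <- stats::rbinom(n, 1L, stats::plogis(eta))
  pop
}

#' Generate a nested case-control cohort
#'
#' Oversamples a source population, then draws exactly `n_cases` cases and
#' `n_controls` controls, mirroring a nested case-control design rather
#' than cohort prevalence. The returned object retains the latent truth.
#'
#' @inheritParams simulate_population
#' @param n_source Source-population size (default chosen to yield ample
#'   cases under the default 2% source prevalence).
#' @return An object of class `cp_cohort`: a list with `truth` (latent
#'   uncensored table), `outcome_spec`, and the seed used.
#' @export
generate_cohort <- function(marginals = default_marginals(),
                            correlations = default_correlations(),
                            covariate_spec = default_covariate_spec(),
                            outcome_spec = default_outcome_spec(),
                            seed = 1L, n_source = 100000L) {
  seeds <- derive_seeds(seed, 2L)
  pop <- simulate_population(n_source, marginals, correlations,
                             covariate_spec, outcome_spec, seeds[1])
  n_cases <- outcome_spec$n_cases
  n_controls <- outcome_spec$n_controls
  cases <- which(pop$case == 1L)
  controls <- which(pop$case == 0L)
  if (length(cases) < n_cases || length(controls) < n_controls)
    abort("source population too small: %d cases / %d controls available, %d / %d requested",
          length(cases), length(controls), n_cases, n_controls)
  set.seed(seeds[2])
  keep <- c(sample(cases, n_cases), sample(controls, n_controls))
  truth <- pop[keep, , drop = FALSE]
  truth$subject_id <- seq_len(nrow(truth))
  rownames(truth) <- NULL
  structure(list(truth = truth, marginals = marginals,
                 outcome_spec = outcome_spec, seed = seed),
            class = "cp_cohort")
}

#' Apply analytical-round batch effects
#'
#' Assigns subjects to analytical rounds, multiplies each latent
#' concentration by the metal-and-round bias times per-sample log-normal
#' measurement noise, and generates the QC replicate table (reference
#' value times the same round bias times QC noise). The latent truth is
#' untouched.
#'
#' @param cohort A `cp_cohort` from [generate_cohort()].
#' @param batch_spec Batch spec ([default_batch_spec()]).
#' @param seed Integer seed.
#' @return The cohort with `observed` (raw exposure table including a
#'   `round` and `lund` column) and `qc` (data.frame round/metal/qc_value)
#'   added.
#' @export
apply_batch_effects <- function(cohort, batch_spec = default_batch_spec(),
                                seed = 1L) {
  validate_batch_spec(batch_spec)
  truth <- cohort$truth
  n <- nrow(truth)
  seeds <- derive_seeds(seed, 3L)

  set.seed(seeds[1])
  round_lab <- sample(batch_spec$rounds, n, replace = TRUE,
                      prob = batch_spec$proportions)
  lund <- stats::rbinom(n, 1L, batch_spec$lund_fraction)

  cv2sdlog <- function(cv) sqrt(log1p(cv^2))
  obs <- truth
  obs$eta <- NULL
  set.seed(seeds[2])
  sdlog <- cv2sdlog(batch_spec$meas_noise_cv)
  for (met in METALS) {
    mult <- batch_spec$multipliers[met, round_lab]
    noise <- if (sdlog > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else 1
    obs[[met]] <- truth[[met]] * mult * noise
  }
  obs$round <- round_lab
  obs$lund <- lund

  set.seed(seeds[3])
  sdq <- cv2sdlog(batch_spec$qc_noise_cv)
  qc <- expand.grid(round = batch_spec$rounds, metal = METALS,
                    rep = seq_len(batch_spec$qc_replicates),
                    stringsAsFactors = FALSE)
  noise <- if (sdq > 0) stats::rlnorm(nrow(qc), -sdq^2 / 2, sdq) else 1
  qc$qc_value <- batch_spec$qc_reference[qc$metal] *
    batch_spec$multipliers[cbind(qc$metal, qc$round)] * noise
  qc$rep <- NULL
  cohort$observed <- obs
  cohort$qc <- qc[order(qc$metal, qc$round), c("round", "metal", "qc_value")]
  rownames(cohort$qc) <- NULL
  cohort
}

#' Censor below-limit values and apply structural missingness
#'
#' Sets As values below LOD and Cd/Co values below LOQ to missing (with
#' reasons `below_lod`/`below_loq`), blanks Mg and Cs for the
#' external-laboratory subset (`not_analysed`), and applies optional MCAR
#' covariate missingness.
#'
#' @param cohort A `cp_cohort` with an `observed` table (see
#'   [apply_batch_effects()]).
#' @param marginals Marginal spec carrying `lod`/`loq`.
#' @param missing_spec Named MCAR rates per covariate
#'   ([default_missing_spec()]); use `NULL` for none.
#' @param seed Integer seed.
#' @return The cohort with censored `observed` and a `reasons` data.frame
#'   (subject_id, variable, reason).
#' @export
censor_and_missing <- function(cohort, marginals = default_marginals(),
                               missing_spec = default_missing_spec(),
                               seed = 1L) {
  obs <- cohort$observed
  if (is.null(obs)) abort("apply_batch_effects() must run before censoring")
  reasons <- list()
  flag <- function(ids, var, why) {
    if (!length(ids)) return(NULL)
    data.frame(subject_id = ids, variable = var, reason = why,
               stringsAsFactors = FALSE)
  }

  lim <- function(met, col) marginals[[col]][marginals$metal == met]
  if (!is.na(lim("as", "lod"))) {
    hit <- which(obs$as < lim("as", "lod"))
    obs$as[hit] <- NA_real_
    reasons[[length(reasons) + 1L]] <- flag(obs$subject_id[hit], "as", "below_lod")
  }
  for (met in c("cd", "co")) {
    lq <- lim(met, "loq")
    if (is.na(lq)) next
    hit <- which(obs[[met]] < lq)
    obs[[met]][hit] <- NA_real_
    reasons[[length(reasons) + 1L]] <- flag(obs$subject_id[hit], met, "below_loq")
  }
  lund <- which(obs$lund == 1L)
  for (met in c("mg", "cs")) {
    obs[[met]][lund] <- NA_real_
    reasons[[length(reasons) + 1L]] <- flag(obs$subject_id[lund], met, "not_analysed")
  }
  if (!is.null(missing_spec) && length(missing_spec)) {
    set.seed(as.integer(seed))
    for (var in names(missing_spec)) {
      if (!var %in% names(obs)) next
      hit <- which(stats::rbinom(nrow(obs), 1L, missing_spec[[var]]) == 1L)
      obs[[var]][hit] <- NA
      reasons[[length(reasons) + 1L]] <- flag(obs$subject_id[hit], var, "mcar")
    }
  }
  cohort$observed <- obs
  cohort$reasons <- do.call(rbind, reasons) %||%
    data.frame(subject_id = integer(0), variable = character(0),
               reason = character(0))
  cohort
}

#' Simulate a complete synthetic cohort
#'
#' One-call wrapper: case-control cohort, batch effects with QC table,
#' censoring and missingness, all from one master seed.
#'
#' @inheritParams generate_cohort
#' @param batch_spec Batch spec ([default_batch_spec()]).
#' @param missing_spec MCAR rates ([default_missing_spec()]).
#' @return A `cp_cohort` with `truth`, `observed`, `qc` and `reasons`.
#' @export
simulate_cohort <- function(seed = 1L,
                            marginals = default_marginals(),
                            correlations = default_correlations(),
                            covariate_spec = default_covariate_spec(),
                            outcome_spec = default_outcome_spec(),
                            batch_spec = default_batch_spec(marginals),
                            missing_spec = default_missing_spec(),
                            n_source = 100000L) {
  seeds <- derive_seeds(seed, 3L)
  cohort <- generate_cohort(marginals, correlations, covariate_spec,
                            outcome_spec, seeds[1], n_source)
  cohort <- apply_batch_effects(cohort, batch_spec, seeds[2])
  censor_and_missing(cohort, marginals, missing_spec, seeds[3])
}
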