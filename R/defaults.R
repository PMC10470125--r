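# Default specifications for the synthetic cohort generator.
#
# The shipped defaults encode the study conditions the pipeline is
# designed for: a nested case-control sample of 144 cerebral-palsy cases
# and 1,082 controls drawn from a pregnancy cohort, with 11 metals and
# essential elements measured in maternal blood across three analytical
# rounds (plus a small external-laboratory subset), left-censoring below
# LOD/LOQ for As/Cd/Co, and the published marginal moments and Spearman
# correlations of the exposure panel.

#' Default marginal specification for the metal panel
#'
#' Arithmetic mean and SD of each metal/element concentration in the full
#' study sample (ug/L; Mg in mg/L), used to calibrate log-normal marginals
#' by the method of moments. Detection/quantification limits are supplied
#' for the three left-censored analytes: As is reported above LOD, Cd and
#' Co above LOQ. The shipped limits are set at the marginal quantiles that
#' reproduce the observed below-limit counts (12, 22 and 33 of 1,226).
#'
#' @return A data.frame with columns `metal`, `mean`, `sd`, `lod`, `loq`,
#'   `unit`.
#' @export
default_marginals <- function() {
  m <- data.frame(
    metal = METALS,
    mean  = c(1.4, 2.4, 0.2, 10.0, 11.5, 92.3, 0.3, 2.4, 1588, 5457, 30.3),
    sd    = c(0.9, 3.0, 0.3,  5.8,  9.4, 20.2, 0.9, 0.9,  248, 1072,  3.5),
    lod   = NA_real_,
    loq   = NA_real_,
    unit  = c(rep("ug/L", 10), "mg/L"),
    stringsAsFactors = FALSE
  )
  # censoring limits calibrated to the observed below-limit fractions
  frac <- c(as = 12 / 1226, cd = 22 / 1226, co = 33 / 1226)
  for (met in names(frac)) {
    i <- match(met, m$metal)
    p <- lognormal_params_from_moments(m$mean[i], m$sd[i])
    q <- stats::qlnorm(frac[[met]], p$mu, p$sigma)
    if (met == "as") m$lod[i] <- q else m$loq[i] <- q
  }
  m
}

#' Default dependence specification
#'
#' Pairwise Spearman correlations of the exposure panel; unlisted pairs
#' default to zero. The two strongest published correlations ship as
#' defaults: As-Hg 0.59 and Mg-Zn 0.53.
#'
#' @return A data.frame with columns `metal_i`, `metal_j`, `rho`.
#' @export
default_correlations <- function() {
  data.frame(
    metal_i = c("as", "mg"),
    metal_j = c("hg", "zn"),
    rho     = c(0.59, 0.53),
    stringsAsFactors = FALSE
  )
}

#' Default covariate specification
#'
#' Marginal distributions matched to the study-sample descriptive table:
#' continuous covariates by mean/SD (normal for maternal age and
#' gestational age; log-normal for the non-negative skewed seafood,
#' folate and BMI variables), binary covariates by prevalence. Covariates
#' are drawn independently.
#'
#' @return A list with elements `continuous` (data.frame: name, mean, sd,
#'   family) and `binary` (data.frame: name, prob, meaning of 1).
#' @export
default_covariate_spec <- function() {
  list(
    continuous = data.frame(
      name   = c("mat_age", "seafood", "folate", "gest_age", "bmi"),
      mean   = c(30.1, 36.2, 515.5, 277.9, 23.5),
      sd     = c(4.5, 21.8, 273.1, 16.0, 6.1),
      family = c("normal", "lognormal", "lognormal", "normal", "lognormal"),
      stringsAsFactors = FALSE
    ),
    binary = data.frame(
      name  = c("parity", "education", "smoking", "sex", "birth_period", "sga"),
      prob  = c(0.560, 0.661, 0.128, 0.325, 0.240, 27 / 1226),
      one   = c("parous", ">=5y university", "smoker", "girl", ">=2006",
                "small for gestational age"),
      stringsAsFactors = FALSE
    )
  )
}

#' Default outcome model specification
#'
#' Logistic case-generating model on the source population. Metal terms
#' are log-odds per 1 SD of the ln-scale concentration; covariate terms
#' are per unit (binary: per level). The default is the global null (all
#' betas zero) with the study's case-control counts; recovery tests and
#' power simulations override `betas`.
#'
#' @param betas Named numeric vector of non-zero log-odds terms (names
#'   among the metals and covariates); unlisted terms are zero.
#' @param intercept Source-population log-odds of being a case.
#' @param n_cases,n_controls Case-control sample sizes to draw.
#' @return A list with class `outcome_spec`.
#' @export
default_outcome_spec <- function(betas = numeric(0),
                                 intercept = stats::qlogis(0.02),
                                 n_cases = 144, n_controls = 1082) {
  stopifnot(all(is.finite(betas)), all(is.finite(intercept)))
  structure(list(intercept = intercept, betas = betas,
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls)),
            class = "outcome_spec")
}

#' Default batch-effect specification
#'
#' Three analytical rounds with subject proportions (0.40, 0.35, 0.25)
#' and multiplicative per-round biases (1.0, 1.1, 0.9) applied to every
#' metal; five QC replicates per round drawn around a per-metal reference
#' value with 5% coefficient of variation; 2% per-sample measurement
#' noise. A fraction 105/1226 of subjects form the external-laboratory
#' ("Lund") subset in which Mg and Cs were not analysed.
#'
#' @param marginals Marginal spec used for the QC reference values
#'   (defaults to the marginal means).
#' @return A list with class `batch_spec`.
#' @export
default_batch_spec <- function(marginals = default_marginals()) {
  mult <- matrix(rep(c(1.0, 1.1, 0.9), each = length(METALS)),
                 nrow = length(METALS),
                 dimnames = list(METALS, c("1", "2", "3")))
  structure(list(
    rounds = c("1", "2", "3"),
    proportions = c(0.40, 0.35, 0.25),
    multipliers = mult,
    qc_reference = stats::setNames(marginals$mean, marginals$metal),
    qc_replicates = 5L,
    qc_noise_cv = 0.05,
    meas_noise_cv = 0.02,
    lund_fraction = 105 / 1226
  ), class = "batch_spec")
}

#' Default missingness specification
#'
#' Covariate missing-completely-at-random rates matched to the study
#' sample's missing counts (seafood 143, folate 273, gestational age 5,
#' education 30, all out of 1,226), applied on top of the structural
#' exposure missingness (below-LOD/LOQ censoring and the external-lab
#' subset handled by [censor_and_missing()]).
#'
#' @return Named numeric vector of MCAR rates per covariate.
#' @export
default_missing_spec <- function() {
  c(seafood = 143 / 1226, folate = 273 / 1226,
    gest_age = 5 / 1226, education = 30 / 1226)
}

validate_marginals <- function(marginals) {
  need <- c("metal", "mean", "sd")
  if (!all(need %in% names(marginals)))
    abort("marginal spec must have columns %s", paste(need, collapse = ", "))
  if (any(marginals$mean <= 0))
    abort("marginal means must be positive (offending: %s)",
          paste(marginals$metal[marginals$mean <= 0], collapse = ", "))
  if (any(marginals$sd < 0)) abort("marginal sd must be non-negative")
  both <- !is.na(marginals$lod) & !is.na(marginals$loq)
  if (any(both & marginals$lod > marginals$loq))
    abort("lod must not exceed loq")
  invisible(marginals)
}

validate_batch_spec <- function(spec) {
  if (abs(sum(spec$proportions) - 1) > 1e-8)
    abort("round proportions must sum to 1")
  if (any(spec$multipliers <= 0)) abort("batch multipliers must be positive")
  invisible(spec)
}
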