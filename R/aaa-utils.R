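#' @keywords internal
"_PACKAGE"

# Metal/element panel, in the column order used by all tables.
# Concentrations in ug/L except Mg (mg/L).
METALS <- c("hg", "as", "cd", "pb", "mn", "se", "co", "cs", "cu", "zn", "mg")

# Minimal adjustment set used by every outcome model.
ADJUST_COVARIATES <- c("sex", "birth_period", "parity", "education",
                       "smoking", "mat_age", "seafood")

# Auxiliary variables that enter the imputation model but not the
# outcome models.
AUX_COVARIATES <- c("gest_age", "folate", "bmi")

#' Metal/element panel names
#'
#' Column names of the 11 measured metals and essential elements, in
#' canonical order. All concentrations are ug/L except magnesium (mg/L).
#'
#' @return Character vector of length 11.
#' @export
metal_names <- function() METALS

#' Adjustment covariate names
#'
#' The minimal covariate adjustment set used by all outcome models:
#' child sex, birth-year period, parity, maternal education, maternal
#' smoking during pregnancy, maternal age at delivery, and maternal
#' seafood intake during pregnancy.
#'
#' @return Character vector of length 7.
#' @export
adjustment_covariates <- function() ADJUST_COVARIATES

# Deterministic per-stage seed derivation: a master seed expands into a
# stream of sub-seeds, all < 2^31, so stages are independently rerunnable.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Quantile rule used throughout: linear interpolation between closest
# ranks (type 7), the common default in scientific software.
quantile7 <- function(x, probs) {
  stats::quantile(x, probs = probs, na.rm = TRUE, names = FALSE, type = 7)
}

geomean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with sprintf formatting, no call in message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
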