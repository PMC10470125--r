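# Batch normalization, winsorization, ln transform, IQR computation.

#' QC-ratio batch adjustment
#'
#' Normalizes measured concentrations across analytical rounds using the
#' QC reference samples: each value is multiplied by the ratio of the
#' pooled geometric mean of that metal's QC replicates (across all
#' rounds) to the geometric mean within the sample's own round. Missing
#' cells stay missing; with a single round the data are unchanged.
#'
#' @param exposures Exposure table with metal columns and a `round`
#'   column.
#' @param qc QC table with columns `round`, `metal`, `qc_value`.
#' @param metals Metal columns to adjust (default: those present).
#' @return The exposure table with adjusted metal columns and an
#'   attribute `adjust_factors` (data.frame metal, round, factor).
#' @export
batch_adjust <- function(exposures, qc, metals = intersect(METALS, names(exposures))) {
  if (!"round" %in% names(exposures))
    abort("exposure table must have a 'round' column")
  if (any(qc$qc_value <= 0, na.rm = TRUE) || anyNA(qc$qc_value))
    abort("QC values must be positive and non-missing")
  rounds_used <- unique(as.character(exposures$round))
  factors <- list()
  for (met in metals) {
    qm <- qc[qc$metal == met, , drop = FALSE]
    observed_rounds <- unique(as.character(exposures$round[!is.na(exposures[[met]])]))
    missing_cov <- setdiff(observed_rounds, as.character(qm$round))
    if (length(missing_cov))
      abort("no QC coverage for metal '%s' in round(s) %s", met,
            paste(missing_cov, collapse = ", "))
    pooled <- geomean(qm$qc_value)
    per_round <- vapply(split(qm$qc_value, as.character(qm$round)),
                        geomean, numeric(1))
    fac <- pooled / per_round
    exposures[[met]] <- exposures[[met]] *
      unname(fac[as.character(exposures$round)])
    factors[[met]] <- data.frame(metal = met, round = names(fac),
                                 factor = unname(fac))
  }
  attr(exposures, "adjust_factors") <- do.call(rbind, factors)
  exposures
}

#' Winsorize a vector at given percentiles
#'
#' Replaces values below the `p_lo` percentile and above the `p_hi`
#' percentile with those percentile values. Percentiles use linear
#' interpolation between closest ranks. Missing values pass through.
#'
#' @param x Numeric vector with at least 2 observed values.
#' @param p_lo,p_hi Percentile bounds (defaults 0.01 and 0.99).
#' @return Winsorized vector with attribute `limits` = c(lo, hi).
#' @export
winsorize <- function(x, p_lo = 0.01, p_hi = 0.99) {
  obs <- sum(!is.na(x))
  if (obs < 2) abort("winsorize needs at least 2 observed values")
  q <- quantile7(x, c(p_lo, p_hi))
  out <- pmin(pmax(x, q[1]), q[2])
  attr(out, "limits") <- q
  out
}

#' Natural log transform
#'
#' Elementwise ln of strictly positive concentrations; missing values
#' pass through.
#'
#' @param x Numeric vector, observed values > 0.
#' @return ln(x).
#' @export
log_transform <- function(x) {
  if (any(x <= 0, na.rm = TRUE))
    abort("log_transform requires strictly positive observed values")
  log(x)
}

#' Interquartile range on the ln scale
#'
#' 75th minus 25th percentile of the supplied ln-scale values under the
#' same percentile rule as [winsorize()]. Used to report odds ratios per
#' interquartile-range increase in exposure.
#'
#' @param x Numeric vector of ln-scale values (>= 4 observed).
#' @return Positive IQR.
#' @export
iqr_ln <- function(x) {
  if (sum(!is.na(x)) < 4) abort("iqr_ln needs at least 4 observed values")
  q <- quantile7(x, c(0.25, 0.75))
  iqr <- q[2] - q[1]
  if (iqr <= 0) abort("degenerate IQR (zero spread)")
  iqr
}

#' Preprocess an exposure table
#'
#' Runs the full normalization chain in fixed order: QC-ratio batch
#' adjustment, winsorization at the pooled 1st/99th percentiles per
#' metal, then natural log transform. Also computes the ln-scale IQR per
#' metal and the adjusted (ln-scale) censoring bounds for below-limit
#' cells used downstream by bounded imputation.
#'
#' @param exposures Raw exposure table (e.g. `cohort$observed`).
#' @param qc QC table.
#' @param marginals Marginal spec carrying LOD/LOQ (for bound
#'   computation); `NULL` to skip bounds.
#' @param reasons Missing-reason table (`cohort$reasons`); `NULL` to
#'   skip bounds.
#' @param winsorize Logical; `FALSE` runs the sensitivity variant
#'   without winsorization.
#' @param eps_ratio Lower imputation bound as a fraction of the limit
#'   (default: limit / 10).
#' @return A list of class `cp_preprocessed`: `data` (metals on the
#'   winsorized ln scale), `iqr` (named vector), `limits` (per-metal
#'   p1/p99 on the adjusted scale), `bounds` (per-cell ln-scale bounds),
#'   `adjust_factors`.
#' @export
preprocess <- function(exposures, qc, marginals = NULL, reasons = NULL,
                       winsorize = TRUE, eps_ratio = 0.1) {
  metals <- intersect(METALS, names(exposures))
  adj <- batch_adjust(exposures, qc, metals)
  factors <- attr(adj, "adjust_factors")
  limits <- list()
  for (met in metals) {
    if (winsorize) {
      w <- winsorize(adj[[met]])
      limits[[met]] <- attr(w, "limits")
      adj[[met]] <- as.numeric(w)
    }
    adj[[met]] <- log_transform(adj[[met]])
  }
  iqr <- vapply(metals, function(m) iqr_ln(adj[[m]]), numeric(1))

  bounds <- NULL
  if (!is.null(marginals) && !is.null(reasons) && nrow(reasons)) {
    cens <- reasons[reasons$reason %in% c("below_lod", "below_loq"), ,
                    drop = FALSE]
    if (nrow(cens)) {
      lim_of <- function(met, why) {
        v <- if (why == "below_lod") marginals$lod else marginals$loq
        v[marginals$metal == met]
      }
      rows <- match(cens$subject_id, adj$subject_id)
      raw_lim <- mapply(lim_of, cens$variable, cens$reason)
      # censoring happened on the raw scale; carry the round's
      # adjustment factor into the bound
      fac <- mapply(function(met, rnd) {
        f <- factors$factor[factors$metal == met & factors$round == rnd]
        if (length(f)) f else 1
      }, cens$variable, as.character(adj$round[rows]))
      upper <- log(raw_lim * fac)
      bounds <- data.frame(subject_id = cens$subject_id,
                           variable = cens$variable,
                           lower = log(raw_lim * fac * eps_ratio),
                           upper = upper, stringsAsFactors = FALSE)
    }
  }
  structure(list(data = adj, iqr = iqr,
                 limits = if (length(limits)) do.call(rbind, limits) else NULL,
                 bounds = bounds, adjust_factors = factors,
                 winsorized = winsorize),
            class = "cp_preprocessed")
}
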