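# TSV/JSON I/O for the pipeline's tabular interfaces. Missing values are
# written as empty fields.

EXPOSURE_COLUMNS <- c("subject_id", "case", METALS, "round", "mat_age",
                      "seafood", "folate", "parity", "education", "smoking",
                      "sex", "birth_period", "gest_age", "bmi")

#' Write / read an exposure table
#'
#' Tab-separated, one row per subject, missing cells empty. Extra
#' columns (e.g. `lund`, `sga`) are preserved after the canonical ones.
#'
#' @param x Exposure table.
#' @param path File path.
#' @return `read_exposures` returns a data.frame.
#' @export
write_exposures <- function(x, path) {
  lead <- intersect(EXPOSURE_COLUMNS, names(x))
  x <- x[, c(lead, setdiff(names(x), lead)), drop = FALSE]
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_exposures
#' @export
read_exposures <- function(path) {
  utils::read.delim(path, na.strings = "", stringsAsFactors = FALSE,
                    colClasses = c(round = "character"))
}

#' Write / read a QC replicate table
#'
#' Columns `round`, `metal`, `qc_value`, one row per replicate.
#'
#' @param x QC table.
#' @param path File path.
#' @export
write_qc <- function(x, path) {
  utils::write.table(x[, c("round", "metal", "qc_value")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_qc
#' @export
read_qc <- function(path) {
  utils::read.delim(path, na.strings = "", stringsAsFactors = FALSE,
                    colClasses = c(round = "character"))
}

#' Write the simulation truth sidecar
#'
#' JSON echo of the generating model: outcome betas, intercept, seeds and
#' marginal spec, so downstream recovery checks can reload the ground
#' truth.
#'
#' @param cohort A `cp_cohort`.
#' @param path File path.
#' @export
write_truth <- function(cohort, path) {
  jsonlite::write_json(list(
    seed = cohort$seed,
    outcome = list(intercept = cohort$outcome_spec$intercept,
                   betas = as.list(cohort$outcome_spec$betas),
                   n_cases = cohort$outcome_spec$n_cases,
                   n_controls = cohort$outcome_spec$n_controls),
    marginals = cohort$marginals
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
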