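# End-to-end orchestration: simulate -> preprocess -> impute -> select
# -> effects -> mixtures, from one config and one master seed.

#' Pipeline configuration
#'
#' Two profiles: `"paper"` reproduces the study-scale resampling counts
#' (200 resamples x 20 imputations for the observed selection
#' probabilities; 1,200 permutations of 20 x 10 reduced runs), `"reduced"`
#' is a desk-scale configuration for simulation studies and tests.
#'
#' @param profile `"reduced"` or `"paper"`.
#' @param ... Named overrides of any config entry.
#' @return Named list of stage parameters.
#' @export
pipeline_config <- function(profile = c("reduced", "paper"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    n_source = 100000L,
    outcome_spec = default_outcome_spec(),
    winsorize = TRUE,
    M_impute = if (profile == "paper") 20L else 5L,
    select = list(
      B = if (profile == "paper") 200L else 20L,
      M = if (profile == "paper") 20L else 5L,
      K = if (profile == "paper") 1200L else 99L,
      B_perm = if (profile == "paper") 20L else 2L,
      M_perm = if (profile == "paper") 10L else 2L,
      alpha = 0.9, nfolds = 5L,
      nlambda = if (profile == "paper") 100L else 20L,
      p_cut = 0.05, psel_cut = 0.6, fdr_alpha = 0.05),
    q = 4L,
    run_boot = FALSE, n_boot = 200L, boot_degree = 2L,
    run_interactions = FALSE,
    scenarios = NULL)
  utils::modifyList(cfg, list(...))
}

#' Validate pipeline input tables
#'
#' Schema and sanity diagnostics for an exposure table and QC table:
#' required columns, positive concentrations, 0/1 case coding, and QC
#' coverage of every observed (metal, round) combination. Returns
#' diagnostics without mutating the data.
#'
#' @param exposures Exposure table.
#' @param qc QC table.
#' @return Data.frame with columns `severity` and `message` (zero rows
#'   when clean).
#' @export
validate_inputs <- function(exposures, qc) {
  issues <- list()
  note <- function(sev, fmt, ...)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = sev, message = sprintf(fmt, ...), stringsAsFactors = FALSE)
  need <- c("subject_id", "case", "round")
  for (col in need) if (!col %in% names(exposures))
    note("error", "exposure table lacks column '%s'", col)
  metals <- intersect(METALS, names(exposures))
  if (!length(metals)) note("error", "exposure table has no metal columns")
  if ("case" %in% names(exposures) &&
      !all(exposures$case %in% c(0, 1)))
    note("error", "case must be coded 0/1")
  for (met in metals)
    if (any(exposures[[met]] <= 0, na.rm = TRUE))
      note("error", "nonpositive concentration in '%s'", met)
  qc_need <- c("round", "metal", "qc_value")
  if (!all(qc_need %in% names(qc))) {
    note("error", "QC table must have columns %s",
         paste(qc_need, collapse = ", "))
  } else if ("round" %in% names(exposures)) {
    for (met in metals) {
      obs_rounds <- unique(as.character(
        exposures$round[!is.na(exposures[[met]])]))
      have <- unique(as.character(qc$round[qc$metal == met]))
      for (r in setdiff(obs_rounds, have))
        note("error", "no QC coverage for metal '%s' in round %s", met, r)
    }
    if (any(qc$qc_value <= 0, na.rm = TRUE))
      note("error", "nonpositive QC value")
  }
  do.call(rbind, issues) %||%
    data.frame(severity = character(0), message = character(0))
}

#' Run the full pipeline
#'
#' Executes simulate, preprocess, impute, select, effects and mixture
#' stages in order from one master seed (each stage gets a derived
#' sub-seed, so stages are independently rerunnable). Any stage input
#' can be supplied externally via `cohort`.
#'
#' @param config From [pipeline_config()].
#' @param seed Master integer seed.
#' @param cohort Optional externally supplied `cp_cohort` (skips the
#'   simulate stage).
#' @return List of class `cp_run_report`: `selection`, `effects`,
#'   `mixtures` (data.frame of 3 rows), `weights`, `iqr`, `config`,
#'   `warnings`, `seed`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         cohort = NULL) {
  seeds <- derive_seeds(seed, 6L)
  warn <- character(0)
  wh <- function(w) { warn <<- c(warn, conditionMessage(w))
                      invokeRestart("muffleWarning") }
  withCallingHandlers({
    marginals <- default_marginals()
    if (is.null(cohort))
      cohort <- simulate_cohort(seed = seeds[1],
                                outcome_spec = config$outcome_spec,
                                n_source = config$n_source)
    diag <- validate_inputs(cohort$observed, cohort$qc)
    if (any(diag$severity == "error"))
      abort("input validation failed: %s",
            paste(diag$message, collapse = "; "))

    pp <- preprocess(cohort$observed, cohort$qc, marginals,
                     cohort$reasons, winsorize = config$winsorize)
    imp <- impute(pp$data, M = config$M_impute, bounds = pp$bounds,
                  seed = seeds[2])

    sl <- config$select
    selection <- select_exposures(
      pp$data, B = sl$B, M = sl$M, K = sl$K, B_perm = sl$B_perm,
      M_perm = sl$M_perm, alpha = sl$alpha, seed = seeds[3],
      bounds = pp$bounds, p_cut = sl$p_cut, psel_cut = sl$psel_cut,
      fdr_alpha = sl$fdr_alpha, nfolds = sl$nfolds, nlambda = sl$nlambda)

    selected <- selection$term[selection$selected]
    effects <- fit_effects(imp, METALS, iqr = pp$iqr, variants = "single")
    if (length(selected))
      effects <- rbind(effects,
                       fit_effects(imp, selected, iqr = pp$iqr,
                                   variants = "co_adjusted"))

    mixtures <- list()
    weights <- list()
    for (mx in c("all", "tox", "essential")) {
      res <- qgcomp_core(imp, mx, q = config$q)
      mixtures[[mx]] <- data.frame(
        mixture = mx, variant = "core", OR = res$OR,
        ci_low = res$ci[1], ci_high = res$ci[2],
        psi = res$psi$point, stringsAsFactors = FALSE)
      w <- res$weights; w$mixture <- mx
      weights[[mx]] <- w
    }
    if (isTRUE(config$run_boot)) {
      res <- qgcomp_boot(imp, "all", q = config$q,
                         degree = config$boot_degree,
                         n_boot = config$n_boot, seed = seeds[4])
      mixtures$boot <- data.frame(
        mixture = "all", variant = "boot", OR = res$OR,
        ci_low = res$ci[1], ci_high = res$ci[2],
        psi = res$psi$point, stringsAsFactors = FALSE)
    }

    report <- list(selection = selection,
                   effects = effects,
                   mixtures = do.call(rbind, mixtures),
                   weights = do.call(rbind, weights),
                   iqr = pp$iqr,
                   config = config, seed = seed, warnings = warn)
    class(report) <- "cp_run_report"
    report
  }, warning = wh)
}

#' Write a run report to disk
#'
#' Serializes the report tables as TSV plus a JSON manifest (config echo
#' and warnings). Output is timestamp-free and byte-stable for a fixed
#' config and seed.
#'
#' @param report A `cp_run_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    write_tsv(format_numeric(as.data.frame(report$selection)),
              file.path(dir, "selection.tsv")),
    write_tsv(format_numeric(report$effects), file.path(dir, "effects.tsv")),
    write_tsv(format_numeric(report$mixtures),
              file.path(dir, "mixtures.tsv")),
    write_tsv(format_numeric(report$weights), file.path(dir, "weights.tsv")))
  manifest <- list(seed = report$seed,
                   profile = report$config$profile,
                   iqr = as.list(round(report$iqr, 10)),
                   warnings = report$warnings)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, file.path(dir, "manifest.json")))
}

# round-trip-stable numeric formatting for byte-identical TSV output
format_numeric <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.12g", df[[j]])
  df
}
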