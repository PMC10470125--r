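#!/usr/bin/env Rscript
# Stage 2: QC-ratio batch normalization, winsorization at the pooled
# 1st/99th percentiles, natural log transform, and ln-scale IQRs.

suppressMessages(library(cpmetals))

cohort_dir <- "results/cohort"
out <- "results/preprocessed"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

exposures <- read_exposures(file.path(cohort_dir, "exposures.tsv"))
qc <- read_qc(file.path(cohort_dir, "qc.tsv"))
reasons <- utils::read.delim(file.path(cohort_dir, "missing_reasons.tsv"),
                             stringsAsFactors = FALSE)

diag <- validate_inputs(exposures, qc)
stopifnot(nrow(diag) == 0)

pp <- preprocess(exposures, qc, default_marginals(), reasons)

utils::write.table(pp$data, file.path(out, "adjusted_ln.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE, na = "")
jsonlite::write_json(
  list(iqr = as.list(pp$iqr),
       winsorization_limits = apply(pp$limits, 1, as.list),
       adjust_factors = pp$adjust_factors),
  file.path(out, "preprocess_meta.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
if (!is.null(pp$bounds))
  utils::write.table(pp$bounds, file.path(out, "censoring_bounds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

cat("per-metal ln-scale IQR (OR reporting scale):\n")
print(round(pp$iqr, 3))
cat(sprintf("censored cells with imputation bounds: %d\n",
            if (is.null(pp$bounds)) 0L else nrow(pp$bounds)))
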