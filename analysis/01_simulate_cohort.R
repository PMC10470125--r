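#!/usr/bin/env Rscript
# Stage 1: generate the synthetic nested case-control cohort.
#
# Draws a source population of 100,000 pregnancies with the packaged
# marginal/dependence/covariate defaults, samples 144 cases and 1,082
# controls, applies three-round batch effects with QC replicates, and
# censors below-LOD/LOQ cells plus the external-lab (Mg/Cs) subset.
# Writes the observed exposure table, the QC table and the truth sidecar.

suppressMessages(library(cpmetals))

seed <- 20260924L
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cohort <- simulate_cohort(seed = seed)

write_exposures(cohort$observed, file.path(out, "exposures.tsv"))
write_qc(cohort$qc, file.path(out, "qc.tsv"))
write_truth(cohort, file.path(out, "truth.json"))
utils::write.table(cohort$reasons, file.path(out, "missing_reasons.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

n <- nrow(cohort$observed)
cat(sprintf("cohort: %d subjects (%d cases / %d controls)\n",
            n, sum(cohort$observed$case), n - sum(cohort$observed$case)))
tab <- table(cohort$reasons$variable, cohort$reasons$reason)
cat("missingness by variable and reason:\n")
print(tab)
cat(sprintf("below-limit cells: As %d, Cd %d, Co %d; external-lab subset %d\n",
            sum(cohort$reasons$variable == "as"),
            sum(cohort$reasons$variable == "cd"),
            sum(cohort$reasons$variable == "co"),
            sum(cohort$observed$lund)))
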