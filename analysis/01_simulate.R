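#!/usr/bin/env Rscript
# Simulate the synthetic study cohorts and export them in the interchange
# formats (WFDB pairs under scratch/, lab table + one example CSV record
# under results/). Later stages regenerate cohorts from the same seeds, so
# this script's outputs are for inspection, not a dependency.

library(ecgkalemia)
dir.create("results", showWarnings = FALSE)
dir.create("scratch/cohort_wfdb", showWarnings = FALSE, recursive = TRUE)

seed <- 1L
cfg <- cohort_config(n_subjects = 4, records_per_class = 2, duration_s = 30,
                     seed = seed)
cohort <- generate_cohort(cfg)
records <- cohort_records(cohort)
cat(sprintf("simulated %d records from %d subjects (%g s @ %g Hz)\n",
            length(records), cfg$n_subjects, cfg$duration_s, cfg$fs))

for (r in records) write_waveform(r, "scratch/cohort_wfdb", "wfdb")
write_waveform(records[[1]], "scratch/cohort_wfdb", "csv")
write_labs(records, "results/labs.csv")

k <- vapply(records, `[[`, numeric(1), "potassium")
cat(sprintf("potassium: normo %.2f (SD %.2f), hyper %.2f (SD %.2f) mEq/L\n",
            mean(k[label_potassium(k) == "normo"]), sd(k[label_potassium(k) == "normo"]),
            mean(k[label_potassium(k) == "hyper"]), sd(k[label_potassium(k) == "hyper"])))
cat("wrote results/labs.csv; waveforms (WFDB + example CSV) under scratch/cohort_wfdb/\n")
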