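#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic study.
#
# Builds the toy atlas (12 regions in 11 macro-region groups on a 32x32x8
# grid), a balanced four-dose design (vehicle, 0.03, 0.3, 3.0 mg/kg; 4
# subjects per group, half female), one phMRI session per subject (250
# acquisitions, TR 6 s, dose-scaled planted activation) and one
# resting-state run per subject (200 timepoints, planted communities and a
# planted hub). Volumes go to scratch/dataset (regenerable binaries);
# ground truth travels in JSON sidecars.

suppressPackageStartupMessages(library(phmri))

out_dir <- "scratch/dataset"
cfg <- sim_config(seed = 42, n_subjects_per_group = 4)

cat("Simulating the study into", out_dir, "...\n")
manifest <- simulate_study(cfg, out_dir)
cat(sprintf("Wrote %d subjects (%d dose groups x %d).\n",
            nrow(manifest), length(cfg$dose_amplitudes),
            cfg$n_subjects_per_group))

design <- read_design(file.path(out_dir, "design.tsv"))
print(table(dose = design$dose_mg_per_kg, sex = design$sex))

dir.create("results", showWarnings = FALSE)
utils::write.table(data.frame(parameter = names(unlist(cfg)),
                              value = unlist(lapply(unlist(cfg), format))),
                   "results/simulation_config.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
cat("Planted conditions: amplitudes",
    paste(sprintf("%s%%", cfg$dose_amplitudes), collapse = "/"),
    "with responsive extents",
    paste(cfg$dose_extent, collapse = "/"),
    "for doses", paste(names(cfg$dose_amplitudes), collapse = "/"), "mg/kg\n")
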