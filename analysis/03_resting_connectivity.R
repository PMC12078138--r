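#!/usr/bin/env Rscript
# Stage 3 — resting-state functional connectivity.
#
# Per subject: band-pass 0.01-0.1 Hz, detrend, then the region-to-region
# Pearson matrix and its Fisher z transform. Per dose group: the one-group
# Z matrix across subjects, the |Z| >= 2.3 adjacency, and the edge list.

suppressPackageStartupMessages(library(phmri))

in_dir <- "scratch/dataset"
if (!dir.exists(in_dir)) stop("run analysis/01_simulate.R first")
dir.create("results", showWarnings = FALSE)

atl <- read_atlas(file.path(in_dir, "atlas_labels.nii.gz"),
                  file.path(in_dir, "atlas_regions.tsv"))
design <- read_design(file.path(in_dir, "design.tsv"))
pcfg <- pipeline_config()

read_rs <- function(s) {
  m <- as.matrix(utils::read.table(file.path(in_dir, paste0(s, "_rs.tsv")),
                                   sep = "\t", row.names = 1))
  structure(m, region_ids = as.integer(rownames(m)), tr_seconds = 1,
            class = "region_ts")
}

doses <- sort(unique(design$dose_mg_per_kg))
groups <- list()
for (d in doses) {
  subs <- design$subject_id[design$dose_mg_per_kg == d]
  conns <- lapply(subs, function(s) run_rsfc_subject(read_rs(s), pcfg))
  gz <- run_rsfc_group(conns, atl, pcfg)
  groups[[format(d, trim = TRUE)]] <- gz
  key <- format(d, trim = TRUE)
  write_matrix(round(gz$group_z$Z, 4),
               sprintf("results/group_z_dose_%s.tsv", key))
  utils::write.table(adjacency_edge_list(gz$adjacency, abs(gz$group_z$Z)),
                     sprintf("results/edges_dose_%s.tsv", key),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  cat(sprintf("dose %-5s: %3d suprathreshold edges (density %.3f), %d profile clusters\n",
              key, sum(gz$adjacency) / 2, gz$metrics$density,
              length(unique(stats::na.omit(gz$clusters)))))
}
saveRDS(groups, "scratch/rsfc_groups.rds")  # handoff to stage 4 (binary, regenerable)
cat("Stage 3 matrices and edge lists written under results/\n")
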