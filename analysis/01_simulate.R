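#!/usr/bin/env Rscript

# Stage 1 — simulate the synthetic cohort.
#
# Builds the study-shaped cohort (17 ROIs of 700 x 700 um, 5 control "IgG"
# vs 12 treated "ICI", ~77,700 cells expected, 32 markers, 8 phenotypes)
# with the treated arm differing in immune abundance and in a planted
# attraction of Kupffer cells and macrophages towards apoptotic (cC3+)
# hepatocytes. Writes the cell table and the config under results/cohort/.
#
#   Rscript analysis/01_simulate.R [seed]

suppressMessages(library(spatpdr))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L

out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- default_sim_config(seed = seed)
sim <- simulate_cohort(cfg, seed = seed)

write_cell_table(sim$cells, file.path(out, "cells.csv"))
write_sim_config(cfg, file.path(out, "config.yaml"))

cat(sprintf("cohort: %d cells in %d ROIs (%s)\n", nrow(sim$cells),
            length(unique(sim$cells$roi_id)),
            paste(sprintf("%s: %d", names(table(sim$cells$condition)),
                          table(sim$cells$condition)), collapse = ", ")))
cat(sprintf("phenotypes: %s\n",
            paste(names(sort(table(sim$cells$true_phenotype),
                             decreasing = TRUE)), collapse = ", ")))
cat("wrote", file.path(out, "cells.csv"), "\n")
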