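#!/usr/bin/env Rscript

# Stage 3 — spatial interaction analysis on the treated arm.
#
# Takes the labelled cells from stage 2, finds each cell's 50 nearest
# neighbours within its ROI, averages neighbour distances per phenotype,
# pools them over the 12 treated (ICI) ROIs into the mean-distance matrix,
# and ranks it into the symmetric pairwise distance rank (PDR). Writes the
# D and PDR matrices with figures, the feature-map layout, and per-phenotype
# neighbour-distance summaries with Welch's ANOVA under results/spatial/.
#
#   Rscript analysis/03_spatial.R [seed]

suppressMessages(library(spatpdr))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L

out <- "results/spatial"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- read_sim_config("results/cohort/config.yaml")
cells <- read_cell_table("results/phenotype/cells_labeled.csv", cfg$panel)
labs <- as.character(cells$phenotype)

nb <- spatial_knn(cells, K = 50)
prof <- phenotype_profiles(nb, labs)
ici <- unique(cells$roi_id[cells$condition == "ICI"])
dd <- mean_distance_matrix(prof, labs, rois = ici, roi_id = cells$roi_id)
write.csv(dd$D, file.path(out, "mean_distance_um.csv"))
write.csv(dd$n, file.path(out, "mean_distance_n.csv"))

pm <- pdr(dd$D)
write.csv(pm, file.path(out, "pdr.csv"))
plot_pdr_heatmap(pm, file.path(out, "pdr_heatmap.png"))

closest <- which(pm == min(pm, na.rm = TRUE), arr.ind = TRUE)
cat(sprintf("closest interacting pair (PDR = %.3f): %s - %s\n",
            min(pm, na.rm = TRUE), rownames(pm)[closest[1, 1]],
            colnames(pm)[closest[1, 2]]))

freq <- table(labs[cells$condition == "ICI"])
fmap <- pdr_feature_map(pm, freq, seed = derive_seed(seed, 3L))
write.csv(fmap$nodes, file.path(out, "feature_map_nodes.csv"), row.names = FALSE)
write.csv(fmap$edges, file.path(out, "feature_map_edges.csv"), row.names = FALSE)
plot_feature_map(fmap, file.path(out, "feature_map.png"))

welch <- list(); per_roi <- list()
for (ph in rownames(pm)) {
  res <- tryCatch(neighbor_distance_summary(prof, labs, cells$roi_id, ph,
                                            rois = ici),
                  error = function(e) NULL)
  if (is.null(res)) next
  welch[[ph]] <- data.frame(phenotype = ph, res$welch)
  per_roi[[ph]] <- data.frame(phenotype = ph, res$per_roi)
}
welch <- do.call(rbind, welch)
write.csv(welch, file.path(out, "neighbor_welch.csv"), row.names = FALSE)
write.csv(do.call(rbind, per_roi), file.path(out, "neighbor_per_roi.csv"),
          row.names = FALSE)
cat("Welch's ANOVA across neighbour phenotypes, per source phenotype:\n")
print(welch[order(welch$p), ], row.names = FALSE)
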