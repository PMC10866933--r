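#' Run the full analysis pipeline on a synthetic or supplied cohort
#'
#' Orchestrates the stages end-to-end and writes every artifact under one
#' run directory: simulate (or ingest) the cohort, transform and cluster
#' the cells, compute per-ROI abundances with condition t-tests, compute
#' the spatial neighbourhood statistics (K nearest neighbours, mean
#' distance matrix, PDR, feature map, per-phenotype neighbour summaries
#' with Welch's ANOVA), render interaction zones, and emit figures plus a
#' machine-readable JSON run report. The analysis condition (default the
#' treated arm) selects the ROIs pooled for the distance ranking. A single
#' seed drives every stochastic stage through [derive_seed()], so a rerun
#' with the same config and seed reproduces identical numeric artifacts.
#'
#' @param config a [sim_config()] describing the cohort to simulate, or
#'   `NULL` when `cells` is supplied.
#' @param out_dir run directory (created if needed).
#' @param seed master seed.
#' @param cells optional pre-existing cell table (skips simulation).
#' @param labels optional phenotype labels; when `NULL` the clustering
#'   stage assigns them.
#' @param k_graph phenotype-graph neighbour count.
#' @param K_spatial spatial neighbourhood size.
#' @param tau interaction-zone decay length, um.
#' @param condition condition whose ROIs enter the spatial analysis.
#' @param control_condition condition compared against in abundance tests.
#' @param ref_phenotypes three labels for the RGB zones; default picks the
#'   three most attraction-involved phenotypes of the config, or the three
#'   most abundant.
#' @param restarts Louvain restarts.
#' @return the run report, invisibly (list; also written as JSON).
#' @export
run_pipeline <- function(config = default_sim_config(), out_dir,
                         seed = 1L, cells = NULL, labels = NULL,
                         k_graph = 30, K_spatial = 50, tau = 25,
                         condition = NULL, control_condition = NULL,
                         ref_phenotypes = NULL, restarts = 10L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  add <- function(p) {
    artifacts[[length(artifacts) + 1L]] <<- p
    p
  }

  # ---- stage 1: cohort -------------------------------------------------
  if (is.null(cells)) {
    sim <- simulate_cohort(config, seed = seed)
    cells <- sim$cells
    write_cell_table(cells, add(file.path(out_dir, "cells.csv")))
    write_sim_config(config, add(file.path(out_dir, "config.yaml")))
  } else {
    cells <- data.table::as.data.table(cells)
  }
  panel <- if (!is.null(config)) config$panel else {
    default_marker_panel(sum(grepl("^marker_", names(cells))))
  }
  conds <- unique(cells$condition)
  condition <- condition %||% (if ("ICI" %in% conds) "ICI" else conds[length(conds)])
  control_condition <- control_condition %||% setdiff(conds, condition)[1]

  # ---- stage 2: phenotyping -------------------------------------------
  if (is.null(labels)) {
    assign_ <- cluster_phenotypes(cells, panel, k = k_graph,
                                  seed = derive_seed(seed, 2L),
                                  restarts = restarts)
    labels <- assign_$labels
    sig <- assign_$signatures
    n_clusters <- assign_$n_clusters
    modularity <- assign_$modularity
  } else {
    expr <- transform_markers(cells, panel)
    sig <- cluster_signatures(expr, labels)
    n_clusters <- length(unique(labels))
    modularity <- NA_real_
  }
  labs_chr <- as.character(labels)
  lab_tab <- data.table::copy(cells)
  lab_tab$phenotype <- labs_chr
  write_cell_table(lab_tab, add(file.path(out_dir, "cells_labeled.csv")))
  utils::write.csv(sig, add(file.path(out_dir, "signatures.csv")))
  plot_signature_heatmap(sig, add(file.path(out_dir, "signatures_heatmap.png")))

  ab <- abundance_matrix(cells, labs_chr)
  ab_out <- data.frame(roi_id = rownames(ab),
                       condition = attr(ab, "condition"), ab,
                       check.names = FALSE)
  utils::write.csv(ab_out, add(file.path(out_dir, "abundance.csv")),
                   row.names = FALSE)
  ab_test <- NULL
  if (!is.na(control_condition) &&
      sum(attr(ab, "condition") == condition) >= 2 &&
      sum(attr(ab, "condition") == control_condition) >= 2) {
    ab_test <- compare_abundance(ab, condition, control_condition)
    utils::write.csv(ab_test, add(file.path(out_dir, "abundance_ttests.csv")),
                     row.names = FALSE)
  }

  # ---- stage 3: spatial interaction -----------------------------------
  nb <- spatial_knn(cells, K = K_spatial)
  prof <- phenotype_profiles(nb, labs_chr)
  sel_rois <- unique(cells$roi_id[cells$condition == condition])
  dd <- mean_distance_matrix(prof, labs_chr, rois = sel_rois,
                             roi_id = cells$roi_id)
  utils::write.csv(dd$D, add(file.path(out_dir, "mean_distance_um.csv")))
  utils::write.csv(dd$n, add(file.path(out_dir, "mean_distance_n.csv")))
  pdr_mat <- pdr(dd$D)
  utils::write.csv(pdr_mat, add(file.path(out_dir, "pdr.csv")))
  plot_pdr_heatmap(pdr_mat, add(file.path(out_dir, "pdr_heatmap.png")))

  freq <- table(labs_chr[cells$condition == condition])
  fmap <- pdr_feature_map(pdr_mat, freq, seed = derive_seed(seed, 3L))
  utils::write.csv(fmap$nodes, add(file.path(out_dir, "feature_map_nodes.csv")),
                   row.names = FALSE)
  utils::write.csv(fmap$edges, add(file.path(out_dir, "feature_map_edges.csv")),
                   row.names = FALSE)
  plot_feature_map(fmap, add(file.path(out_dir, "feature_map.png")))

  # per-phenotype neighbour summaries + Welch, over the analysis ROIs
  welch_rows <- list()
  per_roi_rows <- list()
  for (ph in rownames(pdr_mat)) {
    res <- tryCatch(
      neighbor_distance_summary(prof, labs_chr, cells$roi_id, ph,
                                rois = sel_rois),
      error = function(e) NULL)
    if (is.null(res)) next
    welch_rows[[ph]] <- data.frame(phenotype = ph, res$welch)
    per_roi_rows[[ph]] <- data.frame(phenotype = ph, res$per_roi)
  }
  if (length(welch_rows)) {
    utils::write.csv(do.call(rbind, welch_rows),
                     add(file.path(out_dir, "neighbor_welch.csv")),
                     row.names = FALSE)
    utils::write.csv(do.call(rbind, per_roi_rows),
                     add(file.path(out_dir, "neighbor_per_roi.csv")),
                     row.names = FALSE)
  }

  # ---- stage 4: interaction zones -------------------------------------
  if (is.null(ref_phenotypes)) {
    cnt <- sort(table(labs_chr), decreasing = TRUE)
    ref_phenotypes <- utils::head(names(cnt), 3)
  }
  zone_out <- NULL
  if (length(unique(labs_chr)) >= 3) {
    roi1 <- sel_rois[1]
    in_roi <- cells$roi_id == roi1
    zones <- suppressWarnings(
      interaction_zones(cells[in_roi, ], labs_chr[in_roi],
                        ref_phenotypes, tau = tau))
    utils::write.csv(zones, add(file.path(out_dir, "zones_rgb.csv")),
                     row.names = FALSE)
    plot_zone_image(zones, cells[in_roi, ],
                    add(file.path(out_dir, "zones.png")))
    zone_out <- roi1
  }

  # ---- stage 5: report -------------------------------------------------
  report <- emit_report(
    out_dir = out_dir, artifacts = artifacts, seed = seed,
    cells = cells, n_clusters = n_clusters, modularity = modularity,
    condition = condition, params = list(k_graph = k_graph,
                                         K_spatial = K_spatial, tau = tau,
                                         restarts = restarts,
                                         ref_phenotypes = ref_phenotypes,
                                         zone_roi = zone_out))
  invisible(report)
}

#' Emit the machine-readable run report
#'
#' Collects config, seeds, cluster and cell counts and the paths of every
#' artifact written by the run into a versioned JSON report. Fails if a
#' listed artifact is missing on disk, naming it.
#'
#' @param out_dir run directory.
#' @param artifacts character vector of emitted file paths.
#' @param seed master seed of the run.
#' @param cells the cohort cell table.
#' @param n_clusters number of phenotype clusters.
#' @param modularity final graph modularity (NA when labels were supplied).
#' @param condition analysis condition.
#' @param params list of stage parameters.
#' @return the report list, invisibly; written to `report.json`.
#' @export
emit_report <- function(out_dir, artifacts, seed, cells, n_clusters,
                        modularity, condition, params) {
  missing <- artifacts[!file.exists(unlist(artifacts))]
  if (length(missing)) {
    stop_fmt("missing stage output(s): %s", paste(missing, collapse = ", "))
  }
  per_roi <- table(cells$roi_id)
  per_cond <- table(cells$condition)
  report <- list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("spatpdr")),
    seed = seed,
    analysis_condition = condition,
    n_cells = nrow(cells),
    n_rois = length(per_roi),
    cells_per_roi = as.list(per_roi),
    cells_per_condition = as.list(per_cond),
    n_clusters = n_clusters,
    modularity = modularity,
    params = params,
    artifacts = as.list(basename(unlist(artifacts)))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
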