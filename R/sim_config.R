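#' Phenotype specification for the tissue simulator
#'
#' Describes one planted phenotype: its expected fraction of cells, its
#' marker signature (per-marker mean and standard deviation of intensity, in
#' arbitrary ion-count-like units), and its mean cell area.
#'
#' @param name phenotype label.
#' @param proportion expected fraction of cells, in `[0, 1]`.
#' @param signature_mean numeric vector of per-marker mean intensities
#'   (length = panel size).
#' @param signature_sd numeric vector of per-marker intensity standard
#'   deviations (non-negative, recycled if length 1).
#' @param mean_cell_area mean cell area in square micrometres.
#' @return a `phenotype_spec` list.
#' @export
phenotype_spec <- function(name, proportion, signature_mean, signature_sd,
                           mean_cell_area = 100) {
  if (proportion < 0 || proportion > 1) stop_fmt("proportion must be in [0, 1]")
  signature_sd <- rep_len(signature_sd, length(signature_mean))
  if (any(signature_sd < 0)) stop_fmt("signature_sd must be non-negative")
  if (mean_cell_area <= 0) stop_fmt("mean_cell_area must be positive")
  structure(list(name = as.character(name), proportion = proportion,
                 signature_mean = as.numeric(signature_mean),
                 signature_sd = as.numeric(signature_sd),
                 mean_cell_area = mean_cell_area),
            class = "phenotype_spec")
}

#' Spatial attraction specification
#'
#' Plants an attraction between two phenotypes: a declared fraction of
#' offspring-phenotype cells is placed uniformly within `radius` of a
#' uniformly chosen parent-phenotype cell (a Matern-style cluster process),
#' instead of by complete spatial randomness. Optionally restricted to one
#' condition, so treated and control tissue can differ in spatial structure
#' alone.
#'
#' @param parent parent phenotype label.
#' @param offspring offspring phenotype label.
#' @param radius attraction radius, micrometres (> 0).
#' @param fraction fraction of offspring cells attracted, in `[0, 1]`.
#' @param condition condition label the attraction applies to, or `NULL` for
#'   all conditions.
#' @return an `attraction_spec` list.
#' @export
attraction_spec <- function(parent, offspring, radius, fraction,
                            condition = NULL) {
  if (radius <= 0) stop_fmt("attraction radius must be positive")
  if (fraction < 0 || fraction > 1) stop_fmt("fraction must be in [0, 1]")
  structure(list(parent = as.character(parent),
                 offspring = as.character(offspring),
                 radius = radius, fraction = fraction,
                 condition = condition),
            class = "attraction_spec")
}

#' Simulation configuration for a synthetic IMC cohort
#'
#' Defines the cohort geometry (ROI rectangle, ROIs per condition), expected
#' cells per ROI, the planted phenotypes with their signatures, any planted
#' spatial attractions, and per-condition abundance shifts. The seed fully
#' determines the simulated cohort.
#'
#' @param phenotypes list of [phenotype_spec()]; proportions must sum to 1.
#' @param roi_width,roi_height ROI dimensions, micrometres.
#' @param n_rois named integer vector: ROIs per condition label.
#' @param cells_per_roi expected cell count per ROI (before abundance
#'   shifts); the realised count is Poisson.
#' @param attraction list of [attraction_spec()].
#' @param abundance_shift named list: per condition, a named numeric vector
#'   of multiplicative abundance factors per phenotype (missing phenotypes
#'   default to 1). Conditions absent from the list use factor 1 throughout.
#' @param panel a [marker_panel()]; defaults to 32 phenotyping markers.
#' @param seed default master seed for the simulator.
#' @return a `sim_config` list.
#' @export
sim_config <- function(phenotypes,
                       roi_width = 700, roi_height = 700,
                       n_rois = c(IgG = 5L, ICI = 12L),
                       cells_per_roi = 4570,
                       attraction = list(),
                       abundance_shift = list(),
                       panel = NULL,
                       seed = 1L) {
  if (roi_width <= 0 || roi_height <= 0) stop_fmt("ROI dimensions must be positive")
  if (cells_per_roi <= 0) stop_fmt("cells_per_roi must be positive")
  if (is.null(names(n_rois)) || any(!nzchar(names(n_rois)))) {
    stop_fmt("n_rois must be a named vector of conditions")
  }
  if (inherits(phenotypes, "phenotype_spec")) phenotypes <- list(phenotypes)
  props <- vapply(phenotypes, function(p) p$proportion, numeric(1))
  if (abs(sum(props) - 1) > 1e-9) {
    stop_fmt("phenotype proportions sum to %.6f, not 1", sum(props))
  }
  pnames <- vapply(phenotypes, function(p) p$name, character(1))
  if (anyDuplicated(pnames)) stop_fmt("phenotype names must be unique")
  nmark <- unique(vapply(phenotypes, function(p) length(p$signature_mean),
                         integer(1)))
  if (length(nmark) != 1) stop_fmt("all signatures must have equal length")
  if (is.null(panel)) panel <- default_marker_panel(nmark)
  if (nrow(panel) != nmark) {
    stop_fmt("panel has %d markers but signatures have %d", nrow(panel), nmark)
  }
  if (inherits(attraction, "attraction_spec")) attraction <- list(attraction)
  for (a in attraction) {
    if (!(a$parent %in% pnames)) stop_fmt("unknown parent phenotype '%s'", a$parent)
    if (!(a$offspring %in% pnames)) stop_fmt("unknown offspring phenotype '%s'", a$offspring)
    if (!is.null(a$condition) && !(a$condition %in% names(n_rois))) {
      stop_fmt("attraction condition '%s' not among conditions", a$condition)
    }
  }
  for (cn in names(abundance_shift)) {
    if (!(cn %in% names(n_rois))) stop_fmt("abundance_shift condition '%s' unknown", cn)
    bad <- setdiff(names(abundance_shift[[cn]]), pnames)
    if (length(bad)) stop_fmt("abundance_shift names unknown: %s",
                              paste(bad, collapse = ", "))
  }
  structure(list(roi_width = roi_width, roi_height = roi_height,
                 n_rois = n_rois, cells_per_roi = cells_per_roi,
                 phenotypes = phenotypes, attraction = attraction,
                 abundance_shift = abundance_shift, panel = panel,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default study-shaped simulation configuration
#'
#' A cohort emulating the shape of a two-arm liver IMC study: 17 ROIs of
#' 700 x 700 micrometres (5 control "IgG", 12 treated "ICI"), roughly 4,570
#' cells per ROI (so the cohort totals about 78,000 cells), 32 markers, and
#' eight phenotypes dominated by hepatocytes with a small apoptotic
#' (cC3-positive) hepatocyte cluster and several immune populations. The
#' treated arm carries more lymphocytes and myeloid cells and a planted
#' attraction of Kupffer cells and macrophages towards apoptotic
#' hepatocytes, so treated tissue differs from control in both abundance and
#' spatial structure while phenotype signatures stay identical.
#'
#' Each phenotype's signature elevates a dedicated block of four markers by
#' `sep` standard deviations above the baseline intensity, giving cleanly
#' separable (but noisy) expression profiles.
#'
#' @param cells_per_roi expected cells per control ROI. The default is set
#'   so that, with the treated-arm abundance shifts applied, the expected
#'   cohort total is about 77,700 cells over the 17 ROIs — a per-ROI mean
#'   of roughly 4,570 cells.
#' @param sep signature separation between elevated and baseline markers, in
#'   units of the intensity standard deviation.
#' @param seed master seed stored in the config.
#' @return a [sim_config()].
#' @export
default_sim_config <- function(cells_per_roi = 4287, sep = 4, seed = 1L) {
  panel <- default_marker_panel(32L)
  base_mean <- 2
  sdv <- 0.6
  names <- c("Hepatocyte", "Hep_cC3", "LSEC", "Kupffer",
             "Macrophage", "CD4_T", "CD8_T", "Neutrophil")
  props <- c(0.55, 0.02, 0.11, 0.08, 0.06, 0.06, 0.07, 0.05)
  areas <- c(220, 200, 90, 110, 110, 70, 70, 70)
  phenos <- lapply(seq_along(names), function(p) {
    mu <- rep(base_mean, 32)
    mu[((p - 1) * 4 + 1):(p * 4)] <- base_mean + sep * sdv
    phenotype_spec(names[p], props[p], mu, sdv, mean_cell_area = areas[p])
  })
  sim_config(
    phenotypes = phenos,
    panel = panel,
    cells_per_roi = cells_per_roi,
    attraction = list(
      attraction_spec("Hep_cC3", "Kupffer", radius = 25, fraction = 0.5,
                      condition = "ICI"),
      attraction_spec("Hep_cC3", "Macrophage", radius = 25, fraction = 0.5,
                      condition = "ICI")
    ),
    abundance_shift = list(
      ICI = c(Hep_cC3 = 2.5, CD4_T = 1.6, CD8_T = 1.7, Macrophage = 1.5,
              Kupffer = 1.2, Neutrophil = 1.3, Hepatocyte = 0.85)
    ),
    seed = seed
  )
}

#' Per-phenotype expected cell counts for one condition
#' @keywords internal
expected_counts <- function(config, condition) {
  pnames <- vapply(config$phenotypes, function(p) p$name, character(1))
  props <- vapply(config$phenotypes, function(p) p$proportion, numeric(1))
  shift <- rep(1, length(pnames))
  names(shift) <- pnames
  sh <- config$abundance_shift[[condition]]
  if (!is.null(sh)) shift[names(sh)] <- sh
  config$cells_per_roi * props * shift
}

#' Read / write a simulation configuration as YAML
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `read_sim_config` returns a [sim_config()]; the writer returns
#'   `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  y <- list(
    roi_width = config$roi_width, roi_height = config$roi_height,
    n_rois = as.list(config$n_rois),
    cells_per_roi = config$cells_per_roi,
    seed = config$seed,
    markers = as.list(stats::setNames(config$panel$role, config$panel$marker)),
    phenotypes = lapply(config$phenotypes, function(p) {
      list(name = p$name, proportion = p$proportion,
           signature_mean = p$signature_mean, signature_sd = p$signature_sd,
           mean_cell_area = p$mean_cell_area)
    }),
    attraction = lapply(config$attraction, function(a) {
      list(parent = a$parent, offspring = a$offspring, radius = a$radius,
           fraction = a$fraction, condition = a$condition)
    }),
    abundance_shift = lapply(config$abundance_shift, as.list)
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  panel <- marker_panel(names(y$markers), unlist(y$markers, use.names = FALSE))
  phenos <- lapply(y$phenotypes, function(p) {
    phenotype_spec(p$name, p$proportion, unlist(p$signature_mean),
                   unlist(p$signature_sd), p$mean_cell_area)
  })
  attr_ <- lapply(y$attraction, function(a) {
    attraction_spec(a$parent, a$offspring, a$radius, a$fraction, a$condition)
  })
  shifts <- lapply(y$abundance_shift, function(s) unlist(s))
  sim_config(phenotypes = phenos,
             roi_width = y$roi_width, roi_height = y$roi_height,
             n_rois = unlist(y$n_rois), cells_per_roi = y$cells_per_roi,
             attraction = attr_, abundance_shift = shifts,
             panel = panel, seed = y$seed %||% 1L)
}
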