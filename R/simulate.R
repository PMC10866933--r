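#' Simulate one synthetic ROI
#'
#' Places cells of each planted phenotype in the ROI rectangle. Cells not
#' covered by an attraction are positioned by complete spatial randomness
#' (CSR); for each [attraction_spec()] active in this condition, the declared
#' fraction of offspring-phenotype cells is instead placed uniformly within
#' the declared radius of a uniformly chosen parent cell, with rejection
#' sampling against the ROI bounds (up to 100 attempts, then the offspring
#' falls back to its parent's position, preserving the declared radius).
#' Per-phenotype counts are Poisson around the condition-adjusted
#' expectation. Marker intensities are drawn per cell from a
#' truncated-at-zero normal with the phenotype's signature. Identical
#' `(config, condition, roi_index, seed)` reproduce identical output.
#'
#' @param config a [sim_config()].
#' @param condition condition label (must be declared in `config$n_rois`).
#' @param roi_index 1-based ROI number within the condition.
#' @param seed master seed; defaults to `config$seed`. The ROI's own stream
#'   is derived via [derive_seed()].
#' @return a list with `cells` (a `data.table` cell table: `cell_id`,
#'   `roi_id`, `condition`, `x_um`, `y_um`, `area_um2`, one column per
#'   marker, `true_phenotype`, `parent_id`) and `ground_truth` (true labels,
#'   parent linkage and the config used).
#' @export
simulate_roi <- function(config, condition, roi_index, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!(condition %in% names(config$n_rois))) {
    stop_fmt("unknown condition '%s'", condition)
  }
  cond_idx <- match(condition, names(config$n_rois))
  lambda <- expected_counts(config, condition)
  pnames <- names(lambda)

  # attraction pairs active here; reject configs with no expected parents
  active <- Filter(function(a) is.null(a$condition) || a$condition == condition,
                   config$attraction)
  for (a in active) {
    if (lambda[a$parent] <= 0) {
      stop_fmt("attraction (%s -> %s): zero expected parent cells",
               a$parent, a$offspring)
    }
  }

  roi_seed <- derive_seed(seed, stage = 101L + cond_idx, index = roi_index)
  old <- globalenv()$.Random.seed
  set.seed(roi_seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  counts <- stats::rpois(length(lambda), lambda)
  names(counts) <- pnames
  n <- sum(counts)
  w <- config$roi_width
  h <- config$roi_height

  pheno <- rep(pnames, counts)
  x <- stats::runif(n, 0, w)
  y <- stats::runif(n, 0, h)
  parent <- rep(NA_integer_, n)

  # attraction placement overrides CSR for the chosen offspring cells
  offspring_of <- split(seq_along(active),
                        vapply(active, function(a) a$offspring, character(1)))
  for (off_name in names(offspring_of)) {
    offs <- which(pheno == off_name)
    if (!length(offs)) next
    specs <- active[offspring_of[[off_name]]]
    # each spec claims its fraction of the (remaining) offspring cells
    remaining <- offs
    for (a in specs) {
      parents <- which(pheno == a$parent)
      if (!length(parents)) next  # Poisson drew zero parents this ROI
      n_take <- round(a$fraction * length(offs))
      n_take <- min(n_take, length(remaining))
      if (n_take < 1) next
      take <- remaining[seq_len(n_take)]
      remaining <- remaining[-seq_len(n_take)]
      par_pick <- parents[sample.int(length(parents), n_take, replace = TRUE)]
      for (t in seq_len(n_take)) {
        cell <- take[t]
        px <- x[par_pick[t]]
        py <- y[par_pick[t]]
        placed <- FALSE
        for (att in seq_len(100L)) {
          theta <- stats::runif(1, 0, 2 * pi)
          r <- a$radius * sqrt(stats::runif(1))
          cx <- px + r * cos(theta)
          cy <- py + r * sin(theta)
          if (cx >= 0 && cx <= w && cy >= 0 && cy <= h) {
            x[cell] <- cx
            y[cell] <- cy
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          x[cell] <- px
          y[cell] <- py
        }
        parent[cell] <- par_pick[t]
      }
    }
  }

  # areas and intensities
  area <- numeric(n)
  nm <- nrow(config$panel)
  intens <- matrix(0, n, nm)
  for (p in seq_along(config$phenotypes)) {
    ph <- config$phenotypes[[p]]
    rows <- which(pheno == ph$name)
    if (!length(rows)) next
    area[rows] <- pmax(stats::rnorm(length(rows), ph$mean_cell_area,
                                    0.15 * ph$mean_cell_area), 10)
    for (m in seq_len(nm)) {
      intens[rows, m] <- rtrunc0(length(rows), ph$signature_mean[m],
                                 ph$signature_sd[m])
    }
  }
  colnames(intens) <- config$panel$marker

  roi_id <- sprintf("%s_%02d", condition, roi_index)
  cells <- data.table::data.table(
    cell_id = seq_len(n), roi_id = roi_id, condition = condition,
    x_um = x, y_um = y, area_um2 = area)
  cells <- cbind(cells, data.table::as.data.table(intens))
  cells$true_phenotype <- pheno
  cells$parent_id <- parent

  list(cells = cells,
       ground_truth = list(roi_id = roi_id, true_phenotype = pheno,
                           parent_id = parent, config = config))
}

#' Simulate a full multi-ROI cohort
#'
#' Runs [simulate_roi()] for every condition and ROI declared in the config
#' and binds the results. ROI ids are `<condition>_<index>`.
#'
#' @param config a [sim_config()].
#' @param seed master seed; defaults to `config$seed`.
#' @return a list with `cells` (pooled cell table; `cell_id` unique within
#'   each ROI) and `ground_truth` (per-ROI list plus the config).
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  parts <- list()
  gts <- list()
  for (condition in names(config$n_rois)) {
    for (i in seq_len(config$n_rois[[condition]])) {
      r <- simulate_roi(config, condition, i, seed = seed)
      parts[[length(parts) + 1L]] <- r$cells
      gts[[r$ground_truth$roi_id]] <- r$ground_truth
    }
  }
  cells <- data.table::rbindlist(parts)
  list(cells = cells, ground_truth = list(rois = gts, config = config))
}
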