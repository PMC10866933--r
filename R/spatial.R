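#' K nearest spatial neighbours of every cell, within its ROI
#'
#' Exact Euclidean k-nearest-neighbour search on cell centroids, computed
#' independently per ROI (ROIs are physically separate tissue regions, so
#' no cross-ROI neighbours). The cell itself is excluded; ties are broken
#' by (distance, lower cell index); K is truncated to `n_roi - 1` where a
#' ROI is small. A ROI with a single cell yields an empty neighbour list
#' and a warning.
#'
#' @param cells cell table with `x_um`, `y_um`, `roi_id`.
#' @param K neighbour count; 50 is the default neighbourhood size for the
#'   interaction analysis.
#' @return a `neighbor_set` list: `index` (n x K matrix of 1-based row
#'   indices into `cells`, NA-padded), `distance` (matching distances, um),
#'   `roi_id` per cell, and `K`.
#' @export
spatial_knn <- function(cells, K = 50) {
  if (K < 1) stop_fmt("K must be >= 1")
  cells <- data.table::as.data.table(cells)
  if (!nrow(cells)) stop_fmt("empty cell table")
  if (any(!is.finite(cells$x_um)) || any(!is.finite(cells$y_um))) {
    stop_fmt("non-finite coordinates")
  }
  roi <- as.integer(factor(cells$roi_id))
  sizes <- table(roi)
  if (any(sizes < 2)) {
    warning(sprintf("%d ROI(s) with a single cell: empty neighbour lists",
                    sum(sizes < 2)))
  }
  res <- cpp_knn_groups(cells$x_um, cells$y_um, roi, as.integer(K))
  structure(list(index = res$index, distance = res$distance,
                 roi_id = cells$roi_id, K = as.integer(K)),
            class = "neighbor_set")
}

#' Per-cell mean distance to each phenotype among its neighbours
#'
#' For every cell and every phenotype, the arithmetic mean of the distances
#' to that phenotype's cells within the cell's neighbour set; `NA` where
#' the phenotype does not occur among the neighbours.
#'
#' @param neighbors a `neighbor_set` from [spatial_knn()].
#' @param labels phenotype label per cell (no missing values).
#' @return numeric matrix cells x phenotypes (columns sorted by label).
#' @export
phenotype_profiles <- function(neighbors, labels) {
  if (anyNA(labels)) stop_fmt("unlabelled cells among neighbours")
  labels <- as.character(labels)
  n <- nrow(neighbors$index)
  if (length(labels) != n) stop_fmt("labels do not match neighbour set size")
  phen <- sort(unique(labels))
  idx <- neighbors$index
  dst <- neighbors$distance
  K <- ncol(idx)
  nb_lab <- matrix(NA_integer_, n, K)
  ok <- !is.na(idx)
  nb_lab[ok] <- match(labels[idx[ok]], phen)
  out <- matrix(NA_real_, n, length(phen), dimnames = list(NULL, phen))
  cell_of <- row(idx)
  for (p in seq_along(phen)) {
    sel <- ok & nb_lab == p
    if (!any(sel)) next
    s <- tapply(dst[sel], cell_of[sel], mean)
    out[as.integer(names(s)), p] <- s
  }
  out
}

#' Pooled phenotype-to-phenotype mean neighbour distance matrix
#'
#' `D[A, B]` is the mean, over cells of source phenotype A in the selected
#' ROIs, of their profile entry for target phenotype B (cells whose
#' neighbourhood lacks B are dropped, not imputed). Generally asymmetric.
#' Pairs supported by fewer than `min_n` contributing cells are set to
#' `NA`.
#'
#' @param profiles matrix from [phenotype_profiles()].
#' @param labels phenotype label per cell.
#' @param rois optional character vector of ROI ids to pool over (default:
#'   all); `roi_id` supplies each cell's ROI.
#' @param roi_id ROI id per cell (required when `rois` is given).
#' @param min_n minimal contributing cells per ordered pair.
#' @return list with `D` (phenotypes x phenotypes, um, `NA` diagonal
#'   convention applies downstream) and `n` (contributing cell counts).
#' @export
mean_distance_matrix <- function(profiles, labels, rois = NULL, roi_id = NULL,
                                 min_n = 1L) {
  labels <- as.character(labels)
  keep <- rep(TRUE, length(labels))
  if (!is.null(rois)) {
    if (is.null(roi_id)) stop_fmt("rois given but roi_id missing")
    keep <- roi_id %in% rois
    if (!any(keep)) stop_fmt("ROI selection matches no cells")
  }
  phen <- colnames(profiles)
  src <- sort(unique(labels[keep]))
  D <- matrix(NA_real_, length(src), length(phen), dimnames = list(src, phen))
  N <- matrix(0L, length(src), length(phen), dimnames = list(src, phen))
  for (a in src) {
    rows <- which(keep & labels == a)
    sub <- profiles[rows, , drop = FALSE]
    cnt <- colSums(!is.na(sub))
    mu <- suppressWarnings(colMeans(sub, na.rm = TRUE))
    mu[cnt < min_n] <- NA_real_
    D[a, ] <- mu
    N[a, ] <- cnt
  }
  list(D = D, n = N)
}

#' Symmetric pairwise distance rank (PDR)
#'
#' Ranks all defined ordered off-diagonal entries of the mean-distance
#' matrix (fractional ranks for ties), affinely rescales the ranks to the
#' unit interval (minimum to 0, maximum to 1), and combines the two ordered
#' ranks of each pair by their geometric mean:
#' `PDR[A, B] = sqrt(r(A, B) * r(B, A))`. 0 marks the closest interacting
#' pair and 1 the furthest. The diagonal carries no interaction meaning and
#' is reported `NA`; a pair is `NA` when either ordered entry is
#' undefined. When every defined entry is tied, all ranks collapse to the
#' common midpoint value 0.5.
#'
#' @param D mean-distance matrix (`$D` of [mean_distance_matrix()]), square
#'   on a shared phenotype set.
#' @return symmetric matrix of PDR values in `[0, 1]`.
#' @export
pdr <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D) ||
      !identical(rownames(D), colnames(D))) {
    stop_fmt("D must be square with matching phenotype row/column names")
  }
  P <- nrow(D)
  off <- which(row(D) != col(D) & !is.na(D))
  if (length(off) < 2) stop_fmt("need >= 2 defined off-diagonal entries")
  r <- rank(D[off])  # fractional ranks on ties
  if (max(r) > min(r)) {
    r <- (r - min(r)) / (max(r) - min(r))
  } else {
    r <- rep(0.5, length(r))  # total tie: single common value
  }
  R <- matrix(NA_real_, P, P, dimnames = dimnames(D))
  R[off] <- r
  out <- sqrt(R * t(R))
  diag(out) <- NA_real_
  out
}

#' Feature-map layout of the PDR matrix
#'
#' Embeds the PDR row vectors in 2-D so phenotypes with similar interaction
#' profiles land together. The embedder is pluggable: the default is
#' classical multidimensional scaling of the Euclidean distances between
#' row vectors, which is deterministic and places identical rows at the
#' same point — appropriate for the dozen-or-so phenotypes a feature map
#' carries. UMAP is available for larger matrices (with a fixed seed), but
#' at a handful of points its repulsion term dominates and near-duplicate
#' rows need not land together. With fewer than 3 phenotypes the layout
#' falls back to a deterministic circle and is flagged. Node size is
#' proportional to phenotype frequency, node colour is the row-mean PDR,
#' and edge weight is `1 - PDR` (strong interaction = heavy edge). Missing
#' PDR entries are imputed as 1 (no interaction) for the embedding only,
#' and flagged.
#'
#' @param pdr_mat symmetric PDR matrix.
#' @param frequency named vector of phenotype frequencies (cells or
#'   fractions) matching the PDR rows.
#' @param seed RNG seed for the embedding (used by `"umap"`).
#' @param embedding `"mds"` (default) or `"umap"`.
#' @return list with `nodes` (data.frame `phenotype`, `x`, `y`, `size`,
#'   `mean_pdr`), `edges` (data.frame `a`, `b`, `pdr`, `weight`), and
#'   `flags`.
#' @export
pdr_feature_map <- function(pdr_mat, frequency, seed = 1L,
                            embedding = c("mds", "umap")) {
  embedding <- match.arg(embedding)
  phen <- rownames(pdr_mat)
  frequency <- frequency[phen]
  flags <- character()
  M <- pdr_mat
  if (anyNA(M[row(M) != col(M)])) {
    flags <- c(flags, "missing PDR entries imputed as 1 for embedding")
    M[is.na(M)] <- 1
  }
  diag(M) <- 0
  P <- nrow(M)
  if (P < 3) {
    flags <- c(flags, "fewer than 3 phenotypes: deterministic circular layout")
    ang <- 2 * pi * (seq_len(P) - 1) / max(P, 1)
    xy <- cbind(cos(ang), sin(ang))
  } else if (embedding == "mds") {
    xy <- stats::cmdscale(stats::dist(M), k = 2)
    if (ncol(xy) < 2) xy <- cbind(xy, 0)  # rank-deficient configurations
  } else {
    old <- globalenv()$.Random.seed
    set.seed(derive_seed(seed, stage = 401L))
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    nb <- min(P - 1, 15)
    xy <- uwot::umap(M, n_neighbors = nb, n_threads = 1,
                     n_sgd_threads = 1, init = "spca")
  }
  mean_pdr <- rowMeans(M + diag(NA, P), na.rm = TRUE)
  nodes <- data.frame(phenotype = phen, x = xy[, 1], y = xy[, 2],
                      size = as.numeric(frequency) / sum(frequency),
                      mean_pdr = mean_pdr)
  pr <- which(upper.tri(M), arr.ind = TRUE)
  edges <- data.frame(a = phen[pr[, 1]], b = phen[pr[, 2]],
                      pdr = pdr_mat[pr], weight = 1 - M[pr])
  list(nodes = nodes, edges = edges, flags = flags)
}

#' Per-ROI neighbour distances of one phenotype, with Welch's ANOVA
#'
#' For a chosen source phenotype, computes the mean neighbour distance to
#' every other phenotype separately in each ROI (no pooling), then tests
#' whether the per-ROI means differ across neighbour phenotypes with
#' Welch's heteroscedastic one-way ANOVA (Welch-Satterthwaite degrees of
#' freedom).
#'
#' @param profiles matrix from [phenotype_profiles()].
#' @param labels phenotype label per cell.
#' @param roi_id ROI id per cell.
#' @param source_phenotype the phenotype whose neighbourhood is summarised.
#' @param rois optional ROI subset.
#' @return list with `per_roi` (data.frame `roi_id`, `neighbor_phenotype`,
#'   `mean_distance_um`) and `welch` (data.frame `F`, `df1`, `df2`, `p`).
#' @export
neighbor_distance_summary <- function(profiles, labels, roi_id,
                                      source_phenotype, rois = NULL) {
  labels <- as.character(labels)
  if (is.null(rois)) rois <- sort(unique(roi_id))
  if (length(rois) < 2) stop_fmt("need >= 2 ROIs")
  rows <- which(labels == source_phenotype & roi_id %in% rois)
  if (!length(rows)) stop_fmt("no cells of phenotype '%s'", source_phenotype)
  targets <- setdiff(colnames(profiles), source_phenotype)
  if (length(targets) < 2) stop_fmt("need >= 2 neighbour phenotypes")
  per <- list()
  for (tg in targets) {
    v <- profiles[rows, tg]
    s <- tapply(v, roi_id[rows], function(z) mean(z, na.rm = TRUE))
    per[[tg]] <- data.frame(roi_id = names(s), neighbor_phenotype = tg,
                            mean_distance_um = as.numeric(s))
  }
  per_roi <- do.call(rbind, per)
  rownames(per_roi) <- NULL
  per_roi <- per_roi[is.finite(per_roi$mean_distance_um), ]
  grp_n <- table(per_roi$neighbor_phenotype)
  if (any(grp_n < 2)) {
    stop_fmt("neighbour phenotype(s) with < 2 defined ROI values: %s",
             paste(names(grp_n)[grp_n < 2], collapse = ", "))
  }
  vals <- per_roi$mean_distance_um
  grp <- factor(per_roi$neighbor_phenotype)
  if (stats::sd(vals) == 0 ||
      all(tapply(vals, grp, stats::sd) == 0)) {
    welch <- data.frame(F = 0, df1 = nlevels(grp) - 1, df2 = NA_real_, p = 1)
  } else {
    ow <- stats::oneway.test(vals ~ grp, var.equal = FALSE)
    welch <- data.frame(F = unname(ow$statistic),
                        df1 = unname(ow$parameter[1]),
                        df2 = unname(ow$parameter[2]),
                        p = ow$p.value)
  }
  list(per_roi = per_roi, welch = welch)
}

#' RGB interaction zones
#'
#' Pseudocolours every cell by proximity to three reference phenotypes
#' using one colour channel each: channel `c` of a cell is
#' `exp(-d_c / tau)` where `d_c` is the distance to the nearest cell of
#' reference phenotype `c` within the same ROI (a reference cell's own
#' channel is 1). Cells close to all three references approach white — the
#' three-way interaction zone.
#'
#' @param cells cell table with `x_um`, `y_um`, `roi_id`.
#' @param labels phenotype label per cell.
#' @param ref_phenotypes exactly three labels mapped to (R, G, B).
#' @param tau decay length, micrometres (> 0); default 25, about one to
#'   two cell diameters.
#' @return data.frame with `roi_id`, `x_um`, `y_um`, `phenotype`, `R`,
#'   `G`, `B` in `[0, 1]`.
#' @export
interaction_zones <- function(cells, labels, ref_phenotypes, tau = 25) {
  if (length(ref_phenotypes) != 3) stop_fmt("need exactly 3 reference phenotypes")
  if (tau <= 0) stop_fmt("tau must be positive")
  cells <- data.table::as.data.table(cells)
  labels <- as.character(labels)
  n <- nrow(cells)
  ch <- matrix(0, n, 3)
  for (r in unique(cells$roi_id)) {
    in_roi <- which(cells$roi_id == r)
    for (c3 in 1:3) {
      refs <- in_roi[labels[in_roi] == ref_phenotypes[c3]]
      if (!length(refs)) {
        warning(sprintf("ROI %s: reference phenotype '%s' absent; channel 0",
                        r, ref_phenotypes[c3]))
        next
      }
      dmin <- cpp_min_dist(cells$x_um[in_roi], cells$y_um[in_roi],
                           cells$x_um[refs], cells$y_um[refs])
      is_ref <- labels[in_roi] == ref_phenotypes[c3]
      dmin[is_ref] <- 0
      ch[in_roi, c3] <- exp(-dmin / tau)
    }
  }
  data.frame(roi_id = cells$roi_id, x_um = cells$x_um, y_um = cells$y_um,
             phenotype = labels, R = ch[, 1], G = ch[, 2], B = ch[, 3])
}
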