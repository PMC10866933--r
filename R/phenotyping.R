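#' Variance-stabilising marker transform
#'
#' Applies the cytometry-standard `arcsinh(x / cofactor)` to every
#' phenotyping-marker intensity, then standardises each marker to mean 0 and
#' unit standard deviation over all cells, and finally winsorises at
#' `+/- winsor` standard deviations to blunt hot pixels. Markers constant
#' across all cells map to all-zero columns.
#'
#' @param cells cell table with the panel's marker columns.
#' @param panel a [marker_panel()]; only phenotyping markers are used.
#' @param cofactor arcsinh cofactor (> 0); 5 is the IMC convention.
#' @param winsor clipping point in standard deviations.
#' @return numeric matrix, cells x phenotyping markers.
#' @export
transform_markers <- function(cells, panel, cofactor = 5, winsor = 3) {
  if (cofactor <= 0) stop_fmt("cofactor must be positive")
  markers <- phenotyping_markers(panel)
  if (!length(markers)) stop_fmt("panel has no phenotyping markers")
  cells <- data.table::as.data.table(cells)
  X <- asinh(as.matrix(cells[, markers, with = FALSE]) / cofactor)
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  sd_[sd_ == 0 | is.na(sd_)] <- Inf  # constant markers -> all-zero column
  X <- sweep(sweep(X, 2, mu, "-"), 2, sd_, "/")
  X[X > winsor] <- winsor
  X[X < -winsor] <- -winsor
  X
}

#' Build the PhenoGraph-style k-nearest-neighbour Jaccard graph
#'
#' Finds each cell's `k` nearest neighbours in expression space (exact
#' Euclidean search), takes the union of directed neighbour relations as the
#' undirected edge set, and weights every edge by the Jaccard index of the
#' two cells' augmented neighbour sets (the cell itself plus its `k`
#' neighbours). Zero-weight edges are dropped.
#'
#' @param expr numeric matrix, cells x markers (from [transform_markers()]).
#' @param k neighbour count, `1 <= k < nrow(expr)`.
#' @param exact_threshold below this cell count the brute-force exact search
#'   is used directly; above it, a tree-based exact search
#'   (BiocNeighbors) handles the scale.
#' @return list with `n` (cells) and `edges` (data.frame `i`, `j`,
#'   `weight`, 1-based, `i < j`).
#' @export
build_phenotype_graph <- function(expr, k = 30, exact_threshold = 2000L) {
  n <- nrow(expr)
  if (k < 1 || k >= n) stop_fmt("k must satisfy 1 <= k < n (n = %d)", n)
  if (n <= exact_threshold) {
    nn <- cpp_knn_matrix(expr, as.integer(k))$index
  } else {
    nn <- BiocNeighbors::findKNN(expr, k = k,
                                 BNPARAM = BiocNeighbors::KmknnParam())$index
  }
  src <- rep(seq_len(n), times = ncol(nn))
  dst <- as.vector(nn)
  a <- pmin(src, dst)
  b <- pmax(src, dst)
  ed <- unique(data.table::data.table(i = a, j = b))
  data.table::setorder(ed, i, j)
  w <- cpp_jaccard(nn, ed$i, ed$j)
  keep <- w > 0
  list(n = n, edges = data.frame(i = ed$i[keep], j = ed$j[keep],
                                 weight = w[keep]))
}

#' Louvain community detection with restarts and greedy refinement
#'
#' Maximises weighted Newman-Girvan modularity by the Louvain multilevel
#' heuristic: repeated local-move sweeps (including moves into a fresh
#' singleton community) until no gain above `eps`, then graph aggregation,
#' iterated until stable. Each restart shuffles the node processing order
#' from R's RNG, so `seed` fully determines the result. After the multilevel
#' phase the partition is refined on the original graph by alternating
#' node sweeps with greedy community-pair merges; the best partition over
#' all restarts is returned. Nodes without edges become singleton
#' communities.
#'
#' @param graph list with `n` and `edges` as from
#'   [build_phenotype_graph()].
#' @param seed RNG seed.
#' @param restarts number of independent restarts.
#' @param eps minimal modularity gain counted as an improvement.
#' @param deep_refine_max_n graphs with at most this many nodes additionally
#'   receive Kernighan-Lin chain moves and all-pairs node swaps during
#'   refinement. These passes escape local optima that single-node moves
#'   cannot, but cost O(n^2) per sweep, so they are reserved for small
#'   graphs (where exact modularity optimality matters most).
#' @return integer community labels (1-based, consecutive, in order of
#'   first appearance), with attribute `"modularity"`.
#' @export
louvain_communities <- function(graph, seed = 1L, restarts = 10L,
                                eps = 1e-9, deep_refine_max_n = 200L) {
  if (graph$n == 0) return(integer())
  if (nrow(graph$edges) == 0) {
    lab <- seq_len(graph$n)
    attr(lab, "modularity") <- NA_real_
    return(lab)
  }
  old <- globalenv()$.Random.seed
  set.seed(derive_seed(seed, stage = 301L))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  res <- cpp_louvain(graph$n, graph$edges$i, graph$edges$j,
                     graph$edges$weight, as.integer(restarts), eps,
                     as.integer(deep_refine_max_n))
  lab <- res$membership
  attr(lab, "modularity") <- res$modularity
  lab
}

#' Modularity of a partition of a weighted graph
#' @param graph list with `n` and `edges` (`i`, `j`, `weight`).
#' @param labels integer community labels, one per node.
#' @return weighted Newman-Girvan modularity.
#' @export
graph_modularity <- function(graph, labels) {
  cpp_modularity(graph$n, graph$edges$i, graph$edges$j, graph$edges$weight,
                 as.integer(labels))
}

#' Cluster cells into phenotypes (full PhenoGraph-style chain)
#'
#' Convenience wrapper: [transform_markers()] then
#' [build_phenotype_graph()] then [louvain_communities()], plus cluster
#' signatures. This is the data-driven phenotyping stage; naming clusters
#' biologically is a user-supplied annotation map, not an algorithm.
#'
#' @inheritParams transform_markers
#' @inheritParams build_phenotype_graph
#' @inheritParams louvain_communities
#' @return a `phenotype_assignment` list: `labels` (integer per cell),
#'   `n_clusters`, `signatures` (scaled mean-expression matrix, clusters x
#'   markers), `modularity`, and `params`.
#' @export
cluster_phenotypes <- function(cells, panel, k = 30, cofactor = 5,
                               winsor = 3, seed = 1L, restarts = 10L) {
  expr <- transform_markers(cells, panel, cofactor = cofactor, winsor = winsor)
  graph <- build_phenotype_graph(expr, k = k)
  labels <- louvain_communities(graph, seed = seed, restarts = restarts)
  sig <- cluster_signatures(expr, labels)
  structure(list(labels = as.integer(labels),
                 n_clusters = max(labels),
                 signatures = sig,
                 modularity = attr(labels, "modularity"),
                 params = list(k = k, cofactor = cofactor, winsor = winsor,
                               seed = seed, restarts = restarts)),
            class = "phenotype_assignment")
}

#' Scaled mean-expression signatures per cluster
#'
#' Per cluster, the mean transformed expression of every marker; the matrix
#' is then z-scaled per marker across clusters (the "scaled mean"
#' convention of cluster heatmaps). With a single cluster the scaled matrix
#' is all zeros.
#'
#' @param expr transformed expression matrix (cells x markers).
#' @param labels integer cluster label per cell.
#' @return matrix clusters x markers, z-scaled within each marker column.
#' @export
cluster_signatures <- function(expr, labels) {
  if (length(labels) != nrow(expr)) {
    stop_fmt("labels (%d) do not match expression rows (%d)",
             length(labels), nrow(expr))
  }
  f <- factor(labels)
  means <- apply(expr, 2, function(col) tapply(col, f, mean))
  if (nlevels(f) == 1) means <- matrix(means, nrow = 1,
                                       dimnames = list(levels(f), colnames(expr)))
  ctr <- scale(means)
  ctr[is.nan(ctr)] <- 0  # single cluster or constant marker across clusters
  ctr <- ctr[, , drop = FALSE]
  attr(ctr, "scaled:center") <- NULL
  attr(ctr, "scaled:scale") <- NULL
  rownames(ctr) <- levels(f)
  ctr
}

#' Cells-per-cluster abundance matrix by ROI
#'
#' @param cells cell table with `roi_id` and `condition`.
#' @param labels cluster (or phenotype) label per cell.
#' @return matrix ROIs x clusters of cell counts, with the ROI condition in
#'   attribute `"condition"` (named by ROI).
#' @export
abundance_matrix <- function(cells, labels) {
  cells <- data.table::as.data.table(cells)
  tab <- table(cells$roi_id, labels)
  m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  cond <- vapply(rownames(m), function(r) {
    as.character(cells$condition[match(r, cells$roi_id)])
  }, character(1))
  attr(m, "condition") <- cond
  m
}

#' Per-cluster abundance comparison between two conditions
#'
#' For every cluster, an unpaired two-sample t-test (pooled variance) on
#' cells/ROI between the two conditions; raw p-values are reported together
#' with Holm-adjusted ones.
#'
#' @param ab abundance matrix from [abundance_matrix()].
#' @param condition_a,condition_b condition labels to compare.
#' @return data.frame with `cluster`, group means, `t`, `df`, `p`,
#'   `p_holm`.
#' @export
compare_abundance <- function(ab, condition_a, condition_b) {
  cond <- attr(ab, "condition")
  ra <- which(cond == condition_a)
  rb <- which(cond == condition_b)
  if (length(ra) < 2 || length(rb) < 2) {
    stop_fmt("need >= 2 ROIs per condition (got %d and %d)",
             length(ra), length(rb))
  }
  res <- lapply(colnames(ab), function(cl) {
    a <- ab[ra, cl]
    b <- ab[rb, cl]
    if (stats::sd(c(a, b)) == 0) {
      return(data.frame(cluster = cl, mean_a = mean(a), mean_b = mean(b),
                        t = 0, df = length(a) + length(b) - 2, p = 1))
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    data.frame(cluster = cl, mean_a = mean(a), mean_b = mean(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}
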