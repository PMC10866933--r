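# Marker transform, kNN-Jaccard graph, Louvain, signatures, abundance.

test_that("transform_markers applies arcsinh then standardisation", {
  panel <- default_marker_panel(1)
  cells <- data.frame(marker_01 = c(0, 5 * sinh(1)))
  X <- asinh(as.matrix(cells) / 5)
  expect_equal(unname(X[, 1]), c(0, 1))  # arcsinh inverse fixed point
  tr <- transform_markers(cells, panel, cofactor = 5)
  expect_equal(unname(tr[, 1]), unname(scale(X)[, 1]))
  # all-zero input maps to all-zero output (constant marker convention)
  z <- transform_markers(data.frame(marker_01 = c(0, 0, 0)), panel)
  expect_true(all(z == 0))
})

test_that("transformed columns are standardised before winsorisation", {
  set.seed(2)
  panel <- default_marker_panel(5)
  cells <- as.data.frame(matrix(rexp(500 * 5, 0.2), 500, 5))
  names(cells) <- panel$marker
  tr <- transform_markers(cells, panel, winsor = Inf)
  expect_true(all(abs(colMeans(tr)) < 1e-9))
  expect_true(all(abs(apply(tr, 2, sd) - 1) < 1e-9))
  trw <- transform_markers(cells, panel, winsor = 3)
  expect_true(all(trw >= -3 & trw <= 3))
})

test_that("kNN graph edges and Jaccard weights match a brute-force oracle", {
  # two identical cells, k = 1: one edge of weight 1
  g <- build_phenotype_graph(matrix(c(1, 1, 2, 2), 2, 2, byrow = TRUE)[c(1, 1), ],
                             k = 1)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$weight, 1)

  # 6-point fixture, k = 2, checked against exhaustive set arithmetic
  pts <- matrix(c(0, 0,  1, 0,  0.5, 1,  10, 0,  11, 0,  10.5, 1), 6, 2,
                byrow = TRUE)
  g6 <- build_phenotype_graph(pts, k = 2)
  nn_or <- knn_oracle(pts[, 1], pts[, 2], 2)$index
  sets <- lapply(1:6, function(i) sort(c(i, nn_or[i, ])))
  edges_or <- list()
  for (i in 1:5) for (j in (i + 1):6) {
    if (j %in% nn_or[i, ] || i %in% nn_or[j, ]) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      uni <- length(union(sets[[i]], sets[[j]]))
      if (inter > 0) {
        edges_or[[length(edges_or) + 1]] <-
          data.frame(i = i, j = j, weight = inter / uni)
      }
    }
  }
  edges_or <- do.call(rbind, edges_or)
  got <- g6$edges[order(g6$edges$i, g6$edges$j), ]
  rownames(got) <- NULL
  expect_equal(got, edges_or)

  # two well-separated blobs: no cross-blob edges
  set.seed(4)
  blob <- rbind(matrix(rnorm(200, 0, 0.5), 100, 2),
                matrix(rnorm(200, 50, 0.5), 100, 2))
  gb <- build_phenotype_graph(blob, k = 15)
  cross <- (gb$edges$i <= 100) != (gb$edges$j <= 100)
  expect_equal(sum(cross), 0)
  expect_error(build_phenotype_graph(blob, k = 200), "k must satisfy")
})

test_that("Louvain separates disconnected cliques exactly", {
  cl4 <- t(combn(4, 2))
  edges <- data.frame(i = c(cl4[, 1], cl4[, 1] + 4),
                      j = c(cl4[, 2], cl4[, 2] + 4), weight = 1)
  lab <- louvain_communities(list(n = 8, edges = edges), seed = 1)
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:4])), 1)
  expect_equal(length(unique(lab[5:8])), 1)
  # isolated node becomes its own community
  lab2 <- louvain_communities(list(n = 9, edges = edges), seed = 1)
  expect_equal(sum(lab2 == lab2[9]), 1)
})

test_that("Louvain reaches the exhaustive modularity optimum on small graphs", {
  gs <- louvain_fixture_graphs()
  for (nm in names(gs)) {
    g <- gs[[nm]]
    lab <- louvain_communities(g, seed = 7)
    q <- graph_modularity(g, lab)
    q_or <- modularity_oracle(g$n, g$edges, lab)
    expect_equal(q, q_or, tolerance = 1e-12)  # two modularity routes agree
    best <- best_modularity_oracle(g$n, g$edges)
    expect_gte(q, best - 1e-9)
  }
})

test_that("Louvain is deterministic given a seed and recovers planted partitions", {
  set.seed(99)
  # planted partition: 4 blocks x 50 nodes, p_in 0.4, p_out 0.02
  n <- 200
  block <- rep(1:4, each = 50)
  ii <- c(); jj <- c()
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    p <- if (block[a] == block[b]) 0.4 else 0.02
    if (runif(1) < p) { ii <- c(ii, a); jj <- c(jj, b) }
  }
  g <- list(n = n, edges = data.frame(i = ii, j = jj, weight = 1))
  aris <- vapply(1:10, function(s) {
    ari(louvain_communities(g, seed = s), block)
  }, numeric(1))
  expect_gte(mean(aris >= 0.95), 0.9)
  expect_identical(louvain_communities(g, seed = 3),
                   louvain_communities(g, seed = 3))
})

test_that("modularity never decreases from the singleton partition", {
  gs <- louvain_fixture_graphs()
  for (nm in c("two_triangles", "barbell", "rand_1")) {
    g <- gs[[nm]]
    lab <- louvain_communities(g, seed = 2)
    expect_gte(graph_modularity(g, lab),
               graph_modularity(g, seq_len(g$n)))
  }
})

test_that("cluster signatures are scaled means with the argmax on planted markers", {
  # two clusters with means m and -m: scaled values +/- 1/sqrt(2)
  expr <- rbind(matrix(2, 5, 3), matrix(-2, 5, 3))
  sig <- cluster_signatures(expr, rep(1:2, each = 5))
  expect_equal(unname(sig[1, ]), rep(1 / sqrt(2), 3))
  expect_equal(unname(sig[2, ]), rep(-1 / sqrt(2), 3))
  # one cluster: all zeros
  sig1 <- cluster_signatures(expr, rep(1, 10))
  expect_true(all(sig1 == 0))
  # per-marker mean over clusters is 0
  set.seed(1)
  expr2 <- matrix(rnorm(300), 100, 3)
  sig2 <- cluster_signatures(expr2, sample(1:4, 100, replace = TRUE))
  expect_true(all(abs(colMeans(sig2)) < 1e-9))
  # recovery: argmax marker per cluster matches the planted top marker
  cfg <- blocks_config(n_pheno = 5, cells_per_roi = 800, n_rois = c(ICI = 2L))
  sim <- simulate_cohort(cfg, seed = 21)
  pa <- cluster_phenotypes(sim$cells, cfg$panel, seed = 1)
  hit <- 0
  for (cl in seq_len(pa$n_clusters)) {
    true_ph <- names(which.max(table(
      sim$cells$true_phenotype[pa$labels == cl])))
    p <- as.integer(sub("P", "", true_ph))
    planted_block <- ((p - 1) * 4 + 1):(p * 4)
    if (which.max(pa$signatures[cl, ]) %in% planted_block) hit <- hit + 1
  }
  expect_gte(hit / pa$n_clusters, 0.9)
})

test_that("abundance matrix counts cells and t-tests match the pooled-variance oracle", {
  cfg <- default_sim_config(cells_per_roi = 150)
  sim <- simulate_cohort(cfg, seed = 2)
  ab <- abundance_matrix(sim$cells, sim$cells$true_phenotype)
  expect_equal(unname(rowSums(ab)),
               as.integer(table(sim$cells$roi_id)[rownames(ab)]))
  res <- compare_abundance(ab, "ICI", "IgG")
  for (q in seq_len(nrow(res))) {
    cl <- res$cluster[q]
    o <- ttest_oracle(ab[attr(ab, "condition") == "ICI", cl],
                      ab[attr(ab, "condition") == "IgG", cl])
    expect_equal(res$t[q], o$t, tolerance = 1e-10)
    expect_equal(res$p[q], o$p, tolerance = 1e-10)
  }
  expect_equal(res$p_holm, p.adjust(res$p, "holm"))
  # identical groups: t = 0, p = 1
  ab0 <- matrix(5L, 4, 2, dimnames = list(paste0("r", 1:4), c("c1", "c2")))
  attr(ab0, "condition") <- c("A", "A", "B", "B")
  r0 <- compare_abundance(ab0, "A", "B")
  expect_equal(r0$t, c(0, 0))
  expect_equal(r0$p, c(1, 1))
  expect_error(compare_abundance(ab0, "A", "C"), ">= 2 ROIs")
})

test_that("the full chain recovers planted phenotypes and ignores cell order", {
  cfg <- blocks_config(n_pheno = 4, cells_per_roi = 400, n_rois = c(ICI = 2L))
  sim <- simulate_cohort(cfg, seed = 31)
  pa <- cluster_phenotypes(sim$cells, cfg$panel, seed = 5)
  expect_gte(ari(pa$labels, sim$cells$true_phenotype), 0.99)
  # permutation invariance up to label renaming
  set.seed(8)
  perm <- sample(nrow(sim$cells))
  pa2 <- cluster_phenotypes(sim$cells[perm, ], cfg$panel, seed = 5)
  expect_equal(ari(pa2$labels, pa$labels[perm]), 1)
})
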