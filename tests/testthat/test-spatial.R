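# Spatial neighbourhoods, the PDR statistic, Welch summaries and zones.

test_that("spatial kNN matches the Pythagorean pair and is truncated to n-1", {
  cells <- data.frame(x_um = c(0, 3), y_um = c(0, 4),
                      roi_id = "r1", cell_id = 1:2, condition = "A")
  nb <- spatial_knn(cells, K = 50)
  expect_equal(nb$index[1, 1], 2L)
  expect_equal(nb$distance[1, 1], 5)
  expect_equal(nb$index[2, 1], 1L)
  expect_true(all(is.na(nb$index[, 2:50])))
  # single-cell ROI flagged with empty list
  solo <- data.frame(x_um = 0, y_um = 0, roi_id = "solo",
                     cell_id = 1, condition = "A")
  expect_warning(nbs <- spatial_knn(solo, K = 5), "single cell")
  expect_true(all(is.na(nbs$index)))
})

test_that("spatial kNN equals the exhaustive oracle on random ROIs", {
  set.seed(17)
  for (trial in 1:50) {
    n <- sample(5:200, 1)
    K <- sample(c(1, 3, 10, 50), 1)
    cells <- data.frame(x_um = runif(n, 0, 100), y_um = runif(n, 0, 100),
                        roi_id = "r", cell_id = 1:n, condition = "A")
    nb <- spatial_knn(cells, K = K)
    orc <- knn_oracle(cells$x_um, cells$y_um, K)
    expect_identical(nb$index, orc$index)
    expect_equal(nb$distance, orc$distance, tolerance = 1e-12)
  }
  # neighbours never cross ROI boundaries
  two <- data.frame(x_um = c(0, 1, 0, 1), y_um = c(0, 0, 0, 0),
                    roi_id = rep(c("a", "b"), each = 2),
                    cell_id = c(1, 2, 1, 2), condition = "A")
  nb2 <- spatial_knn(two, K = 3)
  expect_equal(nb2$index[1, 1], 2L)
  expect_equal(nb2$index[3, 1], 4L)
  expect_true(all(is.na(nb2$index[, 2:3])))
})

test_that("phenotype profiles average neighbour distances per phenotype", {
  # neighbours at distances {3,4} phenotype X and {10} phenotype Y
  cells <- data.frame(x_um = c(0, 3, 0, 10), y_um = c(0, 0, 4, 0),
                      roi_id = "r", cell_id = 1:4, condition = "A")
  labels <- c("S", "X", "X", "Y")
  nb <- spatial_knn(cells, K = 3)
  prof <- phenotype_profiles(nb, labels)
  expect_equal(unname(prof[1, "X"]), 3.5)
  expect_equal(unname(prof[1, "Y"]), 10)
  # all neighbours one phenotype: other entries missing
  labels2 <- c("S", "X", "X", "X")
  prof2 <- phenotype_profiles(nb, labels2)
  expect_equal(unname(prof2[1, "X"]), mean(c(3, 4, 10)))
  expect_true(is.na(prof2[1, "S"]))
  expect_error(phenotype_profiles(nb, c("S", NA, "X", "Y")), "unlabelled")
})

test_that("phenotype profiles equal a per-cell loop oracle", {
  set.seed(23)
  n <- 150
  cells <- data.frame(x_um = runif(n, 0, 200), y_um = runif(n, 0, 200),
                      roi_id = "r", cell_id = 1:n, condition = "A")
  labels <- sample(c("A", "B", "C"), n, replace = TRUE)
  nb <- spatial_knn(cells, K = 20)
  prof <- phenotype_profiles(nb, labels)
  for (i in sample(n, 25)) {
    for (ph in c("A", "B", "C")) {
      sel <- which(labels[nb$index[i, ]] == ph)
      if (length(sel)) {
        expect_equal(unname(prof[i, ph]), mean(nb$distance[i, sel]))
      } else {
        expect_true(is.na(prof[i, ph]))
      }
    }
  }
})

test_that("mean distance matrix pools sources and carries units", {
  # one A and one B mutually nearest: D[A,B] = D[B,A] = d
  cells <- data.frame(x_um = c(0, 6), y_um = c(0, 8), roi_id = "r",
                      cell_id = 1:2, condition = "A")
  labels <- c("A", "B")
  nb <- spatial_knn(cells, K = 50)
  prof <- phenotype_profiles(nb, labels)
  dd <- mean_distance_matrix(prof, labels)
  expect_equal(dd$D["A", "B"], 10)
  expect_equal(dd$D["B", "A"], 10)
  expect_equal(dd$n["A", "B"], 1L)
  # homogeneity: scaling coordinates x2 scales D x2
  cells2 <- transform(cells, x_um = 2 * x_um, y_um = 2 * y_um)
  dd2 <- mean_distance_matrix(
    phenotype_profiles(spatial_knn(cells2, K = 50), labels), labels)
  expect_equal(dd2$D["A", "B"], 20)
  # min_n flags under-supported pairs as missing
  dd3 <- mean_distance_matrix(prof, labels, min_n = 2)
  expect_true(is.na(dd3$D["A", "B"]))
  expect_error(mean_distance_matrix(prof, labels, rois = "nope",
                                    roi_id = c("r", "r")), "matches no cells")
})

test_that("attracted pairs sit closer than inert pairs in expectation", {
  diffs <- vapply(1:20, function(s) {
    cfg <- blocks_config(n_pheno = 3, cells_per_roi = 600,
                         n_rois = c(ICI = 1L),
                         attraction = list(attraction_spec("P1", "P2", 20, 1)))
    sim <- simulate_roi(cfg, "ICI", 1, seed = s)
    labs <- sim$cells$true_phenotype
    prof <- phenotype_profiles(spatial_knn(sim$cells, K = 50), labs)
    dd <- mean_distance_matrix(prof, labs)
    dd$D["P1", "P2"] - dd$D["P1", "P3"]
  }, numeric(1))
  expect_lt(mean(diffs), 0)
  expect_gte(mean(diffs < 0), 0.9)
})

test_that("pdr equals the exhaustive rank oracle on a 3-phenotype fixture", {
  D <- matrix(c(NA, 12, 30,
                14, NA, 22,
                28, 25, NA), 3, 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  got <- pdr(D)
  want <- pdr_oracle(D)
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(got, t(got))
  expect_true(all(got[!is.na(got)] >= 0 & got[!is.na(got)] <= 1))
  expect_true(all(is.na(diag(got))))
})

test_that("pdr handles ties, missing entries and degenerate input", {
  # all entries tied: one common value
  Dt <- matrix(5, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  diag(Dt) <- NA
  got <- pdr(Dt)
  expect_equal(length(unique(got[!is.na(got)])), 1)
  # missing ordered entry makes the pair missing, others unaffected
  Dm <- matrix(c(NA, 1, 2, 3, NA, 4, NA, 6, NA), 3, 3, byrow = TRUE,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  gm <- pdr(Dm)
  expect_true(is.na(gm["A", "C"]))
  expect_false(is.na(gm["A", "B"]))
  expect_equal(gm, pdr_oracle(Dm), tolerance = 1e-12)
  # fewer than 2 defined entries is an error
  D1 <- matrix(NA_real_, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  D1["A", "B"] <- 1
  expect_error(pdr(D1), ">= 2 defined")
})

test_that("pdr is invariant to monotone transforms and rescaling, over random instances", {
  set.seed(41)
  for (trial in 1:100) {
    P <- sample(3:8, 1)
    D <- matrix(runif(P * P, 1, 100), P, P)
    dimnames(D) <- list(paste0("P", 1:P), paste0("P", 1:P))
    diag(D) <- NA
    base <- pdr(D)
    expect_equal(base, pdr_oracle(D), tolerance = 1e-12)
    expect_equal(base, t(base))
    rng <- range(base[!is.na(base)])
    expect_gte(rng[1], 0)
    expect_lte(rng[2], 1)
    # strictly increasing transform of D leaves PDR unchanged
    expect_equal(pdr(exp(D / 50)), base, tolerance = 1e-12)
    expect_equal(pdr(2 * D + 7), base, tolerance = 1e-12)
    # extreme ordered pairs attain 0 and 1
    expect_equal(min(rank_matrix_oracle(D), na.rm = TRUE), 0)
    expect_equal(max(rank_matrix_oracle(D), na.rm = TRUE), 1)
  }
})

test_that("coordinate rescaling leaves PDR unchanged end-to-end", {
  cfg <- blocks_config(n_pheno = 4, cells_per_roi = 500, n_rois = c(ICI = 2L))
  sim <- simulate_cohort(cfg, seed = 3)
  labs <- sim$cells$true_phenotype
  dd1 <- mean_distance_matrix(
    phenotype_profiles(spatial_knn(sim$cells, K = 30), labs), labs)
  sc <- data.table::copy(sim$cells)
  sc$x_um <- sc$x_um * 3.7
  sc$y_um <- sc$y_um * 3.7
  dd2 <- mean_distance_matrix(
    phenotype_profiles(spatial_knn(sc, K = 30), labs), labs)
  expect_equal(pdr(dd1$D), pdr(dd2$D), tolerance = 1e-12)
})

test_that("feature map embeds PDR rows with monotone node sizes", {
  D <- matrix(c(NA, 2, 9, 9, 2.2, NA, 9, 9, 9, 9, NA, 3, 9, 9, 3.1, NA),
              4, 4, byrow = TRUE,
              dimnames = list(paste0("P", 1:4), paste0("P", 1:4)))
  pm <- pdr(D)
  freq <- c(P1 = 400, P2 = 100, P3 = 250, P4 = 50)
  fm <- pdr_feature_map(pm, freq, seed = 2)
  expect_equal(order(fm$nodes$size), order(freq))
  # edge weights are 1 - PDR elementwise
  for (q in seq_len(nrow(fm$edges))) {
    expect_equal(fm$edges$weight[q],
                 1 - pm[fm$edges$a[q], fm$edges$b[q]])
  }
  # duplicate rows land closer than any other pair
  pm2 <- pm
  pm2["P2", ] <- pm2["P1", ]
  pm2[, "P2"] <- pm2[, "P1"]
  pm2["P1", "P2"] <- pm2["P2", "P1"] <- 0
  fm2 <- pdr_feature_map(pm2, freq, seed = 2)
  xy <- as.matrix(fm2$nodes[, c("x", "y")])
  dmat <- as.matrix(dist(xy))
  expect_lte(dmat[1, 2], min(dmat[upper.tri(dmat)][-1]) + 1e-9)
  # < 3 phenotypes falls back to a flagged circular layout
  fm3 <- pdr_feature_map(pm[1:2, 1:2], freq[1:2], seed = 1)
  expect_match(fm3$flags, "circular", all = FALSE)
})

test_that("neighbour summaries reproduce the Welch oracle", {
  # fixture groups from per-ROI means
  groups <- list(c(10, 12, 14), c(20, 22, 24), c(30, 32, 34))
  o <- welch_oracle(groups)
  ow <- oneway.test(c(10, 12, 14, 20, 22, 24, 30, 32, 34) ~
                      factor(rep(1:3, each = 3)), var.equal = FALSE)
  expect_equal(unname(ow$statistic), o$F, tolerance = 1e-10)
  expect_equal(unname(ow$parameter[2]), o$df2, tolerance = 1e-10)
  expect_equal(ow$p.value, o$p, tolerance = 1e-10)

  # via the package path on constructed profiles
  cfg <- blocks_config(n_pheno = 3, cells_per_roi = 400, n_rois = c(ICI = 3L))
  sim <- simulate_cohort(cfg, seed = 13)
  labs <- sim$cells$true_phenotype
  prof <- phenotype_profiles(spatial_knn(sim$cells, K = 50), labs)
  res <- neighbor_distance_summary(prof, labs, sim$cells$roi_id, "P1")
  per <- res$per_roi
  glist <- split(per$mean_distance_um, per$neighbor_phenotype)
  o2 <- welch_oracle(glist)
  expect_equal(res$welch$F, o2$F, tolerance = 1e-10)
  expect_equal(res$welch$df2, o2$df2, tolerance = 1e-10)
  expect_equal(res$welch$p, o2$p, tolerance = 1e-10)

  # identical groups: F = 0, p = 1
  profc <- prof
  profc[, c("P2", "P3")] <- 5
  resc <- neighbor_distance_summary(profc, labs, sim$cells$roi_id, "P1")
  expect_equal(resc$welch$F, 0)
  expect_equal(resc$welch$p, 1)
})

test_that("the attracted neighbour phenotype has the lowest group mean", {
  wins <- vapply(1:20, function(s) {
    cfg <- blocks_config(n_pheno = 4, cells_per_roi = 500,
                         n_rois = c(ICI = 3L),
                         attraction = list(attraction_spec("P1", "P2", 20, 0.8)))
    sim <- simulate_cohort(cfg, seed = s)
    labs <- sim$cells$true_phenotype
    prof <- phenotype_profiles(spatial_knn(sim$cells, K = 50), labs)
    res <- neighbor_distance_summary(prof, labs, sim$cells$roi_id, "P1")
    mu <- tapply(res$per_roi$mean_distance_um, res$per_roi$neighbor_phenotype,
                 mean)
    names(which.min(mu)) == "P2"
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("interaction zones follow the exponential proximity kernel", {
  # toy layout: references of three phenotypes plus probe cells
  cells <- data.frame(
    x_um = c(0, 0, 0, 30, 1000), y_um = c(0, 0, 0, 40, 1000),
    roi_id = "r", cell_id = 1:5, condition = "A")
  labels <- c("R", "G", "B", "Q", "Q")
  z <- interaction_zones(cells, labels, c("R", "G", "B"), tau = 25)
  # coincident with all three references: white
  expect_equal(unlist(z[1, c("R", "G", "B")]), c(R = 1, G = 1, B = 1))
  # probe at distance 50 from all three
  expect_equal(unname(unlist(z[4, c("R", "G", "B")])), rep(exp(-2), 3))
  # far cell: all channels ~ 0
  expect_true(all(z[5, c("R", "G", "B")] < 1e-9))

  # brute-force oracle on a random layout with tau = 25
  set.seed(3)
  n <- 60
  rc <- data.frame(x_um = runif(n, 0, 300), y_um = runif(n, 0, 300),
                   roi_id = "r", cell_id = 1:n, condition = "A")
  rl <- sample(c("A", "B", "C", "Q"), n, replace = TRUE)
  zz <- interaction_zones(rc, rl, c("A", "B", "C"), tau = 25)
  for (i in sample(n, 15)) {
    for (ch in c(1, 2, 3)) {
      refs <- which(rl == c("A", "B", "C")[ch])
      d <- min(sqrt((rc$x_um[refs] - rc$x_um[i])^2 +
                    (rc$y_um[refs] - rc$y_um[i])^2))
      expect_equal(unlist(zz[i, c("R", "G", "B")[ch]]),
                   c(exp(-d / 25)), ignore_attr = TRUE)
    }
  }
  # absent reference phenotype: channel 0 with warning
  expect_warning(z0 <- interaction_zones(cells, labels, c("R", "G", "Z"),
                                         tau = 25), "absent")
  expect_true(all(z0$B == 0))
  expect_error(interaction_zones(cells, labels, c("R", "G"), 25), "exactly 3")
  expect_error(interaction_zones(cells, labels, c("R", "G", "B"), 0), "positive")
})
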