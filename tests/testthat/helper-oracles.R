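# Independent oracles used across the suite. These re-derive expected values
# from first principles (explicit loops, closed forms, exhaustive search) and
# deliberately share no code with the package implementation.

# exhaustive kNN: all-pairs distances, sorted with (distance, lower index)
# tie-break, self excluded
knn_oracle <- function(x, y, K) {
  n <- length(x)
  keff <- min(K, n - 1)
  idx <- matrix(NA_integer_, n, K)
  dst <- matrix(NA_real_, n, K)
  for (i in seq_len(n)) {
    d <- sqrt((x - x[i])^2 + (y - y[i])^2)
    ord <- order(d, seq_len(n))
    ord <- ord[ord != i]
    idx[i, seq_len(keff)] <- ord[seq_len(keff)]
    dst[i, seq_len(keff)] <- d[ord[seq_len(keff)]]
  }
  list(index = idx, distance = dst)
}

# fractional ranks by explicit sort + tie averaging (independent of rank())
frac_rank_oracle <- function(v) {
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(v < v[i])
    ties <- sum(v == v[i])
    out[i] <- less + (1 + ties) / 2
  }
  out
}

# PDR oracle: enumerate defined ordered off-diagonal entries, rank, scale
# to [0,1], geometric-mean the two ordered ranks
pdr_oracle <- function(D) {
  P <- nrow(D)
  ent <- list()
  for (a in seq_len(P)) for (b in seq_len(P)) {
    if (a != b && !is.na(D[a, b])) ent[[length(ent) + 1]] <- c(a, b, D[a, b])
  }
  ent <- do.call(rbind, ent)
  r <- frac_rank_oracle(ent[, 3])
  r <- if (max(r) > min(r)) (r - min(r)) / (max(r) - min(r)) else rep(0.5, length(r))
  Rm <- matrix(NA_real_, P, P, dimnames = dimnames(D))
  for (q in seq_len(nrow(ent))) Rm[ent[q, 1], ent[q, 2]] <- r[q]
  out <- matrix(NA_real_, P, P, dimnames = dimnames(D))
  for (a in seq_len(P)) for (b in seq_len(P)) {
    if (a != b && !is.na(Rm[a, b]) && !is.na(Rm[b, a])) {
      out[a, b] <- sqrt(Rm[a, b] * Rm[b, a])
    }
  }
  out
}

# scaled ordered-rank matrix (the intermediate of the PDR oracle)
rank_matrix_oracle <- function(D) {
  P <- nrow(D)
  ent <- list()
  for (a in seq_len(P)) for (b in seq_len(P)) {
    if (a != b && !is.na(D[a, b])) ent[[length(ent) + 1]] <- c(a, b, D[a, b])
  }
  ent <- do.call(rbind, ent)
  r <- frac_rank_oracle(ent[, 3])
  r <- if (max(r) > min(r)) (r - min(r)) / (max(r) - min(r)) else rep(0.5, length(r))
  Rm <- matrix(NA_real_, P, P, dimnames = dimnames(D))
  for (q in seq_len(nrow(ent))) Rm[ent[q, 1], ent[q, 2]] <- r[q]
  Rm
}

# pooled-variance two-sample t-test, textbook formulas
ttest_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Welch's one-way ANOVA, textbook formulas with Welch-Satterthwaite df
welch_oracle <- function(groups) {
  k <- length(groups)
  ni <- vapply(groups, length, numeric(1))
  mi <- vapply(groups, mean, numeric(1))
  vi <- vapply(groups, var, numeric(1))
  wi <- ni / vi
  mw <- sum(wi * mi) / sum(wi)
  A <- sum(wi * (mi - mw)^2) / (k - 1)
  lam <- sum((1 - wi / sum(wi))^2 / (ni - 1)) / (k^2 - 1)
  Fst <- A / (1 + 2 * lam * (k - 2))
  df1 <- k - 1
  df2 <- 1 / (3 * lam)
  list(F = Fst, df1 = df1, df2 = df2, p = pf(Fst, df1, df2, lower.tail = FALSE))
}

# weighted Newman-Girvan modularity straight from the definition
modularity_oracle <- function(n, edges, labels) {
  deg <- numeric(n)
  m2 <- 0
  for (e in seq_len(nrow(edges))) {
    i <- edges$i[e]; j <- edges$j[e]; w <- edges$weight[e]
    if (i == j) {
      deg[i] <- deg[i] + 2 * w
    } else {
      deg[i] <- deg[i] + w
      deg[j] <- deg[j] + w
    }
    m2 <- m2 + 2 * w
  }
  q <- 0
  for (e in seq_len(nrow(edges))) {
    i <- edges$i[e]; j <- edges$j[e]; w <- edges$weight[e]
    if (labels[i] == labels[j]) q <- q + (if (i == j) 2 * w else 2 * w) / m2
  }
  for (c in unique(labels)) {
    q <- q - (sum(deg[labels == c]) / m2)^2
  }
  q
}

# all partitions of n items (restricted growth strings); Bell(8) = 4140
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  prev <- all_partitions(n - 1)
  out <- vector("list", 0)
  for (p in prev) {
    m <- max(p)
    for (g in seq_len(m + 1)) out[[length(out) + 1]] <- c(p, g)
  }
  out
}

# exhaustive modularity optimum over all partitions
best_modularity_oracle <- function(n, edges) {
  best <- -Inf
  for (p in all_partitions(n)) {
    q <- modularity_oracle(n, edges, p)
    if (q > best) best <- q
  }
  best
}

# small fixture set of connected weighted graphs on <= 8 nodes: structured
# motifs plus seeded random graphs
louvain_fixture_graphs <- function() {
  gs <- list()
  edge_df <- function(m) data.frame(i = m[, 1], j = m[, 2], weight = m[, 3])
  # two triangles joined by one weak edge
  gs$two_triangles <- list(n = 6, edges = edge_df(rbind(
    c(1, 2, 1), c(2, 3, 1), c(1, 3, 1),
    c(4, 5, 1), c(5, 6, 1), c(4, 6, 1),
    c(3, 4, 0.1))))
  # path, cycle, star, clique
  gs$path7 <- list(n = 7, edges = edge_df(cbind(1:6, 2:7, 1)))
  gs$cycle8 <- list(n = 8, edges = edge_df(cbind(1:8, c(2:8, 1), 1)))
  gs$star7 <- list(n = 7, edges = edge_df(cbind(1, 2:7, 1)))
  gs$clique5 <- list(n = 5, edges = edge_df(t(combn(5, 2)) |>
                                              (\(m) cbind(m, 1))()))
  # barbell: two 4-cliques with a bridge
  cl4 <- t(combn(4, 2))
  gs$barbell <- list(n = 8, edges = edge_df(rbind(
    cbind(cl4, 1), cbind(cl4 + 4, 1), c(4, 5, 0.2))))
  # seeded random connected weighted graphs
  set.seed(20240601)
  t <- 0
  while (length(gs) < 30) {
    t <- t + 1
    n <- sample(4:8, 1)
    p <- runif(1, 0.3, 0.9)
    m <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(m)) < p
    if (sum(keep) < n - 1) next
    ed <- data.frame(i = m[keep, 1], j = m[keep, 2],
                     weight = round(runif(sum(keep), 0.1, 1), 3))
    # connectivity check by flood fill
    seen <- c(1L)
    repeat {
      nb <- unique(c(ed$j[ed$i %in% seen], ed$i[ed$j %in% seen]))
      newnb <- setdiff(nb, seen)
      if (!length(newnb)) break
      seen <- c(seen, newnb)
    }
    if (length(seen) < n) next
    gs[[paste0("rand_", t)]] <- list(n = n, edges = ed)
  }
  gs
}

# brute-force per-pixel accumulation oracle for featurize_mask
featurize_oracle_px <- function(mask, stack, pixel_size) {
  labs <- sort(setdiff(unique(as.vector(mask)), 0))
  out <- list()
  for (L in labs) {
    sx <- 0; sy <- 0; np <- 0
    sm <- numeric(dim(stack)[3])
    for (rr in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
      if (mask[rr, cc] == L) {
        np <- np + 1
        sx <- sx + (cc - 1) * pixel_size
        sy <- sy + (rr - 1) * pixel_size
        sm <- sm + stack[rr, cc, ]
      }
    }
    out[[as.character(L)]] <- list(x = sx / np, y = sy / np,
                                   area = np * pixel_size^2, mean = sm / np)
  }
  out
}

# minimum distance from each query to a reference point set
min_dist_oracle <- function(qx, qy, rx, ry) {
  vapply(seq_along(qx), function(i) {
    sqrt(min((rx - qx[i])^2 + (ry - qy[i])^2))
  }, numeric(1))
}

# adjusted Rand index (mclust)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
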