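# Shared fixtures and independent oracles, all built in code.

# Random symmetric 0/1 adjacency matrix (no self loops).
rand_adj <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# igraph network with all edges carrying the same |rho|.
net_from_adj <- function(adj, rho = 0.5) {
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  ids <- sprintf("n%02d", seq_len(nrow(adj)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]]),
    directed = FALSE, vertices = data.frame(name = ids))
  igraph::E(g)$rho <- rep_len(rho, nrow(idx))
  igraph::E(g)$weight <- abs(igraph::E(g)$rho)
  igraph::E(g)$dissimilarity <- 1 - abs(igraph::E(g)$rho)
  g
}

# igraph network with explicit edge list and per-edge rho.
net_from_edges <- function(n, from, to, rho) {
  ids <- sprintf("n%02d", seq_len(n))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[from], to = ids[to]),
    directed = FALSE, vertices = data.frame(name = ids))
  igraph::E(g)$rho <- rho
  igraph::E(g)$weight <- abs(rho)
  igraph::E(g)$dissimilarity <- 1 - abs(rho)
  g
}

# Count table fixture with explicit integer entries.
toy_table <- function(counts, groups = NULL) {
  rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  count_table(counts, groups)
}

# Independent weighted betweenness oracle: Floyd-Warshall distances plus
# shortest-path counting over the shortest-path DAG.
brute_betweenness <- function(adj_w) {
  n <- nrow(adj_w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj_w > 0] <- adj_w[adj_w > 0]
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  tol <- 1e-9
  # sigma[s, v]: number of shortest s->v paths
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    ord <- order(d[s, ])
    for (v in ord) {
      if (v == s || !is.finite(d[s, v])) next
      pred <- which(adj_w[, v] > 0 &
                      abs(d[s, ] + adj_w[, v] - d[s, v]) < tol)
      sigma[s, v] <- sum(sigma[s, pred])
    }
  }
  btw <- numeric(n)
  for (s in seq_len(n))
    for (t in seq_len(n)) {
      if (s >= t || !is.finite(d[s, t])) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (abs(d[s, v] + d[v, t] - d[s, t]) < tol)
          btw[v] <- btw[v] + sigma[s, v] * sigma[t, v] / sigma[s, t]
      }
    }
  btw
}

# Weighted Newman modularity of a given partition, computed from scratch.
brute_modularity <- function(net, membership) {
  el <- igraph::as_edgelist(net, names = TRUE)
  w <- igraph::E(net)$weight
  W <- sum(w)
  strength <- setNames(rep(0, igraph::vcount(net)), igraph::V(net)$name)
  for (e in seq_len(nrow(el))) {
    strength[el[e, 1]] <- strength[el[e, 1]] + w[e]
    strength[el[e, 2]] <- strength[el[e, 2]] + w[e]
  }
  q <- 0
  for (e in seq_len(nrow(el)))
    if (membership[el[e, 1]] == membership[el[e, 2]])
      q <- q + w[e] / W
  for (cl in unique(membership))
    q <- q - (sum(strength[membership == cl]) / (2 * W))^2
  q
}

# Default-ish recovery-scale synthetic dataset used by several tests.
recovery_dataset <- function(seed_truth = 101, seed_counts = 201,
                             n_genera = 50, n_samples = 500) {
  sp <- basis_network_spec(n_genera = n_genera, n_modules = 5,
                           p_within = 0.2, p_between = 0.005,
                           corr_magnitude_range = c(0.4, 0.7),
                           negative_edge_fraction = 0.2, seed = seed_truth)
  tr <- generate_basis_correlation(sp)
  ds <- sample_counts(tr, n_samples, seed = seed_counts)
  list(spec = sp, truth = tr, ds = ds)
}
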