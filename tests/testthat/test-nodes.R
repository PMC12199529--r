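test_that("star centralities follow the hand enumeration", {
  net <- net_from_edges(5, rep(1, 4), 2:5, rho = rep(0.5, 4))
  ct <- centralities(net)
  expect_equal(unlist(ct["n01", c("degree_mm", "betweenness_mm",
                                  "closeness_mm")]),
               c(degree_mm = 1, betweenness_mm = 1, closeness_mm = 1))
  leaves <- ct[paste0("n0", 2:5), ]
  expect_true(all(leaves$degree_mm == 0))
  expect_true(all(leaves$betweenness_mm == 0))
  expect_equal(ct["n01", "summed_mm"], 3)
  # leaves tie on every measure
  expect_equal(length(unique(leaves$closeness_mm)), 1)
})

test_that("constant measures min/max scale to zero", {
  net <- net_from_edges(4, c(1, 2, 3, 4), c(2, 3, 4, 1), rho = rep(0.5, 4))
  ct <- centralities(net)
  expect_true(all(ct$betweenness_mm == 0))
  expect_true(all(ct$degree_mm == 0))
})

test_that("weighted betweenness matches a brute-force recount", {
  set.seed(31)
  adj <- rand_adj(20, 0.25, 31)
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  rho <- runif(nrow(idx), 0.2, 0.9)
  net <- net_from_edges(20, idx[, 1], idx[, 2], rho)
  ct <- centralities(net)
  w <- matrix(0, 20, 20)
  w[idx] <- 1 - rho
  w <- w + t(w)
  expect_equal(ct$betweenness_raw, brute_betweenness(w), tolerance = 1e-8)
})

test_that("isolated nodes get zero closeness and scaling stays total", {
  net <- net_from_edges(5, c(1, 2), c(2, 3), rho = c(0.5, 0.5))
  ct <- centralities(net)
  expect_equal(ct["n04", "closeness_raw"], 0)
  expect_equal(ct["n05", "summed_mm"], 0)
  expect_error(centralities(net_from_adj(matrix(0L, 1, 1))), "2 nodes")
})

test_that("min/max scaling absorbs the n-1 normalization", {
  adj <- rand_adj(12, 0.3, 41)
  net <- net_from_adj(adj, rho = 0.6)
  ct <- centralities(net)
  mm <- function(x) if (diff(range(x)) == 0) rep(0, length(x)) else
    (x - min(x)) / diff(range(x))
  expect_equal(ct$betweenness_mm, mm(ct$betweenness_raw))
  expect_equal(ct$closeness_mm, mm(ct$closeness_raw))
})

test_that("hub detection selects dominant nodes and is monotone", {
  # one node dominating all three measures
  net <- net_from_edges(10, c(rep(1, 6), 7, 8), c(2:7, 8, 9),
                        rho = rep(0.5, 8))
  ct <- centralities(net)
  hs <- hubs(ct, 0.90)
  expect_identical(hs$genera, "n01")
  # quantile 0 excludes per-measure minima only
  h0 <- hubs(ct, 0)
  ref <- rownames(ct)[ct$degree_mm > min(ct$degree_mm) &
                        ct$betweenness_mm > min(ct$betweenness_mm) &
                        ct$closeness_mm > min(ct$closeness_mm)]
  expect_setequal(h0$genera, ref)
  # monotone in the quantile
  qs <- c(0, 0.25, 0.5, 0.55, 0.575, 0.75, 0.9)
  sets <- lapply(qs, function(q) hubs(ct, q)$genera)
  for (k in seq_len(length(qs) - 1))
    expect_true(all(sets[[k + 1]] %in% sets[[k]]))
})

test_that("the Jaccard permutation test matches the hypergeometric null", {
  universe <- sprintf("u%02d", 1:20)
  res <- jaccard_test(universe[1:5], universe[4:8], universe,
                      n_perm = 4000, seed = 3)
  expect_equal(res$jaccard, 2 / 8)
  # closed-form null mean over intersection sizes
  k <- 0:5
  exp_j <- sum(dhyper(k, 5, 15, 5) * k / (10 - k))
  sd_j <- sqrt(sum(dhyper(k, 5, 15, 5) * (k / (10 - k))^2) - exp_j^2)
  expect_lt(abs(res$expected - exp_j), 3 * sd_j / sqrt(4000))
  # determinism
  res2 <- jaccard_test(universe[1:5], universe[4:8], universe,
                       n_perm = 4000, seed = 3)
  expect_identical(res, res2)
})

test_that("identical and disjoint sets give extreme Jaccard values", {
  universe <- sprintf("u%02d", 1:30)
  same <- jaccard_test(universe[1:6], universe[1:6], universe, seed = 1)
  expect_equal(same$jaccard, 1)
  expect_lt(same$p_greater, 0.05)
  half <- jaccard_test(universe[1:15], universe[16:30], universe, seed = 1)
  expect_equal(half$jaccard, 0)
  empty <- jaccard_test(character(0), character(0), universe, seed = 1)
  expect_true(empty$degenerate)
  expect_error(jaccard_test("zz", universe[1], universe, seed = 1),
               "universe")
})

test_that("prevalence/abundance core matches a brute-force recount", {
  comp <- matrix(c(0.002, 0.002, 0.002, 0.002,   # always above detection
                   0.002, 0.0005, 0.0005, 0.0005, # 25% prevalence
                   0.0005, 0.0005, 0.0005, 0.0005,
                   0.002, 0.002, 0.0005, 0.0005,  # exactly 50%
                   0.9, 0.9, 0.9, 0.9), 5, 4, byrow = TRUE)
  rownames(comp) <- sprintf("g%d", 1:5)
  core <- core_def1(comp)
  expect_setequal(core$genera, c("g1", "g4", "g5"))
  # naive double loop
  ref <- character(0)
  for (g in seq_len(5)) {
    hits <- 0
    for (s in 1:4) if (comp[g, s] > 0.001) hits <- hits + 1
    if (hits / 4 >= 0.5) ref <- c(ref, rownames(comp)[g])
  }
  expect_setequal(core$genera, ref)
})

test_that("a genus just below the prevalence threshold is excluded", {
  comp <- matrix(0.0005, 1, 100)
  comp <- rbind(comp, 0.002)
  comp[1, 1:49] <- 0.002
  rownames(comp) <- c("border", "core")
  expect_setequal(core_def1(comp)$genera, "core")
})

test_that("hub-quantile core is consistent with the hub rule", {
  # a dominant star center is the unique 90th-percentile hub
  net <- net_from_edges(10, c(rep(1, 6), 7, 8), c(2:7, 8, 9),
                        rho = rep(0.5, 8))
  ct <- centralities(net)
  hs <- hubs(ct, 0.90)
  expect_identical(hs$genera, "n01")
  core <- core_def2(ct, length(hs$genera))
  expect_gte(core$params$quantile, 0.90)
  expect_identical(core$genera, hs$genera)
})

test_that("hub-quantile core returns top-k under a total order", {
  set.seed(61)
  D <- 12
  # build a centrality table with a strict common order directly
  vals <- sort(runif(D), decreasing = TRUE)
  ct <- data.frame(degree_raw = as.integer(rank(vals)),
                   betweenness_raw = vals, closeness_raw = vals,
                   betweenness_norm = vals / (D - 1),
                   closeness_norm = vals / (D - 1),
                   degree_mm = (vals - min(vals)) / diff(range(vals)),
                   betweenness_mm = (vals - min(vals)) / diff(range(vals)),
                   closeness_mm = (vals - min(vals)) / diff(range(vals)),
                   row.names = sprintf("g%02d", 1:D))
  ct$summed_mm <- ct$degree_mm + ct$betweenness_mm + ct$closeness_mm
  class(ct) <- c("centrality_table", "data.frame")
  for (k in c(2, 5, 8)) {
    core <- core_def2(ct, k)
    expect_setequal(core$genera, sprintf("g%02d", 1:k))
    expect_lte(abs(length(core$genera) - k), 2)
  }
})

test_that("core comparison metrics match naive recomputation", {
  m <- matrix(c(10L, 0L, 5L,
                2L, 3L, 0L,
                8L, 8L, 8L), 3, 3, byrow = TRUE)
  tab <- toy_table(m)
  comp <- sweep(m, 2, colSums(m), "/")
  rownames(comp) <- rownames(tab$counts)
  net <- net_from_edges(3, c(1, 2), c(2, 3), rho = c(0.5, 0.4))
  ct <- centralities(net)
  rownames(ct) <- rownames(tab$counts)
  core <- structure(list(definition = "prevalence_abundance",
                         genera = c("g01", "g03"), params = list()),
                    class = "core_set")
  res <- compare_cores(core, tab, ct)
  # naive loops
  prev <- mean(c(mean(c(10, 8) > 0), mean(c(0, 8) > 0),
                 mean(c(5, 8) > 0))) * 100
  cum <- mean(c(10 + 8, 0 + 8, 5 + 8))
  expect_equal(res$average_prevalence_pct, prev)
  expect_equal(res$cumulative_abundance, cum)
  expect_equal(res$mean_summed_centrality,
               mean(ct$summed_mm[c(1, 3)]))
  # single-genus core reduces to that genus's mean abundance
  one <- structure(list(definition = "x", genera = "g03", params = list()),
                   class = "core_set")
  expect_equal(compare_cores(one, tab, ct)$cumulative_abundance, 8)
  # all genera, no zeros -> 100% prevalence
  m2 <- matrix(1L, 3, 4)
  tab2 <- toy_table(m2)
  all_core <- structure(list(definition = "x",
                             genera = rownames(tab2$counts),
                             params = list()), class = "core_set")
  ct2 <- ct; rownames(ct2) <- rownames(tab2$counts)
  expect_equal(compare_cores(all_core, tab2, ct2)$average_prevalence_pct,
               100)
  empty <- structure(list(definition = "x", genera = character(0),
                          params = list()), class = "core_set")
  expect_error(compare_cores(empty, tab, ct), "empty core")
})
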