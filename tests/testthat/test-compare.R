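test_that("relabelings preserve group sizes and are reproducible", {
  group_of <- setNames(c("a", "a", "a", "b", "b"), sprintf("s%d", 1:5))
  for (b in 1:20) {
    perm <- permute_labels(group_of, seed = 4, b = b)
    expect_equal(sort(unname(table(perm))), c(2L, 3L), ignore_attr = TRUE)
    expect_identical(names(perm), names(group_of))
  }
  expect_identical(permute_labels(group_of, 4, 7),
                   permute_labels(group_of, 4, 7))
  expect_error(permute_labels(setNames(rep("a", 4), 1:4), 1, 1),
               "two groups")
})

test_that("all distinct relabelings occur with near-equal frequency", {
  group_of <- setNames(c("a", "a", "a", "b", "b"), sprintf("s%d", 1:5))
  draws <- vapply(seq_len(10000), function(b) {
    perm <- permute_labels(group_of, seed = 11, b = b)
    paste(sort(names(perm)[perm == "a"]), collapse = ",")
  }, character(1))
  tab <- table(draws)
  expect_equal(length(tab), choose(5, 3))
  gof <- suppressWarnings(stats::chisq.test(tab))
  expect_gt(gof$p.value, 1e-3)
})

test_that("a single permutation can only give p of 0.5 or 1", {
  sp <- basis_network_spec(n_genera = 10, n_modules = 2, p_within = 0.5,
                           p_between = 0.05, seed = 810)
  ds <- generate_case_control(sp, sp, 10, 10, seed = 811)
  cfg <- permutation_config(n_permutations = 1, seed = 812,
                            properties = "edge_density", sparsify = "BH")
  res <- property_difference_test(as_count_table(ds), cfg)
  expect_true(res$edge_density$p_value %in% c(0.5, 1))
})

test_that("identical sample columns give zero differences and p = 1", {
  col <- c(5L, 3L, 2L, 7L, 1L)
  m <- matrix(rep(col, 8), 5, 8)
  tab <- toy_table(m, groups = rep(c("a", "b"), each = 4))
  cfg <- permutation_config(n_permutations = 30, seed = 5,
                            properties = "edge_density", sparsify = "BH")
  res <- property_difference_test(tab, cfg)
  expect_equal(res$edge_density$observed_diff, 0)
  expect_equal(res$edge_density$p_value, 1)
})

test_that("fast property shortcuts agree with global_properties", {
  set.seed(820)
  for (r in 1:5) {
    D <- 12
    adj <- rand_adj(D, 0.3, seed = 820 + r)
    idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    rho <- runif(nrow(idx), -0.8, 0.8)
    net <- net_from_edges(D, idx[, 1], idx[, 2], rho)
    gp <- global_properties(net)
    fast <- micronet:::.fast_props(idx[, 1], idx[, 2], rho, D,
                                   c("edge_density", "n_components",
                                     "clustering_coefficient",
                                     "positive_edge_pct",
                                     "natural_connectivity",
                                     "rel_lcc_size", "modularity"))
    expect_equal(fast[["edge_density"]], gp$edge_density)
    expect_equal(fast[["n_components"]], gp$n_components)
    if (!is.na(gp$clustering_coefficient))
      expect_equal(fast[["clustering_coefficient"]],
                   gp$clustering_coefficient)
    expect_equal(fast[["positive_edge_pct"]], gp$positive_edge_pct)
    expect_equal(fast[["natural_connectivity"]], gp$natural_connectivity)
    expect_equal(fast[["rel_lcc_size"]], gp$rel_lcc_size)
    expect_equal(fast[["modularity"]], gp$modularity)
  }
})

test_that("Monte-Carlo p converges to the exact permutation p at tiny n", {
  sp <- basis_network_spec(n_genera = 6, n_modules = 2, p_within = 0.6,
                           p_between = 0.1, seed = 830)
  ds <- generate_case_control(sp, sp, 4, 4, seed = 831,
                              depths = depth_law("constant", depth = 20000))
  tab <- as_count_table(ds)
  cfg <- permutation_config(n_permutations = 3000, seed = 832,
                            properties = "edge_density", sparsify = "BH")
  res <- property_difference_test(tab, cfg)

  # exact enumeration over all C(8, 4) = 70 assignments
  comp <- zero_replace(tab)
  log_comp <- log(unclass(comp))
  pair_idx <- which(upper.tri(matrix(0, 6, 6)), arr.ind = TRUE)
  stat <- function(cols1) {
    cols2 <- setdiff(1:8, cols1)
    p1 <- micronet:::.group_props(log_comp, cols1, cfg,
                                  pair_idx[, 1], pair_idx[, 2])
    p2 <- micronet:::.group_props(log_comp, cols2, cfg,
                                  pair_idx[, 1], pair_idx[, 2])
    p1[["edge_density"]] - p2[["edge_density"]]
  }
  d_obs <- stat(1:4)
  all_assign <- combn(8, 4)
  d_all <- apply(all_assign, 2, stat)
  p_exact <- mean(abs(d_all) >= abs(d_obs) - 1e-12)
  expect_lt(abs(res$edge_density$p_value - p_exact), 0.05)
})

test_that("p-values are invariant to swapping the group labels", {
  sp <- basis_network_spec(n_genera = 10, n_modules = 2, p_within = 0.5,
                           p_between = 0.05, seed = 840)
  ds <- generate_case_control(sp, sp, 12, 12, seed = 841)
  tab <- as_count_table(ds)
  cfg <- permutation_config(n_permutations = 50, seed = 842,
                            properties = "edge_density", sparsify = "BH")
  res1 <- property_difference_test(tab, cfg)
  # renaming the two groups must leave the two-sided p unchanged
  swapped <- count_table(tab$counts,
                         setNames(ifelse(tab$group_of == "control",
                                         "case", "control"),
                                  names(tab$group_of)))
  res2 <- property_difference_test(swapped, cfg)
  expect_equal(res1$edge_density$p_value, res2$edge_density$p_value)
  expect_equal(abs(res1$edge_density$observed_diff),
               abs(res2$edge_density$observed_diff))
})

test_that("a genus with hub structure in one group has a small local p", {
  spa <- basis_network_spec(n_genera = 12, p_within = 0, p_between = 0,
                            seed = 850)
  spb <- basis_network_spec(n_genera = 12, p_within = 0, p_between = 0,
                            hub_ids = 1, hub_extra_degree = 6,
                            corr_magnitude_range = c(0.5, 0.6), seed = 851)
  ds <- generate_case_control(spa, spb, 250, 250, seed = 852)
  cfg <- permutation_config(n_permutations = 99, seed = 853,
                            sparsify = "BH")
  res <- centrality_difference_test(as_count_table(ds), cfg,
                                    measure = "degree_mm")
  expect_equal(res$p_value[1], min(res$p_value))
  expect_lt(res$value_1[1], res$value_2[1])  # hub lives in the second group
})

test_that("per-genus p-values look uniform when groups are identical", {
  sp <- basis_network_spec(n_genera = 20, n_modules = 2, p_within = 0.4,
                           p_between = 0.05, seed = 860)
  ds <- generate_case_control(sp, sp, 50, 50, seed = 861)
  cfg <- permutation_config(n_permutations = 99, seed = 862)
  res <- centrality_difference_test(as_count_table(ds), cfg,
                                    measure = "summed_mm")
  expect_gt(suppressWarnings(
    stats::ks.test(res$p_value, "punif")$p.value), 1e-4)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
})
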