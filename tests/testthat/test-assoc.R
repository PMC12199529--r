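test_that("variation matrix matches direct variance computation", {
  # D = 3 toy over 4 samples, hand-listed fractions
  comp <- matrix(c(0.5, 0.3, 0.2,
                   0.4, 0.4, 0.2,
                   0.6, 0.2, 0.2,
                   0.3, 0.5, 0.2), 3, 4)
  vm <- variation_matrix(comp)
  for (i in 1:3)
    for (j in 1:3) {
      expect_equal(vm$t[i, j],
                   stats::var(log(comp[i, ] / comp[j, ])))
    }
  expect_equal(unname(diag(vm$t)), rep(0, 3))
  # permutation of samples leaves t unchanged
  vm2 <- variation_matrix(comp[, c(3, 1, 4, 2)])
  expect_equal(vm$t, vm2$t)
})

test_that("perfectly proportional genera have zero log-ratio variance", {
  x <- runif(6, 0.05, 0.25)
  comp <- rbind(x, 2 * x, 1 - 3 * x)
  rownames(comp) <- c("a", "b", "c")
  vm <- variation_matrix(comp)
  expect_equal(vm$t["a", "b"], 0)
})

test_that("basis variances solve the exact D = 3 system", {
  t_mat <- matrix(c(0, 2, 3,
                    2, 0, 4,
                    3, 4, 0), 3, 3)
  vm <- structure(list(t = t_mat, n_samples = 10),
                  class = "variation_matrix")
  omega <- basis_variances(vm)
  # omega_i + omega_j = t_ij exactly in the zero-correlation case
  expect_equal(unname(omega), c(0.5, 1.5, 2.5))
})

test_that("iid genera with equal basis variance are recovered exactly", {
  v <- 0.7
  D <- 12
  t_mat <- matrix(2 * v, D, D); diag(t_mat) <- 0
  vm <- structure(list(t = t_mat, n_samples = 100),
                  class = "variation_matrix")
  expect_equal(unname(basis_variances(vm)), rep(v, D))
})

test_that("excluding every pair of a genus is a degenerate system", {
  t_mat <- matrix(1, 3, 3); diag(t_mat) <- 0
  vm <- structure(list(t = t_mat, n_samples = 10),
                  class = "variation_matrix")
  expect_error(basis_variances(vm, excluded = rbind(c(1, 2), c(1, 3))),
               "excluded")
})

test_that("SparCC stays near zero for independent compositions", {
  sp <- basis_network_spec(n_genera = 20, p_within = 0, p_between = 0,
                           seed = 51)
  tr <- generate_basis_correlation(sp)
  ds <- sample_counts(tr, 500, seed = 52)
  est <- sparcc(zero_replace(as_count_table(ds)))
  off <- abs(est$rho); diag(off) <- 0
  expect_lt(max(off), 0.15)
  expect_true(isSymmetric(est$rho))
  expect_equal(unname(diag(est$rho)), rep(1, 20))
})

test_that("SparCC recovers a planted strong pair", {
  sp <- basis_network_spec(n_genera = 20, n_modules = 10, p_within = 1,
                           p_between = 0,
                           corr_magnitude_range = c(0.8, 0.8),
                           negative_edge_fraction = 0, seed = 53)
  tr <- generate_basis_correlation(sp)
  ds <- sample_counts(tr, 500, seed = 54)
  est <- sparcc(zero_replace(as_count_table(ds)))
  e <- tr$true_edges
  expect_true(all(abs(est$rho[cbind(e$i, e$j)] - 0.8) < 0.1))
})

test_that("SparCC is invariant to per-sample rescaling", {
  set.seed(55)
  comp <- matrix(runif(10 * 30, 0.1, 1), 10, 30)
  comp <- sweep(comp, 2, colSums(comp), "/")
  rownames(comp) <- sprintf("g%02d", 1:10)
  est1 <- sparcc(comp)
  scaled <- sweep(comp, 2, runif(30, 0.5, 2), "*")
  est2 <- sparcc(scaled)
  expect_equal(est1$rho, est2$rho)
})

test_that("compiled SparCC core agrees with the linear-system solver", {
  set.seed(56)
  comp <- matrix(runif(8 * 40, 0.05, 1), 8, 40)
  comp <- sweep(comp, 2, colSums(comp), "/")
  rownames(comp) <- sprintf("g%d", 1:8)
  est <- sparcc(comp, exclusion_threshold = 0.1)
  vm <- variation_matrix(comp)
  omega_ref <- basis_variances(vm, excluded = est$excluded_pairs)
  expect_equal(unname(est$basis_variance), unname(omega_ref),
               tolerance = 1e-10)
  rho_ref <- micronet:::.sparcc_rho(vm$t, omega_ref)
  expect_equal(unname(est$rho), unname(rho_ref), tolerance = 1e-10)
})

test_that("edge t-test matches the t distribution", {
  rho <- diag(3)
  rho[1, 2] <- rho[2, 1] <- 0.5
  rownames(rho) <- colnames(rho) <- c("a", "b", "c")
  est <- list(rho = rho, n_samples = 27)
  tst <- edge_significance(est)
  row <- tst[tst$genus_i == "a" & tst$genus_j == "b", ]
  expect_equal(row$t_stat, 0.5 * sqrt(25 / 0.75), tolerance = 1e-6)
  expect_equal(row$p_value, 0.0079127, tolerance = 1e-4)
  zero <- tst[tst$genus_i == "a" & tst$genus_j == "c", ]
  expect_equal(zero$t_stat, 0)
  expect_equal(zero$p_value, 1)
  est$n_samples <- 3
  expect_error(edge_significance(est), "3 samples")
})

test_that("edge p-values are monotone in |rho| at fixed n", {
  rhos <- seq(0.05, 0.95, by = 0.05)
  n <- 50
  p <- 2 * pt(-abs(rhos * sqrt((n - 2) / (1 - rhos^2))), n - 2)
  D <- length(rhos) + 1
  rho <- diag(D)
  rho[1, -1] <- rhos; rho[-1, 1] <- rhos
  rownames(rho) <- colnames(rho) <- sprintf("g%02d", 1:D)
  tst <- edge_significance(list(rho = rho, n_samples = n))
  got <- tst$p_value[tst$i == 1]
  expect_equal(got, p)
  expect_true(all(diff(got) < 0))
})

test_that("lfdr keeps almost nothing under a pure null", {
  kept <- 0; total <- 0
  for (seed in 1:5) {
    sp <- basis_network_spec(n_genera = 40, p_within = 0, p_between = 0,
                             seed = 60 + seed)
    tr <- generate_basis_correlation(sp)
    ds <- sample_counts(tr, 300, seed = 70 + seed)
    est <- sparcc(zero_replace(as_count_table(ds)))
    tst <- lfdr_adjust(edge_significance(est))
    kept <- kept + sum(tst$keep)
    total <- total + nrow(tst)
  }
  expect_lte(kept / total, 0.05 + 3 * sqrt(0.05 * 0.95 / total))
})

test_that("an isolated strong signal gets the smallest lfdr", {
  sp <- basis_network_spec(n_genera = 20, n_modules = 10, p_within = 1,
                           p_between = 0,
                           corr_magnitude_range = c(0.8, 0.8),
                           negative_edge_fraction = 0, seed = 81)
  tr <- generate_basis_correlation(sp)
  R <- diag(20)
  R[1, 2] <- R[2, 1] <- 0.8
  dimnames(R) <- dimnames(tr$basis_correlation)
  tr$basis_correlation <- R
  ds <- sample_counts(tr, 500, seed = 82)
  est <- sparcc(zero_replace(as_count_table(ds)))
  tst <- lfdr_adjust(edge_significance(est))
  target <- tst$i == 1 & tst$j == 2
  expect_lt(tst$lfdr[target], min(tst$lfdr[!target]))
})

test_that("BH fallback reproduces the textbook step-up rule", {
  set.seed(90)
  rho <- diag(15)
  vals <- runif(15 * 14 / 2, -0.6, 0.6)
  rho[upper.tri(rho)] <- vals
  rho <- (rho + t(rho)); diag(rho) <- 1
  rownames(rho) <- colnames(rho) <- sprintf("g%02d", 1:15)
  tst <- lfdr_adjust(edge_significance(list(rho = rho, n_samples = 40)),
                     alpha = 0.05, method = "BH")
  # textbook BH by sorting
  p <- tst$p_value
  m <- length(p)
  ord <- order(p)
  passed <- which(p[ord] <= 0.05 * seq_len(m) / m)
  keep_ref <- logical(m)
  if (length(passed)) keep_ref[ord[seq_len(max(passed))]] <- TRUE
  expect_identical(tst$keep, keep_ref)
})

test_that("keep sets shrink as alpha decreases", {
  d <- recovery_dataset(seed_truth = 95, seed_counts = 96, n_genera = 30,
                        n_samples = 200)
  est <- sparcc(zero_replace(as_count_table(d$ds)))
  tst <- edge_significance(est)
  kept <- lapply(c(0.1, 0.05, 0.01), function(a)
    which(lfdr_adjust(tst, alpha = a)$keep))
  expect_true(all(kept[[2]] %in% kept[[1]]))
  expect_true(all(kept[[3]] %in% kept[[2]]))
})

test_that("lfdr on too few pairs points at the BH fallback", {
  rho <- diag(4)
  rownames(rho) <- colnames(rho) <- letters[1:4]
  tst <- edge_significance(list(rho = rho, n_samples = 20))
  expect_error(lfdr_adjust(tst), "BH")
  expect_silent(lfdr_adjust(tst, method = "BH"))
})
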