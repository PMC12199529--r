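#' Log-ratio variation matrix
#'
#' `t[i, j]` is the sample variance (unbiased, n - 1 denominator) of
#' `log(x_i / x_j)` across samples — the basic quantity from which SparCC
#' infers basis correlations.
#'
#' @param comp Strictly positive genus-by-sample composition matrix.
#' @return A `variation_matrix`: list with symmetric matrix `t`
#'   (zero diagonal) and `n_samples`.
#' @export
variation_matrix <- function(comp) {
  comp <- unclass(comp)
  if (any(comp <= 0)) stop("composition must be strictly positive")
  D <- nrow(comp); n <- ncol(comp)
  if (D < 3) stop("at least 3 genera are required (basis system unsolvable)")
  if (n < 3) stop("at least 3 samples are required")
  C <- cov(t(log(comp)))
  v <- diag(C)
  t_mat <- outer(v, rep(1, D)) + outer(rep(1, D), v) - 2 * C
  t_mat <- (t_mat + t(t_mat)) / 2
  diag(t_mat) <- 0
  t_mat[t_mat < 0] <- 0
  dimnames(t_mat) <- list(rownames(comp), rownames(comp))
  structure(list(t = t_mat, n_samples = n), class = "variation_matrix")
}

#' Solve the SparCC sparsity approximation for basis variances
#'
#' Under the sparsity assumption (most pairwise correlations near zero),
#' the row sums of the variation matrix satisfy the linear system
#' `m_i * omega_i + sum_{j in I(i)} omega_j = t_i`, where `I(i)` are the
#' non-excluded partners of genus i. Without exclusions this reduces to the
#' closed form `omega_i = (t_i - T) / (D - 2)` with
#' `T = sum_i t_i / (2 (D - 1))`; with exclusions the system is solved
#' explicitly. Estimates are floored at a small positive constant.
#'
#' @param vm A [variation_matrix()].
#' @param excluded Optional two-column matrix/data frame of excluded genus
#'   index pairs.
#' @param floor Lower bound for the returned variances.
#' @return Named numeric vector of basis variances `omega`.
#' @export
basis_variances <- function(vm, excluded = NULL, floor = 1e-8) {
  stopifnot(inherits(vm, "variation_matrix"))
  t_mat <- vm$t
  D <- nrow(t_mat)
  incl <- matrix(TRUE, D, D)
  diag(incl) <- FALSE
  if (!is.null(excluded) && NROW(excluded) > 0) {
    excluded <- as.matrix(excluded)
    incl[excluded] <- FALSE
    incl[excluded[, c(2, 1), drop = FALSE]] <- FALSE
  }
  m <- rowSums(incl)
  if (any(m == 0))
    stop(sprintf("genus %s has every pair excluded; system is degenerate",
                 paste(rownames(t_mat)[m == 0], collapse = ", ")))
  t_i <- rowSums(t_mat * incl)
  M <- incl * 1
  diag(M) <- m
  omega <- tryCatch(solve(M, t_i), error = function(e)
    stop("singular SparCC system after exclusions", call. = FALSE))
  pmax(setNames(as.numeric(omega), rownames(t_mat)), floor)
}

# Correlations from basis variances and the variation matrix, clipped.
.sparcc_rho <- function(t_mat, omega) {
  sq <- sqrt(omega)
  rho <- (outer(omega, omega, "+") - t_mat) / (2 * outer(sq, sq))
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  rho
}

# Core SparCC iteration on a precomputed variation matrix (compiled).
.sparcc_core <- function(t_mat, n, exclusion_threshold, max_exclusion_iters) {
  out <- sparcc_core_cpp(t_mat, exclusion_threshold, max_exclusion_iters)
  dimnames(out$rho) <- dimnames(t_mat)
  out$basis_variance <- as.numeric(out$basis_variance)
  if (!is.null(rownames(t_mat))) names(out$basis_variance) <- rownames(t_mat)
  out$excluded_pairs <- out$excluded_pairs[
    seq_len(nrow(out$excluded_pairs)), , drop = FALSE]
  out
}

#' SparCC correlation estimate
#'
#' Estimates genus-genus basis correlations from a strictly positive
#' composition: basis variances are solved from the variation matrix under
#' the sparsity approximation, correlations are computed as
#' `(omega_i + omega_j - t_ij) / (2 sqrt(omega_i omega_j))` and clipped to
#' `[-1, 1]`, and the most strongly correlated pair exceeding
#' `exclusion_threshold` is iteratively excluded from the system (up to
#' `max_exclusion_iters` times, the defaults of the original tool) before
#' the final correlations are reported. Exclusion stops early if a further
#' exclusion would leave a genus with no remaining partners, which keeps
#' the linear system solvable on very small networks. The pass is
#' deterministic: zeros are assumed to have been handled upstream (see
#' [zero_replace()]).
#'
#' @param comp Strictly positive genus-by-sample composition matrix.
#' @param exclusion_threshold Absolute correlation above which the
#'   strongest pair is excluded from the basis-variance system.
#' @param max_exclusion_iters Maximum number of exclusion iterations.
#' @return A `sparcc_estimate`: list with symmetric `rho` (unit diagonal),
#'   `basis_variance`, `excluded_pairs`, `n_samples`.
#' @export
sparcc <- function(comp, exclusion_threshold = 0.1,
                   max_exclusion_iters = 10) {
  vm <- variation_matrix(comp)
  out <- .sparcc_core(vm$t, vm$n_samples, exclusion_threshold,
                      max_exclusion_iters)
  out$n_samples <- vm$n_samples
  class(out) <- "sparcc_estimate"
  out
}

#' Per-edge significance by one-sample t-test
#'
#' Each correlation is tested against zero with
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` and a two-sided p-value from the
#' t distribution with n - 2 degrees of freedom (the sampling distribution
#' of a Pearson correlation; approximate for SparCC estimates).
#' Correlations of +/-1 map to p = 0.
#'
#' @param est A `sparcc_estimate` (or any list with `rho` and `n_samples`).
#' @param alpha Significance level recorded for downstream sparsification.
#' @return An `edge_test` data frame with one row per unordered pair:
#'   `i`, `j` (indices), `genus_i`, `genus_j`, `rho`, `t_stat`, `p_value`,
#'   and placeholder `lfdr` / `keep` columns filled by [lfdr_adjust()].
#' @export
edge_significance <- function(est, alpha = 0.05) {
  rho <- est$rho
  n <- est$n_samples
  if (n <= 3) stop("need more than 3 samples for the edge t-test")
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[idx]
  t_stat <- ifelse(abs(r) >= 1, sign(r) * Inf,
                   r * sqrt((n - 2) / (1 - r^2)))
  p <- ifelse(is.infinite(t_stat), 0, 2 * pt(-abs(t_stat), df = n - 2))
  out <- data.frame(i = idx[, 1], j = idx[, 2],
                    genus_i = rownames(rho)[idx[, 1]],
                    genus_j = rownames(rho)[idx[, 2]],
                    rho = r, t_stat = t_stat, p_value = p,
                    lfdr = NA_real_, keep = NA)
  attr(out, "alpha") <- alpha
  attr(out, "n_samples") <- n
  attr(out, "n_genera") <- nrow(rho)
  class(out) <- c("edge_test", "data.frame")
  out
}

# Local fdr by central matching: fit a quadratic to the log of a kernel
# density estimate of the z-scores around the mode to obtain the empirical
# null N(mu0, sigma0^2) and its proportion pi0.
.lfdr_central_matching <- function(z) {
  d <- density(z, n = 512)
  mode_x <- d$x[which.max(d$y)]
  qz <- quantile(z, c(0.25, 0.75), names = FALSE)
  halfwidth <- max(0.75, (qz[2] - qz[1]) / 2)
  w <- d$x >= mode_x - halfwidth & d$x <= mode_x + halfwidth & d$y > 0
  xs <- d$x[w]; ys <- log(d$y[w])
  X <- cbind(1, xs, xs^2)
  beta <- tryCatch(solve(crossprod(X), crossprod(X, ys)),
                   error = function(e) NULL)
  if (is.null(beta) || beta[3] >= 0) {
    # flat/degenerate central region: fall back to robust moments
    mu0 <- median(z)
    sigma0 <- max((qz[2] - qz[1]) / 1.349, 1e-6)
    pi0 <- 1
  } else {
    mu0 <- -beta[2] / (2 * beta[3])
    sigma0 <- sqrt(-1 / (2 * beta[3]))
    f0 <- exp(beta[1] + beta[2] * mu0 + beta[3] * mu0^2)
    pi0 <- min(1, f0 * sigma0 * sqrt(2 * pi))
  }
  fz <- approx(d$x, d$y, xout = z, rule = 2)$y
  fz <- pmax(fz, 1e-12)
  pmin(1, pi0 * dnorm(z, mu0, sigma0) / fz)
}

#' Local false discovery rate adjustment of edge tests
#'
#' Transforms each correlation to a z-score `atanh(rho) * sqrt(n - 3)`,
#' estimates the marginal density of the z-scores by a Gaussian kernel,
#' fits the empirical null `N(mu0, sigma0^2)` and its proportion `pi0` by
#' central matching (quadratic fit to the log density around its mode),
#' and sets `lfdr(z) = pi0 * phi(z; mu0, sigma0) / f(z)` capped at 1.
#' Edges with `lfdr <= alpha` are kept. With fewer than `min_pairs` pairs
#' the density estimate is unreliable and an error points at the
#' Benjamini-Hochberg fallback (`method = "BH"`), which keeps edges with
#' BH-adjusted p-values at or below `alpha` (the adjusted p is then stored
#' in the `lfdr` column).
#'
#' @param test An [edge_significance()] result.
#' @param alpha Cutoff applied to the lfdr (or BH-adjusted p).
#' @param method `"lfdr"` (default) or `"BH"`.
#' @param min_pairs Minimum number of pairs required for `"lfdr"`.
#' @return The `edge_test` with `lfdr` and `keep` filled in.
#' @export
lfdr_adjust <- function(test, alpha = attr(test, "alpha") %||% 0.05,
                        method = c("lfdr", "BH"), min_pairs = 50) {
  method <- match.arg(method)
  n <- attr(test, "n_samples")
  if (method == "BH") {
    adj <- p.adjust(test$p_value, method = "BH")
    test$lfdr <- adj
    test$keep <- adj <= alpha
  } else {
    if (nrow(test) < min_pairs)
      stop("too few pairs for lfdr density estimation; use method = \"BH\"")
    r <- .clip1(test$rho)
    z <- atanh(pmin(1 - 1e-12, pmax(-1 + 1e-12, r))) * sqrt(n - 3)
    lf <- .lfdr_central_matching(z)
    lf[abs(test$rho) >= 1] <- 0
    test$lfdr <- lf
    test$keep <- lf <= alpha
  }
  attr(test, "alpha") <- alpha
  attr(test, "method") <- method
  test
}

`%||%` <- function(a, b) if (is.null(a)) b else a
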