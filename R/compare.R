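#' Configuration for permutation-based network comparison
#'
#' @param n_permutations Number of label permutations (default 1000).
#' @param seed Integer seed; each permutation draws from a stream derived
#'   from `(seed, b)`.
#' @param alpha Significance level for the reported decisions.
#' @param properties Character vector of global properties to compare
#'   (any of `"edge_density"`, `"n_components"`,
#'   `"clustering_coefficient"`, `"positive_edge_pct"`,
#'   `"natural_connectivity"`, `"modularity"`, `"rel_lcc_size"`).
#' @param sparsify `"lfdr"` (default) or `"BH"` edge sparsification inside
#'   the pipeline.
#' @param sparcc_exclusion_threshold,sparcc_max_iters SparCC settings used
#'   inside the pipeline.
#' @param max_failure_fraction Permutations whose pipeline fails are
#'   dropped; if more than this fraction fail the test aborts.
#' @return A `permutation_config` list.
#' @export
permutation_config <- function(n_permutations = 1000, seed = 1L,
                               alpha = 0.05,
                               properties = c("edge_density",
                                              "natural_connectivity"),
                               sparsify = c("lfdr", "BH"),
                               sparcc_exclusion_threshold = 0.1,
                               sparcc_max_iters = 10,
                               max_failure_fraction = 0.05) {
  stopifnot(n_permutations >= 1)
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), alpha = alpha,
                 properties = properties,
                 sparsify = match.arg(sparsify),
                 sparcc_exclusion_threshold = sparcc_exclusion_threshold,
                 sparcc_max_iters = as.integer(sparcc_max_iters),
                 max_failure_fraction = max_failure_fraction),
            class = "permutation_config")
}

#' Random group relabeling preserving group sizes
#'
#' Uniformly permutes the group labels over the samples; the permutation
#' stream is reproducible given the pair `(seed, b)`.
#'
#' @param group_of Named character vector of group labels (two groups).
#' @param seed Base integer seed.
#' @param b Permutation index (`b = 0` reproduces the stream head).
#' @return Named character vector: a relabeling with the original group
#'   sizes.
#' @export
permute_labels <- function(group_of, seed, b) {
  tab <- table(group_of)
  if (length(tab) != 2) stop("exactly two groups are required")
  if (any(tab == 0)) stop("one group is empty")
  set.seed(.sub_seed(seed, b))
  setNames(sample(unname(group_of)), names(group_of))
}

# Fast global properties straight from the kept-pair list, avoiding graph
# construction where possible. Produces the same values as
# global_properties() on the corresponding network (asserted in tests).
.fast_props <- function(keep_i, keep_j, rho, D, properties) {
  out <- numeric(0)
  n_pairs <- D * (D - 1) / 2
  m <- length(keep_i)
  need_adj <- any(properties %in% c("n_components", "clustering_coefficient",
                                    "natural_connectivity", "rel_lcc_size",
                                    "modularity"))
  if (need_adj) {
    adj <- matrix(0, D, D)
    if (m) {
      adj[cbind(keep_i, keep_j)] <- 1
      adj[cbind(keep_j, keep_i)] <- 1
    }
  }
  comp_id <- NULL
  if (any(properties %in% c("n_components", "rel_lcc_size"))) {
    # label propagation over components
    comp_id <- seq_len(D)
    repeat {
      changed <- FALSE
      if (m) for (e in seq_len(m)) {
        a <- comp_id[keep_i[e]]; b <- comp_id[keep_j[e]]
        if (a != b) {
          comp_id[comp_id == max(a, b)] <- min(a, b)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  for (p in properties) {
    out[p] <- switch(p,
      edge_density = m / n_pairs,
      positive_edge_pct = if (m == 0) NA_real_ else 100 * mean(rho > 0),
      n_components = length(unique(comp_id)),
      rel_lcc_size = max(tabulate(match(comp_id, unique(comp_id)))) / D,
      clustering_coefficient = {
        if (m == 0) NA_real_ else {
          a2 <- adj %*% adj
          tri3 <- sum(a2 * adj)          # 6 x number of triangles
          triples <- sum(colSums(adj) * (colSums(adj) - 1))
          if (triples == 0) NA_real_ else tri3 / triples
        }
      },
      natural_connectivity = .natural_connectivity(adj),
      modularity = {
        g <- igraph::graph_from_data_frame(
          data.frame(from = as.character(keep_i), to = as.character(keep_j)),
          directed = FALSE,
          vertices = data.frame(name = as.character(seq_len(D))))
        if (m) igraph::E(g)$weight <- abs(rho)
        fast_greedy_clusters(g)$modularity_Q
      },
      stop("unknown property: ", p))
  }
  out
}

# Variation matrix from a log-composition submatrix, without transposes.
.varmat_from_log <- function(log_comp, cols) {
  X <- log_comp[, cols, drop = FALSE]
  n <- ncol(X)
  Xc <- X - rowMeans(X)
  C <- tcrossprod(Xc) / (n - 1)
  v <- diag(C)
  t_mat <- outer(v, v, "+") - 2 * C
  diag(t_mat) <- 0
  t_mat[t_mat < 0] <- 0
  t_mat
}

# One group's pipeline from a precomputed log-composition matrix
# (samples restricted by `cols`): SparCC, edge t-test, sparsification,
# then the requested global properties. `pair_i`/`pair_j` index the upper
# triangle and are precomputed by the caller.
.group_props <- function(log_comp, cols, config, pair_i, pair_j) {
  D <- nrow(log_comp)
  n <- length(cols)
  t_mat <- .varmat_from_log(log_comp, cols)
  est <- .sparcc_core(t_mat, n, config$sparcc_exclusion_threshold,
                      config$sparcc_max_iters)
  r <- est$rho[(pair_j - 1L) * D + pair_i]
  keep <- .keep_edges(r, n, config$alpha, config$sparsify)
  .fast_props(pair_i[keep], pair_j[keep], r[keep], D, config$properties)
}

# Vectorized sparsification decision for the permutation hot path;
# mirrors edge_significance() + lfdr_adjust() without the data frames.
.keep_edges <- function(r, n, alpha, method) {
  if (method == "BH") {
    t_stat <- ifelse(abs(r) >= 1, Inf, abs(r) * sqrt((n - 2) / (1 - r^2)))
    p <- 2 * pt(-t_stat, df = n - 2)
    p.adjust(p, method = "BH") <= alpha
  } else {
    z <- atanh(pmin(1 - 1e-12, pmax(-1 + 1e-12, r))) * sqrt(n - 3)
    lf <- .lfdr_central_matching(z)
    lf[abs(r) >= 1] <- 0
    lf <= alpha
  }
}

# Shared machinery: observed and permuted per-group statistics.
.permutation_engine <- function(counts, config, stat_fun) {
  stopifnot(inherits(counts, "count_table"))
  group_of <- counts$group_of
  if (is.null(group_of)) stop("count table has no group labels")
  lev <- unique(unname(group_of))
  if (length(lev) != 2) stop("exactly two groups are required")
  comp <- zero_replace(counts)
  log_comp <- log(unclass(comp))

  observed <- stat_fun(log_comp, group_of, lev)
  B <- config$n_permutations
  null_stats <- vector("list", B)
  failures <- 0L
  for (b in seq_len(B)) {
    perm <- permute_labels(group_of, config$seed, b)
    null_stats[b] <- list(tryCatch(stat_fun(log_comp, perm, lev),
                                   error = function(e) NULL))
    if (is.null(null_stats[[b]])) failures <- failures + 1L
  }
  if (failures > config$max_failure_fraction * B)
    stop(sprintf("%d of %d permutations failed (more than %g%%)",
                 failures, B, 100 * config$max_failure_fraction))
  list(observed = observed,
       null_stats = null_stats[!vapply(null_stats, is.null, TRUE)],
       failures = failures, groups = lev)
}

.perm_pvalue <- function(obs_diff, null_diffs) {
  ok <- !is.na(null_diffs)
  (1 + sum(abs(null_diffs[ok]) >= abs(obs_diff))) / (sum(ok) + 1)
}

#' Permutation test for global network property differences
#'
#' Tests the null hypothesis that a global network property is equal in
#' the two groups. The observed statistic is the between-group difference
#' after running the full per-group pipeline (zero replacement, SparCC,
#' t-test sparsification with lfdr or BH control, property computation);
#' the null distribution is obtained by randomly reassigning group labels
#' to samples (original group sizes preserved) and rerunning the pipeline
#' per permutation. Taxon/sample filters are expected to have been applied
#' once, up front, so the node universe stays fixed across permutations.
#' Two-sided p-values use the `(1 + x) / (B + 1)` correction.
#'
#' @param counts A filtered [count_table()] with exactly two groups.
#' @param config A [permutation_config()].
#' @return A `permutation_result` list, one element per property:
#'   `observed` (per-group values), `observed_diff`, `null_diffs`,
#'   `p_value`, `significant`; plus `n_failures`.
#' @export
property_difference_test <- function(counts, config = permutation_config()) {
  props <- config$properties
  pair_idx <- NULL
  stat_fun <- function(log_comp, labels, lev) {
    if (is.null(pair_idx)) {
      D <- nrow(log_comp)
      pair_idx <<- which(upper.tri(matrix(0, D, D)), arr.ind = TRUE)
    }
    cols1 <- which(unname(labels) == lev[1])
    cols2 <- which(unname(labels) == lev[2])
    rbind(.group_props(log_comp, cols1, config, pair_idx[, 1], pair_idx[, 2]),
          .group_props(log_comp, cols2, config, pair_idx[, 1], pair_idx[, 2]))
  }
  eng <- .permutation_engine(counts, config, stat_fun)
  out <- lapply(props, function(p) {
    obs <- eng$observed[, p]
    d_obs <- obs[1] - obs[2]
    d_null <- vapply(eng$null_stats, function(s) s[1, p] - s[2, p],
                     numeric(1))
    pv <- .perm_pvalue(d_obs, d_null)
    list(observed = setNames(obs, eng$groups), observed_diff = unname(d_obs),
         null_diffs = unname(d_null), p_value = pv,
         significant = pv <= config$alpha)
  })
  names(out) <- props
  out$n_failures <- eng$failures
  class(out) <- "permutation_result"
  out
}

#' Permutation test for per-genus centrality differences
#'
#' Applies the same label-permutation machinery to the min/max-scaled
#' centralities of every genus: per permutation, each group's network is
#' rebuilt and the chosen scaled centrality measure recomputed; genera
#' isolated in a permuted network simply contribute their (zero)
#' centrality, consistent with the isolated-node convention.
#'
#' @param counts A filtered [count_table()] with exactly two groups.
#' @param config A [permutation_config()].
#' @param measure One of `"summed_mm"`, `"degree_mm"`, `"betweenness_mm"`,
#'   `"closeness_mm"`.
#' @return Data frame with one row per genus: `genus`, per-group observed
#'   values, `observed_diff`, `p_value`, `significant`.
#' @export
centrality_difference_test <- function(counts,
                                       config = permutation_config(),
                                       measure = "summed_mm") {
  stat_fun <- function(log_comp, labels, lev) {
    one <- function(cols) {
      n <- length(cols)
      t_mat <- .varmat_from_log(log_comp, cols)
      est <- .sparcc_core(t_mat, n, config$sparcc_exclusion_threshold,
                          config$sparcc_max_iters)
      est$n_samples <- n
      test <- lfdr_adjust(edge_significance(est, alpha = config$alpha),
                          alpha = config$alpha, method = config$sparsify)
      net <- build_network(est, test)
      centralities(net)[[measure]]
    }
    rbind(one(which(unname(labels) == lev[1])),
          one(which(unname(labels) == lev[2])))
  }
  eng <- .permutation_engine(counts, config, stat_fun)
  genera <- rownames(counts$counts)
  d_obs <- eng$observed[1, ] - eng$observed[2, ]
  d_null <- vapply(eng$null_stats, function(s) s[1, ] - s[2, ],
                   numeric(length(genera)))
  if (is.null(dim(d_null))) d_null <- matrix(d_null, nrow = length(genera))
  pv <- vapply(seq_along(genera),
               function(g) .perm_pvalue(d_obs[g], d_null[g, ]), numeric(1))
  data.frame(genus = genera,
             value_1 = eng$observed[1, ], value_2 = eng$observed[2, ],
             observed_diff = unname(d_obs), p_value = pv,
             significant = pv <= config$alpha, row.names = NULL)
}
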