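# Min/max scaling to [0, 1]; a constant column maps to all zeros.
.minmax <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(0, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Node centralities of a microbial network
#'
#' Computes degree (unweighted edge count), betweenness (number of
#' shortest paths through a node, with dissimilarity edge lengths) and
#' closeness. Closeness is computed per component from dissimilarity
#' distances with the reachable-fraction correction
#' `(r_i / (n - 1)) * (r_i / sum of distances)` so that nodes in small
#' components are down-weighted; isolated nodes get closeness zero so the
#' measure is total. Betweenness and closeness are additionally divided by
#' `n - 1` ("normalized" columns) and all three measures are min/max
#' scaled to `[0, 1]` (a constant measure scales to all zeros); the sum of
#' the three scaled values is reported per genus.
#'
#' @param net Network from [build_network()].
#' @param use_weights If `FALSE`, shortest paths ignore dissimilarities.
#' @return A `centrality_table` data frame (row names = genus) with
#'   columns `degree_raw`, `betweenness_raw`, `closeness_raw`,
#'   `betweenness_norm`, `closeness_norm`, `degree_mm`, `betweenness_mm`,
#'   `closeness_mm`, `summed_mm`.
#' @export
centralities <- function(net, use_weights = TRUE) {
  n <- igraph::vcount(net)
  if (n < 2) stop("centralities need at least 2 nodes")
  # igraph requires strictly positive path weights; a perfectly
  # correlated edge (dissimilarity 0) is floored at a tiny epsilon
  w <- if (use_weights && igraph::ecount(net) > 0)
    pmax(igraph::E(net)$dissimilarity, 1e-12) else NA
  deg <- igraph::degree(net)
  btw <- if (igraph::ecount(net) == 0) rep(0, n) else
    igraph::betweenness(net, weights = w, directed = FALSE)
  dmat <- if (igraph::ecount(net) == 0)
    matrix(Inf, n, n) else igraph::distances(net, weights = w)
  diag(dmat) <- Inf
  clo <- vapply(seq_len(n), function(i) {
    reach <- which(is.finite(dmat[i, ]))
    r <- length(reach)
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(dmat[i, reach]))
  }, numeric(1))
  out <- data.frame(
    degree_raw = as.integer(deg),
    betweenness_raw = unname(btw),
    closeness_raw = unname(clo),
    betweenness_norm = unname(btw) / (n - 1),
    closeness_norm = unname(clo) / (n - 1),
    row.names = igraph::V(net)$name)
  out$degree_mm <- .minmax(out$degree_raw)
  out$betweenness_mm <- .minmax(out$betweenness_norm)
  out$closeness_mm <- .minmax(out$closeness_norm)
  out$summed_mm <- out$degree_mm + out$betweenness_mm + out$closeness_mm
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Identify hub genera
#'
#' A genus is a hub when its min/max-scaled degree, betweenness and
#' closeness are all strictly above the per-measure empirical quantile
#' (type-7 interpolation). The strict inequality avoids inflating the hub
#' set under ties.
#'
#' @param table A [centralities()] table.
#' @param quantile Quantile threshold, default the 90th percentile.
#' @return A `hub_set`: list with `quantile` and the character vector
#'   `genera` (possibly empty).
#' @export
hubs <- function(table, quantile = 0.90) {
  stopifnot(inherits(table, "centrality_table"),
            quantile >= 0, quantile < 1)
  qd <- stats::quantile(table$degree_mm, quantile, type = 7, names = FALSE)
  qb <- stats::quantile(table$betweenness_mm, quantile, type = 7, names = FALSE)
  qc <- stats::quantile(table$closeness_mm, quantile, type = 7, names = FALSE)
  sel <- table$degree_mm > qd & table$betweenness_mm > qb &
    table$closeness_mm > qc
  structure(list(quantile = quantile, genera = rownames(table)[sel]),
            class = "hub_set")
}

#' Permutation test for the similarity of two node sets
#'
#' Computes the Jaccard index `|A n B| / |A u B|` of two sets drawn from a
#' shared node universe and tests it against the null of random sets of
#' the same sizes: the null Jaccard distribution is obtained by drawing a
#' uniformly random set of size `|B|` from the universe against the fixed
#' `A` (under the null of independent uniform same-size sets this has
#' exactly the distribution of two random draws). One-sided p-values use
#' the small-sample `+1` correction; the expected index is the null mean.
#'
#' @param set_a,set_b Character vectors (subsets of `universe`).
#' @param universe Character vector: the shared node universe.
#' @param n_perm Number of null draws (default 1000).
#' @param seed Integer seed for the null draws.
#' @return A `jaccard_result`: list with `jaccard`, `expected`,
#'   `p_greater`, `p_less`, `n_perm`, and `degenerate` flag (empty union).
#' @export
jaccard_test <- function(set_a, set_b, universe, n_perm = 1000, seed = 1L) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("sets must be subsets of the universe")
  a <- length(set_a); b <- length(set_b)
  N <- length(universe)
  if (a + b == 0) {
    return(structure(list(jaccard = 0, expected = 0, p_greater = 1,
                          p_less = 1, n_perm = n_perm, degenerate = TRUE),
                     class = "jaccard_result"))
  }
  inter <- length(intersect(set_a, set_b))
  j_obs <- inter / (a + b - inter)
  in_a <- logical(N)
  in_a[match(set_a, universe)] <- TRUE
  set.seed(seed)
  k_null <- vapply(seq_len(n_perm),
                   function(...) sum(in_a[sample.int(N, b)]), numeric(1))
  j_null <- k_null / (a + b - k_null)
  structure(list(jaccard = j_obs,
                 expected = mean(j_null),
                 p_greater = (1 + sum(j_null >= j_obs)) / (n_perm + 1),
                 p_less = (1 + sum(j_null <= j_obs)) / (n_perm + 1),
                 n_perm = n_perm, degenerate = FALSE),
            class = "jaccard_result")
}

#' Core microbiota by prevalence and abundance thresholds
#'
#' The conventional definition: a genus belongs to the core when its
#' relative abundance exceeds `detection` in at least a `prevalence`
#' fraction of the group's samples (defaults 0.1/100 detection, 50/100
#' prevalence).
#'
#' @param comp Genus-by-sample matrix of relative abundances (or a
#'   [count_table()], converted internally).
#' @param detection Relative-abundance detection threshold (strict `>`).
#' @param prevalence Minimum fraction of samples at detection.
#' @return A `core_set`: list with `definition = "prevalence_abundance"`,
#'   `genera`, and `params`.
#' @export
core_def1 <- function(comp, detection = 0.001, prevalence = 0.5) {
  if (inherits(comp, "count_table"))
    comp <- sweep(comp$counts, 2, colSums(comp$counts), "/")
  comp <- unclass(comp)
  sel <- rowMeans(comp > detection) >= prevalence
  structure(list(definition = "prevalence_abundance",
                 genera = rownames(comp)[sel],
                 params = list(detection = detection,
                               prevalence = prevalence)),
            class = "core_set")
}

#' Core microbiota by hub centrality at a tuned quantile
#'
#' The network-based definition: core members are the hub genera obtained
#' by lowering the hub quantile until the hub-set size matches
#' `target_count` (typically the size of the conventional core). The
#' quantile is scanned downward on a fixed grid and the set whose size is
#' closest to the target is returned, preferring the larger (more
#' selective) quantile on ties.
#'
#' @param table A [centralities()] table.
#' @param target_count Desired core size (>= 1).
#' @param q_grid Decreasing grid of quantiles to scan.
#' @return A `core_set` with `definition = "hub_quantile"`, the tuned
#'   quantile in `params$quantile`, and an `exact` flag indicating whether
#'   the target size was met.
#' @export
core_def2 <- function(table, target_count,
                      q_grid = seq(0.95, 0.05, by = -0.005)) {
  stopifnot(target_count >= 1)
  sizes <- vapply(q_grid, function(q) length(hubs(table, q)$genera),
                  numeric(1))
  best <- which.min(abs(sizes - target_count))  # ties -> first = larger q
  hs <- hubs(table, q_grid[best])
  if (sizes[best] != target_count)
    warning(sprintf("target core size %d not attainable; returning %d genera",
                    target_count, sizes[best]))
  structure(list(definition = "hub_quantile",
                 genera = hs$genera,
                 params = list(quantile = q_grid[best],
                               target_count = target_count,
                               exact = sizes[best] == target_count)),
            class = "core_set")
}

#' Summary metrics for a core-microbiota set
#'
#' Reports (i) the average prevalence: mean over samples of the percentage
#' of core genera present (count > 0) per sample, (ii) the cumulative
#' abundance: per-sample sum of core genus counts averaged over samples
#' (on the count scale of the table), and (iii) the mean summed min/max
#' centrality of the core genera.
#'
#' @param core A `core_set`.
#' @param table The group's [count_table()].
#' @param centrality The group's [centralities()] table.
#' @return A `core_comparison` list.
#' @export
compare_cores <- function(core, table, centrality) {
  stopifnot(inherits(core, "core_set"), inherits(table, "count_table"))
  genera <- core$genera
  if (length(genera) == 0) stop("empty core set")
  cts <- table$counts[intersect(genera, rownames(table$counts)), ,
                      drop = FALSE]
  in_table <- rownames(centrality) %in% genera
  structure(list(
    definition = core$definition,
    core_size = length(genera),
    average_prevalence_pct = mean(100 * colMeans(cts > 0)),
    cumulative_abundance = mean(colSums(cts)),
    mean_summed_centrality = if (any(in_table))
      mean(centrality$summed_mm[in_table]) else NA_real_),
    class = "core_comparison")
}

#' Overlap between two core sets
#' @param core_x,core_y `core_set` objects.
#' @return List with `overlap_count` and `overlap_pct` (relative to the
#'   first set's size).
#' @export
core_overlap <- function(core_x, core_y) {
  ov <- length(intersect(core_x$genera, core_y$genera))
  list(overlap_count = ov,
       overlap_pct = if (length(core_x$genera)) 100 * ov /
         length(core_x$genera) else NA_real_)
}
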