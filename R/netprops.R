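#' Build the sparsified microbial co-occurrence network
#'
#' Nodes are genera, edges are the pairs kept by the sparsification step.
#' Every genus remains a node even when isolated (isolated nodes count as
#' components downstream). Edge attributes: `rho` (signed correlation),
#' `weight = |rho|`, `dissimilarity = 1 - |rho|` (used as shortest-path
#' length).
#'
#' @param est A `sparcc_estimate` (provides the node universe).
#' @param test An [lfdr_adjust()]-completed `edge_test` aligned with `est`.
#' @param group_label Optional label stored as a graph attribute.
#' @return An undirected [igraph::igraph] graph.
#' @export
build_network <- function(est, test, group_label = NULL) {
  if (any(is.na(test$keep)))
    stop("edge test has no keep decisions; run lfdr_adjust() first")
  ids <- rownames(est$rho)
  if (attr(test, "n_genera") != length(ids))
    stop("edge test and estimate are not aligned")
  kept <- test[test$keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[kept$i], to = ids[kept$j]),
    directed = FALSE,
    vertices = data.frame(name = ids))
  igraph::E(g)$rho <- kept$rho
  igraph::E(g)$weight <- abs(kept$rho)
  igraph::E(g)$dissimilarity <- 1 - abs(kept$rho)
  if (!is.null(group_label)) g <- igraph::set_graph_attr(g, "group", group_label)
  g
}

#' Fast-greedy modularity clustering
#'
#' Agglomerative greedy modularity maximization on edge weights `|rho|`.
#' Disconnected graphs are handled (each component is clustered); an
#' edgeless graph yields one singleton cluster per node with Q defined
#' as 0.
#'
#' @param net Network from [build_network()].
#' @return A `cluster_assignment`: list with named integer `membership` and
#'   the weighted `modularity_Q` of the returned partition.
#' @export
fast_greedy_clusters <- function(net) {
  n <- igraph::vcount(net)
  if (igraph::ecount(net) == 0) {
    return(structure(list(membership = setNames(seq_len(n),
                                                igraph::V(net)$name),
                          modularity_Q = 0), class = "cluster_assignment"))
  }
  cl <- igraph::cluster_fast_greedy(net, weights = igraph::E(net)$weight)
  # cut the merge tree at the modularity maximum ourselves: igraph's
  # default cut can stop one merge short on very small graphs
  memb <- igraph::cut_at(cl, steps = which.max(cl$modularity) - 1)
  q <- igraph::modularity(net, memb, weights = igraph::E(net)$weight)
  structure(list(membership = setNames(as.integer(memb),
                                       igraph::V(net)$name),
                 modularity_Q = q),
            class = "cluster_assignment")
}

# Natural connectivity: ln of the average exponentiated adjacency
# eigenvalue (unweighted skeleton).
.natural_connectivity <- function(adj) {
  lambda <- eigen(adj, symmetric = TRUE, only.values = TRUE)$values
  m <- max(lambda)
  # log-sum-exp for numerical stability at larger spectra
  m + log(mean(exp(lambda - m)))
}

#' Global network properties
#'
#' Computes the whole-network summary used to compare groups:
#' number of components (isolated nodes count), global clustering
#' coefficient (transitivity of the unweighted skeleton), weighted
#' modularity of the fast-greedy partition, positive edge percentage, edge
#' density, natural connectivity (ln mean exp of adjacency eigenvalues),
#' and the definitional product [edge_number()] = edge density x number of
#' components. On the largest connected component (LCC) it additionally
#' reports the relative LCC size, mean edge dissimilarity, average
#' shortest-path length with dissimilarity edge lengths (both raw and
#' expressed in units of the average dissimilarity), and the LCC-restricted
#' transitivity and modularity (the LCC is re-clustered).
#'
#' @param net Network from [build_network()].
#' @param clusters Optional [fast_greedy_clusters()] result (computed if
#'   missing).
#' @param avg_local_clustering If `TRUE`, also report the mean local
#'   clustering coefficient.
#' @return A `global_properties` list. Undefined quantities (e.g. positive
#'   edge percentage of an edgeless network) are `NA`.
#' @export
global_properties <- function(net, clusters = NULL,
                              avg_local_clustering = FALSE) {
  if (is.null(clusters)) clusters <- fast_greedy_clusters(net)
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  comps <- igraph::components(net)
  adj <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  adj[adj > 0] <- 1

  density <- igraph::edge_density(net)
  trans <- if (m == 0) NA_real_ else
    igraph::transitivity(net, type = "global")
  pos_pct <- if (m == 0) NA_real_ else 100 * mean(igraph::E(net)$rho > 0)
  natcon <- .natural_connectivity(adj)

  lcc_ids <- which(comps$membership == which.max(comps$csize))
  lcc <- igraph::induced_subgraph(net, lcc_ids)
  m_lcc <- igraph::ecount(lcc)
  lcc_avg_diss <- if (m_lcc == 0) NA_real_ else
    mean(igraph::E(lcc)$dissimilarity)
  if (m_lcc > 0) {
    dmat <- igraph::distances(lcc,
                              weights = pmax(igraph::E(lcc)$dissimilarity,
                                             1e-12))
    raw_apl <- mean(dmat[upper.tri(dmat)])
    apl_units <- raw_apl / lcc_avg_diss
  } else {
    raw_apl <- NA_real_; apl_units <- NA_real_
  }
  lcc_clusters <- fast_greedy_clusters(lcc)

  out <- list(
    n_nodes = n,
    edge_count = m,
    n_components = comps$no,
    clustering_coefficient = trans,
    modularity = clusters$modularity_Q,
    positive_edge_pct = pos_pct,
    edge_density = density,
    natural_connectivity = natcon,
    edge_number = edge_number(density, comps$no),
    rel_lcc_size = max(comps$csize) / n,
    lcc_avg_dissimilarity = lcc_avg_diss,
    lcc_avg_path_length = apl_units,
    lcc_avg_path_length_raw = raw_apl,
    lcc_clustering_coefficient = if (m_lcc == 0) NA_real_ else
      igraph::transitivity(lcc, type = "global"),
    lcc_modularity = lcc_clusters$modularity_Q)
  if (avg_local_clustering)
    out$avg_local_clustering <- igraph::transitivity(net, type = "localaverage")
  stopifnot(isTRUE(all.equal(out$edge_number,
                             out$edge_density * out$n_components)))
  structure(out, class = "global_properties")
}

#' Edge number: edge density times number of components
#'
#' Edge density is a relative measure of connectivity; multiplying it by
#' the number of components gives a combined index of network complexity
#' used alongside the other global properties.
#'
#' @param edge_density Edge density in `[0, 1]`.
#' @param n_components Number of components (isolated nodes included).
#' @return The product, a single number.
#' @export
edge_number <- function(edge_density, n_components) {
  stopifnot(edge_density >= 0, edge_density <= 1, n_components >= 1)
  edge_density * n_components
}
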