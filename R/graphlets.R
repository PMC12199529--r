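# Orbits kept for the graphlet correlation matrix: orbits 3, 12, 13, 14
# are redundant (their counts are determined by the remaining eleven, see
# the graphlet-correlation literature) and are dropped.
.NONREDUNDANT_ORBITS <- c(0, 1, 2, 4, 5, 6, 7, 8, 9, 10, 11)

.orbit_names <- function(ids) paste0("O", ids)

.as_adjacency <- function(net) {
  if (inherits(net, "igraph")) {
    adj <- igraph::as_adjacency_matrix(net, sparse = FALSE)
    adj[adj > 0] <- 1
    storage.mode(adj) <- "integer"
    adj
  } else {
    adj <- as.matrix(net)
    adj[adj != 0] <- 1
    diag(adj) <- 0
    storage.mode(adj) <- "integer"
    adj
  }
}

#' Count graphlet orbits up to four nodes
#'
#' For every node, counts how often it occupies each automorphism orbit
#' (orbits 0-14) of every connected induced subgraph on 2-4 nodes, by
#' exact combinatorial enumeration in compiled code. Orbit 0 is the node
#' degree; this identity is asserted on every call.
#'
#' @param net An [igraph::igraph] network or a (0/1) adjacency matrix.
#' @return An `orbit_count_matrix`: integer node x 15 matrix with columns
#'   `O0`..`O14`; the 11 non-redundant columns are available through
#'   [reduced_orbits()].
#' @export
count_orbits <- function(net) {
  adj <- .as_adjacency(net)
  counts <- count_orbits_cpp(adj)
  dimnames(counts) <- list(rownames(adj), .orbit_names(0:14))
  stopifnot(identical(counts[, "O0"],
                      setNames(as.integer(rowSums(adj)), rownames(adj))))
  structure(counts, class = c("orbit_count_matrix", "matrix", "array"))
}

#' Reference orbit counter by exhaustive subset enumeration
#'
#' A deliberately simple pure-R implementation that enumerates every node
#' subset of size 2-4 and classifies the induced subgraph by its edge
#' count and within-subgraph degree sequence. Exact but slow
#' (`O(n^4)` with interpreted loops); intended for validating
#' [count_orbits()] on small graphs.
#'
#' @inheritParams count_orbits
#' @return Integer node x 15 matrix with columns `O0`..`O14`.
#' @export
count_orbits_reference <- function(net) {
  adj <- .as_adjacency(net)
  n <- nrow(adj)
  out <- matrix(0L, n, 15, dimnames = list(rownames(adj),
                                           .orbit_names(0:14)))
  out[, 1] <- as.integer(rowSums(adj))
  add <- function(nodes, orbits) {
    for (t in seq_along(nodes))
      out[nodes[t], orbits[t] + 1L] <<- out[nodes[t], orbits[t] + 1L] + 1L
  }
  if (n >= 3) {
    for (s in asplit(combn(n, 3), 2)) {
      sub <- adj[s, s]
      m <- sum(sub) / 2
      if (m == 3) add(s, c(3, 3, 3))
      else if (m == 2) {
        d <- rowSums(sub)
        add(s, ifelse(d == 2, 2, 1))
      }
    }
  }
  if (n >= 4) {
    for (s in asplit(combn(n, 4), 2)) {
      sub <- adj[s, s]
      m <- sum(sub) / 2
      if (m < 3) next
      d <- rowSums(sub)
      if (min(d) == 0) next          # triangle plus isolated node
      orb <- if (m == 3) {
        if (max(d) == 3) ifelse(d == 3, 7, 6) else ifelse(d == 2, 5, 4)
      } else if (m == 4) {
        if (max(d) == 2) rep(8, 4) else c(9, 10, 11)[d]
      } else if (m == 5) {
        ifelse(d == 2, 12, 13)
      } else rep(14, 4)
      add(s, orb)
    }
  }
  out
}

#' Enumerate the graphlet and orbit taxonomy up to four nodes
#'
#' Generates every labeled graph on 2, 3 and 4 nodes, keeps the connected
#' ones, groups them into isomorphism classes (the graphlets), and derives
#' each graphlet's automorphism orbits by brute-force permutation.
#' Graphlets are ordered by (size, edge count, maximum degree) and orbits
#' within a graphlet by position degree, which reproduces the standard
#' orbit numbering 0-14. The non-redundant subset used for graphlet
#' correlation matrices drops orbits 3, 12, 13 and 14, whose counts are
#' determined by the others.
#'
#' @return A `graphlet_taxonomy` list: `graphlets` (data frame with
#'   graphlet id, size `k`, edge count `m`, orbit ids), `n_graphlets`,
#'   `n_orbits`, `nonredundant_orbits`, `n_nonredundant`.
#' @export
graphlet_taxonomy <- function() {
  classes <- list()
  for (k in 2:4) {
    pairs <- combn(k, 2)
    n_pairs <- ncol(pairs)
    for (mask in seq_len(2^n_pairs) - 1L) {
      on <- which(bitwAnd(mask, 2^(seq_len(n_pairs) - 1)) > 0)
      if (length(on) < k - 1) next
      adj <- matrix(0L, k, k)
      for (e in on) {
        adj[pairs[1, e], pairs[2, e]] <- 1L
        adj[pairs[2, e], pairs[1, e]] <- 1L
      }
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      if (!igraph::is_connected(g)) next
      found <- FALSE
      for (ci in seq_along(classes)) {
        cl <- classes[[ci]]
        if (cl$k == k && cl$m == length(on) &&
            igraph::isomorphic(g, cl$graph)) { found <- TRUE; break }
      }
      if (!found)
        classes[[length(classes) + 1]] <- list(graph = g, adj = adj, k = k,
                                               m = length(on))
    }
  }
  # canonical ordering reproducing the standard graphlet numbering
  ord <- order(vapply(classes, `[[`, 0, "k"),
               vapply(classes, `[[`, 0, "m"),
               vapply(classes, function(cl) max(igraph::degree(cl$graph)), 0))
  classes <- classes[ord]

  orbit_id <- 0L
  rows <- list()
  for (gi in seq_along(classes)) {
    cl <- classes[[gi]]
    k <- cl$k
    perms <- .permutations(k)
    auto <- Filter(function(p) identical(cl$adj[p, p], cl$adj), perms)
    # orbit partition: transitive closure of vertex images under the
    # automorphism group
    rep_of <- seq_len(k)
    for (p in auto)
      for (v in seq_len(k)) {
        a <- min(rep_of[v], rep_of[p[v]])
        rep_of[rep_of == rep_of[v] | rep_of == rep_of[p[v]]] <- a
      }
    orbit_classes <- split(seq_len(k), rep_of)
    # order orbits within the graphlet by position degree
    degs <- igraph::degree(cl$graph)
    orbit_classes <- orbit_classes[order(vapply(orbit_classes,
                                                function(v) degs[v[1]], 0))]
    ids <- orbit_id + seq_along(orbit_classes) - 1L
    orbit_id <- orbit_id + length(orbit_classes)
    rows[[gi]] <- data.frame(graphlet = gi - 1L, k = k, m = cl$m,
                             orbits = I(list(ids)))
  }
  graphlets <- do.call(rbind, rows)
  n_orbits <- orbit_id
  structure(list(graphlets = graphlets,
                 n_graphlets = length(classes),
                 n_orbits = as.integer(n_orbits),
                 nonredundant_orbits = .NONREDUNDANT_ORBITS,
                 n_nonredundant = length(.NONREDUNDANT_ORBITS)),
            class = "graphlet_taxonomy")
}

.permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in .permutations(k - 1))
    for (pos in seq_len(k))
      out[[length(out) + 1]] <- append(p, k, after = pos - 1)
  out
}

#' Reduce an orbit-count matrix to the 11 non-redundant orbits
#' @param counts An `orbit_count_matrix` from [count_orbits()].
#' @return Node x 11 integer matrix (orbits 0, 1, 2, 4, 5, 6, 7, 8, 9,
#'   10, 11).
#' @export
reduced_orbits <- function(counts) {
  counts[, .orbit_names(.NONREDUNDANT_ORBITS), drop = FALSE]
}

#' Graphlet correlation matrix
#'
#' Appends a pseudo-count row of ones to the reduced (11-orbit) count
#' matrix — so that orbits unobserved in the network do not produce
#' undefined correlations — and computes Spearman's correlation (average
#' ranks for ties) between all orbit columns. Entries that are still
#' undefined (a constant column) are reported as `NA`, never imputed.
#'
#' @param counts An `orbit_count_matrix` from [count_orbits()].
#' @return A `gcm` object: 11 x 11 symmetric matrix with unit diagonal and
#'   attribute `n_rows` (nodes + pseudo row), used as the sample size in
#'   [gcm_difference()].
#' @export
gcm <- function(counts) {
  red <- reduced_orbits(counts)
  if (nrow(red) < 3) stop("need at least 3 nodes to correlate orbit columns")
  red <- rbind(red, 1L)   # pseudo-count row
  s <- suppressWarnings(cor(red, method = "spearman"))
  diag(s) <- 1
  structure(s, n_rows = nrow(red), class = c("gcm", "matrix", "array"))
}

#' Compare two graphlet correlation matrices by Fisher's z-test
#'
#' For each upper-triangle orbit pair, the difference between the two
#' networks' graphlet correlations is tested with Fisher's
#' z-transformation: `z = atanh(r)`, statistic
#' `(z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided normal p-value.
#' The sample sizes are the numbers of rows used for each GCM (nodes plus
#' the pseudo row). Correlations of |r| = 1 give an infinite z and are
#' flagged with p = 0. Raw p-values are compared against `alpha` by
#' default; `p_adjust = "BH"` applies Benjamini-Hochberg across the
#' upper-triangle entries first.
#'
#' @param g1,g2 [gcm()] objects for the two groups.
#' @param alpha Significance level.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @param spearman_correction If `TRUE`, use the 1.06/(n-3) variance
#'   inflation appropriate for Spearman correlations.
#' @return A `gcm_difference` data frame with one row per orbit pair:
#'   `orbit_i`, `orbit_j`, `r1`, `r2`, `abs_diff`, `z_stat`, `p_value`,
#'   `significant`, `infinite_z`.
#' @export
gcm_difference <- function(g1, g2, alpha = 0.05,
                           p_adjust = c("none", "BH"),
                           spearman_correction = FALSE) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(g1, "gcm"), inherits(g2, "gcm"))
  n1 <- attr(g1, "n_rows"); n2 <- attr(g2, "n_rows")
  if (n1 <= 3 || n2 <= 3) stop("GCM sample sizes must exceed 3")
  idx <- which(upper.tri(g1), arr.ind = TRUE)
  r1 <- g1[idx]; r2 <- g2[idx]
  infl <- if (spearman_correction) 1.06 else 1
  se <- sqrt(infl / (n1 - 3) + infl / (n2 - 3))
  z1 <- atanh(.clip1(r1)); z2 <- atanh(.clip1(r2))
  z_stat <- (z1 - z2) / se
  p <- 2 * pnorm(-abs(z_stat))
  inf_z <- is.infinite(z1) | is.infinite(z2)
  p[inf_z & is.nan(z_stat)] <- 0
  p[inf_z & !is.nan(z_stat)] <- 0
  z_eq_inf <- is.infinite(z1) & is.infinite(z2) & (sign(z1) == sign(z2))
  p[z_eq_inf] <- 1   # both exactly +/-1 on the same side: no difference
  p_cmp <- if (p_adjust == "BH") p.adjust(p, "BH") else p
  out <- data.frame(
    orbit_i = colnames(g1)[idx[, 1]], orbit_j = colnames(g1)[idx[, 2]],
    r1 = r1, r2 = r2, abs_diff = abs(r1 - r2),
    z_stat = z_stat, p_value = p,
    significant = !is.na(p_cmp) & p_cmp <= alpha,
    infinite_z = inf_z)
  attr(out, "alpha") <- alpha
  class(out) <- c("gcm_difference", "data.frame")
  out
}

#' Select orbits of interest from a GCM comparison
#'
#' Each orbit is scored by the number of significant GCM-difference
#' entries it participates in; orbits with at least `min_hits` hits are
#' returned, ranked by hit count (ties broken by orbit id).
#'
#' @param diff A [gcm_difference()] result.
#' @param min_hits Minimum number of significant entries.
#' @return Integer vector of orbit ids (possibly empty).
#' @export
select_orbits <- function(diff, min_hits = 1) {
  sig <- diff[diff$significant, , drop = FALSE]
  if (nrow(sig) == 0) return(integer(0))
  ids <- as.integer(sub("^O", "", c(sig$orbit_i, sig$orbit_j)))
  hit <- table(ids)
  hit <- hit[hit >= min_hits]
  as.integer(names(hit))[order(-as.integer(hit), as.integer(names(hit)))]
}

#' Map genera to orbits of interest
#'
#' Ranks genera within each selected orbit by their orbit count (ties
#' broken lexicographically by genus id), takes the top `top_k` per orbit,
#' and flags as focal the genera present in the top list of *every*
#' selected orbit. The occurrence `o` of a genus is its mean count over
#' the selected orbits.
#'
#' @param counts An `orbit_count_matrix`.
#' @param orbits Integer vector of orbit ids of interest (non-empty).
#' @param top_k Number of genera retained per orbit (clamped, with a
#'   warning, to the number of genera).
#' @return A `terminal_node_report` data frame (`genus`, `occurrence`,
#'   `focal`), with the per-orbit top lists in attribute `top_by_orbit`
#'   and the selected orbits in attribute `orbits`.
#' @export
map_genera <- function(counts, orbits, top_k = 25) {
  if (length(orbits) == 0) stop("no orbits of interest supplied")
  cols <- .orbit_names(orbits)
  stopifnot(all(cols %in% colnames(counts)))
  genera <- rownames(counts)
  if (top_k > length(genera)) {
    warning("top_k exceeds the number of genera; clamping")
    top_k <- length(genera)
  }
  top_by_orbit <- lapply(cols, function(cn) {
    ord <- order(-counts[, cn], genera)
    genera[ord][seq_len(top_k)]
  })
  names(top_by_orbit) <- cols
  focal_set <- Reduce(intersect, top_by_orbit)
  occ <- rowMeans(counts[, cols, drop = FALSE])
  out <- data.frame(genus = genera, occurrence = unname(occ),
                    focal = genera %in% focal_set, row.names = NULL)
  attr(out, "top_by_orbit") <- top_by_orbit
  attr(out, "orbits") <- orbits
  attr(out, "top_k") <- top_k
  class(out) <- c("terminal_node_report", "data.frame")
  out
}

#' Focal genera exclusive to each of two groups
#' @param report_a,report_b [map_genera()] reports for the two groups.
#' @return List with `exclusive_a`, `exclusive_b`, `shared`.
#' @export
terminal_exclusive <- function(report_a, report_b) {
  fa <- report_a$genus[report_a$focal]
  fb <- report_b$genus[report_b$focal]
  list(exclusive_a = setdiff(fa, fb),
       exclusive_b = setdiff(fb, fa),
       shared = intersect(fa, fb))
}
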