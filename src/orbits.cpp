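#include <Rcpp.h>
using namespace Rcpp;

// Exact per-node graphlet orbit counts (orbits 0-14) for a simple
// undirected graph, by direct enumeration of all 2-, 3- and 4-node
// induced subgraphs with early pruning. Complexity O(n^4); intended for
// genus-level networks (up to a few hundred nodes).
//
// Orbit assignment follows the standard numbering: within each graphlet,
// positions are ordered by their within-subgraph degree.
//   G0 edge:            0
//   G1 path P3:         1 (ends), 2 (middle)
//   G2 triangle:        3
//   G3 path P4:         4 (ends), 5 (middles)
//   G4 star K1,3:       6 (leaves), 7 (center)
//   G5 cycle C4:        8
//   G6 paw:             9 (tail end), 10 (triangle pair), 11 (cut vertex)
//   G7 diamond:         12 (degree-2 pair), 13 (degree-3 pair)
//   G8 clique K4:       14

// [[Rcpp::export]]
IntegerMatrix count_orbits_cpp(IntegerMatrix adj) {
  const int n = adj.nrow();
  if (adj.ncol() != n) stop("adjacency matrix must be square");
  std::vector<unsigned char> A((size_t)n * n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      int v = adj(i, j);
      if (v != 0) A[(size_t)i * n + j] = 1;
    }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < i; ++j)
      if (A[(size_t)i * n + j] != A[(size_t)j * n + i])
        stop("adjacency matrix must be symmetric");

  IntegerMatrix out(n, 15);

  // orbit 0: degree
  for (int i = 0; i < n; ++i) {
    int d = 0;
    for (int j = 0; j < n; ++j) d += A[(size_t)i * n + j];
    out(i, 0) = d;
  }

  // 3-node subgraphs
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int eij = A[(size_t)i * n + j];
      for (int k = j + 1; k < n; ++k) {
        int eik = A[(size_t)i * n + k];
        int ejk = A[(size_t)j * n + k];
        int m = eij + eik + ejk;
        if (m == 3) {
          out(i, 3)++; out(j, 3)++; out(k, 3)++;
        } else if (m == 2) {
          // the node on both edges is the middle of the path
          if (eij && eik)      { out(i, 2)++; out(j, 1)++; out(k, 1)++; }
          else if (eij && ejk) { out(j, 2)++; out(i, 1)++; out(k, 1)++; }
          else                 { out(k, 2)++; out(i, 1)++; out(j, 1)++; }
        }
      }
    }

  // 4-node subgraphs
  int node[4], deg[4];
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int eij = A[(size_t)i * n + j];
      for (int k = j + 1; k < n; ++k) {
        int eik = A[(size_t)i * n + k];
        int ejk = A[(size_t)j * n + k];
        for (int l = k + 1; l < n; ++l) {
          int eil = A[(size_t)i * n + l];
          int ejl = A[(size_t)j * n + l];
          int ekl = A[(size_t)k * n + l];
          int m = eij + eik + ejk + eil + ejl + ekl;
          if (m < 3) continue;
          deg[0] = eij + eik + eil;
          deg[1] = eij + ejk + ejl;
          deg[2] = eik + ejk + ekl;
          deg[3] = eil + ejl + ekl;
          // a vertex of degree 0 means triangle + isolated: disconnected;
          // with min degree >= 1, any subgraph with >= 3 edges is connected
          if (deg[0] == 0 || deg[1] == 0 || deg[2] == 0 || deg[3] == 0)
            continue;
          node[0] = i; node[1] = j; node[2] = k; node[3] = l;
          switch (m) {
          case 3: {
            // P4 (max degree 2) or star K1,3 (max degree 3)
            bool star = (deg[0] == 3 || deg[1] == 3 ||
                         deg[2] == 3 || deg[3] == 3);
            for (int v = 0; v < 4; ++v) {
              if (star) out(node[v], deg[v] == 3 ? 7 : 6)++;
              else      out(node[v], deg[v] == 2 ? 5 : 4)++;
            }
            break;
          }
          case 4: {
            // C4 (all degrees 2) or paw
            bool cyc = (deg[0] == 2 && deg[1] == 2 &&
                        deg[2] == 2 && deg[3] == 2);
            for (int v = 0; v < 4; ++v) {
              if (cyc) out(node[v], 8)++;
              else     out(node[v], deg[v] == 1 ? 9 : (deg[v] == 2 ? 10 : 11))++;
            }
            break;
          }
          case 5:
            for (int v = 0; v < 4; ++v)
              out(node[v], deg[v] == 2 ? 12 : 13)++;
            break;
          default:  // m == 6
            for (int v = 0; v < 4; ++v) out(node[v], 14)++;
          }
        }
      }
    }

  return out;
}
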