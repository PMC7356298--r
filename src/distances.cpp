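#include <Rcpp.h>
using namespace Rcpp;

// All-pairs shortest path lengths by Dijkstra's algorithm from every source,
// specialized to dense length matrices (similarity networks are complete or
// nearly so, where an O(n^2)-per-source scan beats heap-based queues).
// L(i, j) is the edge length between i and j, R_PosInf for absent edges;
// the diagonal is ignored.
// [[Rcpp::export(name = ".dijkstra_all_pairs")]]
NumericMatrix dijkstra_all_pairs(NumericMatrix L) {
  int n = L.nrow();
  if (L.ncol() != n) stop("length matrix must be square");
  NumericMatrix D(n, n);
  std::vector<double> dist(n);
  std::vector<bool> done(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(done.begin(), done.end(), false);
    dist[s] = 0.0;
    for (int iter = 0; iter < n; ++iter) {
      int u = -1;
      double best = R_PosInf;
      for (int v = 0; v < n; ++v)
        if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
      if (u < 0) break;  // remaining vertices unreachable
      done[u] = true;
      // L is symmetric; reading column u keeps the scan contiguous. With
      // non-negative lengths, relaxing settled vertices or the diagonal can
      // never lower a distance (Inf entries propagate harmlessly), so the
      // inner loop needs no branches beyond the comparison itself.
      const double* Lu = &L(0, u);
      const double du = dist[u];
      for (int v = 0; v < n; ++v) {
        const double alt = du + Lu[v];
        if (alt < dist[v]) dist[v] = alt;
      }
    }
    for (int v = 0; v < n; ++v) D(s, v) = dist[v];
  }
  return D;
}
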