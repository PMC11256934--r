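#include <Rcpp.h>
#include <random>
#include <algorithm>

// Second-order (Node2Vec) biased random walks over a CSR adjacency.
// Transition weights from `cur` given previous node `prev`:
//   1/p to return to prev, 1 to a common neighbor of prev, 1/q otherwise,
// normalized over the neighbors of `cur`. The first step is uniform.
// Isolated start nodes (and any dead end) self-pad: the walk stays at the
// current node for the remaining positions, keeping the walk array
// rectangular.

static inline bool has_edge(const Rcpp::IntegerVector& indptr,
                            const Rcpp::IntegerVector& indices,
                            int u, int v) {
  const int* first = &indices[0] + indptr[u];
  const int* last = &indices[0] + indptr[u + 1];
  return std::binary_search(first, last, v);
}

// [[Rcpp::export]]
Rcpp::IntegerMatrix sample_walks_cpp(Rcpp::IntegerVector indptr,
                                     Rcpp::IntegerVector indices,
                                     int n, int k, int T,
                                     double p, double q,
                                     unsigned int seed) {
  Rcpp::IntegerMatrix walks(n * T, k);
  std::mt19937 rng(seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<double> w;
  for (int v = 0; v < n; ++v) {
    for (int t = 0; t < T; ++t) {
      int row = v * T + t;
      walks(row, 0) = v;
      int prev = -1, cur = v;
      for (int step = 1; step < k; ++step) {
        int deg = indptr[cur + 1] - indptr[cur];
        if (deg == 0) {             // isolated/dead end: self-pad
          walks(row, step) = cur;
          continue;
        }
        int nxt;
        if (prev < 0) {             // first hop: uniform over neighbors
          int j = (int)(unif(rng) * deg);
          if (j >= deg) j = deg - 1;
          nxt = indices[indptr[cur] + j];
        } else {
          w.resize(deg);
          double tot = 0.0;
          for (int j = 0; j < deg; ++j) {
            int x = indices[indptr[cur] + j];
            double wt;
            if (x == prev) wt = 1.0 / p;
            else if (has_edge(indptr, indices, prev, x)) wt = 1.0;
            else wt = 1.0 / q;
            w[j] = wt;
            tot += wt;
          }
          double r = unif(rng) * tot, acc = 0.0;
          int j = 0;
          for (; j < deg; ++j) {
            acc += w[j];
            if (r <= acc) break;
          }
          if (j >= deg) j = deg - 1;
          nxt = indices[indptr[cur] + j];
        }
        walks(row, step) = nxt;
        prev = cur;
        cur = nxt;
      }
    }
  }
  return walks;
}
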