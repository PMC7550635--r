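#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Nodal local efficiency: global efficiency of the subgraph induced by
// each node's neighbours (node excluded); 0 for degree < 2.  BFS within
// the induced subgraph only.
// [[Rcpp::export]]
NumericVector local_efficiency_cpp(NumericMatrix adj) {
  const int n = adj.nrow();
  NumericVector out(n);
  std::vector<int> nb;
  nb.reserve(n);
  std::vector<int> dist;
  std::vector<int> queue;
  std::vector<char> sub;
  for (int v = 0; v < n; ++v) {
    nb.clear();
    for (int u = 0; u < n; ++u)
      if (u != v && adj(u, v) != 0) nb.push_back(u);
    const int k = (int)nb.size();
    if (k < 2) { out[v] = 0.0; continue; }
    sub.assign((size_t)k * k, 0);
    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b)
        if (adj(nb[a], nb[b]) != 0) sub[a * k + b] = sub[b * k + a] = 1;
    double acc = 0.0;
    for (int s = 0; s < k; ++s) {
      dist.assign(k, -1);
      queue.clear();
      queue.push_back(s);
      dist[s] = 0;
      for (size_t qi = 0; qi < queue.size(); ++qi) {
        const int cur = queue[qi];
        for (int t = 0; t < k; ++t)
          if (sub[cur * k + t] && dist[t] < 0) {
            dist[t] = dist[cur] + 1;
            queue.push_back(t);
          }
      }
      for (int t = 0; t < k; ++t)
        if (t != s && dist[t] > 0) acc += 1.0 / dist[t];
    }
    out[v] = acc / ((double)k * (k - 1));
  }
  return out;
}
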