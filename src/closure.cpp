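#include <Rcpp.h>
using namespace Rcpp;

// Incremental transitive closure over the weak-preference relation.
//
// W is an n x n raw matrix with W(i,j) == 1 meaning "state i is weakly
// preferred to state j" (reflexive; strict preference is W(i,j) & !W(j,i)).
// prov records how each ordered pair first became known:
//   0 undecided, 1 judged, 2 dominance, 3 implied (transitivity /
//   ceteris-paribus replication of a judged trade-off).
//
// Adding edge x -> y makes every ancestor of x weakly preferred to every
// descendant of y; only entries that flip 0 -> 1 receive a provenance code.

// [[Rcpp::export]]
void pref_add_edges(RawMatrix W, RawMatrix prov,
                    IntegerVector xs, IntegerVector ys, IntegerVector codes) {
  const int n = W.nrow();
  std::vector<int> A, D;
  A.reserve(n); D.reserve(n);
  for (int e = 0; e < xs.size(); ++e) {
    const int x = xs[e] - 1, y = ys[e] - 1;
    if (x == y) continue;
    if (W(x, y)) continue;  // already known, nothing new can be implied
    A.clear(); D.clear();
    for (int u = 0; u < n; ++u) if (u == x || W(u, x)) A.push_back(u);
    for (int v = 0; v < n; ++v) if (v == y || W(y, v)) D.push_back(v);
    const Rbyte code = static_cast<Rbyte>(codes[e]);
    Rbyte *w = W.begin(), *p = prov.begin();
    for (size_t iv = 0; iv < D.size(); ++iv) {   // column-major: v outer
      const int v = D[iv];
      Rbyte *wc = w + static_cast<size_t>(v) * n;
      Rbyte *pc = p + static_cast<size_t>(v) * n;
      for (size_t iu = 0; iu < A.size(); ++iu) {
        const int u = A[iu];
        if (u == v || wc[u]) continue;
        wc[u] = 1;
        pc[u] = (u == x && v == y) ? code : static_cast<Rbyte>(3);
      }
    }
  }
}

// Decision status for a batch of unordered pairs: 0 undecided, 1 a>b, 2 b>a,
// 3 indifferent (both directions weakly preferred).

// [[Rcpp::export]]
IntegerVector pref_status(RawMatrix W, IntegerVector as, IntegerVector bs) {
  IntegerVector out(as.size());
  for (int i = 0; i < as.size(); ++i) {
    const int a = as[i] - 1, b = bs[i] - 1;
    const bool ab = W(a, b), ba = W(b, a);
    out[i] = ab ? (ba ? 3 : 1) : (ba ? 2 : 0);
  }
  return out;
}
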