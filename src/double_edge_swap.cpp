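#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Degree-preserving double-edge swap chain on a simple undirected graph.
//
// Edges are given as a 2-column matrix of 1-based vertex indices. Each
// attempt picks two distinct edge slots uniformly at random, picks one of the
// two endpoint re-pairings at random, and accepts the rewire only if it
// creates neither a self-loop nor a parallel edge. Rewired rows keep their
// slot, so any per-row payload (e.g. an edge weight) travels with the first
// parent edge of its slot. Uses R's RNG stream so results are reproducible
// under set.seed().
//
// Edge existence is tracked in a dense bit matrix when it fits in ~8 MB
// (n <= 8192), which keeps the inner loop cache-resident; larger graphs fall
// back to a hash set of canonical edge keys.

class EdgeSet {
  bool dense;
  int n;
  std::vector<uint64_t> bits;          // row-major upper+lower mirror
  std::unordered_set<long long> hset;
  long long stride;

  inline size_t word(int a, int b) const {
    return (static_cast<size_t>(a - 1) * n + (b - 1)) >> 6;
  }
  inline uint64_t mask(int a, int b) const {
    return 1ULL << ((static_cast<size_t>(a - 1) * n + (b - 1)) & 63);
  }
  inline long long key(int a, int b) const {
    if (a > b) std::swap(a, b);
    return static_cast<long long>(a) * stride + b;
  }

public:
  EdgeSet(int n_nodes, int m) : n(n_nodes), stride(n_nodes + 1) {
    dense = static_cast<long long>(n) * n <= (1LL << 26);  // <= 8 MB of bits
    if (dense) bits.assign((static_cast<size_t>(n) * n + 63) / 64, 0ULL);
    else hset.reserve(static_cast<size_t>(m) * 2);
  }
  inline bool has(int a, int b) const {
    if (dense) return (bits[word(a, b)] & mask(a, b)) != 0;
    return hset.count(key(a, b)) != 0;
  }
  inline void insert(int a, int b) {
    if (dense) {
      bits[word(a, b)] |= mask(a, b);
      bits[word(b, a)] |= mask(b, a);
    } else hset.insert(key(a, b));
  }
  inline void erase(int a, int b) {
    if (dense) {
      bits[word(a, b)] &= ~mask(a, b);
      bits[word(b, a)] &= ~mask(b, a);
    } else hset.erase(key(a, b));
  }
};

// [[Rcpp::export]]
List double_edge_swap_cpp(IntegerMatrix edges, int n_nodes, int n_attempts) {
  const int m = edges.nrow();
  std::vector<int> from(m), to(m);
  EdgeSet eset(n_nodes, m);
  for (int e = 0; e < m; ++e) {
    from[e] = edges(e, 0);
    to[e] = edges(e, 1);
    eset.insert(from[e], to[e]);
  }

  int accepted = 0;
  for (int t = 0; t < n_attempts; ++t) {
    int i = static_cast<int>(unif_rand() * m);
    int j = static_cast<int>(unif_rand() * m);
    if (i >= m) i = m - 1;
    if (j >= m) j = m - 1;
    if (i == j) continue;
    int a = from[i], b = to[i];
    int c = from[j], d = to[j];
    // two possible re-pairings: (a,d)+(c,b) or (a,c)+(b,d)
    if (unif_rand() < 0.5) std::swap(c, d);
    // proposal: replace (a,b),(from[j],to[j]) with (a,d),(c,b)
    if (a == d || c == b) continue;                       // self-loop
    if ((a == c && d == b) || (a == b && c == d)) continue;
    if (eset.has(a, d) || eset.has(c, b)) continue;       // parallel edge
    eset.erase(a, b);
    eset.erase(from[j], to[j]);
    eset.insert(a, d);
    eset.insert(c, b);
    from[i] = a; to[i] = d;
    from[j] = c; to[j] = b;
    ++accepted;
  }

  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    out(e, 0) = from[e];
    out(e, 1) = to[e];
  }
  return List::create(_["edges"] = out,
                      _["attempts"] = n_attempts,
                      _["accepted"] = accepted);
}
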