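#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Node ids: leaves 1..n (sorted label order), internal node of rank t is
// n + t.  A tree arrives as its (n-1) x 2 merge matrix: row t holds the
// ids of the two blocks merged at rank t.  During path construction the
// identity of "the node of rank t" changes, so the working tree keeps
// parent/child pointers plus a rank <-> node bijection.

struct WorkTree {
  int n;
  std::vector<int> par, ch1, ch2, rankof, noderank, minleaf;

  explicit WorkTree(const IntegerMatrix &m) {
    n = m.nrow() + 1;
    int tot = 2 * n;  // 1-based, ids up to 2n-1
    par.assign(tot, 0);
    ch1.assign(tot, 0);
    ch2.assign(tot, 0);
    rankof.assign(tot, 0);
    noderank.assign(n, 0);  // index 1..n-1
    minleaf.assign(tot, 0);
    for (int i = 1; i <= n; ++i) minleaf[i] = i;
    for (int t = 1; t <= n - 1; ++t) {
      int v = n + t, a = m(t - 1, 0), b = m(t - 1, 1);
      if (a < 1 || b < 1 || a >= v || b >= v || a == b)
        stop("malformed merge matrix");
      ch1[v] = a;
      ch2[v] = b;
      par[a] = v;
      par[b] = v;
      rankof[v] = t;
      noderank[t] = v;
      minleaf[v] = std::min(minleaf[a], minleaf[b]);
    }
  }

  // NNI on the edge [rank t, rank t+1]: child `w_out` of the lower node
  // u is exchanged with the upper node's other child subtree c
  void nni(int u, int v, int w_in, int w_out, int c) {
    ch1[u] = w_in;
    ch2[u] = c;
    par[c] = u;
    ch1[v] = u;
    ch2[v] = w_out;
    par[w_out] = v;
    minleaf[u] = std::min(minleaf[w_in], minleaf[c]);
  }

  void rank_swap(int t) {
    int u = noderank[t], v = noderank[t + 1];
    noderank[t] = v;
    noderank[t + 1] = u;
    rankof[u] = t + 1;
    rankof[v] = t;
  }

  // canonical merge matrix of the current tree
  IntegerMatrix merge() const {
    IntegerMatrix m(n - 1, 2);
    for (int t = 1; t <= n - 1; ++t) {
      int v = noderank[t];
      int a = ch1[v] <= n ? ch1[v] : n + rankof[ch1[v]];
      int b = ch2[v] <= n ? ch2[v] : n + rankof[ch2[v]];
      m(t - 1, 0) = std::min(a, b);
      m(t - 1, 1) = std::max(a, b);
    }
    return m;
  }

  void leaves_below(int node, std::vector<int> &out) const {
    if (node <= n) {
      out.push_back(node);
      return;
    }
    leaves_below(ch1[node], out);
    leaves_below(ch2[node], out);
  }
};

// destination clusters as leaf-id lists, one per rank
static std::vector<std::vector<int> > dest_clusters(const IntegerMatrix &m) {
  int n = m.nrow() + 1;
  std::vector<std::vector<int> > cl(n);  // index 1..n-1
  for (int t = 1; t <= n - 1; ++t) {
    for (int s = 0; s < 2; ++s) {
      int c = m(t - 1, s);
      if (c <= n)
        cl[t].push_back(c);
      else
        cl[t].insert(cl[t].end(), cl[c - n].begin(), cl[c - n].end());
    }
  }
  return cl;
}

// FindPath between the trees given by merge matrices (shared leaf-id
// space).  record: 0 = counts only, 1 = compact move list (interval t,
// kind, which child of the lower node is swapped out, children ordered
// by smallest descendant leaf), 2 = additionally the swapped-out leaf
// sets.  Scanning the destination's clusters in rank order, the most
// recent common ancestor of each is pulled down one rank per move; each
// move is O(1) and the mrca is located once per cluster, giving O(n^2)
// total time for the move count.
// [[Rcpp::export(name = ".fp_core")]]
List fp_core(IntegerMatrix mergeT, IntegerMatrix mergeR, int record) {
  if (mergeT.nrow() != mergeR.nrow())
    stop("trees must have the same number of leaves");
  WorkTree T1(mergeT);
  int n = T1.n;
  std::vector<std::vector<int> > clR = dest_clusters(mergeR);

  std::vector<char> inC(n + 1, 0);
  std::vector<int> cnt(2 * n, 0);
  long long n_nni = 0, n_rank = 0;
  std::vector<int> mv_t, mv_kind, mv_which;
  List mv_swap;

  for (int k = 1; k <= n - 2; ++k) {
    const std::vector<int> &C = clR[k];
    int sz = (int)C.size();
    for (size_t i = 0; i < C.size(); ++i) inC[C[i]] = 1;
    // subtree counts in current rank order (children have lower ranks)
    int r = -1;
    for (int t = 1; t <= n - 1; ++t) {
      int v = T1.noderank[t];
      int a = T1.ch1[v], b = T1.ch2[v];
      int ca = a <= n ? inC[a] : cnt[a];
      int cb = b <= n ? inC[b] : cnt[b];
      cnt[v] = ca + cb;
      if (r < 0 && cnt[v] == sz) r = t;
    }
    if (r < k) stop("internal error: mrca below target rank");
    while (r > k) {
      int u = T1.noderank[r - 1], v = T1.noderank[r];
      if (T1.par[u] != v) {
        T1.rank_swap(r - 1);
        ++n_rank;
        if (record > 0) {
          mv_t.push_back(r - 1);
          mv_kind.push_back(0);
          mv_which.push_back(0);
          if (record > 1) mv_swap.push_back(R_NilValue);
        }
      } else {
        int c = T1.ch1[v] == u ? T1.ch2[v] : T1.ch1[v];
        int w1 = T1.ch1[u], w2 = T1.ch2[u];
        int c1 = w1 <= n ? inC[w1] : cnt[w1];
        int c2 = w2 <= n ? inC[w2] : cnt[w2];
        if ((c1 > 0) == (c2 > 0))
          stop("internal error: ambiguous NNI step");
        int w_in = c1 > 0 ? w1 : w2, w_out = c1 > 0 ? w2 : w1;
        if (record > 0) {
          mv_t.push_back(r - 1);
          mv_kind.push_back(1);
          mv_which.push_back(
              T1.minleaf[w_out] < T1.minleaf[w_in] ? 1 : 2);
          if (record > 1) {
            std::vector<int> lv;
            T1.leaves_below(w_out, lv);
            std::sort(lv.begin(), lv.end());
            mv_swap.push_back(IntegerVector(lv.begin(), lv.end()));
          }
        }
        T1.nni(u, v, w_in, w_out, c);
        cnt[u] = sz;
        ++n_nni;
      }
      --r;
    }
    for (size_t i = 0; i < C.size(); ++i) inC[C[i]] = 0;
  }

  List out = List::create(
      _["n_nni"] = (double)n_nni, _["n_rank"] = (double)n_rank);
  if (record > 0) {
    out["t"] = IntegerVector(mv_t.begin(), mv_t.end());
    out["kind"] = IntegerVector(mv_kind.begin(), mv_kind.end());
    out["which"] = IntegerVector(mv_which.begin(), mv_which.end());
  }
  if (record > 1) out["swap"] = mv_swap;
  return out;
}

// Independent replay of a compact move list: applies each move by its
// interval rank and (for NNI) the swapped-out child's position among the
// lower node's children ordered by smallest descendant leaf.  Returns
// the canonical merge matrix of the final tree.
// [[Rcpp::export(name = ".fp_replay")]]
IntegerMatrix fp_replay(IntegerMatrix mergeT, IntegerVector t,
                        IntegerVector kind, IntegerVector which) {
  WorkTree T1(mergeT);
  int n = T1.n;
  int m = t.size();
  for (int i = 0; i < m; ++i) {
    int ti = t[i];
    if (ti < 1 || ti > n - 2) stop("move interval out of range");
    int u = T1.noderank[ti], v = T1.noderank[ti + 1];
    if (kind[i] == 0) {
      if (T1.par[u] == v) stop("rank move on an edge interval");
      T1.rank_swap(ti);
    } else {
      if (T1.par[u] != v) stop("NNI move on a non-edge interval");
      int w1 = T1.ch1[u], w2 = T1.ch2[u];
      int lo = T1.minleaf[w1] < T1.minleaf[w2] ? w1 : w2;
      int hi = lo == w1 ? w2 : w1;
      int w_out = which[i] == 1 ? lo : hi;
      int w_in = w_out == w1 ? w2 : w1;
      int c = T1.ch1[v] == u ? T1.ch2[v] : T1.ch1[v];
      T1.nni(u, v, w_in, w_out, c);
    }
  }
  return T1.merge();
}
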