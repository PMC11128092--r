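// Partial-order alignment (POA), pairwise global alignment maps, weighted
// monotone subsequence selection, and pairwise column mismatch counting.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <set>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Graph {
  std::vector<char> base;
  std::vector<std::vector<int>> pred, succ;
  std::vector<int> ringOf;
  std::vector<std::vector<int>> rings;
  std::unordered_map<long long, int> esup;
  std::vector<std::vector<int>> paths;

  int addNode(char b, int ring = -1) {
    int id = (int)base.size();
    base.push_back(b);
    pred.emplace_back();
    succ.emplace_back();
    if (ring < 0) {
      ringOf.push_back((int)rings.size());
      rings.push_back({id});
    } else {
      ringOf.push_back(ring);
      rings[ring].push_back(id);
    }
    return id;
  }
  void addEdge(int u, int v) {
    long long key = (long long)u * 1000000000LL + v;
    auto it = esup.find(key);
    if (it == esup.end()) {
      esup[key] = 1;
      succ[u].push_back(v);
      pred[v].push_back(u);
    } else {
      it->second++;
    }
  }
  int support(int u, int v) const {
    auto it = esup.find((long long)u * 1000000000LL + v);
    return it == esup.end() ? 0 : it->second;
  }

  std::vector<int> topo() const {
    int V = (int)base.size();
    std::vector<int> indeg(V, 0), order;
    order.reserve(V);
    for (int v = 0; v < V; v++) indeg[v] = (int)pred[v].size();
    std::priority_queue<int, std::vector<int>, std::greater<int>> pq;
    for (int v = 0; v < V; v++) if (indeg[v] == 0) pq.push(v);
    while (!pq.empty()) {
      int v = pq.top(); pq.pop();
      order.push_back(v);
      for (int w : succ[v]) if (--indeg[w] == 0) pq.push(w);
    }
    if ((int)order.size() != V) stop("POA graph is not acyclic");
    return order;
  }

  // Global alignment of seq against the graph; returns alignment score and
  // appends the sequence's node path.
  double alignSeq(const std::string& s, double ms, double mm, double gp) {
    const int L = (int)s.size();
    if (base.empty()) {
      std::vector<int> path;
      int prev = -1;
      for (int j = 0; j < L; j++) {
        int v = addNode(s[j]);
        if (prev >= 0) addEdge(prev, v);
        prev = v;
        path.push_back(v);
      }
      paths.push_back(path);
      return ms * L;
    }
    std::vector<int> order = topo();
    const int V = (int)order.size();
    std::vector<int> rowOf(V + 1, 0);
    for (int r = 0; r < V; r++) rowOf[order[r]] = r + 1;

    const double NEG = -1e18;
    std::vector<double> sc((size_t)(V + 1) * (L + 1), NEG);
    std::vector<unsigned char> mv((size_t)(V + 1) * (L + 1), 0);
    std::vector<int> pc((size_t)(V + 1) * (L + 1), -1);  // chosen pred row
    auto IX = [&](int r, int j) { return (size_t)r * (L + 1) + j; };

    for (int j = 0; j <= L; j++) { sc[IX(0, j)] = gp * j; mv[IX(0, j)] = 3; }
    mv[IX(0, 0)] = 0;

    for (int r = 1; r <= V; r++) {
      int v = order[r - 1];
      std::vector<int> prows;
      if (pred[v].empty()) prows.push_back(0);
      else {
        std::vector<int> ps(pred[v]);
        std::sort(ps.begin(), ps.end());
        for (int u : ps) prows.push_back(rowOf[u]);
      }
      for (int j = 0; j <= L; j++) {
        double best = NEG; unsigned char bmv = 0; int bpr = -1;
        for (int p : prows) {
          if (j > 0) {
            double d = sc[IX(p, j - 1)] + (base[v] == s[j - 1] ? ms : mm);
            if (d > best) { best = d; bmv = 1; bpr = p; }
          }
          double u2 = sc[IX(p, j)] + gp;
          if (u2 > best) { best = u2; bmv = 2; bpr = p; }
        }
        if (j > 0) {
          double l = sc[IX(r, j - 1)] + gp;
          if (l > best) { best = l; bmv = 3; bpr = r; }
        }
        sc[IX(r, j)] = best; mv[IX(r, j)] = bmv; pc[IX(r, j)] = bpr;
      }
    }

    // best sink (no successors), smallest node id on ties
    double best = NEG; int br = -1;
    for (int r = 1; r <= V; r++) {
      int v = order[r - 1];
      if (!succ[v].empty()) continue;
      if (sc[IX(r, L)] > best) { best = sc[IX(r, L)]; br = r; }
    }
    if (br < 0) stop("POA: no sink node");

    // backtrack: ops of (nodeOrNeg, seqIdxOrNeg)
    std::vector<std::pair<int, int>> ops;  // (node id or -1, seq idx or -1)
    int r = br, j = L;
    while (r != 0 || j != 0) {
      unsigned char m = mv[IX(r, j)];
      if (m == 1) {
        ops.push_back({order[r - 1], j - 1});
        r = pc[IX(r, j)]; j--;
      } else if (m == 2) {
        ops.push_back({order[r - 1], -1});
        r = pc[IX(r, j)];
      } else if (m == 3) {
        ops.push_back({-1, j - 1});
        j--;
      } else {
        stop("POA: bad backtrack");
      }
    }
    std::reverse(ops.begin(), ops.end());

    // thread sequence through graph
    std::vector<int> path;
    int prev = -1;
    for (auto& op : ops) {
      if (op.second < 0) continue;  // node skipped, no seq char
      int node;
      if (op.first >= 0) {
        int v = op.first;
        if (base[v] == s[op.second]) {
          node = v;
        } else {
          node = -1;
          for (int w : rings[ringOf[v]])
            if (base[w] == s[op.second]) { node = w; break; }
          if (node < 0) node = addNode(s[op.second], ringOf[v]);
        }
      } else {
        node = addNode(s[op.second]);
      }
      if (prev >= 0) addEdge(prev, node);
      prev = node;
      path.push_back(node);
    }
    paths.push_back(path);
    return best;
  }

  // one column per ring, rings topologically ordered; falls back to one
  // column per node if the ring graph is cyclic
  CharacterVector msa(int nseq) const {
    int R = (int)rings.size();
    std::vector<int> col(base.size(), -1);
    std::vector<std::set<int>> rsucc(R);
    std::vector<int> rindeg(R, 0);
    for (size_t u = 0; u < base.size(); u++)
      for (int v : succ[u]) {
        int ru = ringOf[u], rv = ringOf[v];
        if (ru != rv && rsucc[ru].insert(rv).second) rindeg[rv]++;
      }
    std::priority_queue<int, std::vector<int>, std::greater<int>> pq;
    for (int rr = 0; rr < R; rr++) if (rindeg[rr] == 0) pq.push(rr);
    std::vector<int> rorder;
    while (!pq.empty()) {
      int rr = pq.top(); pq.pop();
      rorder.push_back(rr);
      for (int v : rsucc[rr]) if (--rindeg[v] == 0) pq.push(v);
    }
    int C;
    if ((int)rorder.size() == R) {
      C = R;
      for (int c = 0; c < C; c++)
        for (int v : rings[rorder[c]]) col[v] = c;
    } else {
      std::vector<int> order = topo();
      C = (int)order.size();
      for (int c = 0; c < C; c++) col[order[c]] = c;
    }
    CharacterVector rows(nseq);
    for (int i = 0; i < nseq; i++) {
      std::string row(C, '-');
      for (int v : paths[i]) row[col[v]] = base[v];
      rows[i] = row;
    }
    return rows;
  }
};

Graph buildGraph(const CharacterVector& seqs, double ms, double mm, double gp,
                 std::vector<double>* scores) {
  Graph g;
  for (int i = 0; i < seqs.size(); i++) {
    std::string s = as<std::string>(seqs[i]);
    double sc = g.alignSeq(s, ms, mm, gp);
    if (scores) scores->push_back(sc);
  }
  return g;
}

}  // namespace

// [[Rcpp::export(name = ".poa_align_cpp")]]
List poa_align_cpp(CharacterVector seqs, double match, double mismatch,
                   double gap) {
  std::vector<double> scores;
  Graph g = buildGraph(seqs, match, mismatch, gap, &scores);
  CharacterVector rows = g.msa(seqs.size());
  return List::create(_["rows"] = rows, _["scores"] = wrap(scores));
}

// [[Rcpp::export(name = ".poa_align_many_cpp")]]
List poa_align_many_cpp(List seqlist, double match, double mismatch,
                        double gap) {
  List out(seqlist.size());
  for (int i = 0; i < seqlist.size(); i++) {
    CharacterVector seqs = seqlist[i];
    Graph g = buildGraph(seqs, match, mismatch, gap, nullptr);
    out[i] = g.msa(seqs.size());
  }
  return out;
}

// [[Rcpp::export(name = ".poa_consensus_cpp")]]
String poa_consensus_cpp(CharacterVector seqs, double match, double mismatch,
                         double gap) {
  Graph g = buildGraph(seqs, match, mismatch, gap, nullptr);
  if (g.base.empty()) return "";
  std::vector<int> order = g.topo();
  int V = (int)order.size();
  std::vector<double> W(V, 0);
  std::vector<int> par(V, -1);
  std::vector<int> rowOf(V, 0);
  for (int r = 0; r < V; r++) rowOf[order[r]] = r;
  double best = -1; int bestv = -1;
  for (int r = 0; r < V; r++) {
    int v = order[r];
    double w = 0; int p = -1;
    std::vector<int> ps(g.pred[v]);
    std::sort(ps.begin(), ps.end());
    for (int u : ps) {  // ascending ids: strict > keeps the smallest on ties
      double cand = W[rowOf[u]] + g.support(u, v);
      if (cand > w) { w = cand; p = u; }
    }
    W[r] = w; par[v] = p;
    if (g.succ[v].empty()) {
      if (w > best || (w == best && (bestv < 0 || v < bestv))) {
        best = w; bestv = v;
      }
    }
  }
  std::string cons;
  for (int v = bestv; v >= 0; v = par[v]) cons.push_back(g.base[v]);
  std::reverse(cons.begin(), cons.end());
  return cons;
}

// Global pairwise alignments; for each (ref, qry) pair returns an integer
// vector of length nchar(qry): the 0-based ref offset each query base aligns
// to, or -1 for an insertion.  Pairs whose DP matrix would exceed max_cells
// are returned fully unaligned.
// [[Rcpp::export(name = ".nw_map_many_cpp")]]
List nw_map_many_cpp(CharacterVector refs, CharacterVector qrys, double match,
                     double mismatch, double gap, double max_cells) {
  if (refs.size() != qrys.size()) stop("length mismatch");
  List out(refs.size());
  for (int k = 0; k < refs.size(); k++) {
    std::string a = as<std::string>(refs[k]);   // reference
    std::string b = as<std::string>(qrys[k]);   // query
    const int n = (int)a.size(), m = (int)b.size();
    IntegerVector map(m, -1);
    double cells = ((double)n + 1) * ((double)m + 1);
    if (n == 0 || m == 0 || cells > max_cells) { out[k] = map; continue; }
    std::vector<double> sc((size_t)(n + 1) * (m + 1));
    std::vector<unsigned char> mv((size_t)(n + 1) * (m + 1));
    auto IX = [&](int i, int j) { return (size_t)i * (m + 1) + j; };
    sc[0] = 0; mv[0] = 0;
    for (int i = 1; i <= n; i++) { sc[IX(i, 0)] = gap * i; mv[IX(i, 0)] = 2; }
    for (int j = 1; j <= m; j++) { sc[IX(0, j)] = gap * j; mv[IX(0, j)] = 3; }
    for (int i = 1; i <= n; i++) {
      for (int j = 1; j <= m; j++) {
        double d = sc[IX(i - 1, j - 1)] + (a[i - 1] == b[j - 1] ? match : mismatch);
        double u = sc[IX(i - 1, j)] + gap;
        double l = sc[IX(i, j - 1)] + gap;
        double best = d; unsigned char bm = 1;
        if (u > best) { best = u; bm = 2; }
        if (l > best) { best = l; bm = 3; }
        sc[IX(i, j)] = best; mv[IX(i, j)] = bm;
      }
    }
    int i = n, j = m;
    while (i > 0 || j > 0) {
      unsigned char m2 = mv[IX(i, j)];
      if (m2 == 1) { map[j - 1] = i - 1; i--; j--; }
      else if (m2 == 2) { i--; }
      else { j--; }
    }
    out[k] = map;
  }
  return out;
}

// Maximum-weight strictly monotone subsequence.  Items are taken in input
// order; chosen items must have strictly increasing (or, with decreasing =
// TRUE, strictly decreasing) values.  Returns 1-based indices of the chosen
// items.  Fenwick tree over compressed values; O(k log k).
// [[Rcpp::export(name = ".wis_cpp")]]
IntegerVector wis_cpp(IntegerVector pos, NumericVector w, bool decreasing) {
  const int k = pos.size();
  if (k == 0) return IntegerVector(0);
  std::vector<long long> v(k);
  for (int i = 0; i < k; i++)
    v[i] = decreasing ? -(long long)pos[i] : (long long)pos[i];
  std::vector<long long> sorted(v);
  std::sort(sorted.begin(), sorted.end());
  sorted.erase(std::unique(sorted.begin(), sorted.end()), sorted.end());
  const int M = (int)sorted.size();
  // Fenwick storing (best dp, item index); prefix max
  std::vector<double> fw(M + 1, -1);
  std::vector<int> fi(M + 1, -1);
  std::vector<double> dp(k);
  std::vector<int> par(k, -1);
  auto query = [&](int r, double& bw, int& bi) {  // max over ranks [1, r]
    bw = -1; bi = -1;
    for (; r > 0; r -= r & (-r))
      if (fw[r] > bw) { bw = fw[r]; bi = fi[r]; }
  };
  auto update = [&](int r, double val, int idx) {
    for (; r <= M; r += r & (-r))
      if (val > fw[r]) { fw[r] = val; fi[r] = idx; }
  };
  double best = -1; int bi = -1;
  for (int i = 0; i < k; i++) {
    int r = (int)(std::lower_bound(sorted.begin(), sorted.end(), v[i]) -
                  sorted.begin()) + 1;
    double pw; int pi;
    query(r - 1, pw, pi);
    dp[i] = w[i] + (pw > 0 ? pw : 0);
    par[i] = (pw > 0) ? pi : -1;
    update(r, dp[i], i);
    if (dp[i] > best) { best = dp[i]; bi = i; }
  }
  std::vector<int> chain;
  for (int i = bi; i >= 0; i = par[i]) chain.push_back(i + 1);
  std::reverse(chain.begin(), chain.end());
  return wrap(chain);
}

// Pairwise mismatch / comparable-column counts over equal-length gapped rows.
// Only columns where both rows have a base in {A,C,G,T} are comparable.
// [[Rcpp::export(name = ".pair_counts_cpp")]]
List pair_counts_cpp(CharacterVector rows) {
  const int G = rows.size();
  if (G == 0) stop("no rows");
  std::vector<const char*> p(G);
  int L = LENGTH(STRING_ELT(rows, 0));
  for (int g = 0; g < G; g++) {
    p[g] = CHAR(STRING_ELT(rows, g));
    if (LENGTH(STRING_ELT(rows, g)) != L) stop("row length mismatch");
  }
  std::vector<unsigned char> ok(256, 0);
  ok['A'] = ok['C'] = ok['G'] = ok['T'] = 1;
  IntegerMatrix diff(G, G), comp(G, G);
  for (int i = 0; i < G; i++) {
    for (int j = i + 1; j < G; j++) {
      int d = 0, c = 0;
      const char* a = p[i];
      const char* b = p[j];
      for (int t = 0; t < L; t++) {
        if (ok[(unsigned char)a[t]] && ok[(unsigned char)b[t]]) {
          c++;
          if (a[t] != b[t]) d++;
        }
      }
      diff(i, j) = diff(j, i) = d;
      comp(i, j) = comp(j, i) = c;
    }
  }
  return List::create(_["diff"] = diff, _["comp"] = comp);
}
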