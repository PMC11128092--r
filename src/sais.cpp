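// Multi-genome maximal unique match (MUM) detection.
//
// Builds a generalized suffix array (SA-IS, linear time) over the forward and
// reverse-complement strands of every genome.  Separators and N characters
// are encoded as a shared sentinel byte; the LCP array is computed with
// sentinel-aware equality (a sentinel matches nothing, itself included), so
// matches can never span a separator.  MUMs are read off the LCP array as
// windows of exactly G suffixes, one per genome, whose common prefix is
// longer than the LCP to either neighbour (uniqueness) and whose preceding
// characters are not all identical bases (left-maximality).

#include <Rcpp.h>
#include <vector>
#include <deque>
#include <algorithm>
#include <cstring>
#include <cstdint>

using namespace Rcpp;

namespace {

typedef std::vector<int> ivec;

template <typename TT>
inline bool isLMS(const std::vector<uint8_t>& t, int i) {
  return i > 0 && t[i] && !t[i - 1];
}

template <typename TT>
void getBuckets(const TT* T, int* bkt, int n, int K, bool end) {
  std::fill(bkt, bkt + K, 0);
  for (int i = 0; i < n; i++) bkt[T[i]]++;
  int sum = 0;
  for (int i = 0; i < K; i++) { sum += bkt[i]; bkt[i] = end ? sum : sum - bkt[i]; }
}

template <typename TT>
void induceSAl(const std::vector<uint8_t>& t, int* SA, const TT* T, int* bkt,
               int n, int K) {
  getBuckets(T, bkt, n, K, false);
  for (int i = 0; i < n; i++) {
    int j = SA[i] - 1;
    if (SA[i] > 0 && !t[j]) SA[bkt[T[j]]++] = j;
  }
}

template <typename TT>
void induceSAs(const std::vector<uint8_t>& t, int* SA, const TT* T, int* bkt,
               int n, int K) {
  getBuckets(T, bkt, n, K, true);
  for (int i = n - 1; i >= 0; i--) {
    int j = SA[i] - 1;
    if (SA[i] > 0 && t[j]) SA[--bkt[T[j]]] = j;
  }
}

// T[n-1] must be the unique smallest character.
template <typename TT>
void SA_IS(const TT* T, int* SA, int n, int K) {
  std::vector<uint8_t> t(n);
  t[n - 1] = 1;
  for (int i = n - 2; i >= 0; i--)
    t[i] = (T[i] < T[i + 1]) || (T[i] == T[i + 1] && t[i + 1]);
  std::vector<int> bktv(K);
  int* bkt = bktv.data();

  getBuckets(T, bkt, n, K, true);
  std::fill(SA, SA + n, -1);
  for (int i = 1; i < n; i++)
    if (isLMS<TT>(t, i)) SA[--bkt[T[i]]] = i;
  induceSAl(t, SA, T, bkt, n, K);
  induceSAs(t, SA, T, bkt, n, K);

  int n1 = 0;
  for (int i = 0; i < n; i++)
    if (SA[i] > 0 && isLMS<TT>(t, SA[i])) SA[n1++] = SA[i];
  std::fill(SA + n1, SA + n, -1);

  int name = 0, prev = -1;
  for (int i = 0; i < n1; i++) {
    int pos = SA[i];
    bool diff = false;
    for (int d = 0; d < n; d++) {
      if (prev == -1 || T[pos + d] != T[prev + d] || t[pos + d] != t[prev + d]) {
        diff = true; break;
      } else if (d > 0 && (isLMS<TT>(t, pos + d) || isLMS<TT>(t, prev + d))) {
        break;
      }
    }
    if (diff) { name++; prev = pos; }
    int p2 = pos / 2;
    SA[n1 + p2] = name - 1;
  }
  for (int i = n - 1, j = n - 1; i >= n1; i--)
    if (SA[i] >= 0) SA[j--] = SA[i];

  int* SA1 = SA;
  int* s1 = SA + n - n1;
  if (name < n1) {
    SA_IS<int>(s1, SA1, n1, name);
  } else {
    for (int i = 0; i < n1; i++) SA1[s1[i]] = i;
  }

  getBuckets(T, bkt, n, K, true);
  for (int i = 1, j = 0; i < n; i++)
    if (isLMS<TT>(t, i)) s1[j++] = i;
  for (int i = 0; i < n1; i++) SA1[i] = s1[SA1[i]];
  std::fill(SA + n1, SA + n, -1);
  for (int i = n1 - 1; i >= 0; i--) {
    int j = SA[i]; SA[i] = -1;
    SA[--bkt[T[j]]] = j;
  }
  induceSAl(t, SA, T, bkt, n, K);
  induceSAs(t, SA, T, bkt, n, K);
}

// Kasai's algorithm with sentinel-aware equality: characters < BASE0 (the
// terminator and the shared sentinel) match nothing, so LCP values never
// span a separator.  lcp[i] = lcp(suffix SA[i-1], suffix SA[i]); lcp[0] = 0.
const int BASE0 = 2;  // codes: 0 terminator, 1 sentinel, 2..5 = A,C,G,T

void kasai(const uint8_t* T, const int* SA, int* lcp, int n) {
  std::vector<int> rank(n);
  for (int i = 0; i < n; i++) rank[SA[i]] = i;
  int h = 0;
  lcp[0] = 0;
  for (int i = 0; i < n; i++) {
    if (rank[i] > 0) {
      int j = SA[rank[i] - 1];
      while (i + h < n && j + h < n && T[i + h] == T[j + h] &&
             T[i + h] >= BASE0) h++;
      lcp[rank[i]] = h;
      if (h > 0) h--;
    } else {
      h = 0;
    }
  }
}

inline uint8_t comp_code(uint8_t c) {
  // codes 2..5 = A,C,G,T
  return (uint8_t)(7 - c);
}

struct Mum {
  int len;
  std::vector<int> pos;   // forward-strand 0-based position per genome
  std::vector<uint8_t> fwd;
};

}  // namespace

// [[Rcpp::export(name = ".find_mums_cpp")]]
List find_mums_cpp(CharacterVector seqs, int min_len) {
  const int G = seqs.size();
  if (G < 2) stop("need at least 2 genomes");

  std::vector<const char*> ptr(G);
  std::vector<int> glen(G);
  long long total = 0;
  for (int g = 0; g < G; g++) {
    ptr[g] = CHAR(STRING_ELT(seqs, g));
    glen[g] = LENGTH(STRING_ELT(seqs, g));
    total += glen[g];
  }
  long long N64 = 2 * total + 2LL * G + 1;  // strands + separators + term
  if (N64 >= INT32_MAX) stop("combined genome size too large");
  const int N = (int)N64;

  std::vector<signed char> code(256, -1);
  code['A'] = 2; code['C'] = 3; code['G'] = 4; code['T'] = 5;

  std::vector<uint8_t> T(N);
  std::vector<int16_t> gid(N);
  std::vector<int> fwd_start(G), rev_start(G);
  int k = 0;
  for (int g = 0; g < G; g++) {
    fwd_start[g] = k;
    for (int i = 0; i < glen[g]; i++) {
      signed char c = code[(unsigned char)ptr[g][i]];
      T[k] = (c >= 0) ? (uint8_t)c : (uint8_t)1;
      gid[k] = (int16_t)g;
      k++;
    }
    T[k] = 1; gid[k] = -1; k++;
    rev_start[g] = k;
    for (int i = glen[g] - 1; i >= 0; i--) {
      signed char c = code[(unsigned char)ptr[g][i]];
      T[k] = (c >= 0) ? comp_code((uint8_t)c) : (uint8_t)1;
      gid[k] = (int16_t)g;
      k++;
    }
    T[k] = 1; gid[k] = -1; k++;
  }
  T[k] = 0; gid[k] = -1; k++;  // unique terminator

  ivec SA(N);
  SA_IS<uint8_t>(T.data(), SA.data(), N, 6);
  ivec lcp(N);
  kasai(T.data(), SA.data(), lcp.data(), N);

  // mark sentinel-start suffixes in gid == -1 already; slide a window of
  // exactly G suffixes over the SA
  std::vector<Mum> out;
  std::vector<int> cnt(G, 0);
  int once = 0;   // genomes covered exactly once
  int bad = 0;    // sentinel suffixes in window
  std::deque<int> mq;  // indices into lcp, increasing, values increasing

  auto addEntry = [&](int idx) {
    int g = gid[SA[idx]];
    if (g < 0) { bad++; return; }
    cnt[g]++;
    if (cnt[g] == 1) once++;
    else if (cnt[g] == 2) once--;
  };
  auto delEntry = [&](int idx) {
    int g = gid[SA[idx]];
    if (g < 0) { bad--; return; }
    if (cnt[g] == 1) once--;
    else if (cnt[g] == 2) once++;
    cnt[g]--;
  };

  for (int j = 0; j < G - 1 && j < N; j++) addEntry(j);
  for (int j = 1; j <= G - 2 && j < N; j++) {  // prime interior lcp deque
    while (!mq.empty() && lcp[j] <= lcp[mq.back()]) mq.pop_back();
    mq.push_back(j);
  }
  for (int i = 0; i + G <= N; i++) {
    // window [i, i+G); interior lcp indices i+1 .. i+G-1
    addEntry(i + G - 1);
    if (i > 0) delEntry(i - 1);
    int lo = i + 1, hi = i + G - 1;
    while (!mq.empty() && mq.front() < lo) mq.pop_front();
    while (!mq.empty() && lcp[hi] <= lcp[mq.back()]) mq.pop_back();
    mq.push_back(hi);

    if (bad > 0 || once != G) continue;
    int m = lcp[mq.front()];
    if (m < min_len) continue;
    if (i > 0 && lcp[i] >= m) continue;
    if (i + G < N && lcp[i + G] >= m) continue;

    // left-maximality: preceding characters must not all be the same base
    bool extensible = true;
    int c0 = -2;
    for (int j = i; j < i + G; j++) {
      int p = SA[j];
      int c = (p > 0) ? T[p - 1] : -1;
      if (c < BASE0) { extensible = false; break; }
      if (c0 == -2) c0 = c;
      else if (c != c0) { extensible = false; break; }
    }
    if (extensible) continue;

    // reference occurrence must lie on the forward strand
    Mum mm; mm.len = m;
    mm.pos.assign(G, -1); mm.fwd.assign(G, 1);
    bool reffwd = true;
    for (int j = i; j < i + G; j++) {
      int p = SA[j];
      int g = gid[p];
      if (p < rev_start[g]) {
        mm.pos[g] = p - fwd_start[g];
        mm.fwd[g] = 1;
      } else {
        int off = p - rev_start[g];
        mm.pos[g] = glen[g] - off - m;
        mm.fwd[g] = 0;
        if (g == 0) reffwd = false;
      }
    }
    if (!reffwd) continue;
    out.push_back(std::move(mm));
  }

  // sort by reference position, drop shorter anchors sharing a ref start
  std::sort(out.begin(), out.end(), [](const Mum& a, const Mum& b) {
    if (a.pos[0] != b.pos[0]) return a.pos[0] < b.pos[0];
    return a.len > b.len;
  });
  std::vector<const Mum*> keep;
  for (size_t i = 0; i < out.size(); i++)
    if (i == 0 || out[i].pos[0] != out[i - 1].pos[0]) keep.push_back(&out[i]);

  const int M = (int)keep.size();
  IntegerVector len(M);
  IntegerMatrix pos(M, G);
  LogicalMatrix fwd(M, G);
  for (int i = 0; i < M; i++) {
    len[i] = keep[i]->len;
    for (int g = 0; g < G; g++) {
      pos(i, g) = keep[i]->pos[g];
      fwd(i, g) = keep[i]->fwd[g] == 1;
    }
  }
  return List::create(_["length"] = len, _["pos"] = pos, _["fwd"] = fwd);
}
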