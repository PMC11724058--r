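#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>

using namespace Rcpp;

// Hamming distance with early exit once d exceeds maxd.
static inline int hamming_capped(const char* a, const char* b, int n, int maxd) {
  int d = 0;
  for (int i = 0; i < n; ++i) {
    if (a[i] != b[i] && ++d > maxd) return d;
  }
  return d;
}

// Assign each query barcode to a whitelist entry.
// Returns 1-based whitelist index; 0 = unassigned; -1 = ambiguous.
// Exact matches win immediately; otherwise the unique entry within
// max_mismatch is taken, ties at the minimum distance are ambiguous.
// [[Rcpp::export]]
IntegerVector cpp_assign_barcodes(CharacterVector queries,
                                  CharacterVector whitelist,
                                  int max_mismatch) {
  int nq = queries.size(), nw = whitelist.size();
  std::vector<std::string> wl(nw);
  std::unordered_map<std::string, int> exact;
  exact.reserve(nw * 2);
  for (int j = 0; j < nw; ++j) {
    wl[j] = as<std::string>(whitelist[j]);
    exact[wl[j]] = j + 1;
  }
  int blen = nw > 0 ? (int) wl[0].size() : 0;
  // cache decisions for repeated observed barcodes
  std::unordered_map<std::string, int> seen;
  IntegerVector out(nq);
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    if ((int) q.size() != blen) stop("barcode length mismatch at query %d", i + 1);
    std::unordered_map<std::string, int>::iterator hit = exact.find(q);
    if (hit != exact.end()) { out[i] = hit->second; continue; }
    if (max_mismatch < 1) { out[i] = 0; continue; }
    std::unordered_map<std::string, int>::iterator memo = seen.find(q);
    if (memo != seen.end()) { out[i] = memo->second; continue; }
    int best = max_mismatch + 1, nbest = 0, ibest = 0;
    for (int j = 0; j < nw; ++j) {
      int d = hamming_capped(q.c_str(), wl[j].c_str(), blen, max_mismatch);
      if (d < best) { best = d; nbest = 1; ibest = j + 1; }
      else if (d == best) { ++nbest; }
    }
    int res;
    if (best > max_mismatch) res = 0;
    else if (nbest > 1) res = -1;
    else res = ibest;
    seen[q] = res;
    out[i] = res;
  }
  return out;
}

// Leftmost start (0-based) of an adapter-prefix occurrence with at most
// max_err mismatches and overlap >= min_overlap; -1 if absent.
// [[Rcpp::export]]
IntegerVector cpp_trim_positions(CharacterVector inserts,
                                 std::string adapter,
                                 int min_overlap,
                                 int max_err) {
  int n = inserts.size();
  int alen = (int) adapter.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(inserts[i]);
    int slen = (int) s.size();
    int pos = -1;
    for (int p = 0; p + min_overlap <= slen; ++p) {
      int L = std::min(alen, slen - p);
      int d = hamming_capped(s.c_str() + p, adapter.c_str(), L, max_err);
      if (d <= max_err) { pos = p; break; }
    }
    out[i] = pos;
  }
  return out;
}

// Connected components of the Hamming<=max_dist graph over UMIs.
// Input: unique UMIs of equal length. Returns 1-based component ids.
// [[Rcpp::export]]
IntegerVector cpp_umi_components(CharacterVector umis, int max_dist) {
  int n = umis.size();
  std::vector<std::string> u(n);
  for (int i = 0; i < n; ++i) u[i] = as<std::string>(umis[i]);
  int L = n > 0 ? (int) u[0].size() : 0;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  // union-find with path halving
  struct UF {
    std::vector<int>& p;
    UF(std::vector<int>& p) : p(p) {}
    int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
    void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[b] = a; }
  } uf(parent);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (hamming_capped(u[i].c_str(), u[j].c_str(), L, max_dist) <= max_dist)
        uf.unite(i, j);
    }
  }
  std::unordered_map<int, int> relabel;
  IntegerVector out(n);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf.find(i);
    std::unordered_map<int, int>::iterator it = relabel.find(r);
    if (it == relabel.end()) { relabel[r] = ++next; out[i] = next; }
    else out[i] = it->second;
  }
  return out;
}

// For each insert, 1-based indices of reference entries whose prefix of the
// insert's length matches with <= max_mismatch substitutions.
// [[Rcpp::export]]
List cpp_prefix_match(CharacterVector inserts,
                      CharacterVector refs,
                      int max_mismatch) {
  int n = inserts.size(), r = refs.size();
  std::vector<std::string> rf(r);
  for (int j = 0; j < r; ++j) rf[j] = as<std::string>(refs[j]);
  List out(n);
  std::vector<int> hits;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(inserts[i]);
    int slen = (int) s.size();
    hits.clear();
    for (int j = 0; j < r; ++j) {
      if (slen > (int) rf[j].size()) continue;
      if (hamming_capped(s.c_str(), rf[j].c_str(), slen, max_mismatch) <= max_mismatch)
        hits.push_back(j + 1);
    }
    out[i] = IntegerVector(hits.begin(), hits.end());
  }
  return out;
}

// Pairwise Hamming distances between query strings and one target per query.
// [[Rcpp::export]]
IntegerVector cpp_hamming_to(CharacterVector a, CharacterVector b) {
  int n = a.size();
  if (b.size() != n) stop("length mismatch");
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string x = as<std::string>(a[i]), y = as<std::string>(b[i]);
    if (x.size() != y.size()) stop("string length mismatch at %d", i + 1);
    out[i] = hamming_capped(x.c_str(), y.c_str(), (int) x.size(), (int) x.size());
  }
  return out;
}
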