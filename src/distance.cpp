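#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Unit-cost Levenshtein distance between two strings.
static int lev_dist(const std::string &a, const std::string &b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), sub);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Sequence-Levenshtein distance (Buschmann & Bystrykh): minimum over the
// final row and final column of the Levenshtein DP table. Appropriate for
// fixed-length reads where an indel shifts the downstream frame, so a
// barcode truncated or extended at its end should not be over-penalised.
static int seqlev_dist(const std::string &a, const std::string &b) {
  const int n = a.size(), m = b.size();
  std::vector<std::vector<int> > d(n + 1, std::vector<int>(m + 1));
  for (int i = 0; i <= n; ++i) d[i][0] = i;
  for (int j = 0; j <= m; ++j) d[0][j] = j;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      int sub = d[i - 1][j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      d[i][j] = std::min(std::min(d[i - 1][j] + 1, d[i][j - 1] + 1), sub);
    }
  int best = d[n][m];
  for (int i = 0; i <= n; ++i) best = std::min(best, d[i][m]);
  for (int j = 0; j <= m; ++j) best = std::min(best, d[n][j]);
  return best;
}

static int dist_one(const std::string &a, const std::string &b, int metric) {
  return metric == 0 ? lev_dist(a, b) : seqlev_dist(a, b);
}

// [[Rcpp::export]]
IntegerVector edit_dist_cpp(CharacterVector a, CharacterVector b, int metric) {
  R_xlen_t n = a.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[i]);
    std::string sb = as<std::string>(b[i]);
    out[i] = dist_one(sa, sb, metric);
  }
  return out;
}

// TRUE iff `cand` is at distance >= min_dist from every accepted barcode
// (early exit on first violation).
// [[Rcpp::export]]
bool min_dist_ok_cpp(std::string cand, CharacterVector accepted,
                     int min_dist, int metric) {
  for (R_xlen_t i = 0; i < accepted.size(); ++i) {
    std::string b = as<std::string>(accepted[i]);
    if (dist_one(cand, b, metric) < min_dist) return false;
  }
  return true;
}

// All pairs (i, j), i < j, with distance < min_dist. 1-based indices.
// [[Rcpp::export]]
DataFrame pairwise_violations_cpp(CharacterVector bcs, int min_dist,
                                  int metric) {
  std::vector<int> vi, vj, vd;
  R_xlen_t n = bcs.size();
  std::vector<std::string> s(n);
  for (R_xlen_t i = 0; i < n; ++i) s[i] = as<std::string>(bcs[i]);
  for (R_xlen_t i = 0; i < n; ++i)
    for (R_xlen_t j = i + 1; j < n; ++j) {
      int d = dist_one(s[i], s[j], metric);
      if (d < min_dist) {
        vi.push_back(i + 1);
        vj.push_back(j + 1);
        vd.push_back(d);
      }
    }
  return DataFrame::create(_["i"] = vi, _["j"] = vj, _["distance"] = vd);
}

// Hamming match of fixed-length sequences against a barcode set.
// Returns, per sequence: index (1-based) and distance of the best barcode,
// distance of the second-best barcode, and the number of barcodes within
// `radius`. Ties for best keep the lowest index.
// [[Rcpp::export]]
List hamming_match_cpp(CharacterVector seqs, CharacterVector bcs,
                       int radius) {
  R_xlen_t ns = seqs.size(), nb = bcs.size();
  std::vector<std::string> B(nb);
  for (R_xlen_t j = 0; j < nb; ++j) B[j] = as<std::string>(bcs[j]);
  const int L = nb > 0 ? (int)B[0].size() : 0;
  IntegerVector best_idx(ns), best_d(ns), second_d(ns), n_radius(ns);
  for (R_xlen_t i = 0; i < ns; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int b1 = L + 1, b2 = L + 1, bi = NA_INTEGER, nr = 0;
    for (R_xlen_t j = 0; j < nb; ++j) {
      int d = 0;
      for (int k = 0; k < L; ++k)
        if (s[k] != B[j][k]) { ++d; if (d > b2 && d > radius) break; }
      if (d < b1) { b2 = b1; b1 = d; bi = (int)j + 1; }
      else if (d < b2) b2 = d;
      if (d <= radius) ++nr;
    }
    best_idx[i] = bi;
    best_d[i] = b1;
    second_d[i] = b2;
    n_radius[i] = nr;
  }
  return List::create(_["best_idx"] = best_idx, _["best_dist"] = best_d,
                      _["second_dist"] = second_d,
                      _["n_within_radius"] = n_radius);
}
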