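#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Match each query m/z to the most intense peak within +/- tol.
// mz must be sorted ascending. Ties on intensity go to the lower-m/z peak.
// Returns 1-based peak indices, NA when no peak lies in the window.
// [[Rcpp::export(name = ".matchPeaksCpp")]]
IntegerVector matchPeaksCpp(NumericVector mz, NumericVector intensity,
                            NumericVector query, double tol) {
  int n = mz.size(), q = query.size();
  IntegerVector out(q, NA_INTEGER);
  for (int i = 0; i < q; ++i) {
    double lo = query[i] - tol, hi = query[i] + tol;
    int a = std::lower_bound(mz.begin(), mz.end(), lo) - mz.begin();
    int best = -1;
    double bestInt = -1.0;
    for (int j = a; j < n && mz[j] <= hi; ++j) {
      if (intensity[j] > bestInt) {
        bestInt = intensity[j];
        best = j;
      }
    }
    if (best >= 0) out[i] = best + 1;
  }
  return out;
}

struct Cand {
  double score;
  std::string seq;  // residue indices as chars (1..R), lexicographic order
};

static inline bool candBetter(const Cand &a, const Cand &b) {
  if (a.score != b.score) return a.score > b.score;
  return a.seq < b.seq;
}

// Dynamic program over discretized prefix masses.
//
// siteScores[b] (1-based bin b, prefix mass = b * binWidth) already holds the
// per-site contribution (fragmentation probability minus the site penalty).
// resBins: integerized residue masses in bin units. Paths start at bin 0; an
// extension from bin b > 0 adds siteScores[b] (the site becomes interior).
// Keeps up to k candidates per bin, ordered by score (descending) with
// lexicographic tie-break on the sequence. Distinct sequences reaching the
// same bin follow distinct DP paths, so cells never hold duplicates.
// Returns candidates for final bins in [targetLo, targetHi].
// [[Rcpp::export(name = ".dpSearchCpp")]]
List dpSearchCpp(NumericVector siteScores, IntegerVector resBins,
                 int targetLo, int targetHi, int k) {
  int B = targetHi;
  int R = resBins.size();
  int S = siteScores.size();
  std::vector<std::vector<Cand>> cell(B + 1);
  cell[0].push_back(Cand{0.0, std::string()});
  for (int b = 0; b <= B; ++b) {
    std::vector<Cand> &src = cell[b];
    if (src.empty()) continue;
    double add = (b > 0 && b <= S) ? siteScores[b - 1] : 0.0;
    for (int r = 0; r < R; ++r) {
      int nb = b + resBins[r];
      if (nb > targetHi) continue;
      std::vector<Cand> &dst = cell[nb];
      for (size_t c = 0; c < src.size(); ++c) {
        double ns = src[c].score + (b > 0 ? add : 0.0);
        if ((int)dst.size() >= k) {
          const Cand &worst = dst.back();
          if (ns < worst.score) continue;
          if (ns == worst.score) {
            // lexicographic tie-break against the current worst
            std::string nseq = src[c].seq;
            nseq.push_back((char)(r + 1));
            if (!(nseq < worst.seq)) continue;
            dst.back().seq.swap(nseq);
            dst.back().score = ns;
            std::sort(dst.begin(), dst.end(), candBetter);
            continue;
          }
          dst.pop_back();
        }
        Cand nc;
        nc.score = ns;
        nc.seq = src[c].seq;
        nc.seq.push_back((char)(r + 1));
        std::vector<Cand>::iterator pos =
            std::upper_bound(dst.begin(), dst.end(), nc, candBetter);
        dst.insert(pos, nc);
      }
    }
  }
  std::vector<SEXP> seqs;
  std::vector<double> scores;
  std::vector<int> bins;
  for (int b = std::max(targetLo, 1); b <= targetHi; ++b) {
    for (size_t c = 0; c < cell[b].size(); ++c) {
      const std::string &s = cell[b][c].seq;
      IntegerVector iv(s.size());
      for (size_t j = 0; j < s.size(); ++j) iv[j] = (int)s[j];
      seqs.push_back(iv);
      scores.push_back(cell[b][c].score);
      bins.push_back(b);
    }
  }
  return List::create(Named("seq") = wrap(seqs),
                      Named("score") = wrap(scores),
                      Named("bin") = wrap(bins));
}
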