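// Smith-Waterman local alignment with affine gaps (Gotoh), exact-letter
// scoring and a fully specified deterministic traceback:
//   - a gap of length L costs gapOpen + L * gapExt
//   - cell choice preference on ties: diagonal > gap-in-query (E) >
//     gap-in-subject (F) > stop; within a gap state, opening from H is
//     preferred over extending on ties
//   - the traceback starts at the best-scoring cell with the smallest
//     query index, then the smallest subject index
// so that repeated runs (and an independent reimplementation of the same
// rules) give byte-identical alignments.

#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// [[Rcpp::export(name = ".localAlignCpp")]]
List localAlignCpp(std::string a, std::string b, double match,
                   double mismatch, double gapOpen, double gapExt) {
  const int n = (int)a.size(), m = (int)b.size();
  const double NEG = -1e18;
  std::vector<double> H((n + 1) * (m + 1), 0.0);
  std::vector<double> E((n + 1) * (m + 1), NEG);
  std::vector<double> F((n + 1) * (m + 1), NEG);
  // choices: H: 0 stop, 1 diag, 2 E, 3 F ; E/F: 1 open-from-H, 2 extend
  std::vector<unsigned char> cH((n + 1) * (m + 1), 0);
  std::vector<unsigned char> cE((n + 1) * (m + 1), 0);
  std::vector<unsigned char> cF((n + 1) * (m + 1), 0);
  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int k = idx(i, j);
      const double eOpen = H[idx(i, j - 1)] - gapOpen - gapExt;
      const double eExt  = E[idx(i, j - 1)] - gapExt;
      if (eOpen >= eExt) { E[k] = eOpen; cE[k] = 1; }
      else               { E[k] = eExt;  cE[k] = 2; }
      const double fOpen = H[idx(i - 1, j)] - gapOpen - gapExt;
      const double fExt  = F[idx(i - 1, j)] - gapExt;
      if (fOpen >= fExt) { F[k] = fOpen; cF[k] = 1; }
      else               { F[k] = fExt;  cF[k] = 2; }
      const double diag = H[idx(i - 1, j - 1)] +
        (a[i - 1] == b[j - 1] ? match : mismatch);
      double h = 0.0; unsigned char c = 0;
      if (diag >= h) { h = diag; c = 1; }
      if (E[k] > h)  { h = E[k]; c = 2; }
      if (F[k] > h)  { h = F[k]; c = 3; }
      if (h <= 0.0)  { h = 0.0;  c = 0; }
      H[k] = h; cH[k] = c;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["matches"] = 0,
                        _["alignedLength"] = 0,
                        _["queryStart"] = NA_INTEGER,
                        _["queryEnd"] = NA_INTEGER);

  int i = bi, j = bj, matches = 0, cols = 0;
  char state = 'H';
  while (true) {
    if (state == 'H') {
      const unsigned char c = cH[idx(i, j)];
      if (c == 0 || H[idx(i, j)] <= 0.0) break;
      if (c == 1) {
        ++cols;
        if (a[i - 1] == b[j - 1]) ++matches;
        --i; --j;
      } else if (c == 2) state = 'E';
      else state = 'F';
    } else if (state == 'E') {
      const unsigned char c = cE[idx(i, j)];
      ++cols; --j;                       // gap in query, consumes subject
      if (c == 1) state = 'H';
    } else {
      const unsigned char c = cF[idx(i, j)];
      ++cols; --i;                       // gap in subject, consumes query
      if (c == 1) state = 'H';
    }
  }

  return List::create(_["score"] = best, _["matches"] = matches,
                      _["alignedLength"] = cols,
                      _["queryStart"] = i + 1, _["queryEnd"] = bi);
}
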