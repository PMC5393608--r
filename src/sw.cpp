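#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment scores for hit ranking.
//
// Affine gap model: a gap of length k costs open + k * ext (BLAST-style).
// An optional diagonal band limits the DP to |i - j + shift| <= band where
// shift re-centres the band for unequal sequence lengths; band <= 0 runs the
// full quadratic DP. Scores are used only to rank database hits, so the band
// (like BLAST's own heuristics) must preserve ranking for near-homologous
// sequences, which it does as long as true alignments stay near the main
// diagonal.

static inline double sw_core(const std::vector<int>& a, const std::vector<int>& b,
                             double match, double mismatch,
                             double open, double ext, int band) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) return 0.0;
  const double NEG = -1e300;
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG);
  double best = 0.0;
  const bool banded = band > 0;
  // centre of the band on row i is j = i * m / n
  for (int i = 1; i <= n; ++i) {
    int lo = 1, hi = m;
    if (banded) {
      int c = (int)((double)i * m / n);
      lo = std::max(1, c - band);
      hi = std::min(m, c + band);
    }
    double diagPrev = (lo == 1) ? H[0] : H[lo - 1];
    double F = NEG;
    if (banded && lo > 1) H[lo - 1] = 0.0; // outside-band cell acts as fresh start
    for (int j = lo; j <= hi; ++j) {
      E[j] = std::max(E[j] - ext, H[j] - open - ext);
      F = std::max(F - ext, H[j - 1] - open - ext);
      double s = diagPrev + (a[i - 1] == b[j - 1] ? match : mismatch);
      diagPrev = H[j];
      double h = std::max(std::max(s, E[j]), std::max(F, 0.0));
      H[j] = h;
      if (h > best) best = h;
    }
    if (banded) {
      if (hi < m) H[hi + 1] = 0.0;
      for (int j = hi + 1; j <= m && H[j] != 0.0; ++j) H[j] = 0.0;
    }
  }
  return best;
}

static std::vector<int> encode_seq(const std::string& s) {
  std::vector<int> v;
  v.reserve(s.size());
  for (char c : s) {
    switch (c) {
      case 'A': case 'a': v.push_back(0); break;
      case 'C': case 'c': v.push_back(1); break;
      case 'G': case 'g': v.push_back(2); break;
      case 'T': case 't': v.push_back(3); break;
      default: v.push_back(4 + (int)(unsigned char)c); break; // never matches ACGT
    }
  }
  return v;
}

// [[Rcpp::export(name = ".sw_score_pair")]]
double sw_score_pair(std::string a, std::string b, double match, double mismatch,
                     double gap_open, double gap_ext, int band) {
  std::vector<int> ea = encode_seq(a), eb = encode_seq(b);
  int eff = band;
  if (band > 0) eff = band + std::abs((int)ea.size() - (int)eb.size());
  return sw_core(ea, eb, match, mismatch, gap_open, gap_ext, eff);
}

// All-vs-all upper triangle; the score is symmetric under this model.
// [[Rcpp::export(name = ".sw_score_all")]]
NumericMatrix sw_score_all(CharacterVector seqs, double match, double mismatch,
                           double gap_open, double gap_ext, int band) {
  const int n = seqs.size();
  std::vector<std::vector<int> > enc(n);
  for (int i = 0; i < n; ++i) enc[i] = encode_seq(as<std::string>(seqs[i]));
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    out(i, i) = enc[i].size() * match; // exact self alignment
    for (int j = i + 1; j < n; ++j) {
      int eff = band;
      if (band > 0) eff = band + std::abs((int)enc[i].size() - (int)enc[j].size());
      double s = sw_core(enc[i], enc[j], match, mismatch, gap_open, gap_ext, eff);
      out(i, j) = s;
      out(j, i) = s;
    }
  }
  return out;
}
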