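#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment score with affine gaps.
// A gap of length L costs gap_open + L * gap_extend.

static std::vector<int> encode(const std::string &s,
                               const std::vector<int> &lut) {
  std::vector<int> out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int code = lut[(unsigned char)s[i]];
    if (code < 0)
      stop("unknown residue '%c'", s[i]);
    out[i] = code;
  }
  return out;
}

static std::vector<int> make_lut(const CharacterVector &letters) {
  std::vector<int> lut(256, -1);
  for (int k = 0; k < letters.size(); ++k) {
    std::string l = as<std::string>(letters[k]);
    lut[(unsigned char)l[0]] = k;
  }
  return lut;
}

static int sw_one(const std::vector<int> &a, const std::vector<int> &b,
                  const IntegerMatrix &S, int open, int ext) {
  const int n = a.size(), m = b.size();
  const int NEG = INT_MIN / 4;
  std::vector<int> H(m + 1, 0), E(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int diag = 0;      // H[i-1][j-1]
    int F = NEG;       // gap in b (vertical)
    H[0] = 0;
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(E[j] - ext, H[j] - open - ext);
      F = std::max(F - ext, H[j - 1] - open - ext);
      int h = diag + S(a[i - 1], b[j - 1]);
      if (E[j] > h) h = E[j];
      if (F > h) h = F;
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_cpp")]]
int sw_score_cpp(std::string a, std::string b, IntegerMatrix submat,
                 int gap_open, int gap_extend) {
  CharacterVector letters = rownames(submat);
  std::vector<int> lut = make_lut(letters);
  std::vector<int> ea = encode(a, lut), eb = encode(b, lut);
  return sw_one(ea, eb, submat, gap_open, gap_extend);
}

// All-vs-all score matrix between two sequence sets.
// [[Rcpp::export(name = ".sw_score_matrix_cpp")]]
IntegerMatrix sw_score_matrix_cpp(CharacterVector set_a, CharacterVector set_b,
                                  IntegerMatrix submat, int gap_open,
                                  int gap_extend) {
  CharacterVector letters = rownames(submat);
  std::vector<int> lut = make_lut(letters);
  const int na = set_a.size(), nb = set_b.size();
  std::vector<std::vector<int>> ea(na), eb(nb);
  for (int i = 0; i < na; ++i) ea[i] = encode(as<std::string>(set_a[i]), lut);
  for (int j = 0; j < nb; ++j) eb[j] = encode(as<std::string>(set_b[j]), lut);
  IntegerMatrix out(na, nb);
  for (int i = 0; i < na; ++i) {
    Rcpp::checkUserInterrupt();
    for (int j = 0; j < nb; ++j)
      out(i, j) = sw_one(ea[i], eb[j], submat, gap_open, gap_extend);
  }
  return out;
}
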