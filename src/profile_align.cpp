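// Global profile-profile alignment with affine gaps (Gotoh). Profiles are
// frequency matrices over a residue alphabet whose last row is the gap/unknown
// state (zero-scoring). A gap of length g costs open + g * extend, matching
// the Biostrings pairwiseAlignment convention.

#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_profile_align(const NumericMatrix& profA, const NumericMatrix& profB,
                       const NumericMatrix& submat, double gap_open,
                       double gap_extend) {
  const int na = profA.ncol(), nb = profB.ncol(), ns = submat.nrow();
  const double NEG = -std::numeric_limits<double>::infinity();
  const double gi = gap_open + gap_extend;  // cost of the first gap position

  // expected substitution score between profile columns
  NumericMatrix S(na, nb);
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int a = 0; a < ns; ++a) {
        if (profA(a, i) == 0.0) continue;
        for (int b = 0; b < ns; ++b)
          if (profB(b, j) != 0.0) s += profA(a, i) * profB(b, j) * submat(a, b);
      }
      S(i, j) = s;
    }

  std::vector<std::vector<double>> M(na + 1, std::vector<double>(nb + 1, NEG));
  std::vector<std::vector<double>> X(na + 1, std::vector<double>(nb + 1, NEG));
  std::vector<std::vector<double>> Y(na + 1, std::vector<double>(nb + 1, NEG));
  // traceback: which of M/X/Y fed each cell (0=M,1=X,2=Y)
  std::vector<std::vector<char>> tM(na + 1, std::vector<char>(nb + 1, 0));
  std::vector<std::vector<char>> tX(na + 1, std::vector<char>(nb + 1, 0));
  std::vector<std::vector<char>> tY(na + 1, std::vector<char>(nb + 1, 0));

  M[0][0] = 0.0;
  for (int i = 1; i <= na; ++i) {
    X[i][0] = -(gap_open + gap_extend * i);
    tX[i][0] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= nb; ++j) {
    Y[0][j] = -(gap_open + gap_extend * j);
    tY[0][j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      // M: consume one column of each
      double m0 = M[i - 1][j - 1], m1 = X[i - 1][j - 1], m2 = Y[i - 1][j - 1];
      double best = m0; char tb = 0;
      if (m1 > best) { best = m1; tb = 1; }
      if (m2 > best) { best = m2; tb = 2; }
      if (best > NEG) { M[i][j] = best + S(i - 1, j - 1); tM[i][j] = tb; }
      // X: column of A against a gap
      double xo = (M[i - 1][j] > NEG) ? M[i - 1][j] - gi : NEG;
      double xe = (X[i - 1][j] > NEG) ? X[i - 1][j] - gap_extend : NEG;
      if (xo >= xe) { X[i][j] = xo; tX[i][j] = 0; }
      else          { X[i][j] = xe; tX[i][j] = 1; }
      // Y: column of B against a gap
      double yo = (M[i][j - 1] > NEG) ? M[i][j - 1] - gi : NEG;
      double ye = (Y[i][j - 1] > NEG) ? Y[i][j - 1] - gap_extend : NEG;
      if (yo >= ye) { Y[i][j] = yo; tY[i][j] = 0; }
      else          { Y[i][j] = ye; tY[i][j] = 2; }
    }
  }

  double best = M[na][nb]; char state = 0;
  if (X[na][nb] > best) { best = X[na][nb]; state = 1; }
  if (Y[na][nb] > best) { best = Y[na][nb]; state = 2; }

  // traceback: emit 1-based source column indices, 0 = gap
  std::vector<int> pa, pb;
  int i = na, j = nb;
  while (i > 0 || j > 0) {
    char prev;
    if (state == 0) {
      prev = tM[i][j];
      pa.push_back(i); pb.push_back(j);
      --i; --j;
    } else if (state == 1) {
      prev = tX[i][j];
      pa.push_back(i); pb.push_back(0);
      --i;
    } else {
      prev = tY[i][j];
      pa.push_back(0); pb.push_back(j);
      --j;
    }
    state = prev;
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(Named("score") = best,
                      Named("path_a") = IntegerVector(pa.begin(), pa.end()),
                      Named("path_b") = IntegerVector(pb.begin(), pb.end()));
}
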