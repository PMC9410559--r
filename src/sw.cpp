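#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with uniform match/mismatch rewards and a
// linear per-symbol gap penalty. H is kept as two rolling rows; the score is
// the matrix maximum. Sequences arrive as integer codes (A=0,C=1,G=2,U=3).
static double sw_one(const int* a, int na, const int* b, int nb,
                     double match, double mismatch, double gap) {
  std::vector<double> prev(nb + 1, 0.0), cur(nb + 1, 0.0);
  double best = 0.0;
  for (int i = 1; i <= na; ++i) {
    cur[0] = 0.0;
    for (int j = 1; j <= nb; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double h = prev[j - 1] + s;
      if (prev[j] + gap > h) h = prev[j] + gap;
      if (cur[j - 1] + gap > h) h = cur[j - 1] + gap;
      if (h < 0.0) h = 0.0;
      cur[j] = h;
      if (h > best) best = h;
    }
    std::swap(prev, cur);
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_cpp")]]
double sw_score_cpp(IntegerVector a, IntegerVector b,
                    double match, double mismatch, double gap) {
  return sw_one(INTEGER(a), a.size(), INTEGER(b), b.size(),
                match, mismatch, gap);
}

// Raw SW scores for all pairs of two encoded sequence lists. When
// symmetric = true the two lists must be identical; only the upper
// triangle (including the diagonal) is computed and mirrored.
// [[Rcpp::export(name = ".sw_matrix_cpp")]]
NumericMatrix sw_matrix_cpp(List qs, List rs,
                            double match, double mismatch, double gap,
                            bool symmetric) {
  int nq = qs.size(), nr = rs.size();
  NumericMatrix out(nq, nr);
  std::vector<IntegerVector> q(nq), r(nr);
  for (int i = 0; i < nq; ++i) q[i] = qs[i];
  for (int j = 0; j < nr; ++j) r[j] = rs[j];
  for (int i = 0; i < nq; ++i) {
    int j0 = symmetric ? i : 0;
    for (int j = j0; j < nr; ++j) {
      double s = sw_one(INTEGER(q[i]), q[i].size(),
                        INTEGER(r[j]), r[j].size(), match, mismatch, gap);
      out(i, j) = s;
      if (symmetric && j != i) out(j, i) = s;
    }
  }
  return out;
}
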