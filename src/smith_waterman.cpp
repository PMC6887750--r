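#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Gotoh local alignment with affine gaps. A gap of length k costs
// gap_open + k * gap_extend (both penalties are negative numbers).
// Traceback is deterministic: on ties diagonal > up (gap in subject) >
// left (gap in query); the best cell is the first maximum in row-major
// order. Characters match only if equal AND in {A,C,G,T}, so masked or
// ambiguous symbols always score as mismatches.

static inline bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export]]
List sw_align_cpp(std::string query, std::string subject,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = query.size(), m = subject.size();
  const double NEG = -1e30;
  // H, E (gap in query: move left), F (gap in subject: move up)
  std::vector<std::vector<double>> H(n + 1, std::vector<double>(m + 1, 0.0));
  std::vector<std::vector<double>> E(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double>> F(n + 1, std::vector<double>(m + 1, NEG));
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E[i][j] = std::max(H[i][j - 1] + gap_open + gap_extend,
                         E[i][j - 1] + gap_extend);
      F[i][j] = std::max(H[i - 1][j] + gap_open + gap_extend,
                         F[i - 1][j] + gap_extend);
      char a = query[i - 1], b = subject[j - 1];
      double sub = (a == b && is_base(a)) ? match : mismatch;
      double h = H[i - 1][j - 1] + sub;
      h = std::max(h, std::max(E[i][j], F[i][j]));
      h = std::max(h, 0.0);
      H[i][j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::string qa, sa;
  int i = bi, j = bj;
  // states: 0 = H, 1 = F (up), 2 = E (left)
  int state = 0;
  const double eps = 1e-9;
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (H[i][j] <= eps) break;
      char a = query[i - 1], b = subject[j - 1];
      double sub = (a == b && is_base(a)) ? match : mismatch;
      if (std::abs(H[i][j] - (H[i - 1][j - 1] + sub)) < eps) {
        qa.push_back(a); sa.push_back(b); --i; --j;
      } else if (std::abs(H[i][j] - F[i][j]) < eps) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      qa.push_back(query[i - 1]); sa.push_back('-');
      if (std::abs(F[i][j] - (H[i - 1][j] + gap_open + gap_extend)) < eps) {
        --i; state = 0;
      } else {
        --i; // stay in F
      }
    } else {
      qa.push_back('-'); sa.push_back(subject[j - 1]);
      if (std::abs(E[i][j] - (H[i][j - 1] + gap_open + gap_extend)) < eps) {
        --j; state = 0;
      } else {
        --j;
      }
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  return List::create(
    _["score"] = best,
    _["query_start"] = i, _["query_end"] = bi,     // 0-based half-open
    _["subject_start"] = j, _["subject_end"] = bj,
    _["query_aln"] = qa, _["subject_aln"] = sa);
}
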