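#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalties and fixed,
// documented tie-breaking so that identical inputs always yield the same
// alignment: diagonal (match/mismatch) is preferred over a gap in the read,
// which is preferred over a gap in the reference.
//
// Convention: a "gap in read" consumes a reference base (deletion in the
// read); a "gap in ref" consumes a read base (insertion in the read).
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string read, std::string ref,
                  double match, double mismatch, double gap) {
  const int n = read.size(), m = ref.size();
  // pointers: 0 = diag, 1 = left (gap in read), 2 = up (gap in ref)
  NumericMatrix S(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1);
  for (int j = 1; j <= m; ++j) { S(0, j) = j * gap; P(0, j) = 1; }
  for (int i = 1; i <= n; ++i) { S(i, 0) = i * gap; P(i, 0) = 2; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sub = S(i - 1, j - 1) +
        (read[i - 1] == ref[j - 1] ? match : mismatch);
      double del = S(i, j - 1) + gap;   // gap in read
      double ins = S(i - 1, j) + gap;   // gap in ref
      double best = sub; int ptr = 0;
      if (del > best) { best = del; ptr = 1; }
      if (ins > best) { best = ins; ptr = 2; }
      S(i, j) = best; P(i, j) = ptr;
    }
  }
  std::string ar, az;  // aligned read, aligned ref (reversed during build)
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int ptr = P(i, j);
    if (i > 0 && j > 0 && ptr == 0) {
      ar.push_back(read[--i]); az.push_back(ref[--j]);
    } else if (j > 0 && (ptr == 1 || i == 0)) {
      ar.push_back('-'); az.push_back(ref[--j]);
    } else {
      ar.push_back(read[--i]); az.push_back('-');
    }
  }
  std::reverse(ar.begin(), ar.end());
  std::reverse(az.begin(), az.end());
  return List::create(_["aligned_read"] = ar, _["aligned_ref"] = az,
                      _["score"] = S(n, m));
}
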