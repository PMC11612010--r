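#include <Rcpp.h>
using namespace Rcpp;

// Lempel-Ziv 1976 exhaustive-history pattern count (Kaspar-Schuster
// formulation). Scans left to right; a new component ends as soon as the
// current word is no longer a substring of everything before its last
// symbol. The trailing incomplete word counts as one component.
// [[Rcpp::export(name = ".lz76Count")]]
int lz76Count(IntegerVector s) {
  const int n = s.size();
  if (n == 0) stop("empty symbol sequence");
  int c = 1, i = 0, k = 1, l = 1, kmax = 1;
  if (n == 1) return 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {           // current word is novel: close the component
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
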