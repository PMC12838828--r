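#include <Rcpp.h>

// Lempel-Ziv 1976 complexity of a binary sequence: the number of
// components in the exhaustive production history. Implementation of the
// classic Kaspar-Schuster scan; O(n^2) worst case, linear memory.
// [[Rcpp::export(name = ".lz76_count")]]
int lz76_count(Rcpp::IntegerVector bits) {
  const int n = bits.size();
  if (n == 0) Rcpp::stop("empty sequence");
  int c = 1;          // complexity counter (first symbol is one component)
  int l = 1;          // length of the prefix already parsed
  int i = 0;          // candidate copy start within the prefix
  int k = 1;          // current match length
  int kmax = 1;       // longest match seen for the current component
  while (l + k <= n) {
    if (bits[i + k - 1] == bits[l + k - 1]) {
      ++k;
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {          // no copy source reproduces the extension
        ++c;
        l += kmax;
        i = 0;
        kmax = 1;
      }
      k = 1;
    }
  }
  if (k > 1) ++c;   // count the final (possibly reproducible) partial word
  return c;
}
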