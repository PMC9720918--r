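#include <Rcpp.h>
using namespace Rcpp;

// Count contiguous call windows of every length over a set of in-block
// haplotype strings. Each string is over {'0','1','?'}; '?' splits the read
// into segments before windows are enumerated, so no window ever spans a
// missing call. A record with count c contributes c copies of each window.
//
// Returns an l x 3 matrix: column 0 = evaluable windows of length i,
// column 1 = fully methylated windows, column 2 = fully un-methylated
// windows (i = row + 1, up to the block length l).
// [[Rcpp::export]]
NumericMatrix hap_window_counts(CharacterVector haps, NumericVector counts,
                                int block_len) {
  if (block_len < 1) stop("block length must be >= 1");
  if (haps.size() != counts.size()) stop("haps and counts differ in length");
  NumericMatrix out(block_len, 3);

  for (R_xlen_t r = 0; r < haps.size(); ++r) {
    const char *s = CHAR(STRING_ELT(haps, r));
    const double c = counts[r];
    int n = (int) strlen(s);
    int pos = 0;
    while (pos < n) {
      // next segment of observed ('0'/'1') calls
      while (pos < n && s[pos] != '0' && s[pos] != '1') ++pos;
      int seg_start = pos;
      while (pos < n && (s[pos] == '0' || s[pos] == '1')) ++pos;
      int L = pos - seg_start;
      if (L == 0) continue;
      int maxi = L < block_len ? L : block_len;
      for (int i = 1; i <= maxi; ++i)
        out(i - 1, 0) += c * (L - i + 1);
      // runs of identical calls within the segment
      int q = seg_start;
      while (q < pos) {
        char call = s[q];
        int run_start = q;
        while (q < pos && s[q] == call) ++q;
        int run = q - run_start;
        int col = (call == '1') ? 1 : 2;
        int maxr = run < block_len ? run : block_len;
        for (int i = 1; i <= maxr; ++i)
          out(i - 1, col) += c * (run - i + 1);
      }
    }
  }
  return out;
}
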