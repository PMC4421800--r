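#include <Rcpp.h>
using namespace Rcpp;

// Sliding-window Hamming scan of a short tag along a reference.
// Bases are encoded 0..3; anything >= 4 (e.g. N) mismatches everything.
// Returns a two-column matrix: 0-based window start, mismatch count.

// [[Rcpp::export]]
IntegerMatrix hamming_scan_cpp(IntegerVector tag, IntegerVector ref,
                               int max_mm) {
  const int w = tag.size(), n = ref.size();
  std::vector<int> starts, mms;
  for (int s = 0; s + w <= n; ++s) {
    int mm = 0;
    for (int i = 0; i < w; ++i) {
      int a = tag[i], b = ref[s + i];
      if (a != b || a >= 4) {
        if (++mm > max_mm) break;
      }
    }
    if (mm <= max_mm) {
      starts.push_back(s);
      mms.push_back(mm);
    }
  }
  IntegerMatrix out(starts.size(), 2);
  for (size_t r = 0; r < starts.size(); ++r) {
    out(r, 0) = starts[r];
    out(r, 1) = mms[r];
  }
  return out;
}
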