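#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Merge dwells (runs of constant level) shorter than min_dwell samples into
// the preceding run's level (an initial short run adopts the following
// run's level). Runs that coalesce are re-examined, so the result contains
// no run shorter than min_dwell unless the whole trace is one run.
// [[Rcpp::export]]
IntegerVector merge_short_dwells(IntegerVector lev, int min_dwell) {
  const int n = lev.size();
  if (n == 0 || min_dwell <= 1) return clone(lev);

  std::vector<int> val, len;
  val.reserve(n); len.reserve(n);
  int cur = lev[0], cnt = 1;
  for (int i = 1; i < n; ++i) {
    if (lev[i] == cur) ++cnt;
    else { val.push_back(cur); len.push_back(cnt); cur = lev[i]; cnt = 1; }
  }
  val.push_back(cur); len.push_back(cnt);

  bool changed = true;
  while (changed && val.size() > 1) {
    changed = false;
    size_t i = 0;
    while (i < val.size() && val.size() > 1) {
      if (len[i] < min_dwell) {
        if (i == 0) val[0] = val[1]; else val[i] = val[i - 1];
        changed = true;
      }
      // coalesce with previous if equal
      if (i > 0 && val[i] == val[i - 1]) {
        len[i - 1] += len[i];
        val.erase(val.begin() + i);
        len.erase(len.begin() + i);
      } else ++i;
    }
  }

  IntegerVector out(n);
  int pos = 0;
  for (size_t r = 0; r < val.size(); ++r)
    for (int k = 0; k < len[r]; ++k) out[pos++] = val[r];
  return out;
}
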