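// Exhaustive direct-repeat scan over all provirus-like separations.
// For every candidate separation S the sequence is compared against itself
// at lag S; maximal runs where a sliding window of matches stays above a
// density floor are emitted as repeat-pair candidates. Complements the
// k-mer seeding, which can miss highly diverged repeat pairs that happen to
// share no exact seed; the windowed density floor (default 0.55 over 100 bp)
// sits far above the 0.25 background of random sequence, so random contigs
// emit nothing.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".diagonalScanCpp")]]
DataFrame diagonalScanCpp(IntegerVector x, int minSep, int maxSep,
                          int window = 100, double minFrac = 0.55,
                          int maxRuns = 5000) {
  const int n = x.size();
  std::vector<int> sepOut, startOut, endOut;
  const int need = (int)std::ceil(minFrac * window);
  for (int S = minSep; S <= maxSep; ++S) {
    const int L = n - S;                     // overlap length at this lag
    if (L < window) break;
    int cnt = 0;
    for (int i = 0; i < window; ++i)
      cnt += (x[i] >= 0 && x[i] == x[i + S]);
    int runStart = -1;
    for (int i = 0;; ++i) {                  // window starts at i
      bool hot = cnt >= need;
      if (hot && runStart < 0) runStart = i;
      if (!hot && runStart >= 0) {
        sepOut.push_back(S);
        startOut.push_back(runStart + 1);    // 1-based
        endOut.push_back(i - 1 + window);    // last covered position
        runStart = -1;
        if ((int)sepOut.size() >= maxRuns) i = L;  // safety cap
      }
      if (i + window >= L) {
        if (runStart >= 0) {
          sepOut.push_back(S);
          startOut.push_back(runStart + 1);
          endOut.push_back(i + window);
        }
        break;
      }
      cnt -= (x[i] >= 0 && x[i] == x[i + S]);
      cnt += (x[i + window] >= 0 && x[i + window] == x[i + window + S]);
    }
    if ((int)sepOut.size() >= maxRuns) break;
  }
  return DataFrame::create(_["s"] = sepOut, _["start"] = startOut,
                           _["end"] = endOut);
}
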