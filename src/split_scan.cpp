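#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// One scan direction: for each piece length i, the best ungapped
// placement of the piece over all offsets. Separating the cumulative
// match update from the running-max scan keeps both loops branch-light.
static void scan_dir(const char* read, int L, const char* ref, int N,
                     int* best_m, int* best_o) {
  std::vector<int> cum(N, 0);
  int* c = cum.data();
  for (int i = 1; i <= L; ++i) {
    const char ch = read[i - 1];
    const int omax = N - i;
    const char* rp = ref + i - 1;
    for (int o = 0; o <= omax; ++o) c[o] += (rp[o] == ch);
    int best = -1, boff = 0;
    for (int o = 0; o <= omax; ++o) {
      if (c[o] > best) { best = c[o]; boff = o; }
    }
    best_m[i - 1] = best;
    best_o[i - 1] = boff;
  }
}

// Exhaustive ungapped fit of every read prefix and suffix against one
// reference strand.
//
// For each prefix length i (read[0..i-1]) the best placement is the
// reference offset maximising the number of matching bases; likewise for
// each suffix read[i-1..L-1]. Offsets run over all placements that keep
// the piece fully inside the reference. Scores are match-counts; the
// caller converts to match(+1)/mismatch(-1) scores and identities.
//
// Returns a list with integer matrices `pref` and `suf` (L rows):
//   pref[i-1,] = (best matches, 1-based ref start) for prefix length i
//   suf[i-1,]  = (best matches, 1-based ref start) for suffix read[i..L]
// Ties resolve deterministically (smallest offset on the scanned
// orientation).
// [[Rcpp::export(name = ".piece_scan")]]
List piece_scan(std::string read, std::string ref) {
  const int L = (int)read.size();
  const int N = (int)ref.size();
  if (L == 0 || N == 0 || L > N) {
    stop("piece_scan: read must be non-empty and no longer than reference");
  }
  IntegerMatrix pref(L, 2), suf(L, 2);
  std::vector<int> bm(L), bo(L);

  scan_dir(read.c_str(), L, ref.c_str(), N, bm.data(), bo.data());
  for (int i = 0; i < L; ++i) {
    pref(i, 0) = bm[i];
    pref(i, 1) = bo[i] + 1;
  }

  // suffix pass on the reversed strings, offsets mapped back
  std::string rread(read.rbegin(), read.rend());
  std::string rref(ref.rbegin(), ref.rend());
  scan_dir(rread.c_str(), L, rref.c_str(), N, bm.data(), bo.data());
  for (int k = 1; k <= L; ++k) {
    const int i = L - k + 1; // suffix starts at read position i (1-based)
    suf(i - 1, 0) = bm[k - 1];
    suf(i - 1, 1) = N - bo[k - 1] - k + 1;
  }

  return List::create(_["pref"] = pref, _["suf"] = suf);
}
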