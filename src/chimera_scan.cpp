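#include <Rcpp.h>
using namespace Rcpp;

// Reference-based two-parent chimera scan.
//
// For every query, match indicators against each reference are computed
// twice: left-aligned (shared prefix coordinates) and right-aligned (shared
// suffix coordinates), which under a substitution-only error model equal the
// free-end-gap alignment match profiles. The best single-reference score s1
// is the maximum full-length match count; the best chimeric score maximizes,
// over breakpoints b with both segments >= minSegment, the best prefix
// matches on [0, b) plus the best suffix matches on [b, L) over *distinct*
// references. Ties prefer the lowest reference index (callers pass
// references sorted by id) and the smallest breakpoint.
//
// [[Rcpp::export]]
DataFrame chimeraScanC(CharacterVector queries, CharacterVector refs,
                       int minSegment, int minGain) {
  const int nq = queries.size(), nr = refs.size();
  std::vector<std::string> R(nr);
  for (int r = 0; r < nr; ++r) R[r] = as<std::string>(refs[r]);

  IntegerVector bestSingle(nq), bestChimeric(nq), breakpoint(nq),
      parentA(nq), parentB(nq), singleRef(nq);
  LogicalVector isChimera(nq), tooShort(nq);

  std::vector<std::vector<int>> pref(nr), suff(nr);
  for (int q = 0; q < nq; ++q) {
    const std::string Q = as<std::string>(queries[q]);
    const int L = (int)Q.size();
    // cumulative match profiles per reference
    for (int r = 0; r < nr; ++r) {
      const std::string &S = R[r];
      const int M = (int)S.size();
      pref[r].assign(L + 1, 0);
      for (int i = 0; i < L; ++i)
        pref[r][i + 1] = pref[r][i] + ((i < M && Q[i] == S[i]) ? 1 : 0);
      suff[r].assign(L + 1, 0);
      for (int i = L - 1; i >= 0; --i) {
        int j = M - (L - i);
        suff[r][i] = suff[r][i + 1] +
                     ((j >= 0 && j < M && Q[i] == S[j]) ? 1 : 0);
      }
    }
    int s1 = -1, r1 = -1;
    for (int r = 0; r < nr; ++r)
      if (pref[r][L] > s1) { s1 = pref[r][L]; r1 = r; }
    bestSingle[q] = s1;
    singleRef[q] = r1 + 1;

    int sc = -1, bb = -1, pa = -1, pb = -1;
    if (L >= 2 * minSegment) {
      for (int b = minSegment; b <= L - minSegment; ++b) {
        // best and runner-up prefix refs at this breakpoint
        int p1 = -1, p1r = -1, p2 = -1, p2r = -1;
        int s1b = -1, s1r = -1, s2b = -1, s2r = -1;
        for (int r = 0; r < nr; ++r) {
          int pv = pref[r][b];
          if (pv > p1) { p2 = p1; p2r = p1r; p1 = pv; p1r = r; }
          else if (pv > p2) { p2 = pv; p2r = r; }
          int sv = suff[r][b];
          if (sv > s1b) { s2b = s1b; s2r = s1r; s1b = sv; s1r = r; }
          else if (sv > s2b) { s2b = sv; s2r = r; }
        }
        int tot, ra, rb;
        if (p1r != s1r) { tot = p1 + s1b; ra = p1r; rb = s1r; }
        else {
          int t1 = (p2r >= 0) ? p2 + s1b : -1;
          int t2 = (s2r >= 0) ? p1 + s2b : -1;
          if (t1 >= t2) { tot = t1; ra = p2r; rb = s1r; }
          else          { tot = t2; ra = p1r; rb = s2r; }
        }
        if (ra < 0 || rb < 0) continue;
        if (tot > sc) { sc = tot; bb = b; pa = ra; pb = rb; }
      }
    } else {
      tooShort[q] = true;
    }
    bestChimeric[q] = sc;
    bool chim = (sc >= 0) && (sc - s1 >= minGain);
    isChimera[q] = chim;
    if (chim) {
      breakpoint[q] = bb;
      parentA[q] = pa + 1;
      parentB[q] = pb + 1;
    } else {
      breakpoint[q] = NA_INTEGER;
      parentA[q] = NA_INTEGER;
      parentB[q] = NA_INTEGER;
    }
  }
  return DataFrame::create(
      _["isChimera"] = isChimera, _["bestSingle"] = bestSingle,
      _["bestChimeric"] = bestChimeric, _["breakpoint"] = breakpoint,
      _["parentA"] = parentA, _["parentB"] = parentB,
      _["singleRef"] = singleRef, _["tooShort"] = tooShort);
}
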