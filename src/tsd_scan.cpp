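// Anchored direct-repeat (TSD) scan: the body-side copy is pinned near the
// alignment boundary, the tail-side copy slides across the tail region, and
// candidates are scored by length - 4 * mismatches with junction-local tail
// purity validation.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".rfTsdScan")]]
List rf_tsd_scan(const std::string& seq, int bs, int be, bool plus,
                 int maxLen, int minLen, double maxMismatchFrac, int slop,
                 int maxTail, double minTailPurity) {
  // seq is the full chromosome; bs/be 1-based body interval
  const int L = seq.size();
  int lo = bs - maxLen - slop - maxTail, hi = be + maxLen + slop + maxTail;
  if (lo < 1 || hi > L) return R_NilValue;
  const char tailBase = plus ? 'A' : 'T';
  double bestScore = -1e18;
  int bestMm = 1 << 30, bestLs = 1 << 30;
  double bestPur = -1;
  List best = R_NilValue;

  for (int len = maxLen; len >= minLen; --len) {
    int maxMm = (int)std::floor(maxMismatchFrac * len);
    for (int ls = -slop; ls <= slop; ++ls) {
      int pinA, pinB;  // pinned copy, 1-based inclusive
      if (plus) { pinA = bs + ls - len; pinB = bs + ls - 1; }
      else { pinA = be + ls + 1; pinB = be + ls + len; }
      if (pinA < 1 || pinB > L) continue;
      int pFrom, pTo;  // tail-side copy start (plus) or end (minus)
      if (plus) { pFrom = be - slop + 1; pTo = be + maxTail; }
      else { pFrom = bs - maxTail; pTo = bs + slop - 1; }
      for (int p = pFrom; p <= pTo; ++p) {
        int oA, oB;
        if (plus) { oA = p; oB = p + len - 1; }
        else { oA = p - len + 1; oB = p; }
        if (oA < 1 || oB > L) continue;
        int mm = 0;
        for (int k = 0; k < len; ++k) {
          if (seq[pinA - 1 + k] != seq[oA - 1 + k]) {
            if (++mm > maxMm) break;
          }
        }
        if (mm > maxMm) continue;
        // implied tail region between body and the tail-side copy
        int tA, tB;
        if (plus) { tA = be + 1; tB = p - 1; }
        else { tA = p + 1; tB = bs - 1; }
        int tlen = tB - tA + 1;
        if (tlen < 0) tlen = 0;
        double purity = 1.0;
        if (tlen > 0) {
          int cnt = 0;
          for (int k = tA; k <= tB; ++k) if (seq[k - 1] == tailBase) ++cnt;
          purity = (double)cnt / tlen;
          if (tlen >= 4) {
            // the 8 nt abutting the scanned copy must be pure tail
            int jA, jB;
            if (plus) { jB = tB; jA = std::max(tA, tB - 7); }
            else { jA = tA; jB = std::min(tB, tA + 7); }
            int jc = 0;
            for (int k = jA; k <= jB; ++k) if (seq[k - 1] == tailBase) ++jc;
            if ((double)jc / (jB - jA + 1) < minTailPurity) continue;
          }
        }
        double score = len - 4.0 * mm;
        int als = std::abs(ls);
        bool better = score > bestScore ||
          (score == bestScore && (mm < bestMm ||
            (mm == bestMm && (purity > bestPur ||
              (purity == bestPur && als < bestLs)))));
        if (!better) continue;
        bestScore = score; bestMm = mm; bestPur = purity; bestLs = als;
        int insA, insB, lA, lB, rA, rB;
        if (plus) {
          insA = bs + ls; insB = p - 1;
          lA = pinA; lB = pinB; rA = oA; rB = oB;
        } else {
          insA = p + 1; insB = be + ls;
          lA = oA; lB = oB; rA = pinA; rB = pinB;
        }
        best = List::create(
          _["seq"] = seq.substr(pinA - 1, len), _["len"] = len,
          _["mismatches"] = mm,
          _["left"] = IntegerVector::create(lA, lB),
          _["right"] = IntegerVector::create(rA, rB),
          _["insert"] = IntegerVector::create(insA, insB),
          _["tailLength"] = tlen,
          _["tailPurity"] = tlen > 0 ? purity : NA_REAL);
      }
    }
  }
  return best;
}
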