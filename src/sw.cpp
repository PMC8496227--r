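// Affine-gap Smith-Waterman local alignment with traceback, used by the
// seed-and-extend scanner on candidate windows. A gap of length L costs
// gapOpen + L * gapExt (penalties given as positive numbers).

#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// [[Rcpp::export(name = ".rfSwAlign")]]
List rf_sw_align(const std::string& query, const std::string& target,
                 double match, double mismatch, double gapOpen, double gapExt) {
  const int m = query.size(), n = target.size();
  if (m == 0 || n == 0) stop("empty sequence");
  if ((double)m * (double)n > 2.5e8)
    stop("alignment problem too large for the dense DP");

  const double NEG = -1e18;
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Eprev(n + 1, NEG), Ecur(n + 1, NEG);
  std::vector<double> Fcur(n + 1, NEG);
  // traceback state per cell: 2 bits H-source (0 stop, 1 diag, 2 E, 3 F),
  // 1 bit E-extend, 1 bit F-extend
  std::vector<unsigned char> tb((size_t)(m + 1) * (n + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0.0;
    Fcur[0] = NEG;
    for (int j = 1; j <= n; ++j) {
      // E: gap in query (consume target)
      double eOpen = Hcur[j - 1] - gapOpen - gapExt;
      double eExt = Ecur[j - 1] - gapExt;
      Ecur[j] = std::max(eOpen, eExt);
      // F: gap in target (consume query)
      double fOpen = Hprev[j] - gapOpen - gapExt;
      double fExt = Fcur[j] - gapExt;  // Fcur[j] currently holds row i-1 value
      double fval = std::max(fOpen, fExt);
      double s = (query[i - 1] == target[j - 1]) ? match : mismatch;
      double diag = Hprev[j - 1] + s;
      double h = 0.0;
      unsigned char st = 0;
      if (diag > h) { h = diag; st = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; st = 2; }
      if (fval > h) { h = fval; st = 3; }
      unsigned char flags = st;
      if (eExt >= eOpen) flags |= 4;
      if (fExt >= fOpen) flags |= 8;
      tb[(size_t)i * (n + 1) + j] = flags;
      Hcur[j] = h;
      Fcur[j] = fval;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
    std::fill(Ecur.begin(), Ecur.end(), NEG);
  }

  // traceback collecting gapless blocks
  std::vector<int> qs, qe, ts, te, bm, bmm;
  int i = bi, j = bj;
  int curQe = -1, curTe = -1, nm = 0, nmm = 0;
  int state = 0;  // 0 = in H
  auto flushBlock = [&](int qi, int tj) {
    if (curQe >= 0) {
      qs.push_back(qi + 1); qe.push_back(curQe);
      ts.push_back(tj + 1); te.push_back(curTe);
      bm.push_back(nm); bmm.push_back(nmm);
      curQe = -1; nm = 0; nmm = 0;
    }
  };
  while (i > 0 && j > 0) {
    unsigned char flags = tb[(size_t)i * (n + 1) + j];
    if (state == 0) {
      unsigned char st = flags & 3;
      if (st == 0) break;
      if (st == 1) {
        if (curQe < 0) { curQe = i; curTe = j; }
        if (query[i - 1] == target[j - 1]) ++nm; else ++nmm;
        --i; --j;
      } else if (st == 2) {
        flushBlock(i, j);
        state = 2;
      } else {
        flushBlock(i, j);
        state = 3;
      }
    } else if (state == 2) {
      bool ext = flags & 4;
      --j;
      if (!ext) state = 0;
      else flags = 0;
    } else {
      bool ext = flags & 8;
      --i;
      if (!ext) state = 0;
    }
  }
  flushBlock(i, j);
  std::reverse(qs.begin(), qs.end()); std::reverse(qe.begin(), qe.end());
  std::reverse(ts.begin(), ts.end()); std::reverse(te.begin(), te.end());
  std::reverse(bm.begin(), bm.end()); std::reverse(bmm.begin(), bmm.end());

  return List::create(
      _["score"] = best,
      _["qstart"] = (qs.empty() ? NA_INTEGER : qs.front()),
      _["qend"] = (qe.empty() ? NA_INTEGER : qe.back()),
      _["tstart"] = (ts.empty() ? NA_INTEGER : ts.front()),
      _["tend"] = (te.empty() ? NA_INTEGER : te.back()),
      _["blocks"] = DataFrame::create(_["qstart"] = qs, _["qend"] = qe,
                                      _["tstart"] = ts, _["tend"] = te,
                                      _["nmatch"] = bm, _["nmismatch"] = bmm));
}
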