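#include <Rcpp.h>
using namespace Rcpp;

// Base encoding: A=0 C=1 G=2 U=3, anything else -1 (always a mismatch).
static inline int enc(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': case 'T': return 3;
    default:  return -1;
  }
}

// Watson-Crick complement table indexed by sRNA base code: the transcript
// base that pairs with it (A-U, C-G, G-C, U-A).
static const int WC[4] = {3, 2, 1, 0};

// Ungapped antiparallel scan of every sRNA against every length-L window of
// every transcript.  sRNA position p (1..L from the 5' end) pairs with
// transcript position end - p + 1.  Per-position penalty: match 0, G:U
// wobble wobble_pen, mismatch mismatch_pen; multiplied by core_mult for
// sRNA positions core_start..core_end.  Windows with total penalty
// <= max_penalty are reported.
// [[Rcpp::export]]
List scan_core(CharacterVector srna_seqs, CharacterVector tx_seqs,
               double max_penalty, int core_start, int core_end,
               double wobble_pen, double mismatch_pen, double core_mult) {
  std::vector<int> out_s, out_t, out_start;
  std::vector<double> out_pen;
  std::vector<std::string> out_pair;
  const double eps = 1e-9;

  for (int si = 0; si < srna_seqs.size(); ++si) {
    std::string s = as<std::string>(srna_seqs[si]);
    const int L = (int)s.size();
    std::vector<int> sc(L);
    for (int p = 0; p < L; ++p) sc[p] = enc(s[p]);

    for (int ti = 0; ti < tx_seqs.size(); ++ti) {
      std::string t = as<std::string>(tx_seqs[ti]);
      const int n = (int)t.size();
      if (n < L) continue;
      std::vector<int> tc(n);
      for (int i = 0; i < n; ++i) tc[i] = enc(t[i]);

      std::string pairing(L, 'X');
      for (int start = 0; start + L <= n; ++start) {
        double pen = 0.0;
        bool keep = true;
        for (int p = 1; p <= L; ++p) {
          // transcript index (0-based) opposite sRNA position p
          int tb = tc[start + L - p];
          int sb = sc[p - 1];
          char code;
          if (sb >= 0 && tb == WC[sb]) {
            code = 'M';
          } else if ((sb == 2 && tb == 3) || (sb == 3 && tb == 2)) {
            code = 'W';
          } else {
            code = 'X';
          }
          double w = (p >= core_start && p <= core_end) ? core_mult : 1.0;
          if (code == 'W') pen += w * wobble_pen;
          else if (code == 'X') pen += w * mismatch_pen;
          if (pen > max_penalty + eps) { keep = false; break; }
          pairing[p - 1] = code;
        }
        if (keep) {
          out_s.push_back(si + 1);
          out_t.push_back(ti + 1);
          out_start.push_back(start + 1);
          out_pen.push_back(pen);
          out_pair.push_back(pairing);
        }
      }
    }
  }
  return List::create(_["srna_idx"] = wrap(out_s),
                      _["tx_idx"] = wrap(out_t),
                      _["start"] = wrap(out_start),
                      _["penalty"] = wrap(out_pen),
                      _["pairing"] = wrap(out_pair));
}
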