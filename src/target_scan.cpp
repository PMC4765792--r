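// Complementarity scoring of miRNA / target-site duplexes.
//
// Expectation score on the antiparallel duplex, miRNA 5'->3' against the
// target 3'->5': each aligned position costs 0 (Watson-Crick), gu_penalty
// (G:U wobble) or mm_penalty (mismatch); every bulged target nucleotide
// costs bulge_penalty. Costs are multiplied by seed_mult when the miRNA
// position (for bulges: the first miRNA position 3' of the bulge) falls in
// [seed_from, seed_to]. At most one target-side bulge of up to max_bulge
// nucleotides is allowed, so a window is miRNA-length to miRNA-length +
// max_bulge nucleotides long.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>

using namespace Rcpp;

static inline char norm_base(char c) {
  switch (c) {
    case 'a': return 'A'; case 'c': return 'C'; case 'g': return 'G';
    case 't': case 'u': case 'U': return 'T';
    case 'A': case 'C': case 'G': case 'T': return c;
    default: return 'N';
  }
}

// penalty (x10 to stay integral) for miRNA base vs target base
static inline int pos_penalty(char m, char t, int gu10, int mm10) {
  if (m == 'N' || t == 'N') return mm10;
  if ((m == 'A' && t == 'T') || (m == 'T' && t == 'A') ||
      (m == 'C' && t == 'G') || (m == 'G' && t == 'C')) return 0;
  if ((m == 'G' && t == 'T') || (m == 'T' && t == 'G')) return gu10;
  return mm10;
}

// score one miRNA/window duplex; returns list(score, bulge_after)
// bulge_after = miRNA position (1-based) after which the target bulge sits,
// 0..m; NA-like -1 when no bulge (window length == miRNA length).
// [[Rcpp::export(name = ".score_site_cpp")]]
List score_site_cpp(std::string mirna, std::string window,
                    double gu_penalty = 0.5, double mm_penalty = 1.0,
                    double bulge_penalty = 2.0, int seed_from = 2,
                    int seed_to = 13, double seed_mult = 2.0) {
  int m = (int) mirna.size();
  int w = (int) window.size();
  int d = w - m;
  if (m == 0 || w == 0) stop("empty miRNA or target window");
  if (d < 0) stop("target window shorter than the miRNA");
  std::string mi(m, 'N'), rw(w, 'N');
  for (int i = 0; i < m; ++i) mi[i] = norm_base(mirna[i]);
  for (int i = 0; i < w; ++i) rw[i] = norm_base(window[w - 1 - i]); // 3'->5'
  int gu10 = (int) (gu_penalty * 10 + 0.5);
  int mm10 = (int) (mm_penalty * 10 + 0.5);
  int bu10 = (int) (bulge_penalty * 10 + 0.5);
  int sm10 = (int) (seed_mult * 10 + 0.5);
  int best = INT_MAX, best_b = -1;
  int bmax = (d == 0) ? 0 : m;
  int bmin = (d == 0) ? 0 : 0;
  for (int b = bmin; b <= bmax; ++b) {
    // miRNA pos k (1-based): partner rw index k-1 for k<=b, k-1+d for k>b
    long s = 0;
    if (d > 0) {
      int k_after = b + 1; // first miRNA position 3' of the bulge
      int mult = (k_after >= seed_from && k_after <= seed_to) ? sm10 : 10;
      s += (long) d * bu10 * mult / 10;
    }
    bool ok = true;
    for (int k = 1; k <= m; ++k) {
      int t_idx = (k <= b || d == 0) ? (k - 1) : (k - 1 + d);
      int mult = (k >= seed_from && k <= seed_to) ? sm10 : 10;
      s += (long) pos_penalty(mi[k - 1], rw[t_idx], gu10, mm10) * mult / 10;
      if (s >= best) { ok = false; break; }
    }
    if (ok && s < best) { best = (int) s; best_b = (d == 0) ? -1 : b; }
    if (d == 0) break;
  }
  return List::create(_["score"] = best / 10.0, _["bulge_after"] = best_b);
}

// scan every window of a transcript for one miRNA; returns hits with
// expectation <= cutoff as parallel vectors (start 1-based, window length,
// score, bulge_after).
// [[Rcpp::export(name = ".scan_transcript_cpp")]]
DataFrame scan_transcript_cpp(std::string mirna, std::string transcript,
                              double cutoff = 3.0, int max_bulge = 3,
                              double gu_penalty = 0.5, double mm_penalty = 1.0,
                              double bulge_penalty = 2.0, int seed_from = 2,
                              int seed_to = 13, double seed_mult = 2.0) {
  int m = (int) mirna.size();
  int L = (int) transcript.size();
  if (m == 0) stop("empty miRNA");
  std::string mi(m, 'N');
  for (int i = 0; i < m; ++i) mi[i] = norm_base(mirna[i]);
  std::string tx(L, 'N');
  for (int i = 0; i < L; ++i) tx[i] = norm_base(transcript[i]);
  int gu10 = (int) (gu_penalty * 10 + 0.5);
  int mm10 = (int) (mm_penalty * 10 + 0.5);
  int bu10 = (int) (bulge_penalty * 10 + 0.5);
  int sm10 = (int) (seed_mult * 10 + 0.5);
  int cut10 = (int) (cutoff * 10 + 0.5);
  std::vector<int> r_start, r_len, r_bulge;
  std::vector<double> r_score;
  for (int s0 = 0; s0 < L; ++s0) {
    for (int d = 0; d <= max_bulge && s0 + m + d <= L; ++d) {
      int w = m + d;
      int best = cut10 + 1, best_b = -1;
      int bmax = (d == 0) ? 0 : m;
      for (int b = 0; b <= bmax; ++b) {
        long s = 0;
        if (d > 0) {
          int k_after = b + 1;
          int mult = (k_after >= seed_from && k_after <= seed_to) ? sm10 : 10;
          s += (long) d * bu10 * mult / 10;
        }
        bool ok = (s < best);
        if (ok) {
          for (int k = 1; k <= m; ++k) {
            int t_idx = (k <= b || d == 0) ? (k - 1) : (k - 1 + d);
            // window runs s0..s0+w-1 on the transcript; rw[i]=tx[s0+w-1-i]
            char tb = tx[s0 + w - 1 - t_idx];
            int mult = (k >= seed_from && k <= seed_to) ? sm10 : 10;
            s += (long) pos_penalty(mi[k - 1], tb, gu10, mm10) * mult / 10;
            if (s >= best) { ok = false; break; }
          }
        }
        if (ok && s < best) { best = (int) s; best_b = (d == 0) ? -1 : b; }
        if (d == 0) break;
      }
      if (best <= cut10) {
        r_start.push_back(s0 + 1);
        r_len.push_back(w);
        r_score.push_back(best / 10.0);
        r_bulge.push_back(best_b);
      }
    }
  }
  return DataFrame::create(_["start"] = r_start, _["width"] = r_len,
                           _["expectation"] = r_score,
                           _["bulge_after"] = r_bulge,
                           _["stringsAsFactors"] = false);
}
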