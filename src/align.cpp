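#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Global (end-to-end) pairwise alignment with affine gap penalties.
// Scoring: +match for identical A/C/G/T, +mismatch otherwise (N mismatches
// everything, including N). A gap of length k scores gap_open + k*gap_ext
// (both supplied negative).
//
// Tie-breaking is deterministic: at equal score the traceback prefers the
// diagonal (match/mismatch) state, then deletion-from-reference, then
// insertion; gap openings are thereby pushed toward the 5' end of the
// reference (leftmost placement in repeat runs).

static const double NEG = -1e18;

static inline double subscore(char a, char b, double match, double mismatch) {
  if (a == b && a != 'N') return match;
  return mismatch;
}

// [[Rcpp::export(name = ".align_affine_cpp")]]
List align_affine_cpp(CharacterVector reads, std::string ref,
                      double match = 1.0, double mismatch = -3.0,
                      double gap_open = -5.0, double gap_ext = -2.0) {
  const int m = ref.size();
  const int nreads = reads.size();
  List out(nreads);

  for (int r = 0; r < nreads; ++r) {
    std::string pat = as<std::string>(reads[r]);
    const int n = pat.size();
    // DP over (n+1) x (m+1); states: 0=M diag, 1=D (gap in read, consumes
    // ref), 2=I (gap in ref, consumes read)
    std::vector<double> M((n + 1) * (m + 1), NEG);
    std::vector<double> D((n + 1) * (m + 1), NEG);
    std::vector<double> I((n + 1) * (m + 1), NEG);
    // traceback: which predecessor state fed each cell's state
    std::vector<unsigned char> tbM((n + 1) * (m + 1), 0);
    std::vector<unsigned char> tbD((n + 1) * (m + 1), 0);
    std::vector<unsigned char> tbI((n + 1) * (m + 1), 0);
    auto ix = [m](int i, int j) { return i * (m + 1) + j; };

    M[ix(0, 0)] = 0.0;
    for (int j = 1; j <= m; ++j) {
      D[ix(0, j)] = gap_open + gap_ext * j;
      tbD[ix(0, j)] = (j == 1) ? 0 : 1;
    }
    for (int i = 1; i <= n; ++i) {
      I[ix(i, 0)] = gap_open + gap_ext * i;
      tbI[ix(i, 0)] = (i == 1) ? 0 : 2;
    }

    for (int i = 1; i <= n; ++i) {
      for (int j = 1; j <= m; ++j) {
        const double s = subscore(pat[i - 1], ref[j - 1], match, mismatch);
        // M: from any state at (i-1, j-1); prefer M, then D, then I
        {
          double bm = M[ix(i - 1, j - 1)], bd = D[ix(i - 1, j - 1)],
                 bi = I[ix(i - 1, j - 1)];
          double best = bm; unsigned char st = 0;
          if (bd > best) { best = bd; st = 1; }
          if (bi > best) { best = bi; st = 2; }
          M[ix(i, j)] = best + s;
          tbM[ix(i, j)] = st;
        }
        // D: consume ref base j (deletion from read); open from M/I, extend D
        {
          double op = M[ix(i, j - 1)] + gap_open + gap_ext;
          double opI = I[ix(i, j - 1)] + gap_open + gap_ext;
          double ext = D[ix(i, j - 1)] + gap_ext;
          double best = op; unsigned char st = 0;
          if (ext > best) { best = ext; st = 1; }
          if (opI > best) { best = opI; st = 2; }
          D[ix(i, j)] = best;
          tbD[ix(i, j)] = st;
        }
        // I: consume read base i (insertion to ref)
        {
          double op = M[ix(i - 1, j)] + gap_open + gap_ext;
          double opD = D[ix(i - 1, j)] + gap_open + gap_ext;
          double ext = I[ix(i - 1, j)] + gap_ext;
          double best = op; unsigned char st = 0;
          if (opD > best) { best = opD; st = 1; }
          if (ext > best) { best = ext; st = 2; }
          I[ix(i, j)] = best;
          tbI[ix(i, j)] = st;
        }
      }
    }

    // terminal: prefer M, then D, then I at equal score
    double best = M[ix(n, m)]; unsigned char st = 0;
    if (D[ix(n, m)] > best) { best = D[ix(n, m)]; st = 1; }
    if (I[ix(n, m)] > best) { best = I[ix(n, m)]; st = 2; }

    // traceback
    std::string ap, as;
    ap.reserve(n + m); as.reserve(n + m);
    int i = n, j = m;
    while (i > 0 || j > 0) {
      if (st == 0) {
        unsigned char prev = tbM[ix(i, j)];
        ap.push_back(pat[i - 1]); as.push_back(ref[j - 1]);
        --i; --j; st = prev;
      } else if (st == 1) {
        unsigned char prev = tbD[ix(i, j)];
        ap.push_back('-'); as.push_back(ref[j - 1]);
        --j; st = prev;
      } else {
        unsigned char prev = tbI[ix(i, j)];
        ap.push_back(pat[i - 1]); as.push_back('-');
        --i; st = prev;
      }
    }
    std::reverse(ap.begin(), ap.end());
    std::reverse(as.begin(), as.end());

    out[r] = List::create(_["score"] = best,
                          _["pattern"] = ap,
                          _["subject"] = as);
  }
  return out;
}
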