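#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

// Alignment engines shared by the mining and LTR-comparison code.
// Scoring is fixed package-wide (match +1, mismatch -1, gap open -3,
// gap extend -1; a gap of length L costs open + (L-1) * extend) so that
// identities are reproducible bit-exactly.

static const int NEG_INF = -1000000000;

inline int subst(char a, char b, int match, int mismatch) {
  // N (or any non-ACGT) never matches, counts as mismatch
  if (a != b) return mismatch;
  if (a == 'A' || a == 'C' || a == 'G' || a == 'T') return match;
  return mismatch;
}

// Global (Needleman-Wunsch/Gotoh) alignment with affine gaps and
// deterministic traceback: diagonal > gap-in-A > gap-in-B on ties.
// States: 0 = M (a_i ~ b_j), 1 = X (gap in A, consumes b_j),
//         2 = Y (gap in B, consumes a_i).
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  int match = 1, int mismatch = -1,
                  int gap_open = -3, int gap_extend = -1) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");

  std::vector<int> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
  std::vector<int> Mcur(m + 1), Xcur(m + 1), Ycur(m + 1);
  // traceback: predecessor state for each cell/state, 3 bytes per cell
  std::vector<uint8_t> tbM((size_t)(n + 1) * (m + 1));
  std::vector<uint8_t> tbX((size_t)(n + 1) * (m + 1));
  std::vector<uint8_t> tbY((size_t)(n + 1) * (m + 1));
  const size_t W = (size_t)m + 1;

  Mprev[0] = 0; Xprev[0] = NEG_INF; Yprev[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG_INF;
    Xprev[j] = gap_open + (j - 1) * gap_extend;
    Yprev[j] = NEG_INF;
    tbX[(size_t)0 * W + j] = 1;
  }
  for (int i = 1; i <= n; ++i) {
    Mcur[0] = NEG_INF;
    Xcur[0] = NEG_INF;
    Ycur[0] = gap_open + (i - 1) * gap_extend;
    tbY[(size_t)i * W + 0] = 2;
    for (int j = 1; j <= m; ++j) {
      // M from best of previous diagonal, tie-break M > X > Y
      int s = subst(a[i - 1], b[j - 1], match, mismatch);
      int bestPrev = Mprev[j - 1]; uint8_t st = 0;
      if (Xprev[j - 1] > bestPrev) { bestPrev = Xprev[j - 1]; st = 1; }
      if (Yprev[j - 1] > bestPrev) { bestPrev = Yprev[j - 1]; st = 2; }
      Mcur[j] = (bestPrev <= NEG_INF / 2) ? NEG_INF : bestPrev + s;
      tbM[(size_t)i * W + j] = st;
      // X: gap in A, consumes b_j (move left)
      int xo = (Mcur[j - 1] <= NEG_INF / 2) ? NEG_INF : Mcur[j - 1] + gap_open;
      int xe = (Xcur[j - 1] <= NEG_INF / 2) ? NEG_INF : Xcur[j - 1] + gap_extend;
      int yo = (Ycur[j - 1] <= NEG_INF / 2) ? NEG_INF : Ycur[j - 1] + gap_open;
      int bx = xo; uint8_t sx = 0;
      if (xe > bx) { bx = xe; sx = 1; }
      if (yo > bx) { bx = yo; sx = 2; }
      Xcur[j] = bx; tbX[(size_t)i * W + j] = sx;
      // Y: gap in B, consumes a_i (move up)
      int ym = (Mprev[j] <= NEG_INF / 2) ? NEG_INF : Mprev[j] + gap_open;
      int yx = (Xprev[j] <= NEG_INF / 2) ? NEG_INF : Xprev[j] + gap_open;
      int ye = (Yprev[j] <= NEG_INF / 2) ? NEG_INF : Yprev[j] + gap_extend;
      int by = ym; uint8_t sy = 0;
      if (yx > by) { by = yx; sy = 1; }
      if (ye > by) { by = ye; sy = 2; }
      Ycur[j] = by; tbY[(size_t)i * W + j] = sy;
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  int score = Mprev[m]; uint8_t state = 0;
  if (Xprev[m] > score) { score = Xprev[m]; state = 1; }
  if (Yprev[m] > score) { score = Yprev[m]; state = 2; }

  // traceback
  std::string outa, outb;
  outa.reserve(n + m); outb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      uint8_t prev = tbM[(size_t)i * W + j];
      outa.push_back(a[i - 1]); outb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      uint8_t prev = tbX[(size_t)i * W + j];
      outa.push_back('-'); outb.push_back(b[j - 1]);
      --j; state = prev;
    } else {
      uint8_t prev = tbY[(size_t)i * W + j];
      outa.push_back(a[i - 1]); outb.push_back('-');
      --i; state = prev;
    }
  }
  std::reverse(outa.begin(), outa.end());
  std::reverse(outb.begin(), outb.end());
  return List::create(_["aligned_a"] = outa, _["aligned_b"] = outb,
                      _["score"] = score);
}

// Banded local (Smith-Waterman/Gotoh) alignment of a reference against a
// genomic window. The band constrains j - i (window minus reference
// coordinate) to [band_lo, band_hi]. Returns the best local alignment,
// its column statistics and a projection of reference positions onto
// window positions (NA where the reference base sits in a gap column).
// [[Rcpp::export]]
List local_align_banded_cpp(std::string a, std::string b,
                            int band_lo, int band_hi,
                            int match = 1, int mismatch = -1,
                            int gap_open = -3, int gap_extend = -1) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if (band_hi < band_lo) stop("invalid band");
  const int w = band_hi - band_lo + 1;

  std::vector<int> Mprev(w, 0), Xprev(w, NEG_INF), Yprev(w, NEG_INF);
  std::vector<int> Mcur(w), Xcur(w), Ycur(w);
  std::vector<uint8_t> tbM((size_t)(n + 1) * w, 255);
  std::vector<uint8_t> tbX((size_t)(n + 1) * w, 255);
  std::vector<uint8_t> tbY((size_t)(n + 1) * w, 255);

  int best = 0, bi = 0, bj = 0; uint8_t bstate = 0;
  // row i = reference prefix length; cell jj maps to j = i + band_lo + jj
  // row 0: local start anywhere => 0
  for (int i = 1; i <= n; ++i) {
    for (int jj = 0; jj < w; ++jj) {
      int j = i + band_lo + jj;
      if (j < 0 || j > m) { Mcur[jj] = NEG_INF; Xcur[jj] = NEG_INF; Ycur[jj] = NEG_INF; continue; }
      if (j == 0) { Mcur[jj] = NEG_INF; Xcur[jj] = NEG_INF; Ycur[jj] = NEG_INF; continue; }
      // diagonal predecessor (i-1, j-1) is same jj in previous row
      int s = subst(a[i - 1], b[j - 1], match, mismatch);
      int dM = Mprev[jj], dX = Xprev[jj], dY = Yprev[jj];
      int bestPrev = 0; uint8_t st = 3;           // 3 = local start
      if (dM > bestPrev) { bestPrev = dM; st = 0; }
      if (dX > bestPrev) { bestPrev = dX; st = 1; }
      if (dY > bestPrev) { bestPrev = dY; st = 2; }
      int mval = bestPrev + s;
      if (mval < 0) { mval = NEG_INF; st = 255; } // dead cell: never tracebacked
      Mcur[jj] = mval; tbM[(size_t)i * w + jj] = st;
      // X: (i, j-1) -> jj - 1 in current row
      int xM = (jj > 0) ? Mcur[jj - 1] : NEG_INF;
      int xX = (jj > 0) ? Xcur[jj - 1] : NEG_INF;
      int bx = (xM <= NEG_INF / 2) ? NEG_INF : xM + gap_open; uint8_t sx = 0;
      int xe = (xX <= NEG_INF / 2) ? NEG_INF : xX + gap_extend;
      if (xe > bx) { bx = xe; sx = 1; }
      Xcur[jj] = bx; tbX[(size_t)i * w + jj] = sx;
      // Y: (i-1, j) -> jj + 1 in previous row
      int yM = (jj + 1 < w) ? Mprev[jj + 1] : NEG_INF;
      int yY = (jj + 1 < w) ? Yprev[jj + 1] : NEG_INF;
      int by = (yM <= NEG_INF / 2) ? NEG_INF : yM + gap_open; uint8_t sy = 0;
      int ye = (yY <= NEG_INF / 2) ? NEG_INF : yY + gap_extend;
      if (ye > by) { by = ye; sy = 1; }
      Ycur[jj] = by; tbY[(size_t)i * w + jj] = sy;

      if (Mcur[jj] > best) { best = Mcur[jj]; bi = i; bj = j; bstate = 0; }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  IntegerVector proj(n, NA_INTEGER);
  if (best <= 0)
    return List::create(_["score"] = 0, _["ref_start"] = NA_INTEGER,
                        _["ref_end"] = NA_INTEGER, _["win_start"] = NA_INTEGER,
                        _["win_end"] = NA_INTEGER, _["matches"] = 0,
                        _["columns"] = 0, _["proj"] = proj);

  int i = bi, j = bj; uint8_t state = bstate;
  int matches = 0, columns = 0;
  int ref_end = bi, win_end = bj, ref_start = bi, win_start = bj;
  while (true) {
    if (state == 0) {
      uint8_t prev = tbM[(size_t)i * w + (j - i - band_lo)];
      proj[i - 1] = j;
      ++columns;
      if (subst(a[i - 1], b[j - 1], 1, -1) == 1) ++matches;
      ref_start = i; win_start = j;
      --i; --j;
      if (prev == 3) break;
      state = prev;
    } else if (state == 1) {
      uint8_t prev = tbX[(size_t)i * w + (j - i - band_lo)];
      ++columns; --j; state = prev;
    } else {
      uint8_t prev = tbY[(size_t)i * w + (j - i - band_lo)];
      ++columns; --i; state = prev;
    }
  }
  return List::create(_["score"] = best, _["ref_start"] = ref_start,
                      _["ref_end"] = ref_end, _["win_start"] = win_start,
                      _["win_end"] = win_end, _["matches"] = matches,
                      _["columns"] = columns, _["proj"] = proj);
}

// Exact k-mer seed matching (2-bit encoding, k <= 15). Returns a two-column
// matrix of 1-based (ref_pos, genome_pos) start coordinates; k-mers
// containing non-ACGT bases never seed.
// [[Rcpp::export]]
IntegerMatrix kmer_hits_cpp(std::string ref, std::string genome, int k = 12) {
  if (k < 4 || k > 15) stop("k must be in [4,15]");
  const int n = (int)ref.size(), m = (int)genome.size();
  std::unordered_map<uint32_t, std::vector<int> > index;
  if (m >= k) index.reserve((size_t)m);

  auto code = [](char c) -> int {
    switch (c) { case 'A': return 0; case 'C': return 1;
                 case 'G': return 2; case 'T': return 3; default: return -1; }
  };
  const uint32_t mask = (k < 16) ? ((1u << (2 * k)) - 1u) : 0xFFFFFFFFu;

  uint32_t h = 0; int run = 0;
  for (int i = 0; i < m; ++i) {
    int c = code(genome[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t)c) & mask;
    if (++run >= k) index[h].push_back(i - k + 2); // 1-based start
  }

  std::vector<int> rp, gp;
  h = 0; run = 0;
  for (int i = 0; i < n; ++i) {
    int c = code(ref[i]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t)c) & mask;
    if (++run >= k) {
      auto it = index.find(h);
      if (it != index.end()) {
        int rstart = i - k + 2;
        for (int g : it->second) { rp.push_back(rstart); gp.push_back(g); }
      }
    }
  }
  IntegerMatrix out((int)rp.size(), 2);
  for (size_t t = 0; t < rp.size(); ++t) { out(t, 0) = rp[t]; out(t, 1) = gp[t]; }
  colnames(out) = CharacterVector::create("ref_pos", "genome_pos");
  return out;
}
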