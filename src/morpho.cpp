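#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 8-connected component labeling by flood fill with an explicit stack.
// Labels are consecutive 1..k in order of first (column-major) encounter.
// [[Rcpp::export]]
IntegerMatrix label8_cpp(const IntegerMatrix& img) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (img(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int r2 = cr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (img(r2, c2) != 0 && lab(r2, c2) == 0) {
              lab(r2, c2) = next;
              stack.push_back(r2 + c2 * nr);
            }
          }
        }
      }
    }
  }
  lab.attr("object_count") = next;
  return lab;
}

// Yokoi connectivity number for 8-connected foreground.
// n[0..7] = E, NE, N, NW, W, SW, S, SE (1 = foreground).
static inline int yokoi8(const int* n) {
  int c = 0;
  for (int k = 0; k < 8; k += 2) {
    int a = 1 - n[k];
    int b = 1 - n[(k + 1) % 8];
    int d = 1 - n[(k + 2) % 8];
    c += a - a * b * d;
  }
  return c;
}

// Homotopic thinning ("ultimate thinning"): sequentially delete simple,
// non-endpoint border pixels, cycling over the four cardinal border
// directions until stable. Preserves the 8-connectivity of every
// component (a pixel is removed only if its Yokoi connectivity number
// is 1) and keeps line endpoints, so path lengths survive thinning.
// [[Rcpp::export]]
IntegerMatrix thin_cpp(const IntegerMatrix& img) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix out(clone(img));
  // direction offsets for the "border" test: N, S, E, W in (dr, dc)
  const int bdr[4] = {-1, 1, 0, 0};
  const int bdc[4] = {0, 0, 1, -1};
  // neighbour order E, NE, N, NW, W, SW, S, SE
  const int ndr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int ndc[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 4; ++d) {
      // collect this direction's border pixels first, so each pass peels
      // at most one layer (fully sequential deletion would let whole
      // columns cascade away within one scan)
      cand.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (out(r, c) == 0) continue;
          int rb = r + bdr[d], cb = c + bdc[d];
          int border = (rb < 0 || rb >= nr || cb < 0 || cb >= nc) ? 1 : (out(rb, cb) == 0);
          if (border) cand.push_back(r + c * nr);
        }
      }
      // delete sequentially (re-checking simplicity on the evolving
      // image preserves topology even among neighbouring candidates)
      for (size_t i = 0; i < cand.size(); ++i) {
        int r = cand[i] % nr, c = cand[i] / nr;
        if (out(r, c) == 0) continue;
        int n[8], cnt = 0;
        for (int k = 0; k < 8; ++k) {
          int r2 = r + ndr[k], c2 = c + ndc[k];
          n[k] = (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) ? 0 : (out(r2, c2) != 0);
          cnt += n[k];
        }
        if (cnt <= 1) continue;          // endpoint or isolated: keep
        if (yokoi8(n) != 1) continue;    // not simple: removal breaks topology
        out(r, c) = 0;
        changed = true;
      }
    }
  }
  return out;
}

// Length of a one-pixel-wide skeleton: each 4-adjacent pixel pair is one
// unit step, each diagonal pair counts sqrt(2) unless the two pixels share
// a 4-adjacent skeleton neighbour (the diagonal would double-count a
// corner already traversed orthogonally).
// [[Rcpp::export]]
double skeleton_length_cpp(const IntegerMatrix& skel) {
  const int nr = skel.nrow(), nc = skel.ncol();
  double len = 0.0;
  const double SQ2 = std::sqrt(2.0);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (skel(r, c) == 0) continue;
      // orthogonal pairs, counted once: right and down
      if (c + 1 < nc && skel(r, c + 1) != 0) len += 1.0;
      if (r + 1 < nr && skel(r + 1, c) != 0) len += 1.0;
      // diagonal pairs, counted once: down-right and down-left
      if (r + 1 < nr && c + 1 < nc && skel(r + 1, c + 1) != 0) {
        if (skel(r, c + 1) == 0 && skel(r + 1, c) == 0) len += SQ2;
      }
      if (r + 1 < nr && c - 1 >= 0 && skel(r + 1, c - 1) != 0) {
        if (skel(r, c - 1) == 0 && skel(r + 1, c) == 0) len += SQ2;
      }
    }
  }
  return len;
}
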