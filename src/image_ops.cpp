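// Low-level raster operations: separable convolution with reflective
// borders, min/max (erosion/dilation) filtering with replicate borders,
// 8-connected component labelling, Moore boundary tracing and
// flood-fill-from-outside hole filling.  All matrices are R column-major;
// coordinates returned to R are 1-based (row, col).
#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // symmetric half-sample reflection: -1 -> 0, -2 -> 1, n -> n-1, ...
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// [[Rcpp::export(name = ".sep_conv_reflect")]]
NumericMatrix sep_conv_reflect(const NumericMatrix& img,
                               const NumericVector& kern) {
  const int nr = img.nrow(), nc = img.ncol(), k = kern.size();
  const int half = (k - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // convolve along rows (vertical direction)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int d = -half; d <= half; ++d)
        s += kern[d + half] * img(reflect_idx(r + d, nr), c);
      tmp(r, c) = s;
    }
  // convolve along columns (horizontal direction)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int d = -half; d <= half; ++d)
        s += kern[d + half] * tmp(r, reflect_idx(c + d, nc));
      out(r, c) = s;
    }
  return out;
}

// [[Rcpp::export(name = ".minmax_filter")]]
NumericMatrix minmax_filter(const NumericMatrix& img,
                            const LogicalMatrix& support,
                            const bool take_min) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kr = support.nrow(), kc = support.ncol();
  const int hr = (kr - 1) / 2, hc = (kc - 1) / 2;
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double best = take_min ? R_PosInf : R_NegInf;
      for (int dc = -hc; dc <= hc; ++dc)
        for (int dr = -hr; dr <= hr; ++dr) {
          if (!support(dr + hr, dc + hc)) continue;
          // replicate padding: clamp to the border
          int rr = std::min(std::max(r + dr, 0), nr - 1);
          int cc = std::min(std::max(c + dc, 0), nc - 1);
          double v = img(rr, cc);
          if (take_min ? (v < best) : (v > best)) best = v;
        }
      out(r, c) = best;
    }
  return out;
}

// 8-connected component labelling of nonzero pixels.  Labels are assigned
// in raster order (scanning rows top-to-bottom, left-to-right), so
// component 1 contains the top-left-most foreground pixel.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(r2, c2) != 0 && lab(r2, c2) == 0) {
              lab(r2, c2) = next;
              stack.push_back(r2 + c2 * nr);
            }
          }
      }
    }
  return lab;
}

// Moore-neighbour tracing of the outer boundary of a single 8-connected
// component, clockwise, starting at the top-left-most pixel.  Terminates
// when the start pixel is re-entered from the same backtrack direction
// (Jacob's stopping criterion).  Returns an n x 2 matrix of 1-based
// (row, col) coordinates.
// [[Rcpp::export(name = ".trace_boundary")]]
IntegerMatrix trace_boundary(const LogicalMatrix& comp) {
  const int nr = comp.nrow(), nc = comp.ncol();
  int sr = -1, sc = -1;
  for (int r = 0; r < nr && sr < 0; ++r)
    for (int c = 0; c < nc; ++c)
      if (comp(r, c)) { sr = r; sc = c; break; }
  if (sr < 0) return IntegerMatrix(0, 2);
  // clockwise Moore neighbourhood, starting west:
  // W, NW, N, NE, E, SE, S, SW
  static const int DR[8] = { 0, -1, -1, -1, 0, 1, 1, 1 };
  static const int DC[8] = { -1, -1, 0, 1, 1, 1, 0, -1 };
  std::vector<int> rows, cols;
  rows.push_back(sr); cols.push_back(sc);
  // backtrack of the start: the pixel just before it in raster order is
  // background (start is top-left-most), i.e. its west neighbour.
  int cr = sr, cc = sc, back = 0;  // direction index pointing to backtrack
  // the walk is a deterministic function of the state (pixel, backtrack),
  // so the contour closes exactly when the state reached after the first
  // step recurs
  int first_r = -1, first_c = -1, first_b = -1;
  int guard = 8 * nr * nc + 8;
  while (guard-- > 0) {
    int found = -1;
    for (int i = 1; i <= 8; ++i) {
      int d = (back + i) % 8;
      int r2 = cr + DR[d], c2 = cc + DC[d];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (comp(r2, c2)) { found = d; break; }
    }
    if (found < 0) break;  // isolated pixel
    int r2 = cr + DR[found], c2 = cc + DC[found];
    // new backtrack points from the new pixel towards the neighbour just
    // before `found` in the clockwise scan (a background pixel)
    int prev = (found + 7) % 8;
    int br = cr + DR[prev], bc = cc + DC[prev];
    int nb = 0;
    for (int d = 0; d < 8; ++d)
      if (r2 + DR[d] == br && c2 + DC[d] == bc) { nb = d; break; }
    if (first_r < 0) {
      first_r = r2; first_c = c2; first_b = nb;
    } else if (r2 == first_r && c2 == first_c && nb == first_b) {
      break;
    }
    cr = r2; cc = c2; back = nb;
    rows.push_back(cr); cols.push_back(cc);
  }
  // drop a trailing revisit of the start pixel; closure is implicit
  if (rows.size() > 1 && rows.back() == sr && cols.back() == sc) {
    rows.pop_back(); cols.pop_back();
  }
  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = rows[i] + 1;
    out(i, 1) = cols[i] + 1;
  }
  return out;
}

// Fill holes of a binary image: background is flood-filled 4-connectedly
// from a 1-pixel virtual outside frame; pixels not reached become
// foreground.  4-connected background is the topological dual of
// 8-connected foreground.
// [[Rcpp::export(name = ".fill_holes")]]
LogicalMatrix fill_holes(const LogicalMatrix& m) {
  const int nr = m.nrow(), nc = m.ncol();
  std::vector<char> outside((size_t)nr * nc, 0);
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if ((r == 0 || r == nr - 1 || c == 0 || c == nc - 1) &&
          !m(r, c) && !outside[r + (size_t)c * nr]) {
        outside[r + (size_t)c * nr] = 1;
        stack.push_back(r + c * nr);
        while (!stack.empty()) {
          int idx = stack.back(); stack.pop_back();
          int rr = idx % nr, cc = idx / nr;
          const int dr4[4] = { -1, 1, 0, 0 };
          const int dc4[4] = { 0, 0, -1, 1 };
          for (int d = 0; d < 4; ++d) {
            int r2 = rr + dr4[d], c2 = cc + dc4[d];
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (!m(r2, c2) && !outside[r2 + (size_t)c2 * nr]) {
              outside[r2 + (size_t)c2 * nr] = 1;
              stack.push_back(r2 + c2 * nr);
            }
          }
        }
      }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = !outside[r + (size_t)c * nr];
  return out;
}
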