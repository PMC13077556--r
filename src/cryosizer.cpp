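#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// 3x3 median filter with replicated borders.
// [[Rcpp::export(name = "median3x3")]]
NumericMatrix median3x3(NumericMatrix x) {
  int H = x.nrow(), W = x.ncol();
  NumericMatrix out(H, W);
  double v[9];
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int k = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = std::min(std::max(j + dj, 0), W - 1);
        for (int di = -1; di <= 1; ++di) {
          int ii = std::min(std::max(i + di, 0), H - 1);
          v[k++] = x(ii, jj);
        }
      }
      std::nth_element(v, v + 4, v + 9);
      out(i, j) = v[4];
    }
  }
  return out;
}

// Hough circle accumulator. Outline pixel coordinates are 1-based (row, col);
// offsets[[j]] is an integer matrix of (dy, dx) perimeter offsets for the
// j-th radius. Each outline pixel votes for every candidate centre
// (y - dy, x - dx) that lies inside the image. Returns an integer vote
// array of dim (H, W, n_radii).
// [[Rcpp::export(name = "hough_accumulate_cpp")]]
IntegerVector hough_accumulate_cpp(int H, int W, IntegerVector ys,
                                   IntegerVector xs, List offsets) {
  int nr = offsets.size();
  IntegerVector acc(static_cast<R_xlen_t>(H) * W * nr, 0);
  acc.attr("dim") = IntegerVector::create(H, W, nr);
  int n = ys.size();
  for (int j = 0; j < nr; ++j) {
    IntegerMatrix off = offsets[j];
    int m = off.nrow();
    R_xlen_t plane = static_cast<R_xlen_t>(H) * W * j;
    for (int p = 0; p < n; ++p) {
      int y = ys[p], x = xs[p];
      for (int q = 0; q < m; ++q) {
        int cy = y - off(q, 0), cx = x - off(q, 1);
        if (cy >= 1 && cy <= H && cx >= 1 && cx <= W)
          ++acc[plane + static_cast<R_xlen_t>(cx - 1) * H + (cy - 1)];
      }
    }
  }
  return acc;
}

// 8-connectivity connected-component labelling (iterative flood fill).
// Returns an integer matrix with background 0 and components 1..n in
// raster-scan discovery order.
// [[Rcpp::export(name = "label_components8")]]
IntegerMatrix label_components8(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        int ci = stack.back().first, cj = stack.back().second;
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= H || nj >= W) continue;
            if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}

static inline int px(const IntegerMatrix &m, int i, int j) {
  if (i < 0 || j < 0 || i >= m.nrow() || j >= m.ncol()) return 0;
  return m(i, j) != 0 ? 1 : 0;
}

// Zhang-Suen thinning of a binary matrix to a 1-pixel-wide skeleton.
// Preserves connectivity, so an annulus thins to a closed ring.
// [[Rcpp::export(name = "zhang_suen_thin")]]
IntegerMatrix zhang_suen_thin(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix m = clone(mask);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) m(i, j) = m(i, j) != 0 ? 1 : 0;
  bool changed = true;
  std::vector<std::pair<int, int> > del;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      del.clear();
      for (int j = 0; j < W; ++j) {
        for (int i = 0; i < H; ++i) {
          if (!m(i, j)) continue;
          int p2 = px(m, i - 1, j),     p3 = px(m, i - 1, j + 1);
          int p4 = px(m, i, j + 1),     p5 = px(m, i + 1, j + 1);
          int p6 = px(m, i + 1, j),     p7 = px(m, i + 1, j - 1);
          int p8 = px(m, i, j - 1),     p9 = px(m, i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(i, j));
        }
      }
      if (!del.empty()) changed = true;
      for (size_t k = 0; k < del.size(); ++k)
        m(del[k].first, del[k].second) = 0;
    }
  }
  return m;
}
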