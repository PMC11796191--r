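#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Connected-component labelling with selectable connectivity.
// Components are numbered in the order their first pixel is met in a
// row-major scan (top-left to bottom-right), which fixes a deterministic
// instance ordering downstream.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> dr, dc;
  if (connectivity == 4) {
    dr = {-1, 1, 0, 0}; dc = {0, 0, -1, 1};
  } else {
    dr = {-1, 1, 0, 0, -1, -1, 1, 1}; dc = {0, 0, -1, 1, -1, 1, -1, 1};
  }
  int next = 0;
  std::queue<std::pair<int,int>> q;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push({r, c});
      while (!q.empty()) {
        auto pc = q.front(); q.pop();
        for (size_t k = 0; k < dr.size(); ++k) {
          int rr = pc.first + dr[k], cc = pc.second + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push({rr, cc});
          }
        }
      }
    }
  }
  return lab;
}

// Even-odd scanline polygon fill at pixel centres. Vertices are in pixel
// coordinates (x = column, y = row), 0-based, pixel centre of (r, c) at
// (x = c, y = r). Multiple rings may be passed concatenated with `ring_start`
// giving 0-based offsets; even-odd parity across all rings handles holes.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_polygon(NumericVector xs, NumericVector ys,
                               IntegerVector ring_start, int nrow, int ncol) {
  LogicalMatrix out(nrow, ncol);
  int nring = ring_start.size();
  for (int r = 0; r < nrow; ++r) {
    double y = r;
    std::vector<double> xcross;
    for (int g = 0; g < nring; ++g) {
      int s = ring_start[g];
      int e = (g + 1 < nring) ? ring_start[g + 1] : xs.size();
      int n = e - s;
      if (n < 3) continue;
      for (int i = 0; i < n; ++i) {
        double x1 = xs[s + i], y1 = ys[s + i];
        double x2 = xs[s + (i + 1) % n], y2 = ys[s + (i + 1) % n];
        // half-open rule avoids double-counting vertices on the scanline
        if ((y1 <= y && y2 > y) || (y2 <= y && y1 > y)) {
          xcross.push_back(x1 + (y - y1) / (y2 - y1) * (x2 - x1));
        }
      }
    }
    if (xcross.empty()) continue;
    std::sort(xcross.begin(), xcross.end());
    for (size_t k = 0; k + 1 < xcross.size(); k += 2) {
      int c0 = (int)std::ceil(xcross[k]);
      int c1 = (int)std::floor(xcross[k + 1]);
      // pixel centre strictly inside on the right edge (half-open)
      if (std::floor(xcross[k + 1]) == xcross[k + 1]) c1 -= 1;
      if (c0 < 0) c0 = 0;
      if (c1 >= ncol) c1 = ncol - 1;
      for (int c = c0; c <= c1; ++c) out(r, c) = true;
    }
  }
  return out;
}

// Local thickness by maximal-disk stamping. `dist` holds the Euclidean
// distance transform of the mask (distance to nearest background pixel).
// Disk centres whose disk is contained in a neighbour's disk are pruned
// (this preserves the exact result: a dominated disk never contributes to
// the max-composite). Each surviving centre stamps value D(c) on pixels
// strictly within distance D(c); compositing keeps the maximum.
// [[Rcpp::export]]
NumericMatrix cpp_local_thickness(NumericMatrix dist) {
  int H = dist.nrow(), W = dist.ncol();
  NumericMatrix out(H, W);
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const double dd[8] = {1, 1, 1, 1, M_SQRT2, M_SQRT2, M_SQRT2, M_SQRT2};
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double d = dist(r, c);
      if (d <= 0) continue;
      bool dominated = false;
      for (int k = 0; k < 8 && !dominated; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (dist(rr, cc) >= d + dd[k]) dominated = true;
      }
      if (dominated) continue;
      int rad = (int)std::ceil(d);
      double d2 = d * d;
      for (int q = std::max(0, c - rad); q <= std::min(W - 1, c + rad); ++q) {
        double dx2 = (double)(q - c) * (q - c);
        for (int p = std::max(0, r - rad); p <= std::min(H - 1, r + rad); ++p) {
          double rr2 = dx2 + (double)(p - r) * (p - r);
          if (rr2 < d2 && out(p, q) < d) out(p, q) = d;
        }
      }
    }
  }
  return out;
}

// Pairwise overlap table between two instance labellings of the same image:
// counts of pixels carrying (true label i, predicted label j), i,j >= 1.
// [[Rcpp::export]]
IntegerMatrix cpp_overlap_table(IntegerMatrix truth, IntegerMatrix pred,
                                int n_true, int n_pred) {
  IntegerMatrix out(n_true, n_pred);
  int n = truth.size();
  for (int i = 0; i < n; ++i) {
    int t = truth[i], p = pred[i];
    if (t > 0 && p > 0) out(t - 1, p - 1)++;
  }
  return out;
}
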