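// Phase singularity detection by the 2x2 circular line integral, and
// 8-connected component labelling for decoding dense PS prediction images.
#include <Rcpp.h>
using namespace Rcpp;

static inline double wrap_pi(double d) {
  // map to (-pi, pi]
  d = std::fmod(d + M_PI, 2.0 * M_PI);
  if (d <= 0) d += 2.0 * M_PI;
  return d - M_PI;
}

// phases: H x W x T array (NA allowed); mask: H x W logical (or 0-length).
// Returns matrix with columns t (1-based frame), x, y (0-based, plaquette
// centre at +0.5), chirality.
// [[Rcpp::export]]
NumericMatrix ps_detect(NumericVector phases, LogicalVector mask, double tol) {
  IntegerVector dm = phases.attr("dim");
  int H = dm[0], W = dm[1], T = (dm.size() > 2) ? dm[2] : 1;
  bool has_mask = mask.size() == H * W;
  std::vector<double> out;
  const double two_pi = 2.0 * M_PI;
  for (int t = 0; t < T; ++t) {
    const double* ph = &phases[(R_xlen_t)t * H * W];
    for (int c = 0; c + 1 < W; ++c) {
      for (int r = 0; r + 1 < H; ++r) {
        if (has_mask &&
            !(mask[r + H * c] && mask[r + 1 + H * c] && mask[r + H * (c + 1)] &&
              mask[r + 1 + H * (c + 1)]))
          continue;
        double p00 = ph[r + H * c], p01 = ph[r + H * (c + 1)],
               p11 = ph[r + 1 + H * (c + 1)], p10 = ph[r + 1 + H * c];
        if (ISNAN(p00) || ISNAN(p01) || ISNAN(p11) || ISNAN(p10)) continue;
        double s = wrap_pi(p01 - p00) + wrap_pi(p11 - p01) +
                   wrap_pi(p10 - p11) + wrap_pi(p00 - p10);
        if (std::fabs(std::fabs(s) - two_pi) < tol) {
          out.push_back(t + 1);
          out.push_back(c + 0.5);
          out.push_back(r + 0.5);
          out.push_back(s > 0 ? 1.0 : -1.0);
        }
      }
    }
  }
  int n = out.size() / 4;
  NumericMatrix res(n, 4);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 4; ++j) res(i, j) = out[4 * i + j];
  colnames(res) = CharacterVector::create("t", "x", "y", "chirality");
  return res;
}

// 8-connected component labelling of a logical matrix (iterative flood fill).
// [[Rcpp::export]]
IntegerMatrix label_components8(LogicalMatrix img) {
  int H = img.nrow(), W = img.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!img(r, c) || lab(r, c)) continue;
      ++next;
      stack.clear();
      stack.push_back({r, c});
      lab(r, c) = next;
      while (!stack.empty()) {
        auto [rr, cc] = stack.back();
        stack.pop_back();
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (!dr && !dc) continue;
            int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
            if (img(r2, c2) && !lab(r2, c2)) {
              lab(r2, c2) = next;
              stack.push_back({r2, c2});
            }
          }
        }
      }
    }
  }
  return lab;
}
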