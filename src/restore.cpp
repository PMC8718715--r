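// Spatio-temporal kernel operations on complex-encoded phase movies:
// Kuramoto order parameter, Jacobi inpainting, phasor smoothing.
// Phase movies are passed as cos/sin arrays (H x W x T) with NaN = missing.
#include <Rcpp.h>
using namespace Rcpp;

struct DiskOffsets {
  std::vector<int> dr, dc;
};

static DiskOffsets disk_offsets(double d) {
  DiskOffsets o;
  int rad = (int)std::floor(d / 2.0);
  double r2 = (d / 2.0) * (d / 2.0);
  for (int dc = -rad; dc <= rad; ++dc)
    for (int dr = -rad; dr <= rad; ++dr)
      if (dr * dr + dc * dc <= r2) {
        o.dr.push_back(dr);
        o.dc.push_back(dc);
      }
  return o;
}

// Kuramoto order parameter r(x,y;t) over disk (diameter d) x dt_frames window.
// mask (H x W logical, may be length 0): pixels outside mask are ignored.
// [[Rcpp::export]]
NumericVector kuramoto_movie(NumericVector cosA, NumericVector sinA,
                             LogicalVector mask, double d, int dt_frames) {
  IntegerVector dm = cosA.attr("dim");
  int H = dm[0], W = dm[1], T = (dm.size() > 2) ? dm[2] : 1;
  bool has_mask = mask.size() == H * W;
  DiskOffsets o = disk_offsets(d);
  int hw = dt_frames / 2;
  NumericVector out(cosA.size());
  out.attr("dim") = dm;
  for (int t = 0; t < T; ++t) {
    int t0 = std::max(0, t - hw), t1 = std::min(T - 1, t + hw);
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        if (has_mask && !mask[r + H * c]) {
          out[r + H * (c + (R_xlen_t)W * t)] = NA_REAL;
          continue;
        }
        double sc = 0.0, ss = 0.0;
        int n = 0;
        for (size_t j = 0; j < o.dr.size(); ++j) {
          int rr = r + o.dr[j], cc = c + o.dc[j];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (has_mask && !mask[rr + H * cc]) continue;
          for (int tt = t0; tt <= t1; ++tt) {
            R_xlen_t k = rr + H * (cc + (R_xlen_t)W * tt);
            double cv = cosA[k];
            if (ISNAN(cv)) continue;
            sc += cv;
            ss += sinA[k];
            ++n;
          }
        }
        out[r + H * (c + (R_xlen_t)W * t)] =
            (n > 0) ? std::sqrt(sc * sc + ss * ss) / n : NA_REAL;
      }
    }
  }
  return out;
}

// Jacobi inpainting: missing entries (NaN) filled by the argument of the
// kernel phasor mean when at least min_frac of the in-image (and in-mask)
// kernel entries are valid. Newly filled values are used only from the next
// iteration. Runs n_iter iterations, or until filled when fill_all is true
// (hard cap 1000). Returns list(cos, sin, unfilled, iterations).
// [[Rcpp::export]]
List inpaint_movie(NumericVector cosA, NumericVector sinA, LogicalVector mask,
                   double d, int dt_frames, double min_frac, int n_iter,
                   bool fill_all) {
  IntegerVector dm = cosA.attr("dim");
  int H = dm[0], W = dm[1], T = (dm.size() > 2) ? dm[2] : 1;
  bool has_mask = mask.size() == H * W;
  DiskOffsets o = disk_offsets(d);
  int hw = dt_frames / 2;
  std::vector<double> C(cosA.begin(), cosA.end()), S(sinA.begin(), sinA.end());
  std::vector<double> C2, S2;
  R_xlen_t total = (R_xlen_t)H * W * T;
  int it = 0, cap = fill_all ? std::max(n_iter, 1000) : n_iter;
  R_xlen_t missing = 0;
  for (R_xlen_t i = 0; i < total; ++i) {
    int px = i % ((R_xlen_t)H * W);
    if (has_mask && !mask[px]) continue;
    if (ISNAN(C[i])) ++missing;
  }
  while (missing > 0 && it < cap) {
    C2 = C;
    S2 = S;
    R_xlen_t filled = 0;
    for (int t = 0; t < T; ++t) {
      int t0 = std::max(0, t - hw), t1 = std::min(T - 1, t + hw);
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          R_xlen_t k0 = r + H * (c + (R_xlen_t)W * t);
          if (!ISNAN(C[k0])) continue;
          if (has_mask && !mask[r + H * c]) continue;
          double sc = 0.0, ss = 0.0;
          int nvalid = 0, ntot = 0;
          for (size_t j = 0; j < o.dr.size(); ++j) {
            int rr = r + o.dr[j], cc = c + o.dc[j];
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            if (has_mask && !mask[rr + H * cc]) continue;
            for (int tt = t0; tt <= t1; ++tt) {
              R_xlen_t k = rr + H * (cc + (R_xlen_t)W * tt);
              ++ntot;
              if (ISNAN(C[k])) continue;
              sc += C[k];
              ss += S[k];
              ++nvalid;
            }
          }
          if (ntot > 0 && nvalid >= min_frac * ntot && nvalid > 0) {
            double nrm = std::sqrt(sc * sc + ss * ss);
            if (nrm > 0) {
              C2[k0] = sc / nrm;
              S2[k0] = ss / nrm;
            } else {
              C2[k0] = 1.0;
              S2[k0] = 0.0;
            }
            ++filled;
          }
        }
      }
    }
    C.swap(C2);
    S.swap(S2);
    missing -= filled;
    ++it;
    if (filled == 0 && fill_all) break;
    if (filled == 0 && !fill_all && missing > 0 && it < cap) break;
  }
  NumericVector Cout(C.begin(), C.end()), Sout(S.begin(), S.end());
  Cout.attr("dim") = dm;
  Sout.attr("dim") = dm;
  return List::create(_["cos"] = Cout, _["sin"] = Sout,
                      _["unfilled"] = (double)missing, _["iterations"] = it);
}

// Phasor smoothing: every value replaced by the argument of the kernel mean
// phasor (valid entries only). Returns list(cos, sin) of unit phasors.
// [[Rcpp::export]]
List smooth_movie(NumericVector cosA, NumericVector sinA, LogicalVector mask,
                  double d, int dt_frames) {
  IntegerVector dm = cosA.attr("dim");
  int H = dm[0], W = dm[1], T = (dm.size() > 2) ? dm[2] : 1;
  bool has_mask = mask.size() == H * W;
  DiskOffsets o = disk_offsets(d);
  int hw = dt_frames / 2;
  NumericVector Cout(cosA.size()), Sout(sinA.size());
  Cout.attr("dim") = dm;
  Sout.attr("dim") = dm;
  for (int t = 0; t < T; ++t) {
    int t0 = std::max(0, t - hw), t1 = std::min(T - 1, t + hw);
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        R_xlen_t k0 = r + H * (c + (R_xlen_t)W * t);
        if (has_mask && !mask[r + H * c]) {
          Cout[k0] = NA_REAL;
          Sout[k0] = NA_REAL;
          continue;
        }
        double sc = 0.0, ss = 0.0;
        int n = 0;
        for (size_t j = 0; j < o.dr.size(); ++j) {
          int rr = r + o.dr[j], cc = c + o.dc[j];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (has_mask && !mask[rr + H * cc]) continue;
          for (int tt = t0; tt <= t1; ++tt) {
            R_xlen_t k = rr + H * (cc + (R_xlen_t)W * tt);
            if (ISNAN(cosA[k])) continue;
            sc += cosA[k];
            ss += sinA[k];
            ++n;
          }
        }
        if (n == 0) {
          Cout[k0] = NA_REAL;
          Sout[k0] = NA_REAL;
        } else {
          double nrm = std::sqrt(sc * sc + ss * ss);
          if (nrm > 0) {
            Cout[k0] = sc / nrm;
            Sout[k0] = ss / nrm;
          } else {
            Cout[k0] = 1.0;
            Sout[k0] = 0.0;
          }
        }
      }
    }
  }
  return List::create(_["cos"] = Cout, _["sin"] = Sout);
}

// Sliding-window min-max normalization per pixel (centered window, truncated
// at the edges) using monotonic deques. Constant-window pixels map to 0 and
// are flagged. Returns list(frames, flagged).
// [[Rcpp::export]]
List sliding_window_minmax(NumericVector frames, int window) {
  IntegerVector dm = frames.attr("dim");
  int H = dm[0], W = dm[1], T = (dm.size() > 2) ? dm[2] : 1;
  NumericVector out(frames.size());
  out.attr("dim") = dm;
  LogicalMatrix flagged(H, W);
  int hw = window / 2;
  std::vector<double> x(T);
  std::vector<double> mn(T), mx(T);
  std::deque<int> qmin, qmax;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      for (int t = 0; t < T; ++t) x[t] = frames[r + H * (c + (R_xlen_t)W * t)];
      // sliding windows [t-hw, t+hw] intersect [0, T-1]
      qmin.clear();
      qmax.clear();
      int right = -1;
      for (int t = 0; t < T; ++t) {
        int lo = std::max(0, t - hw), hi = std::min(T - 1, t + hw);
        while (right < hi) {
          ++right;
          while (!qmin.empty() && x[qmin.back()] >= x[right]) qmin.pop_back();
          qmin.push_back(right);
          while (!qmax.empty() && x[qmax.back()] <= x[right]) qmax.pop_back();
          qmax.push_back(right);
        }
        while (qmin.front() < lo) qmin.pop_front();
        while (qmax.front() < lo) qmax.pop_front();
        mn[t] = x[qmin.front()];
        mx[t] = x[qmax.front()];
      }
      bool anyflat = false;
      for (int t = 0; t < T; ++t) {
        double range = mx[t] - mn[t];
        R_xlen_t k = r + H * (c + (R_xlen_t)W * t);
        if (range <= 0) {
          out[k] = 0.0;
          anyflat = true;
        } else {
          out[k] = (x[t] - mn[t]) / range;
        }
      }
      flagged(r, c) = anyflat;
    }
  }
  return List::create(_["frames"] = out, _["flagged"] = flagged);
}
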