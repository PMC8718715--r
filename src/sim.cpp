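// Explicit-Euler integrator for the two-variable Aliev-Panfilov model on a
// regular 2D grid with no-flux boundaries.
#include <Rcpp.h>
using namespace Rcpp;

// index helper: column-major (r + H*c)
static inline int ix(int r, int c, int H) { return r + H * c; }

// Laplacian with zero-gradient (no-flux) boundaries.
// stencil: 5 -> standard 5-point cross; 9 -> isotropic 9-point
// (2/3 cross + 1/6 diagonals - 10/3 centre).
static void laplacian(const double* V, double* L, int H, int W, int stencil) {
  for (int c = 0; c < W; ++c) {
    int cm = (c > 0) ? c - 1 : 0;
    int cp = (c < W - 1) ? c + 1 : W - 1;
    for (int r = 0; r < H; ++r) {
      int rm = (r > 0) ? r - 1 : 0;
      int rp = (r < H - 1) ? r + 1 : H - 1;
      double ctr = V[ix(r, c, H)];
      double cross = V[ix(rm, c, H)] + V[ix(rp, c, H)] +
                     V[ix(r, cm, H)] + V[ix(r, cp, H)];
      if (stencil == 5) {
        L[ix(r, c, H)] = cross - 4.0 * ctr;
      } else {
        double diag = V[ix(rm, cm, H)] + V[ix(rm, cp, H)] +
                      V[ix(rp, cm, H)] + V[ix(rp, cp, H)];
        L[ix(r, c, H)] = (2.0 / 3.0) * cross + (1.0 / 6.0) * diag -
                         (10.0 / 3.0) * ctr;
      }
    }
  }
}

// One reaction-diffusion Euler step; V, r updated in place via buffers.
static void euler_step(std::vector<double>& V, std::vector<double>& r,
                       std::vector<double>& lap, int H, int W,
                       double a, double k, double eps0, double mu1, double mu2,
                       double D, double dt, double inv_dx2, int stencil) {
  laplacian(V.data(), lap.data(), H, W, stencil);
  int n = H * W;
  for (int i = 0; i < n; ++i) {
    double v = V[i], u = r[i];
    double dV = D * lap[i] * inv_dx2 - k * v * (v - a) * (v - 1.0) - v * u;
    double eps = eps0 + mu1 * u / (v + mu2);
    double dr = eps * (k * v * (a + 1.0 - v) - u);
    V[i] = v + dt * dV;
    r[i] = u + dt * dr;
  }
}

static void apply_disk(std::vector<double>& V, int H, int W, double x, double y,
                       double radius, double amplitude) {
  double r2 = radius * radius;
  int c0 = std::max(0, (int)std::floor(x - radius)),
      c1 = std::min(W - 1, (int)std::ceil(x + radius));
  int r0 = std::max(0, (int)std::floor(y - radius)),
      r1 = std::min(H - 1, (int)std::ceil(y + radius));
  for (int c = c0; c <= c1; ++c)
    for (int rr = r0; rr <= r1; ++rr) {
      double dx = c - x, dy = rr - y;
      if (dx * dx + dy * dy <= r2)
        V[ix(rr, c, H)] = std::max(V[ix(rr, c, H)], amplitude);
    }
}

// Integrate n_steps Euler steps from (V0, r0), applying events, optionally
// recording snapshots. events: matrix with columns
//   step | type (0 = disk stim, 1 = column-band, 2 = rect region) |
//   p1..p4 (disk: x y radius amplitude; band: col0 col1 amplitude -;
//           rect: row0 row1 col0 col1 -> amplitude fixed at 1)
// record_from: first step index (0-based) at which snapshots are taken;
// snapshots are taken when (step - record_from) %% stride == 0, AFTER the step.
// [[Rcpp::export]]
List ap_integrate(NumericMatrix V0, NumericMatrix r0, NumericMatrix events,
                  double a, double k, double eps0, double mu1, double mu2,
                  double D, double dt, double dx, int stencil,
                  int n_steps, int record_from, int stride, int n_snapshots) {
  int H = V0.nrow(), W = V0.ncol();
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> r(r0.begin(), r0.end());
  std::vector<double> lap(H * W);
  double inv_dx2 = 1.0 / (dx * dx);

  NumericVector frames;
  if (n_snapshots > 0) {
    frames = NumericVector(Dimension(H, W, n_snapshots));
  }
  int ne = events.nrow(), ei = 0, taken = 0;

  for (int s = 0; s < n_steps; ++s) {
    while (ei < ne && (int)events(ei, 0) == s) {
      int type = (int)events(ei, 1);
      if (type == 0) {
        apply_disk(V, H, W, events(ei, 2), events(ei, 3), events(ei, 4),
                   events(ei, 5));
      } else if (type == 1) {
        int c0 = std::max(0, (int)events(ei, 2));
        int c1 = std::min(W - 1, (int)events(ei, 3));
        double amp = events(ei, 4);
        for (int c = c0; c <= c1; ++c)
          for (int rr = 0; rr < H; ++rr)
            V[ix(rr, c, H)] = std::max(V[ix(rr, c, H)], amp);
      } else {
        int rr0 = std::max(0, (int)events(ei, 2));
        int rr1 = std::min(H - 1, (int)events(ei, 3));
        int c0 = std::max(0, (int)events(ei, 4));
        int c1 = std::min(W - 1, (int)events(ei, 5));
        for (int c = c0; c <= c1; ++c)
          for (int rr = rr0; rr <= rr1; ++rr)
            V[ix(rr, c, H)] = std::max(V[ix(rr, c, H)], 1.0);
      }
      ++ei;
    }
    euler_step(V, r, lap, H, W, a, k, eps0, mu1, mu2, D, dt, inv_dx2, stencil);
    if (n_snapshots > 0 && s >= record_from &&
        (s - record_from) % stride == 0 && taken < n_snapshots) {
      std::copy(V.begin(), V.end(), frames.begin() + (R_xlen_t)taken * H * W);
      ++taken;
    }
    if ((s & 1023) == 0) {
      // divergence guard: sample a value
      double v = V[ix(H / 2, W / 2, H)];
      if (!std::isfinite(v))
        stop("integration diverged (non-finite V) at step %d; dt=%g dx=%g", s,
             dt, dx);
    }
  }
  for (int i = 0; i < H * W; ++i)
    if (!std::isfinite(V[i]) || !std::isfinite(r[i]))
      stop("integration diverged (non-finite field); dt=%g dx=%g", dt, dx);

  NumericMatrix Vout(H, W), rout(H, W);
  std::copy(V.begin(), V.end(), Vout.begin());
  std::copy(r.begin(), r.end(), rout.begin());
  return List::create(_["V"] = Vout, _["r"] = rout, _["frames"] = frames,
                      _["n_recorded"] = taken);
}
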