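// Time integration of solute advection-diffusion on the tensor finite-volume
// grid. Advection: explicit flux-form MUSCL upwind with minmod limiter
// (positivity-preserving at CFL <= ~0.5). Diffusion: implicit, dimensional
// splitting (Thomas solves per row/column). All boundary solute fluxes are
// zero: walls and interface pass no solute, the bottom inflow carries pure
// water. Mass is therefore conserved to round-off by construction.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double minmod(double a, double b) {
  if (a > 0.0 && b > 0.0) return a < b ? a : b;
  if (a < 0.0 && b < 0.0) return a > b ? a : b;
  return 0.0;
}

// [[Rcpp::export]]
List transport_run_cpp(NumericVector c0, int nx, int ny,
                       NumericVector dx, NumericVector dy,
                       NumericVector xc, NumericVector yc,
                       NumericVector Fx, NumericVector Fy,
                       double D, double dt, int nsteps,
                       IntegerVector snap_steps, double c_in,
                       NumericVector Fy_bottom) {
  const int ncell = nx * ny;
  std::vector<double> c(c0.begin(), c0.end()), cnew(ncell), flux(ncell);
  std::vector<double> vol(ncell);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) vol[j * nx + i] = dx[i] * dy[j];

  // precomputed implicit-diffusion coefficients
  std::vector<double> ax(nx - 1), ay(ny - 1);
  for (int i = 0; i + 1 < nx; ++i) ax[i] = D / (xc[i + 1] - xc[i]);
  for (int j = 0; j + 1 < ny; ++j) ay[j] = D / (yc[j + 1] - yc[j]);

  // Thomas scratch
  std::vector<double> cp(std::max(nx, ny)), dp(std::max(nx, ny));

  NumericMatrix snaps(ncell, snap_steps.size());
  int isnap = 0;
  // snapshot at step 0 if requested
  while (isnap < snap_steps.size() && snap_steps[isnap] == 0) {
    for (int q = 0; q < ncell; ++q) snaps(q, isnap) = c[q];
    ++isnap;
  }

  for (int step = 1; step <= nsteps; ++step) {
    // ---- advection (explicit, limited upwind) ----
    std::fill(flux.begin(), flux.end(), 0.0);
    // interior x faces: face f between cells (f-1, j) and (f, j)
    for (int j = 0; j < ny; ++j) {
      const double* cr = &c[j * nx];
      double* fr = &flux[j * nx];
      for (int f = 1; f < nx; ++f) {
        const double F = Fx[j * (nx + 1) + f];
        if (F == 0.0) continue;
        int up, dn;
        double cf;
        if (F > 0.0) { up = f - 1; dn = f; } else { up = f; dn = f - 1; }
        double s = 0.0;
        const int uu = up + (up - dn); // second-upwind cell index
        if (uu >= 0 && uu < nx) {
          const double s1 = (cr[up] - cr[uu]) / (xc[up] - xc[uu]);
          const double s2 = (cr[dn] - cr[up]) / (xc[dn] - xc[up]);
          s = minmod(s1, s2);
        }
        // face position is midway between the uniform-x centers
        cf = cr[up] + s * 0.5 * (xc[dn] - xc[up]);
        const double q = F * cf;        // solute flux in +x through the face
        fr[f - 1] -= q;
        fr[f] += q;
      }
    }
    // interior y faces: face g between cells (i, g-1) and (i, g)
    for (int g = 1; g < ny; ++g) {
      for (int i = 0; i < nx; ++i) {
        const double F = Fy[g * nx + i];
        if (F == 0.0) continue;
        int up, dn;
        if (F > 0.0) { up = g - 1; dn = g; } else { up = g; dn = g - 1; }
        double s = 0.0;
        const int uu = up + (up - dn);
        if (uu >= 0 && uu < ny) {
          const double s1 = (c[up * nx + i] - c[uu * nx + i]) / (yc[up] - yc[uu]);
          const double s2 = (c[dn * nx + i] - c[up * nx + i]) / (yc[dn] - yc[up]);
          s = minmod(s1, s2);
        }
        // distance from upwind center to the face
        const double dface = (F > 0.0) ? (yc[up] + 0.5 * dy[up] - yc[up])
                                       : (yc[up] - 0.5 * dy[up] - yc[up]);
        const double cf = c[up * nx + i] + s * dface;
        const double q = F * cf;        // solute flux in +y through the face
        flux[(g - 1) * nx + i] -= q;
        flux[g * nx + i] += q;
      }
    }
    // sample-laden feed: advective solute influx through the bottom faces
    if (c_in > 0.0) {
      for (int i = 0; i < nx; ++i)
        flux[i] += Fy_bottom[i] * c_in;
    }
    for (int q = 0; q < ncell; ++q) c[q] += dt * flux[q] / vol[q];

    // ---- diffusion, x sweep (implicit) ----
    for (int j = 0; j < ny; ++j) {
      double* cr = &c[j * nx];
      // tridiagonal: (vol/dt + sum a) c* - a_w c*_w - a_e c*_e = vol/dt c
      // a between i and i+1: ax[i] * dy[j]
      double b0 = vol[j * nx] / dt + ax[0] * dy[j];
      cp[0] = -ax[0] * dy[j] / b0;
      dp[0] = (vol[j * nx] / dt) * cr[0] / b0;
      for (int i = 1; i < nx; ++i) {
        const double aw = ax[i - 1] * dy[j];
        const double ae = (i < nx - 1) ? ax[i] * dy[j] : 0.0;
        const double b = vol[j * nx + i] / dt + aw + ae;
        const double m = b + aw * cp[i - 1];
        cp[i] = -ae / m;
        dp[i] = ((vol[j * nx + i] / dt) * cr[i] + aw * dp[i - 1]) / m;
      }
      cr[nx - 1] = dp[nx - 1];
      for (int i = nx - 2; i >= 0; --i) cr[i] = dp[i] - cp[i] * cr[i + 1];
    }
    // ---- diffusion, y sweep (implicit) ----
    for (int i = 0; i < nx; ++i) {
      double b0 = vol[i] / dt + ay[0] * dx[i];
      cp[0] = -ay[0] * dx[i] / b0;
      dp[0] = (vol[i] / dt) * c[i] / b0;
      for (int j = 1; j < ny; ++j) {
        const double aw = ay[j - 1] * dx[i];
        const double ae = (j < ny - 1) ? ay[j] * dx[i] : 0.0;
        const double b = vol[j * nx + i] / dt + aw + ae;
        const double m = b + aw * cp[j - 1];
        cp[j] = -ae / m;
        dp[j] = ((vol[j * nx + i] / dt) * c[j * nx + i] + aw * dp[j - 1]) / m;
      }
      c[(ny - 1) * nx + i] = dp[ny - 1];
      for (int j = ny - 2; j >= 0; --j)
        c[j * nx + i] = dp[j] - cp[j] * c[(j + 1) * nx + i];
    }

    while (isnap < snap_steps.size() && snap_steps[isnap] == step) {
      for (int q = 0; q < ncell; ++q) snaps(q, isnap) = c[q];
      ++isnap;
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  double cmin = c[0], total = 0.0;
  for (int q = 0; q < ncell; ++q) {
    if (c[q] < cmin) cmin = c[q];
    total += c[q] * vol[q];
  }
  return List::create(_["c"] = NumericVector(c.begin(), c.end()),
                      _["snapshots"] = snaps,
                      _["min_c"] = cmin,
                      _["mass"] = total);
}
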