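// Euler-Maruyama Brownian-dynamics tracer in a precomputed node-velocity
// field: x' = x + u(x) dt + sqrt(2 D dt) xi, specular reflection at all
// boundaries (walls and interface pass no solute). Uses the R RNG so that
// set.seed() in R makes trajectories bit-reproducible.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// locate interval index k with grid[k] <= p < grid[k+1], given a hint
static inline int locate(const NumericVector& grid, double p, int hint) {
  int n = grid.size();
  int k = hint;
  if (k < 0) k = 0;
  if (k > n - 2) k = n - 2;
  while (k > 0 && p < grid[k]) --k;
  while (k < n - 2 && p >= grid[k + 1]) ++k;
  return k;
}

// [[Rcpp::export]]
NumericMatrix walk_cpp(double x0, double y0, double D, double dt, int nsteps,
                       int save_every,
                       NumericVector xn, NumericVector yn,
                       NumericMatrix u, NumericMatrix v) {
  const int nxn = xn.size(), nyn = yn.size();
  const double W = xn[nxn - 1], H = yn[nyn - 1];
  const double sig = std::sqrt(2.0 * D * dt);
  const int nsave = nsteps / save_every;
  NumericMatrix out(nsave + 1, 2);
  double x = x0, y = y0;
  out(0, 0) = x; out(0, 1) = y;
  int ix = 0, iy = 0, irow = 1;
  for (int step = 1; step <= nsteps; ++step) {
    ix = locate(xn, x, ix);
    iy = locate(yn, y, iy);
    const double tx = (x - xn[ix]) / (xn[ix + 1] - xn[ix]);
    const double ty = (y - yn[iy]) / (yn[iy + 1] - yn[iy]);
    const double ui =
      (1 - tx) * ((1 - ty) * u(ix, iy) + ty * u(ix, iy + 1)) +
      tx * ((1 - ty) * u(ix + 1, iy) + ty * u(ix + 1, iy + 1));
    const double vi =
      (1 - tx) * ((1 - ty) * v(ix, iy) + ty * v(ix, iy + 1)) +
      tx * ((1 - ty) * v(ix + 1, iy) + ty * v(ix + 1, iy + 1));
    x += ui * dt + sig * norm_rand();
    y += vi * dt + sig * norm_rand();
    // specular reflection (repeat in case of overshoot past both walls)
    for (int rep = 0; rep < 8; ++rep) {
      bool ok = true;
      if (x < 0) { x = -x; ok = false; }
      if (x > W) { x = 2 * W - x; ok = false; }
      if (y < 0) { y = -y; ok = false; }
      if (y > H) { y = 2 * H - y; ok = false; }
      if (ok) break;
    }
    if (x < 0) x = 0; else if (x > W) x = W;
    if (y < 0) y = 0; else if (y > H) y = H;
    if (step % save_every == 0) {
      out(irow, 0) = x; out(irow, 1) = y; ++irow;
    }
    if (step % 100000 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
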