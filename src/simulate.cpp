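// Overdamped Brownian-dynamics generator for channel-water systems.
//
// Waters evolve by position Langevin dynamics
//   r <- r - (D/kBT) grad U dt + sqrt(2 D dt) xi
// with a tabulated potential U(z) (supplied as its derivative on a uniform
// grid), periodic x/y/z, an impenetrable membrane slab |z| < span/2 outside a
// cylindrical channel of given radius.
//
// Single-file mode realizes the site-hopping picture of a tight pore, the
// standard model for which the pf/pd = N+1 law is derived: the N in-channel
// waters occupy evenly spaced solvation sites (spacing a = span/N) and
// advance by concerted one-site hops.  The hops are driven by a continuous
// internal column coordinate X performing overdamped BD with collective
// diffusion D/N (additive friction) under the summed potential force; each
// time X accumulates a full site spacing the file shifts one site — the
// leading water exits into its reservoir and the reservoir water nearest
// the opposite mouth is admitted at the trailing site, keeping the
// occupancy at exactly N at all times.  Each occupant additionally jitters
// around its site with a bounded sub-Angstrom Ornstein-Uhlenbeck term, so
// waters never pass each other and in-channel waters never reach the
// detection compartments between hops.
//
// All randomness comes from a private mt19937_64 seeded explicitly, so a
// given spec is bit-reproducible regardless of R's RNG state.

#include <Rcpp.h>
#include <random>
#include <algorithm>
using namespace Rcpp;

static inline double wrap(double x, double L) {
  return x - L * std::floor(x / L + 0.5);
}

// linear interpolation of the tabulated dU/dz; zero outside the grid
static inline double interp_du(double z, const std::vector<double>& gz,
                               const std::vector<double>& gdu) {
  if (gz.empty() || z <= gz.front() || z >= gz.back()) return 0.0;
  double h = gz[1] - gz[0];
  size_t i = (size_t)((z - gz.front()) / h);
  if (i >= gz.size() - 1) return 0.0;
  double f = (z - gz[i]) / h;
  return gdu[i] * (1.0 - f) + gdu[i + 1] * f;
}

// [[Rcpp::export]]
List cpp_simulate_channel(int n_waters, double Lx, double Ly, double Lz,
                          double span, double radius,
                          NumericVector pot_z, NumericVector pot_du,
                          double D, double kT, double dt,
                          int n_steps, int save_every,
                          bool single_file, int occupancy,
                          bool membrane, int seed) {
  std::mt19937_64 gen((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<double> gz(pot_z.begin(), pot_z.end());
  std::vector<double> gdu(pot_du.begin(), pot_du.end());

  std::vector<double> x(n_waters), y(n_waters), z(n_waters);
  const double half_span = span / 2.0, r2max = radius * radius;
  const double res_lo0 = -Lz / 2.0, res_lo1 = -half_span;
  const double res_hi0 = half_span, res_hi1 = Lz / 2.0;

  // single-file state
  const int N = occupancy;
  const double a = span / std::max(N, 1);        // site spacing
  const double Dcol = D / std::max(N, 1);        // collective diffusion
  const double jit_sd = std::min(0.4, 0.1 * a);  // site jitter amplitude
  const double jit_clamp = std::min(3.0 * jit_sd, 0.45 * a);
  const double jit_tau = jit_sd * jit_sd / std::max(D, 1e-12);
  const double jit_decay = std::exp(-dt / jit_tau);
  const double jit_noise = jit_sd * std::sqrt(1.0 - jit_decay * jit_decay);
  const double lat_sd = std::min(jit_sd, radius / 3.0);
  double X = 0.0;                                // column offset
  std::vector<int> chan;                         // occupant ids, bottom->top
  std::vector<double> jz, jx, jy;                // per-occupant jitters
  std::vector<bool> in_chan(n_waters, false);
  // observable site centres: X stays internal, positions advance by hops
  auto site_z = [&](int k) { return -half_span + (k + 0.5) * a; };

  // --- initial placement -------------------------------------------------
  if (single_file) {
    if (N > n_waters) stop("occupancy exceeds n_waters");
    for (int j = 0; j < N; ++j) {
      chan.push_back(j); in_chan[j] = true;
      jz.push_back(0.0); jx.push_back(0.0); jy.push_back(0.0);
      x[j] = 0.0; y[j] = 0.0; z[j] = site_z(j);
    }
    for (int j = N; j < n_waters; ++j) {
      bool low = (j % 2 == 0);
      x[j] = (unif(gen) - 0.5) * Lx; y[j] = (unif(gen) - 0.5) * Ly;
      z[j] = low ? res_lo0 + unif(gen) * (res_lo1 - res_lo0)
                 : res_hi0 + unif(gen) * (res_hi1 - res_hi0);
    }
  } else {
    for (int j = 0; j < n_waters; ++j) {
      for (int tries = 0; tries < 10000; ++tries) {
        double px = (unif(gen) - 0.5) * Lx, py = (unif(gen) - 0.5) * Ly;
        double pz = (unif(gen) - 0.5) * Lz;
        if (membrane && std::fabs(pz) < half_span && px * px + py * py >= r2max)
          continue;
        x[j] = px; y[j] = py; z[j] = pz; break;
      }
    }
  }

  const int n_frames = n_steps / save_every + 1;
  NumericVector coords(static_cast<R_xlen_t>(n_waters) * 3 * n_frames);
  auto save_frame = [&](int f) {
    R_xlen_t off = static_cast<R_xlen_t>(f) * n_waters * 3;
    for (int j = 0; j < n_waters; ++j) {
      coords[off + j] = x[j];
      coords[off + n_waters + j] = y[j];
      coords[off + 2 * n_waters + j] = z[j];
    }
  };
  save_frame(0);

  const double step_sd = std::sqrt(2.0 * D * dt);
  const double col_sd = std::sqrt(2.0 * Dcol * dt);
  const double mob = D / kT * dt;
  int n_exchanges = 0;

  for (int s = 1; s <= n_steps; ++s) {
    // free waters (all of them in non-single-file mode)
    for (int j = 0; j < n_waters; ++j) {
      if (in_chan[j]) continue;
      double drift = -mob * interp_du(z[j], gz, gdu);
      double nx = wrap(x[j] + step_sd * gauss(gen), Lx);
      double ny = wrap(y[j] + step_sd * gauss(gen), Ly);
      double nz = wrap(z[j] + drift + step_sd * gauss(gen), Lz);
      bool inside_new = membrane && std::fabs(nz) < half_span;
      if (single_file) {
        // reservoir waters may not enter the membrane slab; entry is only
        // via the site exchange below
        if (!inside_new) { x[j] = nx; y[j] = ny; z[j] = nz; }
      } else if (!inside_new || nx * nx + ny * ny < r2max) {
        x[j] = nx; y[j] = ny; z[j] = nz;
      }
    }

    if (single_file && N > 0) {
      // collective column move, driven by the total potential force
      double ftot = 0.0;
      for (int k = 0; k < N; ++k) ftot += interp_du(site_z(k) + jz[k], gz, gdu);
      X += -(Dcol / kT) * ftot * dt + col_sd * gauss(gen);
      // per-occupant bounded OU jitter
      for (int k = 0; k < N; ++k) {
        jz[k] = jz[k] * jit_decay + jit_noise * gauss(gen);
        if (jz[k] > jit_clamp) jz[k] = jit_clamp;
        if (jz[k] < -jit_clamp) jz[k] = -jit_clamp;
        jx[k] = jx[k] * jit_decay + (lat_sd * std::sqrt(1 - jit_decay * jit_decay)) * gauss(gen);
        jy[k] = jy[k] * jit_decay + (lat_sd * std::sqrt(1 - jit_decay * jit_decay)) * gauss(gen);
        double r2 = jx[k] * jx[k] + jy[k] * jy[k];
        if (r2 >= r2max && r2 > 0) {
          double f = 0.9 * radius / std::sqrt(r2);
          jx[k] *= f; jy[k] *= f;
        }
      }
      // site shifts once the column has slid a full site spacing (the
      // relabelled configuration coincides exactly with the old one, so
      // positions stay continuous and shifts are clean +/-a renewals):
      // the leading water exits, a reservoir water is admitted
      while (X >= a) {
        int top = chan.back();
        chan.pop_back(); in_chan[top] = false;
        z[top] = half_span + 0.1;          // just outside the top mouth
        x[top] = jx.back(); y[top] = jy.back();
        jz.pop_back(); jx.pop_back(); jy.pop_back();
        int best = -1; double bz = -1e30;
        for (int j = 0; j < n_waters; ++j)
          if (!in_chan[j] && z[j] <= -half_span && z[j] > bz) { best = j; bz = z[j]; }
        if (best < 0) stop("single-file exchange: bottom reservoir empty");
        chan.insert(chan.begin(), best); in_chan[best] = true;
        jz.insert(jz.begin(), 0.0); jx.insert(jx.begin(), 0.0);
        jy.insert(jy.begin(), 0.0);
        X -= a;
        ++n_exchanges;
      }
      while (X <= -a) {
        int bot = chan.front();
        chan.erase(chan.begin()); in_chan[bot] = false;
        z[bot] = -half_span - 0.1;         // just outside the bottom mouth
        x[bot] = jx.front(); y[bot] = jy.front();
        jz.erase(jz.begin()); jx.erase(jx.begin()); jy.erase(jy.begin());
        int best = -1; double bz = 1e30;
        for (int j = 0; j < n_waters; ++j)
          if (!in_chan[j] && z[j] >= half_span && z[j] < bz) { best = j; bz = z[j]; }
        if (best < 0) stop("single-file exchange: top reservoir empty");
        chan.push_back(best); in_chan[best] = true;
        jz.push_back(0.0); jx.push_back(0.0); jy.push_back(0.0);
        X += a;
        ++n_exchanges;
      }
      // write occupant positions
      for (int k = 0; k < N; ++k) {
        int j = chan[k];
        z[j] = site_z(k) + jz[k];
        x[j] = jx[k]; y[j] = jy[k];
      }
    }

    if (s % save_every == 0) save_frame(s / save_every);
  }

  coords.attr("dim") = IntegerVector::create(n_waters, 3, n_frames);
  return List::create(_["coords"] = coords,
                      _["n_frames"] = n_frames,
                      _["n_exchanges"] = n_exchanges);
}
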