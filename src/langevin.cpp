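#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Overdamped Langevin (Brownian) dynamics of a bead-spring chain.
//
// Forces per step:
//  - consecutive beads: linear (harmonic) spring about rest length b0;
//  - optional excluded volume: constant-magnitude repulsion along the
//    centre-centre line for any pair closer than rep_cutoff (beads may
//    interpenetrate - the force is finite, not a hard core);
//  - optional confinement: constant inward radial force on beads outside
//    the sphere of radius conf_radius (or radial reflection if
//    reflect = true);
//  - thermal kicks with variance 2*kT*dt/zeta per coordinate
//    (fluctuation-dissipation).
// Euler update: r += F/zeta * dt + sqrt(2*kT*dt/zeta) * xi.
//
// Positions of the beads listed in `record` (1-based) are stored every
// `stride` steps once `equil_steps` steps have passed.  Uses the R RNG,
// so results are reproducible under set.seed().
//
// [[Rcpp::export]]
List bd_integrate(NumericMatrix pos0, int n_steps, int equil_steps,
                  int stride, double dt, double k_bond, double b0,
                  bool excluded, double f_rep, double rep_cutoff,
                  bool confined, double conf_radius, double f_conf,
                  bool reflect, double kT, double zeta, double max_step,
                  IntegerVector record) {
  const int n = pos0.nrow();
  if (pos0.ncol() != 3) stop("positions must be n x 3");
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
  }
  const int n_rec = record.size();
  const int n_frames = n_steps / stride + 1;
  NumericVector traj(static_cast<R_xlen_t>(n_frames) * 3 * n_rec);
  traj.attr("dim") = IntegerVector::create(n_frames, 3, n_rec);

  std::vector<double> fx(n), fy(n), fz(n);
  const double noise = std::sqrt(2.0 * kT * dt / zeta);
  const double mob = dt / zeta;
  const double cut2 = rep_cutoff * rep_cutoff;
  const int total = equil_steps + n_steps;
  int frame = 0;

  GetRNGstate();
  for (int step = 0; step <= total; ++step) {
    if (step >= equil_steps && (step - equil_steps) % stride == 0 &&
        frame < n_frames) {
      for (int r = 0; r < n_rec; ++r) {
        const int b = record[r] - 1;
        traj[frame + n_frames * (0 + 3 * r)] = x[b];
        traj[frame + n_frames * (1 + 3 * r)] = y[b];
        traj[frame + n_frames * (2 + 3 * r)] = z[b];
      }
      ++frame;
    }
    if (step == total) break;
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    // bonds
    for (int i = 0; i < n - 1; ++i) {
      const double dx = x[i + 1] - x[i], dy = y[i + 1] - y[i],
                   dz = z[i + 1] - z[i];
      const double len = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (len < 1e-14) continue;
      const double fmag = k_bond * (len - b0) / len;
      fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
      fx[i + 1] -= fmag * dx; fy[i + 1] -= fmag * dy; fz[i + 1] -= fmag * dz;
    }
    // excluded volume: constant-force repulsion on overlap
    if (excluded) {
      for (int i = 0; i < n - 1; ++i) {
        for (int j = i + 1; j < n; ++j) {
          const double dx = x[j] - x[i];
          if (std::fabs(dx) > rep_cutoff) continue;
          const double dy = y[j] - y[i];
          if (std::fabs(dy) > rep_cutoff) continue;
          const double dz = z[j] - z[i];
          const double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 >= cut2 || d2 < 1e-20) continue;
          const double inv = f_rep / std::sqrt(d2);
          fx[i] -= inv * dx; fy[i] -= inv * dy; fz[i] -= inv * dz;
          fx[j] += inv * dx; fy[j] += inv * dy; fz[j] += inv * dz;
        }
      }
    }
    // confinement
    if (confined && !reflect) {
      for (int i = 0; i < n; ++i) {
        const double r2 = x[i] * x[i] + y[i] * y[i] + z[i] * z[i];
        if (r2 > conf_radius * conf_radius) {
          const double inv = f_conf / std::sqrt(r2);
          fx[i] -= inv * x[i]; fy[i] -= inv * y[i]; fz[i] -= inv * z[i];
        }
      }
    }
    // Euler step
    double max_disp2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double ddx = fx[i] * mob + noise * norm_rand();
      const double ddy = fy[i] * mob + noise * norm_rand();
      const double ddz = fz[i] * mob + noise * norm_rand();
      const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 > max_disp2) max_disp2 = d2;
      x[i] += ddx; y[i] += ddy; z[i] += ddz;
    }
    if (max_disp2 > max_step * max_step) {
      PutRNGstate();
      stop("displacement %g exceeded %g in one step: reduce the time step",
           std::sqrt(max_disp2), max_step);
    }
    if (confined && reflect) {
      for (int i = 0; i < n; ++i) {
        const double r = std::sqrt(x[i] * x[i] + y[i] * y[i] + z[i] * z[i]);
        if (r > conf_radius) {
          const double s = (2.0 * conf_radius - r) / r;
          x[i] *= s; y[i] *= s; z[i] *= s;
        }
      }
    }
  }
  PutRNGstate();

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = x[i]; out(i, 1) = y[i]; out(i, 2) = z[i];
  }
  return List::create(_["trajectory"] = traj, _["final"] = out,
                      _["n_frames"] = n_frames);
}
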