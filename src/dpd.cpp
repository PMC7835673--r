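#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dissipative particle dynamics in 3D with harmonic bonds/crosslinks and
// oscillatory Lees-Edwards shear. Reduced units: r_c = 1, m = 1, k_B T = 1.
// Pairwise conservative (soft repulsion a_ij (1 - r)), dissipative and
// random forces obey fluctuation-dissipation (sigma^2 = 2 gamma kT), so the
// thermostat is Galilean invariant and momentum is conserved exactly.

struct PairSums { double virial_xy; };

// [[Rcpp::export]]
List dpd_run_cpp(NumericMatrix pos0, NumericMatrix vel0, IntegerVector type,
                 IntegerMatrix bonds, NumericVector bond_k,
                 NumericVector bond_r0, double box, NumericMatrix a_ij,
                 double gamma_d, double sigma_r, double kT, double dt,
                 int n_steps, double gamma0, double omega, int record_every) {
  const int n = pos0.nrow();
  const double rc = 1.0, rc2 = 1.0;
  const double inv_sqrt_dt = 1.0 / std::sqrt(dt);

  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n),
      fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0); y[i] = pos0(i, 1); z[i] = pos0(i, 2);
    vx[i] = vel0(i, 0); vy[i] = vel0(i, 1); vz[i] = vel0(i, 2);
  }

  const int nb = bonds.nrow();
  const int nc = std::max(3, (int)std::floor(box / rc));
  const double cell_w = box / nc;
  std::vector<int> head(nc * nc * nc), nxt(n);

  const double V = box * box * box;
  std::vector<double> rec_t, rec_gamma, rec_sigma, rec_temp;

  double virial_xy = 0.0;

  auto compute_forces = [&](double t) {
    const double gam = gamma0 * std::sin(omega * t);
    const double gdot = gamma0 * omega * std::cos(omega * t);
    const double shift = gam * box;
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    virial_xy = 0.0;

    // bin on wrapped coordinates (y, z cubic; x shifted at the y boundary)
    std::fill(head.begin(), head.end(), -1);
    std::vector<double> wx(n), wy(n), wz(n);
    for (int i = 0; i < n; ++i) {
      double yy = y[i] - box * std::floor(y[i] / box);
      double xx = x[i], zz = z[i];
      xx -= box * std::floor(xx / box);
      zz -= box * std::floor(zz / box);
      wx[i] = xx; wy[i] = yy; wz[i] = zz;
      int cx = std::min((int)(xx / cell_w), nc - 1);
      int cy = std::min((int)(yy / cell_w), nc - 1);
      int cz = std::min((int)(zz / cell_w), nc - 1);
      int b = (cz * nc + cy) * nc + cx;
      nxt[i] = head[b]; head[b] = i;
    }

    auto pair_force = [&](int i, int j) {
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double dvx_corr = 0.0;
      const double cy_img = std::round(dy / box);
      if (cy_img != 0.0) {  // Lees-Edwards: x-shift and velocity offset
        dx -= cy_img * shift;
        dy -= cy_img * box;
        dvx_corr = -cy_img * gdot * box;
      }
      dx -= box * std::round(dx / box);
      dz -= box * std::round(dz / box);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2 || r2 < 1e-12) return;
      const double r = std::sqrt(r2);
      const double wr = 1.0 - r;  // DPD weight w(r) = 1 - r/rc
      const double ex = dx / r, ey = dy / r, ez = dz / r;
      const double dvxx = vx[i] - vx[j] + dvx_corr;
      const double dvy = vy[i] - vy[j], dvz = vz[i] - vz[j];
      const double vdote = dvxx * ex + dvy * ey + dvz * ez;
      const double a = a_ij(type[i], type[j]);
      double f = a * wr - gamma_d * wr * wr * vdote +
                 sigma_r * wr * R::norm_rand() * inv_sqrt_dt;
      fx[i] += f * ex; fy[i] += f * ey; fz[i] += f * ez;
      fx[j] -= f * ex; fy[j] -= f * ey; fz[j] -= f * ez;
      virial_xy += f * ex * dy;
    };

    for (int i = 0; i < n; ++i) {
      int cx = std::min((int)(wx[i] / cell_w), nc - 1);
      int cy = std::min((int)(wy[i] / cell_w), nc - 1);
      int cz = std::min((int)(wz[i] / cell_w), nc - 1);
      // under shear the x-search widens: images across the y-boundary are
      // displaced by up to gamma0 * box in x
      int ex_x = (gamma0 > 0)
        ? std::min((int)std::ceil(gamma0 * box / cell_w), (nc - 3) / 2) : 0;
      for (int ox = -1 - ex_x; ox <= 1 + ex_x; ++ox)
        for (int oy = -1; oy <= 1; ++oy)
          for (int oz = -1; oz <= 1; ++oz) {
            int bx = (cx + ox + nc) % nc, by = (cy + oy + nc) % nc,
                bz = (cz + oz + nc) % nc;
            for (int j = head[(bz * nc + by) * nc + bx]; j >= 0; j = nxt[j])
              if (j > i) pair_force(i, j);
          }
    }

    for (int b = 0; b < nb; ++b) {
      const int i = bonds(b, 0), j = bonds(b, 1);
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      const double cy_img = std::round(dy / box);
      if (cy_img != 0.0) { dx -= cy_img * shift; dy -= cy_img * box; }
      dx -= box * std::round(dx / box);
      dz -= box * std::round(dz / box);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      const double f = -bond_k[b] * (r - bond_r0[b]);
      const double ex = dx / r, ey = dy / r, ez = dz / r;
      fx[i] += f * ex; fy[i] += f * ey; fz[i] += f * ez;
      fx[j] -= f * ex; fy[j] -= f * ey; fz[j] -= f * ez;
      virial_xy += f * ex * dy;
    }
  };

  compute_forces(0.0);
  for (int step = 1; step <= n_steps; ++step) {
    const double t_new = step * dt;
    const double shift_new = gamma0 * std::sin(omega * t_new) * box;
    const double gdot_new = gamma0 * omega * std::cos(omega * t_new);
    for (int i = 0; i < n; ++i) {
      vx[i] += 0.5 * dt * fx[i];
      vy[i] += 0.5 * dt * fy[i];
      vz[i] += 0.5 * dt * fz[i];
      x[i] += dt * vx[i]; y[i] += dt * vy[i]; z[i] += dt * vz[i];
      // Lees-Edwards remap: crossing the y-boundary shifts x by the
      // instantaneous strain offset and vx by the boundary velocity
      const double ny = std::floor(y[i] / box);
      if (ny != 0.0) {
        y[i] -= ny * box;
        x[i] -= ny * shift_new;
        vx[i] -= ny * gdot_new * box;
      }
      x[i] -= box * std::floor(x[i] / box);
      z[i] -= box * std::floor(z[i] / box);
    }
    compute_forces(t_new);
    for (int i = 0; i < n; ++i) {
      vx[i] += 0.5 * dt * fx[i];
      vy[i] += 0.5 * dt * fy[i];
      vz[i] += 0.5 * dt * fz[i];
    }
    if (record_every > 0 && step % record_every == 0) {
      const double gam = gamma0 * std::sin(omega * t_new);
      const double gdot = gamma0 * omega * std::cos(omega * t_new);
      double kin_xy = 0.0, ke = 0.0;
      for (int i = 0; i < n; ++i) {
        // peculiar velocity: the image-consistent affine flow is
        // gdot * y at the *unwrapped* y coordinate
        const double ux = vx[i] - gdot * y[i];
        kin_xy += ux * vy[i];
        ke += ux * ux + vy[i] * vy[i] + vz[i] * vz[i];
      }
      rec_t.push_back(t_new);
      rec_gamma.push_back(gam);
      // mechanical stress = minus the momentum-flux (pressure) tensor
      rec_sigma.push_back(-(kin_xy + virial_xy) / V);
      rec_temp.push_back(ke / (3.0 * n));
    }
  }

  NumericMatrix pos(n, 3), vel(n, 3);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = x[i]; pos(i, 1) = y[i]; pos(i, 2) = z[i];
    vel(i, 0) = vx[i]; vel(i, 1) = vy[i]; vel(i, 2) = vz[i];
  }
  return List::create(
      _["pos"] = pos, _["vel"] = vel,
      _["record"] = DataFrame::create(
          _["time"] = rec_t, _["gamma"] = rec_gamma,
          _["sigma_xy"] = rec_sigma, _["temperature"] = rec_temp));
}
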