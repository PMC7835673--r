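#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 2D run-and-tumble spherocylinders with linear growth and binary division.
// Interactions: split Lennard-Jones on the minimum distance between the two
// body segments -- full-strength WCA repulsion continued by an attractive
// tail scaled to well depth lambda*epsilon (lambda = 0.2 by default,
// mimicking polymer-induced depletion attraction). Overdamped translation;
// orientation changes only by Poisson tumbling and division noise.

struct Cell {
  double x, y, theta, len, age_h;
  int id, parent;
  double inv_tdup_h;  // per-cell elongation rate factor (1 / duplication h)
};

static inline double pbc(double d, double box) {
  return d - box * std::round(d / box);
}

// minimum distance between segments p +/- hp*up and q +/- hq*uq (2D),
// with the center displacement already minimum-imaged
static double seg_seg_dist2(double dx, double dy,
                            double upx, double upy, double hp,
                            double uqx, double uqy, double hq,
                            double* nx, double* ny) {
  // segment P: s in [-hp, hp] along up, from origin; Q: t in [-hq, hq]
  // from (dx, dy). Standard closest-point-of-segments reduction.
  const double d1x = upx * 2 * hp, d1y = upy * 2 * hp;
  const double d2x = uqx * 2 * hq, d2y = uqy * 2 * hq;
  const double p1x = -upx * hp, p1y = -upy * hp;
  const double p2x = dx - uqx * hq, p2y = dy - uqy * hq;
  const double rx = p1x - p2x, ry = p1y - p2y;
  const double a = d1x * d1x + d1y * d1y;
  const double e = d2x * d2x + d2y * d2y;
  const double f = d2x * rx + d2y * ry;
  double s = 0.0, t = 0.0;
  const double tiny = 1e-12;
  if (a <= tiny && e <= tiny) { s = t = 0.0; }
  else if (a <= tiny) { t = std::min(std::max(f / e, 0.0), 1.0); }
  else {
    const double c = d1x * rx + d1y * ry;
    if (e <= tiny) { s = std::min(std::max(-c / a, 0.0), 1.0); }
    else {
      const double b = d1x * d2x + d1y * d2y;
      const double denom = a * e - b * b;
      if (denom > tiny) s = std::min(std::max((b * f - c * e) / denom, 0.0), 1.0);
      t = (b * s + f) / e;
      if (t < 0.0) { t = 0.0; s = std::min(std::max(-c / a, 0.0), 1.0); }
      else if (t > 1.0) { t = 1.0; s = std::min(std::max((b - c) / a, 0.0), 1.0); }
    }
  }
  const double cpx = p1x + d1x * s, cpy = p1y + d1y * s;
  const double cqx = p2x + d2x * t, cqy = p2y + d2y * t;
  *nx = cpx - cqx; *ny = cpy - cqy;  // vector from Q-point to P-point
  return (*nx) * (*nx) + (*ny) * (*ny);
}

// split-LJ force magnitude / r (so F = fr * (nx, ny)); sigma = width
static inline double split_lj_fr(double r2, double sigma, double eps,
                                 double lambda, double rcut2) {
  if (r2 >= rcut2) return 0.0;
  // clamp: crossing rods (r -> 0 after a tumble) must not overflow
  r2 = std::max(r2, 0.0025 * sigma * sigma);
  const double s2 = sigma * sigma / r2;
  const double s6 = s2 * s2 * s2;
  const double rmin2 = std::cbrt(2.0) * sigma * sigma;  // (2^(1/6) s)^2
  double f = 24.0 * eps * s6 * (2.0 * s6 - 1.0) / r2;
  if (r2 > rmin2) f *= lambda;
  return f;
}

// [[Rcpp::export]]
List colony_run_cpp(NumericMatrix state0, List cfg, int n_steps,
                    int save_every, bool grow, bool move) {
  const double v = cfg["v"], tau_run = cfg["tau_run"], eps = cfg["epsilon"],
      lambda = cfg["attraction_strength"], t_dup = cfg["t_dup"],
      l0 = cfg["l0"], w = cfg["w"], dt = cfg["dt"], box = cfg["box"],
      mob = cfg["mobility"], div_sd = cfg["div_angle_sd"],
      growth_cv = cfg["growth_cv"], max_step = cfg["max_step"];
  const double rcut = 2.5 * w, rcut2 = rcut * rcut;
  const double p_tumble = 1.0 - std::exp(-dt / tau_run);
  const double dt_h = dt / 3600.0;

  std::vector<Cell> cells;
  int next_id = 1;
  for (int i = 0; i < state0.nrow(); ++i) {
    Cell c;
    c.x = state0(i, 0); c.y = state0(i, 1); c.theta = state0(i, 2);
    c.len = state0(i, 3); c.age_h = state0(i, 4);
    c.id = (int)state0(i, 5); c.parent = (int)state0(i, 6);
    c.inv_tdup_h = state0(i, 7);
    if (c.inv_tdup_h <= 0) {
      double fac = (growth_cv > 0) ? std::exp(growth_cv * R::norm_rand()) : 1.0;
      c.inv_tdup_h = 1.0 / (t_dup * fac);
    }
    next_id = std::max(next_id, c.id + 1);
    cells.push_back(c);
  }

  std::vector<NumericMatrix> frames;
  std::vector<double> frame_times;
  auto snapshot = [&](double t_s) {
    NumericMatrix m(cells.size(), 8);
    for (size_t i = 0; i < cells.size(); ++i) {
      m(i, 0) = cells[i].x; m(i, 1) = cells[i].y; m(i, 2) = cells[i].theta;
      m(i, 3) = cells[i].len; m(i, 4) = cells[i].age_h;
      m(i, 5) = cells[i].id; m(i, 6) = cells[i].parent;
      m(i, 7) = cells[i].inv_tdup_h;
    }
    frames.push_back(m);
    frame_times.push_back(t_s);
  };
  snapshot(0.0);

  std::vector<double> fx, fy;
  const double range = rcut + 2.0 * l0;  // center distance bound for contact
  int deep_overlap_steps = 0;            // consecutive steps below w/2
  for (int step = 1; step <= n_steps; ++step) {
    const size_t n = cells.size();
    fx.assign(n, 0.0); fy.assign(n, 0.0);
    double min_r2 = 1e30;
    if (eps > 0 && n > 1) {
      // linked-cell binning on wrapped coordinates; brute force when the
      // box is too small for distinct 3x3 neighbourhoods
      int nc = std::max(1, (int)std::floor(box / range));
      if (nc < 3) nc = 1;
      double cell_w = box / nc;
      std::vector<int> head(nc * nc, -1), nxt(n, -1);
      std::vector<int> cxs(n), cys(n);
      for (size_t i = 0; i < n; ++i) {
        double wx = cells[i].x - box * std::floor(cells[i].x / box);
        double wy = cells[i].y - box * std::floor(cells[i].y / box);
        int cx = std::min((int)(wx / cell_w), nc - 1);
        int cy = std::min((int)(wy / cell_w), nc - 1);
        cxs[i] = cx; cys[i] = cy;
        int b = cy * nc + cx;
        nxt[i] = head[b]; head[b] = i;
      }
      for (size_t i = 0; i < n; ++i) {
        const double hi = std::max(cells[i].len - w, 0.0) / 2.0;
        const double uix = std::cos(cells[i].theta),
                     uiy = std::sin(cells[i].theta);
        const int o_lo = (nc == 1) ? 0 : -1, o_hi = (nc == 1) ? 0 : 1;
        for (int ox = o_lo; ox <= o_hi; ++ox) for (int oy = o_lo; oy <= o_hi; ++oy) {
          int cx = (cxs[i] + ox + nc) % nc, cy = (cys[i] + oy + nc) % nc;
          for (int j = head[cy * nc + cx]; j >= 0; j = nxt[j]) {
            if ((size_t)j <= i) continue;
            double dx = pbc(cells[j].x - cells[i].x, box);
            double dy = pbc(cells[j].y - cells[i].y, box);
            double cd2 = dx * dx + dy * dy;
            if (cd2 > range * range) continue;
            const double hj = std::max(cells[j].len - w, 0.0) / 2.0;
            double nx_, ny_;
            double r2 = seg_seg_dist2(dx, dy, uix, uiy, hi,
                                      std::cos(cells[j].theta),
                                      std::sin(cells[j].theta), hj,
                                      &nx_, &ny_);
            if (r2 < min_r2) min_r2 = r2;
            const double clamp2 = 0.0025 * w * w;
            if (r2 < clamp2) {
              // crossed spines: the connecting vector degenerates, so
              // separate the pair along the center-center line instead
              const double cd = std::sqrt(cd2);
              const double rc = std::sqrt(clamp2);
              if (cd > 1e-9) { nx_ = -dx / cd * rc; ny_ = -dy / cd * rc; }
              else {
                const double a = R::unif_rand() * 2.0 * M_PI;
                nx_ = std::cos(a) * rc; ny_ = std::sin(a) * rc;
              }
              r2 = clamp2;
            }
            double fr = split_lj_fr(r2, w, eps, lambda, rcut2);
            if (fr != 0.0) {
              fx[i] += fr * nx_; fy[i] += fr * ny_;
              fx[j] -= fr * nx_; fy[j] -= fr * ny_;
            }
          }
        }
      }
      // transient deep overlaps (division insertions, tumble-induced rod
      // crossings) are resolved by the capped repulsion within a few steps;
      // an overlap the integrator cannot relax signals a too-large timestep
      if (min_r2 < 0.25 * w * w) {
        if (++deep_overlap_steps > 60)
          stop("timestep too large: unresolved overlap deeper than half a "
               "width (min segment distance %.3f um < %.3f um) at t = %.2f s",
               std::sqrt(min_r2), w / 2.0, step * dt);
      } else deep_overlap_steps = 0;
    }

    for (size_t i = 0; i < n; ++i) {
      Cell& c = cells[i];
      if (move) {
        double ddx = v * dt * std::cos(c.theta) + mob * fx[i] * dt;
        double ddy = v * dt * std::sin(c.theta) + mob * fy[i] * dt;
        double dd = std::sqrt(ddx * ddx + ddy * ddy);
        if (dd > max_step) { ddx *= max_step / dd; ddy *= max_step / dd; }
        c.x += ddx; c.y += ddy;
        if (R::unif_rand() < p_tumble)
          c.theta = R::unif_rand() * 2.0 * M_PI;
      }
      if (grow) {
        c.len += l0 * c.inv_tdup_h * dt_h;
        c.age_h += dt_h;
      }
    }

    if (grow) {
      const size_t n_now = cells.size();
      for (size_t i = 0; i < n_now; ++i) {
        if (cells[i].len >= 2.0 * l0) {
          Cell m = cells[i];
          const double ux = std::cos(m.theta), uy = std::sin(m.theta);
          for (int d = 0; d < 2; ++d) {
            Cell dtr;
            const double sgn = d == 0 ? 1.0 : -1.0;
            dtr.x = m.x + sgn * ux * l0 / 2.0;
            dtr.y = m.y + sgn * uy * l0 / 2.0;
            dtr.theta = m.theta + (div_sd > 0 ? div_sd * R::norm_rand() : 0.0);
            dtr.len = l0; dtr.age_h = 0.0;
            dtr.id = next_id++; dtr.parent = m.id;
            double fac = (growth_cv > 0)
              ? std::exp(growth_cv * R::norm_rand()) : 1.0;
            dtr.inv_tdup_h = 1.0 / (t_dup * fac);
            if (d == 0) cells[i] = dtr; else cells.push_back(dtr);
          }
        }
      }
    }

    if (save_every > 0 && step % save_every == 0) snapshot(step * dt);
  }
  if (save_every == 0 || n_steps % save_every != 0) snapshot(n_steps * dt);

  List fr(frames.size());
  for (size_t k = 0; k < frames.size(); ++k) fr[k] = frames[k];
  return List::create(_["frames"] = fr,
                      _["times_s"] = NumericVector(frame_times.begin(),
                                                   frame_times.end()),
                      _["next_id"] = next_id);
}
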