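// Compiled kernels: deterministic RNG, Euler-Maruyama integrators for the
// three node models, fused BNI-map sweeps, and digraph enumeration with
// canonical labeling.  All stochastic kernels derive their stream from
// (master seed, network id, removed-node id, cell index) so any grid cell
// can be reproduced in isolation and results do not depend on sweep order.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <set>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----

static inline uint64_t splitmix64_next(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static uint64_t derive_seed(uint64_t master, uint64_t net_id,
                            uint64_t removed_id, uint64_t cell) {
  uint64_t x = master;
  uint64_t h = splitmix64_next(x);
  x = h ^ (net_id * 0xA24BAED4963EE407ULL);
  h = splitmix64_next(x);
  x = h ^ (removed_id * 0x9FB21C651E98DF25ULL);
  h = splitmix64_next(x);
  x = h ^ (cell * 0xD6E8FEB86659FD93ULL);
  h = splitmix64_next(x);
  return h;
}

struct Rng {
  uint64_t s[4];
  bool has_spare;
  double spare;
  explicit Rng(uint64_t seed) : has_spare(false), spare(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64_next(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform on (0,1), never exactly 0 or 1
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// ----------------------------------------------------------- utilities ----

// in-neighbour lists: i receives from j iff M(i, j) == 1
static std::vector< std::vector<int> > in_neighbours(const IntegerMatrix &M) {
  int n = M.nrow();
  std::vector< std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (M(i, j) != 0) nb[i].push_back(j);
  return nb;
}

static inline double circ_dist(double th, double ref) {
  return std::fabs(std::remainder(th - ref, 2.0 * M_PI));
}

static void check_finite(double v, int step, const char *model) {
  if (!std::isfinite(v))
    stop("non-finite state in %s model at step %d (blow-up); "
         "reduce dt or check parameters", model, step);
}

// ---------------------------------------------------------- theta model ----

// One Euler-Maruyama trajectory of the theta model.  Returns (n_steps+1) x n
// matrix of (unwrapped) phases; row 0 is the initial condition.
// [[Rcpp::export]]
NumericMatrix cpp_sim_theta(IntegerMatrix adj, double p, double alpha,
                            double sigma, double dt, int n_steps,
                            double theta_s, NumericVector theta0,
                            double master, int net_id, int removed_id,
                            int cell_index) {
  int n = adj.nrow();
  std::vector< std::vector<int> > nb = in_neighbours(adj);
  Rng rng(derive_seed((uint64_t)master, (uint64_t)net_id,
                      (uint64_t)removed_id, (uint64_t)cell_index));
  NumericMatrix out(n_steps + 1, n);
  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> g(n), nw(n, 0.0), nth(n);
  for (int i = 0; i < n; ++i) out(0, i) = th[i];
  const double amp = sigma * std::sqrt(dt);
  for (int s = 1; s <= n_steps; ++s) {
    for (int j = 0; j < n; ++j) g[j] = 1.0 - std::cos(th[j] - theta_s);
    if (sigma > 0.0) for (int i = 0; i < n; ++i) nw[i] = rng.norm();
    for (int i = 0; i < n; ++i) {
      double c = 0.0;
      for (size_t k = 0; k < nb[i].size(); ++k) c += g[nb[i][k]];
      double ci = std::cos(th[i]);
      double drift = (1.0 - ci) + (1.0 + ci) * (p + alpha * c);
      nth[i] = th[i] + dt * drift + (1.0 + ci) * amp * nw[i];
    }
    for (int i = 0; i < n; ++i) {
      check_finite(nth[i], s, "theta");
      th[i] = nth[i];
      out(s, i) = th[i];
    }
  }
  return out;
}

// ------------------------------------------------------- bistable model ----

// One trajectory of the bistable (subcritical Hopf normal form) model.
// Coupling acts on the real part only; x and y receive independent noise.
// [[Rcpp::export]]
List cpp_sim_bistable(IntegerMatrix adj, double p, double omega, double alpha,
                      double noise_amp, double dt, int n_steps,
                      NumericVector x0, NumericVector y0,
                      double master, int net_id, int removed_id,
                      int cell_index) {
  int n = adj.nrow();
  std::vector< std::vector<int> > nb = in_neighbours(adj);
  Rng rng(derive_seed((uint64_t)master, (uint64_t)net_id,
                      (uint64_t)removed_id, (uint64_t)cell_index));
  NumericMatrix xm(n_steps + 1, n), ym(n_steps + 1, n);
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  std::vector<double> nwx(n, 0.0), nwy(n, 0.0), nx(n), ny(n);
  for (int i = 0; i < n; ++i) { xm(0, i) = x[i]; ym(0, i) = y[i]; }
  const double amp = noise_amp * std::sqrt(dt);
  for (int s = 1; s <= n_steps; ++s) {
    if (noise_amp > 0.0)
      for (int i = 0; i < n; ++i) { nwx[i] = rng.norm(); nwy[i] = rng.norm(); }
    for (int i = 0; i < n; ++i) {
      double u = x[i] * x[i] + y[i] * y[i];
      double f = p + 2.0 * u - u * u;
      double c = 0.0;
      for (size_t k = 0; k < nb[i].size(); ++k) c += x[nb[i][k]];
      nx[i] = x[i] + dt * (-omega * y[i] + x[i] * f + alpha * c) + amp * nwx[i];
      ny[i] = y[i] + dt * ( omega * x[i] + y[i] * f) + amp * nwy[i];
    }
    for (int i = 0; i < n; ++i) {
      check_finite(nx[i], s, "bistable");
      x[i] = nx[i]; y[i] = ny[i];
      xm(s, i) = x[i]; ym(s, i) = y[i];
    }
  }
  return List::create(_["x"] = xm, _["y"] = ym);
}

// -------------------------------------------------- physiological model ----

struct PhysP {
  double A, B, G, Ad, a, b, g, ad, C1, C2, C3, C4, C5, C6, C7, nu0, e0, r;
};

static PhysP phys_unpack(const NumericVector &pp) {
  PhysP q;
  q.A = pp["A"]; q.B = pp["B"]; q.G = pp["G"]; q.Ad = pp["A_d"];
  q.a = pp["a"]; q.b = pp["b"]; q.g = pp["g"]; q.ad = pp["a_d"];
  q.C1 = pp["C1"]; q.C2 = pp["C2"]; q.C3 = pp["C3"]; q.C4 = pp["C4"];
  q.C5 = pp["C5"]; q.C6 = pp["C6"]; q.C7 = pp["C7"];
  q.nu0 = pp["nu0"]; q.e0 = pp["e0"]; q.r = pp["r"];
  return q;
}

static inline double sigm(double v, const PhysP &q) {
  return 2.0 * q.e0 / (1.0 + std::exp(q.r * (q.nu0 - v)));
}

// Integrate the 12-variable neural mass model; writes the pyramidal output
// y3 - y5 - y7 row by row; state is updated in place.
static void phys_run(std::vector<double> *Y, const IntegerMatrix &adj,
                     const std::vector< std::vector<int> > &nb,
                     const PhysP &q, double p, double alpha, double sigma,
                     double dt, int n_steps, Rng *rng,
                     NumericMatrix *out, int out_offset) {
  int n = adj.nrow();
  std::vector<double> nw(n, 0.0);
  std::vector<double> ny(12);
  std::vector<double> newY(12 * n);
  const double namp = sigma * std::sqrt(dt);
  for (int s = 1; s <= n_steps; ++s) {
    if (sigma > 0.0 && rng) for (int i = 0; i < n; ++i) nw[i] = rng->norm();
    for (int i = 0; i < n; ++i) {
      const double *y = &(*Y)[12 * i];
      double R = 0.0;
      for (size_t k = 0; k < nb[i].size(); ++k)
        R += (*Y)[12 * nb[i][k] + 10];  // y11 of source node
      R *= alpha;
      double o = y[2] - y[4] - y[6];
      ny[0]  = y[0] + dt * y[1];
      ny[1]  = y[1] + dt * (q.A * q.a * sigm(o, q) - 2.0 * q.a * y[1] - q.a * q.a * y[0]);
      ny[2]  = y[2] + dt * y[3];
      ny[3]  = y[3] + dt * (q.A * q.a * (p + R + q.C2 * sigm(q.C1 * y[0], q))
                            - 2.0 * q.a * y[3] - q.a * q.a * y[2])
                    + q.A * q.a * namp * nw[i];
      ny[4]  = y[4] + dt * y[5];
      ny[5]  = y[5] + dt * (q.B * q.b * q.C4 * sigm(q.C3 * y[0], q)
                            - 2.0 * q.b * y[5] - q.b * q.b * y[4]);
      ny[6]  = y[6] + dt * y[7];
      ny[7]  = y[7] + dt * (q.G * q.g * q.C7 * sigm(q.C5 * y[0] - y[8], q)
                            - 2.0 * q.g * y[7] - q.g * q.g * y[6]);
      ny[8]  = y[8] + dt * y[9];
      ny[9]  = y[9] + dt * (q.B * q.b * q.C6 * sigm(q.C3 * y[0], q)
                            - 2.0 * q.b * y[9] - q.b * q.b * y[8]);
      ny[10] = y[10] + dt * y[11];
      ny[11] = y[11] + dt * (q.Ad * q.ad * sigm(o, q)
                             - 2.0 * q.ad * y[11] - q.ad * q.ad * y[10]);
      for (int v = 0; v < 12; ++v) newY[12 * i + v] = ny[v];
    }
    for (int i = 0; i < n; ++i) {
      check_finite(newY[12 * i + 2], s, "physiological");
      for (int v = 0; v < 12; ++v) (*Y)[12 * i + v] = newY[12 * i + v];
      if (out)
        (*out)(out_offset + s, i) =
          (*Y)[12 * i + 2] - (*Y)[12 * i + 4] - (*Y)[12 * i + 6];
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_sim_phys(IntegerMatrix adj, double p, double alpha,
                           double sigma, double dt, int n_steps,
                           NumericVector params, NumericMatrix y0,
                           double master, int net_id, int removed_id,
                           int cell_index) {
  int n = adj.nrow();
  PhysP q = phys_unpack(params);
  std::vector< std::vector<int> > nb = in_neighbours(adj);
  Rng rng(derive_seed((uint64_t)master, (uint64_t)net_id,
                      (uint64_t)removed_id, (uint64_t)cell_index));
  std::vector<double> Y(12 * n);
  for (int i = 0; i < n; ++i)
    for (int v = 0; v < 12; ++v) Y[12 * i + v] = y0(i, v);
  NumericMatrix out(n_steps + 1, n);
  for (int i = 0; i < n; ++i) out(0, i) = Y[12*i+2] - Y[12*i+4] - Y[12*i+6];
  phys_run(&Y, adj, nb, q, p, alpha, sigma, dt, n_steps, &rng, &out, 0);
  return out;
}

// ---------------------------------------------------- fused BNI sweeps ----

// Theta model BNI map with spike-proximity ictal marking: a node is ictal
// at a retained sample iff a spike (upward crossing of theta_s + pi + 2 pi k
// in the unwrapped phase) occurs within `spike_half_steps` steps of it.
// Coverage is accumulated as a union of per-spike windows clipped to the
// retained interval, so overlapping windows are not double counted.
// [[Rcpp::export]]
NumericMatrix cpp_bni_map_theta(IntegerMatrix adj, NumericVector p_vec,
                                NumericVector alpha_vec, double sigma,
                                double dt, int burn_steps, int ref_steps,
                                int spike_half_steps, double master,
                                int net_id, int removed_id) {
  int n = adj.nrow();
  int np = p_vec.size(), na = alpha_vec.size();
  std::vector< std::vector<int> > nb = in_neighbours(adj);
  NumericMatrix bni(np, na);
  std::vector<double> th(n), g(n), nw(n, 0.0), nth(n), next_cross(n);
  std::vector<long> covered(n), last_cov(n);
  const double amp_base = sigma * std::sqrt(dt);
  for (int ip = 0; ip < np; ++ip) {
    double p = p_vec[ip];
    double theta_s = (p <= 0.0)
      ? -std::acos((1.0 + p) / (1.0 - p)) : M_PI;
    for (int ia = 0; ia < na; ++ia) {
      double alpha = alpha_vec[ia];
      uint64_t cell = (uint64_t)ip * (uint64_t)na + (uint64_t)ia;
      Rng rng(derive_seed((uint64_t)master, (uint64_t)net_id,
                          (uint64_t)removed_id, cell));
      int total = burn_steps + ref_steps;
      for (int i = 0; i < n; ++i) {
        th[i] = theta_s;
        next_cross[i] = theta_s + M_PI;
        covered[i] = 0;
        last_cov[i] = burn_steps;  // retained steps are burn_steps+1 .. total
      }
      for (int s = 1; s <= total; ++s) {
        for (int j = 0; j < n; ++j) g[j] = 1.0 - std::cos(th[j] - theta_s);
        if (sigma > 0.0) for (int i = 0; i < n; ++i) nw[i] = rng.norm();
        for (int i = 0; i < n; ++i) {
          double c = 0.0;
          for (size_t k = 0; k < nb[i].size(); ++k) c += g[nb[i][k]];
          double ci = std::cos(th[i]);
          double drift = (1.0 - ci) + (1.0 + ci) * (p + alpha * c);
          nth[i] = th[i] + dt * drift + (1.0 + ci) * amp_base * nw[i];
        }
        for (int i = 0; i < n; ++i) {
          check_finite(nth[i], s, "theta");
          th[i] = nth[i];
          while (th[i] >= next_cross[i]) {  // spike at step s
            long lo = std::max((long)(s - spike_half_steps), last_cov[i] + 1);
            long hi = std::min((long)(s + spike_half_steps), (long)total);
            if (hi >= lo) { covered[i] += hi - lo + 1; last_cov[i] = hi; }
            next_cross[i] += 2.0 * M_PI;
          }
        }
      }
      long count = 0;
      for (int i = 0; i < n; ++i) count += covered[i];
      bni(ip, ia) = (double)count / ((double)n * (double)ref_steps);
    }
  }
  return bni;
}

// Bistable model BNI map: escape-time definition.  All nodes start at z = 0;
// BNI = 1 - mean first-passage time to |z|^2 >= escape_r2 (censored at the
// reference time) / reference time.
// [[Rcpp::export]]
NumericMatrix cpp_bni_map_bistable(IntegerMatrix adj, NumericVector p_vec,
                                   NumericVector alpha_vec, double omega,
                                   double noise_amp, double dt, int ref_steps,
                                   double escape_r2, double master, int net_id,
                                   int removed_id) {
  int n = adj.nrow();
  int np = p_vec.size(), na = alpha_vec.size();
  std::vector< std::vector<int> > nb = in_neighbours(adj);
  NumericMatrix bni(np, na);
  std::vector<double> x(n), y(n), nwx(n, 0.0), nwy(n, 0.0), nx(n), ny(n);
  std::vector<int> esc(n);
  const double amp = noise_amp * std::sqrt(dt);
  const double t_ref = ref_steps * dt;
  for (int ip = 0; ip < np; ++ip) {
    double p = p_vec[ip];
    for (int ia = 0; ia < na; ++ia) {
      double alpha = alpha_vec[ia];
      uint64_t cell = (uint64_t)ip * (uint64_t)na + (uint64_t)ia;
      Rng rng(derive_seed((uint64_t)master, (uint64_t)net_id,
                          (uint64_t)removed_id, cell));
      for (int i = 0; i < n; ++i) { x[i] = 0.0; y[i] = 0.0; esc[i] = -1; }
      int n_escaped = 0;
      for (int s = 1; s <= ref_steps && n_escaped < n; ++s) {
        if (noise_amp > 0.0)
          for (int i = 0; i < n; ++i) { nwx[i] = rng.norm(); nwy[i] = rng.norm(); }
        for (int i = 0; i < n; ++i) {
          double u = x[i] * x[i] + y[i] * y[i];
          double f = p + 2.0 * u - u * u;
          double c = 0.0;
          for (size_t k = 0; k < nb[i].size(); ++k) c += x[nb[i][k]];
          nx[i] = x[i] + dt * (-omega * y[i] + x[i] * f + alpha * c) + amp * nwx[i];
          ny[i] = y[i] + dt * ( omega * x[i] + y[i] * f) + amp * nwy[i];
        }
        for (int i = 0; i < n; ++i) {
          check_finite(nx[i], s, "bistable");
          x[i] = nx[i]; y[i] = ny[i];
          if (esc[i] < 0 && x[i] * x[i] + y[i] * y[i] >= escape_r2) {
            esc[i] = s;
            ++n_escaped;
          }
        }
      }
      double mean_t = 0.0;
      for (int i = 0; i < n; ++i)
        mean_t += (esc[i] < 0) ? t_ref : esc[i] * dt;
      mean_t /= n;
      bni(ip, ia) = 1.0 - mean_t / t_ref;
    }
  }
  return bni;
}

// Physiological model BNI map.  Per cell: a noise-free run supplies the
// per-node baseline output (mean over the last `base_avg` of `base_steps`
// samples); the stochastic run then counts retained samples with
// |output - baseline| > threshold.
// [[Rcpp::export]]
NumericMatrix cpp_bni_map_phys(IntegerMatrix adj, NumericVector p_vec,
                               NumericVector alpha_vec, double sigma,
                               double dt, int burn_steps, int ref_steps,
                               int base_steps, int base_avg, double threshold,
                               NumericVector params, double master,
                               int net_id, int removed_id) {
  int n = adj.nrow();
  int np = p_vec.size(), na = alpha_vec.size();
  PhysP q = phys_unpack(params);
  std::vector< std::vector<int> > nb = in_neighbours(adj);
  NumericMatrix bni(np, na);
  NumericMatrix traj(base_steps + 1, n);
  std::vector<double> Y(12 * n), base(n);
  for (int ip = 0; ip < np; ++ip) {
    double p = p_vec[ip];
    for (int ia = 0; ia < na; ++ia) {
      double alpha = alpha_vec[ia];
      uint64_t cell = (uint64_t)ip * (uint64_t)na + (uint64_t)ia;
      Rng rng(derive_seed((uint64_t)master, (uint64_t)net_id,
                          (uint64_t)removed_id, cell));
      // deterministic baseline
      std::fill(Y.begin(), Y.end(), 0.0);
      phys_run(&Y, adj, nb, q, p, alpha, 0.0, dt, base_steps, NULL, &traj, 0);
      for (int i = 0; i < n; ++i) {
        double m = 0.0;
        for (int s = base_steps - base_avg + 1; s <= base_steps; ++s)
          m += traj(s, i);
        base[i] = m / base_avg;
      }
      // stochastic run
      std::fill(Y.begin(), Y.end(), 0.0);
      phys_run(&Y, adj, nb, q, p, alpha, sigma, dt, burn_steps, &rng, NULL, 0);
      long count = 0;
      std::vector<double> nw(n, 0.0), ny(12), newY(12 * n);
      const double namp = sigma * std::sqrt(dt);
      for (int s = 1; s <= ref_steps; ++s) {
        if (sigma > 0.0) for (int i = 0; i < n; ++i) nw[i] = rng.norm();
        for (int i = 0; i < n; ++i) {
          const double *y = &Y[12 * i];
          double R = 0.0;
          for (size_t k = 0; k < nb[i].size(); ++k)
            R += Y[12 * nb[i][k] + 10];
          R *= alpha;
          double o = y[2] - y[4] - y[6];
          ny[0]  = y[0] + dt * y[1];
          ny[1]  = y[1] + dt * (q.A * q.a * sigm(o, q) - 2.0 * q.a * y[1] - q.a * q.a * y[0]);
          ny[2]  = y[2] + dt * y[3];
          ny[3]  = y[3] + dt * (q.A * q.a * (p + R + q.C2 * sigm(q.C1 * y[0], q))
                                - 2.0 * q.a * y[3] - q.a * q.a * y[2])
                        + q.A * q.a * namp * nw[i];
          ny[4]  = y[4] + dt * y[5];
          ny[5]  = y[5] + dt * (q.B * q.b * q.C4 * sigm(q.C3 * y[0], q)
                                - 2.0 * q.b * y[5] - q.b * q.b * y[4]);
          ny[6]  = y[6] + dt * y[7];
          ny[7]  = y[7] + dt * (q.G * q.g * q.C7 * sigm(q.C5 * y[0] - y[8], q)
                                - 2.0 * q.g * y[7] - q.g * q.g * y[6]);
          ny[8]  = y[8] + dt * y[9];
          ny[9]  = y[9] + dt * (q.B * q.b * q.C6 * sigm(q.C3 * y[0], q)
                                - 2.0 * q.b * y[9] - q.b * q.b * y[8]);
          ny[10] = y[10] + dt * y[11];
          ny[11] = y[11] + dt * (q.Ad * q.ad * sigm(o, q)
                                 - 2.0 * q.ad * y[11] - q.ad * q.ad * y[10]);
          for (int v = 0; v < 12; ++v) newY[12 * i + v] = ny[v];
        }
        for (int i = 0; i < n; ++i) {
          check_finite(newY[12 * i + 2], s, "physiological");
          for (int v = 0; v < 12; ++v) Y[12 * i + v] = newY[12 * i + v];
          double o = Y[12*i+2] - Y[12*i+4] - Y[12*i+6];
          if (std::fabs(o - base[i]) > threshold) ++count;
        }
      }
      bni(ip, ia) = (double)count / ((double)n * (double)ref_steps);
    }
  }
  return bni;
}

// ----------------------------------------------------- graph utilities ----

// canonical key: minimum over all node permutations of the row-major
// adjacency bit string (n <= 7 so the key fits in 49 bits, exact in double)
static uint64_t canon_key(const std::vector<uint8_t> &a, int n) {
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  uint64_t best = ~0ULL;
  do {
    uint64_t key = 0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        key <<= 1;
        key |= a[perm[i] * n + perm[j]];
      }
    if (key < best) best = key;
  } while (std::next_permutation(perm.begin(), perm.end()));
  return best;
}

static bool weakly_connected(const std::vector<uint8_t> &a, int n) {
  std::vector<int> stack(1, 0);
  std::vector<bool> seen(n, false);
  seen[0] = true;
  int found = 1;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    for (int j = 0; j < n; ++j) {
      if (!seen[j] && (a[v * n + j] || a[j * n + v])) {
        seen[j] = true;
        stack.push_back(j);
        ++found;
      }
    }
  }
  return found == n;
}

// [[Rcpp::export]]
double cpp_canonical_key(IntegerMatrix adj) {
  int n = adj.nrow();
  if (n > 7) stop("canonical key supported for n <= 7");
  std::vector<uint8_t> a(n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) a[i * n + j] = adj(i, j) != 0;
  return (double)canon_key(a, n);
}

static int popcount64(uint64_t x) {
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
}

// Exhaustive enumeration of weakly connected, nonisomorphic simple digraphs
// without self-loops.  Returns one canonical representative per class, in a
// deterministic order (by edge count, then canonical key).
// [[Rcpp::export]]
List cpp_enumerate_digraphs(int n) {
  if (n < 2 || n > 5) stop("exhaustive enumeration supported for 2 <= n <= 5");
  int nbits = n * (n - 1);
  std::vector<int> bi(nbits), bj(nbits);
  int k = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j) { bi[k] = i; bj[k] = j; ++k; }
  std::set<uint64_t> keys;
  std::vector<uint8_t> a(n * n);
  for (uint64_t mask = 1; mask < (1ULL << nbits); ++mask) {
    std::fill(a.begin(), a.end(), 0);
    for (int b = 0; b < nbits; ++b)
      if (mask & (1ULL << b)) a[bi[b] * n + bj[b]] = 1;
    if (!weakly_connected(a, n)) continue;
    keys.insert(canon_key(a, n));
  }
  std::vector<uint64_t> sorted(keys.begin(), keys.end());
  std::stable_sort(sorted.begin(), sorted.end(),
                   [](uint64_t x, uint64_t y) {
                     int px = popcount64(x), py = popcount64(y);
                     if (px != py) return px < py;
                     return x < y;
                   });
  List out(sorted.size());
  for (size_t m = 0; m < sorted.size(); ++m) {
    IntegerMatrix M(n, n);
    uint64_t key = sorted[m];
    for (int i = n - 1; i >= 0; --i)
      for (int j = n - 1; j >= 0; --j) {
        M(i, j) = key & 1ULL;
        key >>= 1;
      }
    out[m] = M;
  }
  return out;
}

// Deterministic single-node bistable integrator with Heun (RK2) steps.
// Explicit Euler injects radial energy at rate omega^2 dt / 2, which at
// omega = 20 visibly shifts the saddle-node of limit cycles; Heun's O(dt^2)
// error makes the bifurcation diagnostics accurate at modest steps.
// [[Rcpp::export]]
List cpp_bistable_det(double p, double omega, double dt, int n_steps,
                      double x0, double y0, double tail_frac) {
  double x = x0, y = y0;
  auto fx = [&](double xx, double yy) {
    double u = xx * xx + yy * yy;
    return -omega * yy + xx * (p + 2.0 * u - u * u);
  };
  auto fy = [&](double xx, double yy) {
    double u = xx * xx + yy * yy;
    return omega * xx + yy * (p + 2.0 * u - u * u);
  };
  int tail_start = (int)((1.0 - tail_frac) * n_steps);
  double acc = 0.0;
  long n_acc = 0;
  for (int s = 1; s <= n_steps; ++s) {
    double k1x = fx(x, y), k1y = fy(x, y);
    double px = x + dt * k1x, py = y + dt * k1y;
    double k2x = fx(px, py), k2y = fy(px, py);
    x += 0.5 * dt * (k1x + k2x);
    y += 0.5 * dt * (k1y + k2y);
    check_finite(x, s, "bistable");
    if (s >= tail_start) { acc += x * x + y * y; ++n_acc; }
  }
  return List::create(_["u_final"] = x * x + y * y,
                      _["u_tail_mean"] = acc / n_acc);
}
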