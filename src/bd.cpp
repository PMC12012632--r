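// Overdamped Brownian dynamics: 2D multi-well toy potentials and the
// (active) worm-like bead chain.  Euler-Maruyama with per-component noise
// variance 2*kT*dt/gamma, i.e. <xi.xi'> = 4 kT gamma^-1 delta(t-t') in 2D.
// The Gaussian stream is seeded from R's RNG, so set.seed() gives
// bit-identical trajectories.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Fast Gaussian stream for the integrators: xoshiro256++ + Box-Muller,
// seeded from R's RNG so set.seed() still fully determines trajectories.
struct GaussRNG {
  uint64_t s[4];
  double spare;
  bool has_spare;
  GaussRNG() : has_spare(false) {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo ^ (0x9E3779B97F4A7C15ULL * (i + 1));
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next_u64() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double next_unif() {           // in (0, 1)
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double next_norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u = next_unif(), v = next_unif();
    double r = std::sqrt(-2.0 * std::log(u));
    double a = 6.283185307179586476925286766559 * v;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// ---------- toy potentials ----------

// V(x,y) = W*(x^p + y^p) - sum_i G(x,xi)G(y,yi),  G(u,u0)=exp(-(u-u0)^2/(2 s^2))
// p = 6 (three-well) or 4 (four-well).
static inline double toy_V(double x, double y, double W, int p, double s,
                           const arma::mat& centers) {
  double v = W * (std::pow(x, p) + std::pow(y, p));
  const double inv2s2 = 1.0 / (2.0 * s * s);
  for (arma::uword i = 0; i < centers.n_rows; ++i) {
    double dx = x - centers(i, 0), dy = y - centers(i, 1);
    v -= std::exp(-(dx * dx) * inv2s2) * std::exp(-(dy * dy) * inv2s2);
  }
  return v;
}

static inline void toy_F(double x, double y, double W, int p, double s,
                         const arma::mat& centers, double& fx, double& fy) {
  fx = -W * p * std::pow(x, p - 1);
  fy = -W * p * std::pow(y, p - 1);
  const double inv2s2 = 1.0 / (2.0 * s * s);
  const double invs2 = 1.0 / (s * s);
  for (arma::uword i = 0; i < centers.n_rows; ++i) {
    double dx = x - centers(i, 0), dy = y - centers(i, 1);
    double g = std::exp(-(dx * dx) * inv2s2) * std::exp(-(dy * dy) * inv2s2);
    fx -= g * dx * invs2;
    fy -= g * dy * invs2;
  }
}

// [[Rcpp::export]]
double toy_energy_cpp(double x, double y, double W, int p, double s,
                      const arma::mat& centers) {
  return toy_V(x, y, W, p, s, centers);
}

// [[Rcpp::export]]
NumericVector toy_force_cpp(double x, double y, double W, int p, double s,
                            const arma::mat& centers) {
  double fx, fy;
  toy_F(x, y, W, p, s, centers, fx, fy);
  return NumericVector::create(fx, fy);
}

// [[Rcpp::export]]
arma::mat bd_toy_cpp(double x0, double y0, double W, int p, double s,
                     const arma::mat& centers, double dt, double gamma,
                     double kT, int n_steps, int stride) {
  const int n_save = n_steps / stride + 1;
  arma::mat out(n_save, 2);
  double x = x0, y = y0;
  out(0, 0) = x; out(0, 1) = y;
  const double mob = dt / gamma;
  const double amp = std::sqrt(2.0 * kT * dt / gamma);
  GaussRNG rng;
  double fx, fy;
  int row = 1;
  for (int step = 1; step <= n_steps; ++step) {
    toy_F(x, y, W, p, s, centers, fx, fy);
    x += mob * fx + amp * rng.next_norm();
    y += mob * fy + amp * rng.next_norm();
    if (!std::isfinite(x) || !std::isfinite(y))
      stop("integration diverged at step %d", step);
    if (step % stride == 0) { out(row, 0) = x; out(row, 1) = y; ++row; }
  }
  return out;
}

// ---------- worm-like bead chain ----------

// V_bond = sum (k0/2)(|r_{i+1}-r_i| - d0)^2
// V_bend = sum (k_ang/2)(theta_i - theta0)^2  at interior beads
// V_nb   = sum_{|i-j|>=2, r<sigma} E (1 - r/sigma)^{5/2}   (Hertzian contact)
// Self-propulsion: each bond adds f_m * t_hat split equally on its two beads.

// [[Rcpp::export]]
double polymer_energy_cpp(const arma::mat& pos, double d0, double k0,
                          double kang, double theta0, double E, double sigma) {
  const arma::uword N = pos.n_rows;
  double v = 0.0;
  for (arma::uword i = 0; i + 1 < N; ++i) {
    double b = arma::norm(pos.row(i + 1) - pos.row(i));
    v += 0.5 * k0 * (b - d0) * (b - d0);
  }
  for (arma::uword j = 1; j + 1 < N; ++j) {
    arma::rowvec u = pos.row(j - 1) - pos.row(j);
    arma::rowvec w = pos.row(j + 1) - pos.row(j);
    double c = arma::dot(u, w) / (arma::norm(u) * arma::norm(w));
    c = std::max(-1.0, std::min(1.0, c));
    double th = std::acos(c);
    v += 0.5 * kang * (th - theta0) * (th - theta0);
  }
  for (arma::uword i = 0; i + 2 < N; ++i)
    for (arma::uword j = i + 2; j < N; ++j) {
      double r = arma::norm(pos.row(j) - pos.row(i));
      if (r < sigma) v += E * std::pow(1.0 - r / sigma, 2.5);
    }
  return v;
}

static void polymer_forces(const arma::mat& pos, double d0, double k0,
                           double kang, double theta0, double E, double sigma,
                           double fm, arma::mat& F) {
  const int N = pos.n_rows;
  F.zeros(N, 2);
  const double* px = pos.colptr(0);
  const double* py = pos.colptr(1);
  double* fx = F.colptr(0);
  double* fy = F.colptr(1);
  // bonds (+ tangential self-propulsion split onto the bond's two beads)
  const double halffm = 0.5 * fm;
  for (int i = 0; i + 1 < N; ++i) {
    double dx = px[i + 1] - px[i], dy = py[i + 1] - py[i];
    double b = std::sqrt(dx * dx + dy * dy);
    double c = k0 * (b - d0) / b;
    fx[i] += c * dx; fy[i] += c * dy;
    fx[i + 1] -= c * dx; fy[i + 1] -= c * dy;
    if (fm != 0.0) {
      double tx = halffm * dx / b, ty = halffm * dy / b;
      fx[i] += tx; fy[i] += ty;
      fx[i + 1] += tx; fy[i + 1] += ty;
    }
  }
  // bending: harmonic in the angle at interior bead j.  The 1/sin(theta)
  // factor of d theta/d r stays bounded because (theta - pi) ~ -sin(theta)
  // near the straight chain.
  for (int j = 1; j + 1 < N; ++j) {
    double ux = px[j - 1] - px[j], uy = py[j - 1] - py[j];
    double wx = px[j + 1] - px[j], wy = py[j + 1] - py[j];
    double nu = std::sqrt(ux * ux + uy * uy);
    double nw = std::sqrt(wx * wx + wy * wy);
    double uhx = ux / nu, uhy = uy / nu, whx = wx / nw, why = wy / nw;
    double c = std::max(-1.0, std::min(1.0, uhx * whx + uhy * why));
    double th = std::acos(c);
    double s = std::sqrt(std::max(1.0 - c * c, 1e-16));
    double coef = -kang * (th - theta0) / s;
    double dpx = (c * uhx - whx) / nu, dpy = (c * uhy - why) / nu;
    double dnx = (c * whx - uhx) / nw, dny = (c * why - uhy) / nw;
    fx[j - 1] += coef * dpx; fy[j - 1] += coef * dpy;
    fx[j + 1] += coef * dnx; fy[j + 1] += coef * dny;
    fx[j] -= coef * (dpx + dnx); fy[j] -= coef * (dpy + dny);
  }
  // Hertzian contacts between non-bonded pairs
  const double sig2 = sigma * sigma;
  for (int i = 0; i + 2 < N; ++i)
    for (int j = i + 2; j < N; ++j) {
      double dx = px[j] - px[i], dy = py[j] - py[i];
      double r2 = dx * dx + dy * dy;
      if (r2 < sig2) {
        double r = std::sqrt(r2);
        double mag = 2.5 * E * std::pow(1.0 - r / sigma, 1.5) / (sigma * r);
        fx[j] += mag * dx; fy[j] += mag * dy;
        fx[i] -= mag * dx; fy[i] -= mag * dy;
      }
    }
}

// [[Rcpp::export]]
arma::mat polymer_force_cpp(const arma::mat& pos, double d0, double k0,
                            double kang, double theta0, double E, double sigma,
                            double fm) {
  arma::mat F;
  polymer_forces(pos, d0, k0, kang, theta0, E, sigma, fm, F);
  return F;
}

// [[Rcpp::export]]
arma::cube bd_polymer_cpp(const arma::mat& init, double d0, double k0,
                          double kang, double theta0, double E, double sigma,
                          double fm, double dt, double gamma, double kT,
                          int n_steps, int stride) {
  const arma::uword N = init.n_rows;
  const int n_save = n_steps / stride + 1;
  arma::cube out(N, 2, n_save);
  arma::mat pos = init, F;
  out.slice(0) = pos;
  const double mob = dt / gamma;
  const double amp = std::sqrt(2.0 * kT * dt / gamma);
  GaussRNG rng;
  int slot = 1;
  for (int step = 1; step <= n_steps; ++step) {
    polymer_forces(pos, d0, k0, kang, theta0, E, sigma, fm, F);
    for (arma::uword i = 0; i < N; ++i) {
      pos(i, 0) += mob * F(i, 0) + amp * rng.next_norm();
      pos(i, 1) += mob * F(i, 1) + amp * rng.next_norm();
    }
    if (!pos.is_finite())
      stop("integration diverged at step %d", step);
    if (step % stride == 0) out.slice(slot++) = pos;
  }
  return out;
}
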