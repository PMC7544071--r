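#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>

// Stochastic Heun integration of the coupled bistable-node network
//
//   dz_n = [ (-nu_n + i*omega) z_n + 2 z_n |z_n|^2 - z_n |z_n|^4
//            + beta * sum_m A[n,m] (z_m - z_n) ] dt + alpha dW_n
//
// from z_n(0) = 0, recording the first time |z_n| exceeds the escape
// threshold xi for every node.  The additive Wiener increment is shared
// between the predictor and the corrector stage.  State is kept as
// separate real/imaginary doubles: the drift is polynomial and the hot
// loop must not fall back to library complex multiplication.
//
// Randomness comes from a counter-based xoshiro256++ generator seeded per
// realization from (seed, realization index), so ensembles are reproducible
// and realizations are independent streams regardless of execution order.

namespace {

// splitmix64: expands a single 64-bit value into generator state
inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// Ziggurat tables for the standard normal (Marsaglia & Tsang 2000,
// 128 layers), built once at load time.
struct ZigguratTables {
  uint32_t kn[128];
  double wn[128], fn[128];
  ZigguratTables() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; --i) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};
static const ZigguratTables zig;

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double runif() {   // uniform on (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // standard normal via the ziggurat method
  inline double rnorm() {
    for (;;) {
      int32_t hz = (int32_t)(uint32_t)(next() >> 32);
      uint32_t iz = (uint32_t)hz & 127u;
      if ((uint32_t)std::abs(hz) < zig.kn[iz])
        return hz * zig.wn[iz];                       // ~98% fast path
      const double r = 3.442619855899;
      double x = hz * zig.wn[iz];
      if (iz == 0) {                                  // base-layer tail
        double y;
        do {
          x = -std::log(runif()) / r;
          y = -std::log(runif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -r - x;
      }
      if (zig.fn[iz] + runif() * (zig.fn[iz - 1] - zig.fn[iz]) <
          std::exp(-0.5 * x * x))
        return x;
    }
  }
};

} // namespace

// Raw access to the simulator's normal generator, for distributional tests.
// [[Rcpp::export(name = ".sim_rnorm_cpp")]]
Rcpp::NumericVector sim_rnorm_cpp(int n, double seed_hi, double seed_lo,
                                  int stream) {
  const uint64_t base =
    ((uint64_t)(uint32_t)(int64_t)seed_hi << 32) ^ (uint64_t)(uint32_t)(int64_t)seed_lo;
  uint64_t sm = base;
  uint64_t mix = splitmix64(sm) ^ (0xA0761D6478BD642FULL * (uint64_t)(stream + 1));
  Xoshiro256pp rng(mix);
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rng.rnorm();
  return out;
}

// [[Rcpp::export(name = ".heun_escape_cpp")]]
Rcpp::List heun_escape_cpp(Rcpp::NumericMatrix A, double beta,
                           Rcpp::NumericVector nu, double omega,
                           double alpha, double h, double t_max, double xi,
                           int K, double seed_hi, double seed_lo,
                           bool first_escape, bool real_noise) {
  const int N = nu.size();
  if (A.nrow() != N || A.ncol() != N)
    Rcpp::stop("adjacency matrix does not match the excitability vector");

  // flat sparse neighbour lists: A[n,m] != 0 means input from m to n
  std::vector<int> nbr_off(N + 1, 0), nbr_idx;
  std::vector<double> nbr_w, rowsum(N, 0.0);
  for (int n = 0; n < N; ++n) {
    for (int m = 0; m < N; ++m)
      if (A(n, m) != 0.0 && m != n) {
        nbr_idx.push_back(m);
        nbr_w.push_back(A(n, m));
        rowsum[n] += A(n, m);
      }
    nbr_off[n + 1] = (int)nbr_idx.size();
  }

  // chain fast path: every node's inputs are exactly its index neighbours,
  // so the coupling term is a shifted elementwise product and the step
  // loops vectorize
  bool is_chain = true;
  for (int n = 0; n < N && is_chain; ++n) {
    int deg = nbr_off[n + 1] - nbr_off[n];
    for (int j = nbr_off[n]; j < nbr_off[n + 1]; ++j) {
      int m = nbr_idx[j];
      if (m != n - 1 && m != n + 1) is_chain = false;
    }
    if (deg > 2) is_chain = false;
  }
  // left/right weights for the chain path (0 where absent/severed)
  std::vector<double> wl(N, 0.0), wrgt(N, 0.0);
  if (is_chain)
    for (int n = 0; n < N; ++n)
      for (int j = nbr_off[n]; j < nbr_off[n + 1]; ++j) {
        if (nbr_idx[j] == n - 1) wl[n] = nbr_w[j];
        if (nbr_idx[j] == n + 1) wrgt[n] = nbr_w[j];
      }

  Rcpp::NumericMatrix tau(K, N);
  Rcpp::LogicalMatrix censored(K, N);
  Rcpp::IntegerVector diverged(K);
  const double sq_h = std::sqrt(h);
  const double xi2 = xi * xi;
  const long n_steps = (long)std::ceil(t_max / h);
  const uint64_t base =
    ((uint64_t)(uint32_t)(int64_t)seed_hi << 32) ^ (uint64_t)(uint32_t)(int64_t)seed_lo;

  // padded state arrays (index 1..N) so chain neighbours never branch
  std::vector<double> zr(N + 2, 0.0), zi(N + 2, 0.0), pr(N + 2, 0.0),
                      pi_(N + 2, 0.0), fr(N, 0.0), fi(N, 0.0),
                      wr(N, 0.0), wi(N, 0.0), damp(N);
  std::vector<char> escaped(N);
  for (int n = 0; n < N; ++n) damp[n] = nu[n] + beta * rowsum[n];

  for (int k = 0; k < K; ++k) {
    if ((k & 15) == 0) Rcpp::checkUserInterrupt();
    uint64_t sm = base;
    uint64_t mix = splitmix64(sm) ^ (0xA0761D6478BD642FULL * (uint64_t)(k + 1));
    Xoshiro256pp rng(mix);

    std::fill(zr.begin(), zr.end(), 0.0);
    std::fill(zi.begin(), zi.end(), 0.0);
    std::fill(pr.begin(), pr.end(), 0.0);
    std::fill(pi_.begin(), pi_.end(), 0.0);
    std::fill(escaped.begin(), escaped.end(), 0);
    int n_escaped = 0;
    bool blew_up = false;

    for (long step = 0; step < n_steps; ++step) {
      for (int n = 0; n < N; ++n) {
        wr[n] = alpha * sq_h * rng.rnorm();
        wi[n] = real_noise ? 0.0 : alpha * sq_h * rng.rnorm();
      }
      if (is_chain) {
        // predictor: f evaluated at z
        for (int n = 0; n < N; ++n) {
          double cr = wl[n] * zr[n] + wrgt[n] * zr[n + 2];
          double ci = wl[n] * zi[n] + wrgt[n] * zi[n + 2];
          double a2 = zr[n + 1] * zr[n + 1] + zi[n + 1] * zi[n + 1];
          double g = -damp[n] + (2.0 - a2) * a2;   // radial drift / |z|
          fr[n] = g * zr[n + 1] - omega * zi[n + 1] + beta * cr;
          fi[n] = g * zi[n + 1] + omega * zr[n + 1] + beta * ci;
          pr[n + 1]  = zr[n + 1] + h * fr[n] + wr[n];
          pi_[n + 1] = zi[n + 1] + h * fi[n] + wi[n];
        }
        // corrector: f at the predictor point, same Wiener increment
        for (int n = 0; n < N; ++n) {
          double cr = wl[n] * pr[n] + wrgt[n] * pr[n + 2];
          double ci = wl[n] * pi_[n] + wrgt[n] * pi_[n + 2];
          double a2 = pr[n + 1] * pr[n + 1] + pi_[n + 1] * pi_[n + 1];
          double g = -damp[n] + (2.0 - a2) * a2;
          double fpr = g * pr[n + 1] - omega * pi_[n + 1] + beta * cr;
          double fpi = g * pi_[n + 1] + omega * pr[n + 1] + beta * ci;
          zr[n + 1] += 0.5 * h * (fr[n] + fpr) + wr[n];
          zi[n + 1] += 0.5 * h * (fi[n] + fpi) + wi[n];
        }
      } else {
        for (int n = 0; n < N; ++n) {
          double cr = 0.0, ci = 0.0;
          for (int j = nbr_off[n]; j < nbr_off[n + 1]; ++j) {
            cr += nbr_w[j] * zr[nbr_idx[j] + 1];
            ci += nbr_w[j] * zi[nbr_idx[j] + 1];
          }
          double a2 = zr[n + 1] * zr[n + 1] + zi[n + 1] * zi[n + 1];
          double g = -damp[n] + (2.0 - a2) * a2;
          fr[n] = g * zr[n + 1] - omega * zi[n + 1] + beta * cr;
          fi[n] = g * zi[n + 1] + omega * zr[n + 1] + beta * ci;
          pr[n + 1]  = zr[n + 1] + h * fr[n] + wr[n];
          pi_[n + 1] = zi[n + 1] + h * fi[n] + wi[n];
        }
        for (int n = 0; n < N; ++n) {
          double cr = 0.0, ci = 0.0;
          for (int j = nbr_off[n]; j < nbr_off[n + 1]; ++j) {
            cr += nbr_w[j] * pr[nbr_idx[j] + 1];
            ci += nbr_w[j] * pi_[nbr_idx[j] + 1];
          }
          double a2 = pr[n + 1] * pr[n + 1] + pi_[n + 1] * pi_[n + 1];
          double g = -damp[n] + (2.0 - a2) * a2;
          double fpr = g * pr[n + 1] - omega * pi_[n + 1] + beta * cr;
          double fpi = g * pi_[n + 1] + omega * pr[n + 1] + beta * ci;
          zr[n + 1] += 0.5 * h * (fr[n] + fpr) + wr[n];
          zi[n + 1] += 0.5 * h * (fi[n] + fpi) + wi[n];
        }
      }
      // threshold crossings and blow-up, separate from the arithmetic
      bool any_new = false;
      for (int n = 0; n < N; ++n) {
        double zn2 = zr[n + 1] * zr[n + 1] + zi[n + 1] * zi[n + 1];
        if (!escaped[n] && zn2 > xi2) {
          escaped[n] = 1;
          ++n_escaped;
          tau(k, n) = (step + 1) * h;
          any_new = true;
        }
        if (zn2 > 100.0) blew_up = true;   // |z| > 10: numerical blow-up
      }
      if (blew_up) break;
      if (any_new && (first_escape || n_escaped == N)) break;
    }

    for (int n = 0; n < N; ++n)
      if (!escaped[n]) {
        tau(k, n) = NA_REAL;
        censored(k, n) = true;
      }
    diverged[k] = blew_up ? 1 : 0;
  }

  return Rcpp::List::create(Rcpp::Named("tau") = tau,
                            Rcpp::Named("censored") = censored,
                            Rcpp::Named("diverged") = diverged);
}
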