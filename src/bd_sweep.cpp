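// Euler--Maruyama particle kernel for constant-speed gravitational-sweep
// sedimentation: dr = s w^2 r dt + sqrt(2 D dt) xi, reflecting meniscus,
// absorbing cell bottom. A dedicated counter-based RNG (xoshiro256++,
// splitmix64-seeded) keeps the hot loop cheap and runs bit-reproducible for
// a given seed independent of R's RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>

namespace {

inline uint64_t rotl(const uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

struct Xoshiro256pp {
  uint64_t s[4];
  bool have_cached;
  double cached;

  explicit Xoshiro256pp(uint64_t seed) : have_cached(false), cached(0.0) {
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {           // splitmix64 expansion
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }

  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }

  inline double unif() {                    // (0, 1)
    return ((next() >> 11) + 0.5) * 0x1.0p-53;
  }

  inline double norm() {                    // Box-Muller, pair cached
    if (have_cached) { have_cached = false; return cached; }
    double u1 = unif(), u2 = unif();
    double rad = std::sqrt(-2.0 * std::log(u1));
    double ang = 6.283185307179586 * u2;
    cached = rad * std::sin(ang);
    have_cached = true;
    return rad * std::cos(ang);
  }
};

} // namespace

// One species: n particles started proportional to r on [r_m, r_b] (sector
// geometry), stepped n_steps times with step dt. Counts inside the detector
// window [det_lo, det_hi] are recorded at t = 0 and every record_every-th
// step. Returns the count trace.
// [[Rcpp::export]]
Rcpp::IntegerVector bd_sweep_kernel(int n_particles, double s_si, double D,
                                    double omega2, double dt, int n_steps,
                                    int record_every, double r_m, double r_b,
                                    double det_lo, double det_hi,
                                    double seed) {
  Xoshiro256pp rng(static_cast<uint64_t>(seed));
  std::vector<double> r(n_particles);
  const double rm2 = r_m * r_m, rb2 = r_b * r_b;
  for (int i = 0; i < n_particles; ++i)
    r[i] = std::sqrt(rm2 + rng.unif() * (rb2 - rm2));

  const int n_rec = n_steps / record_every;
  Rcpp::IntegerVector counts(n_rec + 1);
  const double drift = s_si * omega2 * dt;
  const double sig = std::sqrt(2.0 * D * dt);
  const bool diffuse = sig > 0.0;

  int c0 = 0;
  for (int i = 0; i < n_particles; ++i)
    if (r[i] >= det_lo && r[i] < det_hi) ++c0;
  counts[0] = c0;

  int rec = 1;
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n_particles; ++i) {
      double ri = r[i];
      if (ri >= r_b) continue;              // accumulated at the bottom
      ri += drift * ri;
      if (diffuse) ri += sig * rng.norm();
      if (ri < r_m) ri = 2.0 * r_m - ri;    // reflect at the meniscus
      if (ri >= r_b) ri = r_b;              // absorb at the bottom
      r[i] = ri;
    }
    if (step % record_every == 0) {
      int c = 0;
      for (int i = 0; i < n_particles; ++i)
        if (r[i] >= det_lo && r[i] < det_hi) ++c;
      counts[rec++] = c;
    }
  }
  return counts;
}
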