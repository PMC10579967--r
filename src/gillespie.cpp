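// Direct-method stochastic simulator for the three-state chromatin model
// with piecewise-constant IFNg input and optional TF adaptation feedback.
//
// Propensities are constant between reaction events because the stimulus is
// piecewise constant and the TF depends only on the current IFNg level and
// the current regulator-protein count; the sampler therefore only needs a
// forced propensity refresh at stimulus switch times, where the pending
// waiting time is discarded and redrawn (the exponential clock is
// memoryless, so this is exact for this model class).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t& x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  // uniform in (0, 1)
  double unif() {
    uint64_t z = splitmix64(s);
    return ((z >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double rexp() { return -std::log(unif()); }
  // Knuth Poisson sampler; molecule-scale means stay far below the
  // underflow limit of exp(-lambda)
  long rpois(double lambda) {
    if (lambda <= 0.0) return 0;
    double L = std::exp(-lambda), p = 1.0;
    long k = 0;
    do { ++k; p *= unif(); } while (p > L);
    return k - 1;
  }
};

// [[Rcpp::export(name = ".gillespie_core")]]
IntegerMatrix gillespie_core(NumericVector kin, NumericVector adapt,
                             NumericVector sw_times, NumericVector sw_ifng,
                             NumericVector record, NumericVector init,
                             double seed_lo, double seed_hi,
                             bool sample_init = false) {
  const double k1 = kin["k1"], k2 = kin["k2"], k3 = kin["k3"], k4 = kin["k4"];
  const double k5 = kin["k5"], k6 = kin["k6"];
  const double dM = kin["deltaM"], dP = kin["deltaP"];
  const double alpha = kin["alpha"], Kd = kin["Kd"];
  const bool ad_on = adapt["enabled"] > 0.5;
  const double a_regM = adapt["a_regM"], a_regP = adapt["a_regP"];
  const double d_regM = adapt["delta_regM"], d_regP = adapt["delta_regP"];
  const double reg_thr = adapt["reg_thr"], c1 = adapt["c1"], c2 = adapt["c2"];

  uint64_t seed = (static_cast<uint64_t>(seed_hi) << 32) ^
                  static_cast<uint64_t>(seed_lo);
  Rng rng(seed);

  long C, OU, OI, M, P, regM, regP;
  if (sample_init) {
    // init holds the fractional resting state: multinomial chromatin
    // over the loci, Poisson molecule counts
    double tot = init[0] + init[1] + init[2];
    long n_loci = static_cast<long>(std::lround(tot));
    C = OU = OI = 0;
    for (long l = 0; l < n_loci; ++l) {
      double u = rng.unif() * tot;
      if (u < init[0]) ++C;
      else if (u < init[0] + init[1]) ++OU;
      else ++OI;
    }
    M = rng.rpois(init[3]);
    P = rng.rpois(init[4]);
    regM = rng.rpois(init[5]);
    regP = rng.rpois(init[6]);
  } else {
    C = std::lround(init[0]); OU = std::lround(init[1]);
    OI = std::lround(init[2]); M = std::lround(init[3]);
    P = std::lround(init[4]); regM = std::lround(init[5]);
    regP = std::lround(init[6]);
  }

  const int n_rec = record.size();
  IntegerMatrix out(n_rec, 7);
  int i_rec = 0;

  const int n_sw = sw_times.size();  // sw_times ascending, last = horizon
  int i_sw = 0;
  double t = record[0];
  double ifng = sw_ifng[0];
  // position the switch index at the current time
  while (i_sw < n_sw - 1 && sw_times[i_sw] <= t) ++i_sw;
  ifng = sw_ifng[i_sw];
  const double t_end = sw_times[n_sw - 1];

  const int NR = 12;
  double a[NR];

  while (true) {
    // propensities at current state and stimulus level
    double tf = std::tanh(alpha * (ifng + Kd));
    if (ad_on)
      tf /= 1.0 + std::pow(static_cast<double>(regP) / reg_thr, c1);
    a[0] = k1 * tf * C;   // open:    C -> OU
    a[1] = k2 * OU;       // close:   OU -> C
    a[2] = k3 * tf * OU;  // init:    OU -> OI
    a[3] = k4 * OI;       // deinit:  OI -> OU
    a[4] = k5 * OI;       // mRNA synthesis
    a[5] = dM * M;        // mRNA decay
    a[6] = k6 * M;        // protein synthesis
    a[7] = dP * P;        // protein decay
    if (ad_on) {
      double h = std::pow(tf, c2);
      a[8] = a_regM * h / (1.0 + h);  // regM synthesis
      a[9] = d_regM * regM;           // regM decay
      a[10] = a_regP * regM;          // regP synthesis
      a[11] = d_regP * regP;          // regP decay
    } else {
      a[8] = a[9] = a[10] = a[11] = 0.0;
    }
    double a0 = 0.0;
    for (int j = 0; j < NR; ++j) a0 += a[j];

    double t_next = (a0 > 0.0) ? t + rng.rexp() / a0 : R_PosInf;
    double t_sw = sw_times[i_sw];
    double t_stop = (t_next < t_sw) ? t_next : t_sw;

    // record all grid points passed before the next event / switch
    while (i_rec < n_rec && record[i_rec] <= t_stop) {
      out(i_rec, 0) = C; out(i_rec, 1) = OU; out(i_rec, 2) = OI;
      out(i_rec, 3) = M; out(i_rec, 4) = P;
      out(i_rec, 5) = regM; out(i_rec, 6) = regP;
      ++i_rec;
    }
    if (i_rec >= n_rec || t_stop >= t_end) break;

    if (t_next >= t_sw) {
      // stimulus switch: discard pending clock, refresh propensities
      t = t_sw;
      if (i_sw < n_sw - 1) ++i_sw;
      ifng = sw_ifng[i_sw];
      continue;
    }

    t = t_next;
    double r = rng.unif() * a0, acc = 0.0;
    int j = 0;
    for (; j < NR - 1; ++j) { acc += a[j]; if (r <= acc) break; }
    switch (j) {
      case 0:  --C; ++OU; break;
      case 1:  --OU; ++C; break;
      case 2:  --OU; ++OI; break;
      case 3:  --OI; ++OU; break;
      case 4:  ++M; break;
      case 5:  --M; break;
      case 6:  ++P; break;
      case 7:  --P; break;
      case 8:  ++regM; break;
      case 9:  --regM; break;
      case 10: ++regP; break;
      case 11: --regP; break;
    }
  }
  colnames(out) = CharacterVector::create("C", "OU", "OI", "M", "P",
                                          "regM", "regP");
  return out;
}

// [[Rcpp::export(name = ".derive_stream_seed")]]
NumericVector derive_stream_seed(double master_lo, double master_hi,
                                 int index) {
  uint64_t s = (static_cast<uint64_t>(master_hi) << 32) ^
               static_cast<uint64_t>(master_lo);
  s ^= 0x9E3779B97F4A7C15ULL * static_cast<uint64_t>(index + 1);
  uint64_t z = splitmix64(s);
  return NumericVector::create(
      static_cast<double>(z & 0xFFFFFFFFULL),
      static_cast<double>(z >> 32));
}
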