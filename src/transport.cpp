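// Monte Carlo neutron transport and dose scoring in a tissue cylinder.
//
// Analog transport: exponential free paths on the total macroscopic cross
// section, elastic scattering (isotropic in the centre of mass; free-gas
// target motion at the medium temperature below a cutoff energy) and
// capture (1/v), with charged capture/recoil products deposited locally
// (kerma approximation; product ranges are microns versus 0.25 cm bins).
// Capture photons follow a configurable policy: discarded (logged),
// deposited locally, or transported one exponential step (first-interaction
// kernel). Each history owns an independent counter-seeded PRNG stream, so
// history i is reproducible regardless of batching.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----
// splitmix64-seeded xoshiro256**
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; i++) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double u()   { return (next() >> 11) * 1.1102230246251565e-16; }  // [0,1)
  double uoc() { return 1.0 - u(); }                                 // (0,1]
};

static inline uint64_t history_seed(uint64_t seed, uint64_t i) {
  return seed ^ (0xD1B54A32D192ED03ULL * (i + 1));
}

// ------------------------------------------------------------ geometry ---
static inline void rotate_direction(const double* u, double mu, double phi,
                                    double* out) {
  double s = std::sqrt(std::max(0.0, 1.0 - mu * mu));
  double cp = std::cos(phi), sp = std::sin(phi);
  double a2 = 1.0 - u[2] * u[2];
  if (a2 < 1e-20) {  // along +-z
    double sgn = u[2] > 0 ? 1.0 : -1.0;
    out[0] = s * cp; out[1] = s * sp; out[2] = mu * sgn;
  } else {
    double a = std::sqrt(a2);
    out[0] = mu * u[0] + s * (u[0] * u[2] * cp - u[1] * sp) / a;
    out[1] = mu * u[1] + s * (u[1] * u[2] * cp + u[0] * sp) / a;
    out[2] = mu * u[2] - s * a * cp;
  }
  double n = std::sqrt(out[0]*out[0] + out[1]*out[1] + out[2]*out[2]);
  out[0] /= n; out[1] /= n; out[2] /= n;
}

static inline void isotropic_direction(Rng& rng, double* out) {
  double mu = 2.0 * rng.u() - 1.0;
  double phi = 2.0 * M_PI * rng.u();
  double s = std::sqrt(std::max(0.0, 1.0 - mu * mu));
  out[0] = s * std::cos(phi); out[1] = s * std::sin(phi); out[2] = mu;
}

// ------------------------------------------------------- cross sections --
// free-gas effective elastic factor g(x), x^2 = A E / kT
static inline double free_gas_factor(double x2) {
  if (x2 < 1e-12) x2 = 1e-12;
  if (x2 > 250.0) return 1.0 + 0.5 / x2;
  double x = std::sqrt(x2);
  return (1.0 + 0.5 / x2) * std::erf(x) +
         std::exp(-x2) / (x * std::sqrt(M_PI));
}

struct MaterialXS {
  int k;
  const double *N, *sel, *scap, *A;
  const int *kind;
  double e_ref, cutoff, kT;
  bool effective;  // free-gas effective elastic sigma below cutoff?
  std::vector<double> sig_el, sig_cap;  // macroscopic, 1/cm
  double tot_el, tot_cap, tot;

  MaterialXS(const NumericVector& N_, const NumericVector& sel_,
             const NumericVector& scap_, const IntegerVector& kind_,
             const NumericVector& A_, double e_ref_, double cutoff_,
             double kT_, bool effective_)
    : k(N_.size()), N(N_.begin()), sel(sel_.begin()), scap(scap_.begin()),
      A(A_.begin()), kind(kind_.begin()), e_ref(e_ref_), cutoff(cutoff_),
      kT(kT_), effective(effective_), sig_el(k), sig_cap(k) {}

  void evaluate(double E) {
    const double barn = 1e-24;
    tot_el = tot_cap = 0.0;
    double inv_v = std::sqrt(e_ref / E);
    bool broaden = effective && E <= cutoff;
    for (int i = 0; i < k; i++) {
      double se = sel[i];
      if (broaden && se > 0.0) se *= free_gas_factor(A[i] * E / kT);
      sig_el[i]  = N[i] * se * barn;
      sig_cap[i] = N[i] * scap[i] * inv_v * barn;
      tot_el += sig_el[i]; tot_cap += sig_cap[i];
    }
    tot = tot_el + tot_cap;
  }

  // returns nuclide index; sets *capture
  int sample_channel(Rng& rng, bool* capture) {
    double xi = rng.u() * tot;
    for (int i = 0; i < k; i++) {
      if (xi < sig_el[i]) { *capture = false; return i; }
      xi -= sig_el[i];
    }
    for (int i = 0; i < k; i++) {
      if (xi < sig_cap[i]) { *capture = true; return i; }
      xi -= sig_cap[i];
    }
    *capture = tot_cap > 0;  // numeric edge: last open channel
    return k - 1;
  }
};

// -------------------------------------------------------- elastic event --
// Maxwellian target velocity conditioned on the relative-speed collision
// rate (standard rejection scheme); speeds in sqrt(eV) units so KE = v^2
// for the neutron and A v^2 for the target.
static void sample_target_velocity(Rng& rng, double A, double kT, double E,
                                   const double* dir, double* vt) {
  double y = std::sqrt(A * E / kT);
  double alpha = 1.0 / (1.0 + 0.88622692545275801 * y);  // sqrt(pi)/2
  double x, mu;
  for (;;) {
    double x2;
    if (rng.u() < alpha) {
      x2 = -std::log(rng.uoc()) - std::log(rng.uoc());
    } else {
      double c = std::cos(0.5 * M_PI * rng.u());
      x2 = -std::log(rng.uoc()) - std::log(rng.uoc()) * c * c;
    }
    x = std::sqrt(x2);
    mu = 2.0 * rng.u() - 1.0;
    double vrel = std::sqrt(y * y + x2 - 2.0 * y * x * mu);
    if (rng.u() * (y + x) <= vrel) break;
  }
  double w = x * std::sqrt(kT / A);
  double tdir[3];
  rotate_direction(dir, mu, 2.0 * M_PI * rng.u(), tdir);
  vt[0] = w * tdir[0]; vt[1] = w * tdir[1]; vt[2] = w * tdir[2];
}

// isotropic-in-CM elastic scatter; updates dir, returns new energy (eV)
static double elastic_event(Rng& rng, double A, double kT, double E,
                            double* dir, bool free_gas) {
  double vn[3] = { std::sqrt(E) * dir[0], std::sqrt(E) * dir[1],
                   std::sqrt(E) * dir[2] };
  double vt[3] = {0.0, 0.0, 0.0};
  if (free_gas) sample_target_velocity(rng, A, kT, E, dir, vt);
  double vcm[3], vr[3];
  for (int j = 0; j < 3; j++) {
    vcm[j] = (vn[j] + A * vt[j]) / (1.0 + A);
    vr[j] = vn[j] - vcm[j];
  }
  double c = std::sqrt(vr[0]*vr[0] + vr[1]*vr[1] + vr[2]*vr[2]);
  double om[3];
  isotropic_direction(rng, om);
  double vnew[3] = { vcm[0] + c * om[0], vcm[1] + c * om[1],
                     vcm[2] + c * om[2] };
  double e2 = vnew[0]*vnew[0] + vnew[1]*vnew[1] + vnew[2]*vnew[2];
  if (e2 < 1e-13) return 1e-13;  // measure-zero guard; keep old direction
  double n = std::sqrt(e2);
  dir[0] = vnew[0] / n; dir[1] = vnew[1] / n; dir[2] = vnew[2] / n;
  return e2;
}

// ------------------------------------------------------------ main run ---
// tally components
enum Comp { BORON_ALPHA = 0, BORON_LI7, CAPTURE_GAMMA, PROTON_RECOIL,
            N14_PROTON, C14_RECOIL, OTHER_RECOIL, NCOMP };
// capture kinds (match R side)
enum CapKind { CK_NONE = 0, CK_B10 = 1, CK_H = 2, CK_N14 = 3, CK_GENERIC = 4 };

// [[Rcpp::export]]
List mc_run_cpp(NumericVector N, NumericVector sigma_el,
                NumericVector sigma_cap, IntegerVector cap_kind,
                NumericVector A_u,
                double E0_eV, double beam_radius_cm,
                double cyl_radius_cm, double cyl_length_cm, double bin_cm,
                int n_histories, double seed, int gamma_policy,
                double cutoff_eV, double kT_eV, double e_ref_eV,
                bool effective_sigma, List cap_const) {
  if (n_histories < 1) stop("n_histories must be >= 1");
  if (E0_eV <= 0) stop("beam energy must be positive");

  const double p_exc      = cap_const["b10_p_excited"];
  const double q_exc      = cap_const["b10_Q_excited"];
  const double q_gnd      = cap_const["b10_Q_ground"];
  const double e_gamma478 = cap_const["b10_gamma"];
  const double b10_fl     = cap_const["b10_frac_light"];
  const double h_Q        = cap_const["h_Q"];
  const double h_recoil   = cap_const["h_recoil"];
  const double n14_Q      = cap_const["n14_Q"];
  const double n14_fl     = cap_const["n14_frac_light"];
  const double mu478      = cap_const["mu_gamma_478"];
  const double mu2224     = cap_const["mu_gamma_2224"];

  const int nbins = (int) std::ceil(cyl_length_cm / bin_cm - 1e-9);
  const double r2max = cyl_radius_cm * cyl_radius_cm;
  const uint64_t useed = (uint64_t) seed;

  MaterialXS xs(N, sigma_el, sigma_cap, cap_kind, A_u,
                e_ref_eV, cutoff_eV, kT_eV, effective_sigma);

  NumericMatrix tally(nbins, NCOMP);
  NumericVector capture_counts(nbins);
  NumericVector sum_tot(nbins), sumsq_tot(nbins);
  NumericVector sum_bor(nbins), sumsq_bor(nbins);
  std::vector<double> h_tot(nbins, 0.0), h_bor(nbins, 0.0);
  std::vector<char> is_touched(nbins, 0);
  std::vector<int> touched; touched.reserve(64);

  double escaped_MeV = 0.0, gamma_disc_MeV = 0.0, bath_MeV = 0.0;
  double max_resid = 0.0;
  long n_escaped = 0, n_absorbed = 0;
  double n_collisions = 0.0;
  const long max_steps = 1000000L;

  for (int h = 0; h < n_histories; h++) {
    Rng rng(history_seed(useed, (uint64_t) h));
    double pos[3] = {0.0, 0.0, 0.0};
    if (beam_radius_cm > 0) {
      double r = beam_radius_cm * std::sqrt(rng.u());
      double ph = 2.0 * M_PI * rng.u();
      pos[0] = r * std::cos(ph); pos[1] = r * std::sin(ph);
    }
    double dir[3] = {0.0, 0.0, 1.0};
    double E = E0_eV;
    // MeV ledger; bath = energy gained from thermal target motion
    double dep = 0.0, esc = 0.0, gam = 0.0, q_rel = 0.0, bath = 0.0;
    bool alive = true;

    auto score = [&](int bin, int comp, double mev) {
      tally(bin, comp) += mev;
      if (!is_touched[bin]) { is_touched[bin] = 1; touched.push_back(bin); }
      h_tot[bin] += mev;
      if (comp == BORON_ALPHA || comp == BORON_LI7) h_bor[bin] += mev;
      dep += mev;
    };

    auto emit_gamma = [&](int bin, double e_mev) {
      if (gamma_policy == 0) { gam += e_mev; return; }
      if (gamma_policy == 1) { score(bin, CAPTURE_GAMMA, e_mev); return; }
      // first-interaction kernel
      double mu = e_mev < 1.0 ? mu478 : mu2224;
      double gdir[3];
      isotropic_direction(rng, gdir);
      double d = -std::log(rng.uoc()) / mu;
      double gp[3] = { pos[0] + d * gdir[0], pos[1] + d * gdir[1],
                       pos[2] + d * gdir[2] };
      if (gp[2] >= 0 && gp[2] <= cyl_length_cm &&
          gp[0]*gp[0] + gp[1]*gp[1] <= r2max) {
        int gb = (int)(gp[2] / bin_cm); if (gb >= nbins) gb = nbins - 1;
        score(gb, CAPTURE_GAMMA, e_mev);
      } else {
        gam += e_mev;
      }
    };

    long steps = 0;
    while (alive) {
      if (++steps > max_steps)
        stop("history exceeded the step limit; check the material definition");
      xs.evaluate(E);
      if (xs.tot <= 0.0) { esc += E * 1e-6; n_escaped++; break; }
      double s = -std::log(rng.uoc()) / xs.tot;
      pos[0] += s * dir[0]; pos[1] += s * dir[1]; pos[2] += s * dir[2];
      if (pos[2] < 0 || pos[2] > cyl_length_cm ||
          pos[0]*pos[0] + pos[1]*pos[1] > r2max) {
        esc += E * 1e-6; n_escaped++; break;
      }
      int bin = (int)(pos[2] / bin_cm); if (bin >= nbins) bin = nbins - 1;
      n_collisions += 1.0;

      bool capture;
      int i = xs.sample_channel(rng, &capture);
      if (!capture) {
        double e_new = elastic_event(rng, A_u[i], kT_eV, E, dir,
                                     E <= cutoff_eV);
        // net transfer to the medium is the recoil dose; an up-scatter
        // (possible only in the free-gas regime) draws energy from the
        // thermal bath instead of depositing
        if (e_new <= E) {
          int comp = (A_u[i] < 1.5) ? PROTON_RECOIL : OTHER_RECOIL;
          score(bin, comp, (E - e_new) * 1e-6);
        } else {
          bath += (e_new - E) * 1e-6;
        }
        E = e_new;
      } else {
        double en_mev = E * 1e-6;
        switch (cap_kind[i]) {
        case CK_B10: {
          if (rng.u() < p_exc) {
            double avail = q_exc + en_mev;
            score(bin, BORON_ALPHA, avail * b10_fl);
            score(bin, BORON_LI7, avail * (1.0 - b10_fl));
            emit_gamma(bin, e_gamma478);
          } else {
            double avail = q_gnd + en_mev;
            score(bin, BORON_ALPHA, avail * b10_fl);
            score(bin, BORON_LI7, avail * (1.0 - b10_fl));
          }
          q_rel += q_gnd;
          break;
        }
        case CK_H: {
          score(bin, OTHER_RECOIL, h_recoil);
          emit_gamma(bin, h_Q + en_mev - h_recoil);
          q_rel += h_Q;
          break;
        }
        case CK_N14: {
          double avail = n14_Q + en_mev;
          score(bin, N14_PROTON, avail * n14_fl);
          score(bin, C14_RECOIL, avail * (1.0 - n14_fl));
          q_rel += n14_Q;
          break;
        }
        case CK_GENERIC: {
          score(bin, OTHER_RECOIL, en_mev);
          break;
        }
        default:
          stop("capture sampled on a nuclide with no capture model");
        }
        capture_counts[bin] += 1.0;
        n_absorbed++;
        alive = false;
      }
    }

    double e_in = E0_eV * 1e-6 + q_rel + bath;
    double resid = std::fabs(e_in - dep - esc - gam) / std::max(e_in, 1e-12);
    bath_MeV += bath;
    if (resid > max_resid) max_resid = resid;
    escaped_MeV += esc;
    gamma_disc_MeV += gam;

    for (int b : touched) {
      sum_tot[b] += h_tot[b]; sumsq_tot[b] += h_tot[b] * h_tot[b];
      sum_bor[b] += h_bor[b]; sumsq_bor[b] += h_bor[b] * h_bor[b];
      h_tot[b] = 0.0; h_bor[b] = 0.0; is_touched[b] = 0;
    }
    touched.clear();
    if ((h & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["tally_MeV"] = tally,
    _["capture_counts"] = capture_counts,
    _["sum_tot"] = sum_tot, _["sumsq_tot"] = sumsq_tot,
    _["sum_bor"] = sum_bor, _["sumsq_bor"] = sumsq_bor,
    _["n_bins"] = nbins,
    _["n_escaped"] = (double) n_escaped,
    _["n_absorbed"] = (double) n_absorbed,
    _["n_collisions"] = n_collisions,
    _["escaped_MeV"] = escaped_MeV,
    _["gamma_discarded_MeV"] = gamma_disc_MeV,
    _["bath_gain_MeV"] = bath_MeV,
    _["max_ledger_residual"] = max_resid);
}

// --------------------------------------------------- exposed primitives --

// [[Rcpp::export]]
NumericVector mc_exp_samples(double rate_per_cm, int n, double seed) {
  if (rate_per_cm <= 0) stop("rate must be positive");
  NumericVector out(n);
  Rng rng(history_seed((uint64_t) seed, 0));
  for (int i = 0; i < n; i++) out[i] = -std::log(rng.uoc()) / rate_per_cm;
  return out;
}

// [[Rcpp::export]]
IntegerVector mc_bernoulli(double p, int n, double seed) {
  IntegerVector out(n);
  Rng rng(history_seed((uint64_t) seed, 0));
  for (int i = 0; i < n; i++) out[i] = rng.u() < p ? 1 : 0;
  return out;
}

// [[Rcpp::export]]
List mc_collision_samples(NumericVector N, NumericVector sigma_el,
                          NumericVector sigma_cap, IntegerVector cap_kind,
                          NumericVector A_u, double E_eV,
                          double cutoff_eV, double kT_eV, double e_ref_eV,
                          bool effective_sigma, int n, double seed) {
  MaterialXS xs(N, sigma_el, sigma_cap, cap_kind, A_u,
                e_ref_eV, cutoff_eV, kT_eV, effective_sigma);
  xs.evaluate(E_eV);
  if (xs.tot <= 0) stop("total macroscopic cross section is zero");
  IntegerVector nuclide(n);
  LogicalVector capture(n);
  Rng rng(history_seed((uint64_t) seed, 0));
  for (int i = 0; i < n; i++) {
    bool cap;
    nuclide[i] = xs.sample_channel(rng, &cap) + 1;
    capture[i] = cap;
  }
  return List::create(_["nuclide"] = nuclide, _["capture"] = capture);
}

// [[Rcpp::export]]
NumericMatrix mc_scatter_samples(double E0_eV, double A, double kT_eV,
                                 int n, double seed, bool free_gas) {
  NumericMatrix out(n, 2);
  colnames(out) = CharacterVector::create("E_out_eV", "mu_lab");
  Rng rng(history_seed((uint64_t) seed, 0));
  for (int i = 0; i < n; i++) {
    double dir[3] = {0.0, 0.0, 1.0};
    out(i, 0) = elastic_event(rng, A, kT_eV, E0_eV, dir, free_gas);
    out(i, 1) = dir[2];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector mc_chain_energies(double E0_eV, double A, double kT_eV,
                                int n_collisions, int n_chains, double seed) {
  NumericVector out(n_chains);
  for (int c = 0; c < n_chains; c++) {
    Rng rng(history_seed((uint64_t) seed, (uint64_t) c));
    double dir[3] = {0.0, 0.0, 1.0};
    double E = E0_eV;
    for (int j = 0; j < n_collisions; j++)
      E = elastic_event(rng, A, kT_eV, E, dir, true);
    out[c] = E;
  }
  return out;
}
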