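// Forward-Euler integrator for the two-layer model: a linear-nonlinear-
// Poisson V1 front end (Gabor-filtered noisy images) driving a recurrent
// network of exponential integrate-and-fire (EIF) neurons with
// double-exponential current-based synapses.
//
// Units: time ms, voltage mV, currents I/C_m in mV/ms. Synaptic kernels are
// normalised to unit integral, so a synapse of weight w (mV) contributes a
// current transient integrating to w.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// --- self-contained RNG (xoshiro256++ seeded by splitmix64) so that
//     simulations are bit-identical for a given seed -----------------------
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {            // (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_norm = false;
  double cached = 0.0;
  inline double norm() {            // Box-Muller
    if (have_norm) { have_norm = false; return cached; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    cached = r * std::sin(2.0 * M_PI * u2);
    have_norm = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

struct Kernel {
  double ad, br, c, inv;    // decay factors, transfer coef, spike increment
  void set(double taur, double taud, double dt) {
    ad = std::exp(-dt / taud);
    br = std::exp(-dt / taur);
    c = (ad - br) * taur * taud / (taud - taur);
    inv = 1.0 / (taur * taud);
  }
};

// [[Rcpp::export]]
List sim_eif_network(
    int n_e, int n_i,
    NumericVector epar, NumericVector ipar,   // taum EL VT Vth DT Vre tref
    IntegerVector e_ptr, IntegerVector e_tgt, NumericVector e_w,
    IntegerVector i_ptr, IntegerVector i_tgt, NumericVector i_w,
    IntegerVector f_ptr, IntegerVector f_tgt, NumericVector f_w,
    NumericVector kern,   // taur_e taud_e taur_i taud_i taur_s taud_s pf ps
    arma::mat F1, arma::mat F2,
    arma::mat bases1, arma::mat bases2,
    IntegerMatrix seg_modes,    // segments x 4: mode1 base1 mode2 base2
    NumericVector seg_tend, NumericVector seg_rate1, NumericVector seg_rate2,
    double gain, double noise_scale, double tau_n, double sigma_n,
    double T, double dt, double rate_dt, double rec_dt, double burnin,
    IntegerVector trace_ids, bool record_v1,
    double I_ext_e, double I_ext_i,
    NumericVector V0,
    double seed) {

  const int n = n_e + n_i;
  const int n1 = F1.n_rows, n2 = F2.n_rows;
  const int np1 = F1.n_cols, np2 = F2.n_cols;
  const int nsteps = (int)std::lround(T / dt);
  const int rate_every = std::max(1, (int)std::lround(rate_dt / dt));
  const int rec_every = std::max(1, (int)std::lround(rec_dt / dt));
  Rng rng((uint64_t)seed);

  Kernel ke, ki, ks;
  ke.set(kern[0], kern[1], dt);
  ki.set(kern[2], kern[3], dt);
  ks.set(kern[4], kern[5], dt);
  const double pf = kern[6], ps = kern[7];

  // neuron state
  std::vector<double> V(n), taum(n), EL(n), VT(n), Vth(n), DT(n), Vre(n);
  std::vector<int> refsteps(n), refcnt(n, 0);
  for (int j = 0; j < n; ++j) {
    const NumericVector& p = (j < n_e) ? epar : ipar;
    taum[j] = p[0]; EL[j] = p[1]; VT[j] = p[2]; Vth[j] = p[3];
    DT[j] = p[4]; Vre[j] = p[5];
    refsteps[j] = std::max(1, (int)std::lround(p[6] / dt));
  }
  if (V0.size() == n) {
    for (int j = 0; j < n; ++j) V[j] = V0[j];
  } else {
    for (int j = 0; j < n; ++j)
      V[j] = Vre[j] + (VT[j] - Vre[j]) * rng.unif();
  }

  // synaptic states: per neuron, channels ff-fast, ff-slow, rec-E, rec-I
  std::vector<double> xf(n, 0), sf(n, 0), xs(n, 0), ss(n, 0),
      xe(n, 0), se(n, 0), xi(n, 0), si(n, 0);

  // OU pixel noise state (stationary init)
  std::vector<double> xi1(np1), xi2(np2);
  const double sd_stat = sigma_n / std::sqrt(2.0 * tau_n);
  for (int p = 0; p < np1; ++p) xi1[p] = sd_stat * rng.norm();
  for (int p = 0; p < np2; ++p) xi2[p] = sd_stat * rng.norm();
  const double ou_a = rate_dt / tau_n;
  const double ou_b = (sigma_n / tau_n) * std::sqrt(rate_dt);

  std::vector<double> pbin1(n1, 0.0), pbin2(n2, 0.0);
  arma::vec xv1(np1), xv2(np2);

  // outputs
  std::vector<int> sp_unit; std::vector<double> sp_time;
  sp_unit.reserve(1 << 20); sp_time.reserve(1 << 20);
  std::vector<int> v1_unit; std::vector<double> v1_time;
  IntegerVector counts(n), v1_counts(n1 + n2);
  NumericMatrix cur_mean(n, 3);
  const int ntr = trace_ids.size();
  int nsamp = 0;
  for (int s = 0; s < nsteps; s += rec_every)
    if (s * dt >= burnin - 1e-9) ++nsamp;
  NumericMatrix traces(ntr > 0 ? nsamp : 0, 3 * ntr);
  NumericVector trace_t(ntr > 0 ? nsamp : 0);
  int nmean = 0, isamp = 0;

  int cur_seg = 0;
  const int nseg = seg_tend.size();
  std::vector<int> spike_buf; spike_buf.reserve(4096);
  std::vector<int> v1_buf; v1_buf.reserve(4096);

  auto update_rates = [&](double t) {
    while (cur_seg < nseg - 1 && t >= seg_tend[cur_seg] - 1e-9) ++cur_seg;
    // population 1
    int mode = seg_modes(cur_seg, 0), b = seg_modes(cur_seg, 1);
    if (n1 > 0) {
      if (mode == 0) {
        for (int p = 0; p < np1; ++p) xv1[p] = xi1[p];
        arma::vec resp = F1 * xv1;
        for (int i = 0; i < n1; ++i) {
          double r = gain * std::max(bases1(i, b) + noise_scale * resp[i], 0.0);
          pbin1[i] = r * dt / 1000.0;
        }
      } else if (mode == 1) {
        double p0 = seg_rate1[cur_seg] * dt / 1000.0;
        std::fill(pbin1.begin(), pbin1.end(), p0);
      } else {
        for (int i = 0; i < n1; ++i) pbin1[i] = bases1(i, b) * dt / 1000.0;
      }
    }
    mode = seg_modes(cur_seg, 2); b = seg_modes(cur_seg, 3);
    if (n2 > 0) {
      if (mode == 0) {
        for (int p = 0; p < np2; ++p) xv2[p] = xi2[p];
        arma::vec resp = F2 * xv2;
        for (int i = 0; i < n2; ++i) {
          double r = gain * std::max(bases2(i, b) + noise_scale * resp[i], 0.0);
          pbin2[i] = r * dt / 1000.0;
        }
      } else if (mode == 1) {
        double p0 = seg_rate2[cur_seg] * dt / 1000.0;
        std::fill(pbin2.begin(), pbin2.end(), p0);
      } else {
        for (int i = 0; i < n2; ++i) pbin2[i] = bases2(i, b) * dt / 1000.0;
      }
    }
  };

  for (int step = 0; step < nsteps; ++step) {
    const double t = step * dt;
    if (step % rate_every == 0) {
      if (step > 0) {   // advance OU by rate_dt (Euler-Maruyama)
        for (int p = 0; p < np1; ++p)
          xi1[p] += -ou_a * xi1[p] + ou_b * rng.norm();
        for (int p = 0; p < np2; ++p)
          xi2[p] += -ou_a * xi2[p] + ou_b * rng.norm();
      }
      update_rates(t);
    }

    // V1 Poisson spikes (Bernoulli thinning per dt bin)
    v1_buf.clear();
    for (int i = 0; i < n1; ++i)
      if (rng.unif() < pbin1[i]) v1_buf.push_back(i);
    for (int i = 0; i < n2; ++i)
      if (rng.unif() < pbin2[i]) v1_buf.push_back(n1 + i);

    // synaptic state decay (exact update of the double-exponential filters)
    for (int j = 0; j < n; ++j) {
      sf[j] = sf[j] * ke.ad + xf[j] * ke.c;  xf[j] *= ke.br;
      ss[j] = ss[j] * ks.ad + xs[j] * ks.c;  xs[j] *= ks.br;
      se[j] = se[j] * ke.ad + xe[j] * ke.c;  xe[j] *= ke.br;
      si[j] = si[j] * ki.ad + xi[j] * ki.c;  xi[j] *= ki.br;
    }

    // membrane update
    spike_buf.clear();
    for (int j = 0; j < n; ++j) {
      if (refcnt[j] > 0) {
        if (--refcnt[j] == 0) V[j] = Vre[j];
        continue;
      }
      const double Isyn = pf * sf[j] + ps * ss[j] + se[j] + si[j] +
          ((j < n_e) ? I_ext_e : I_ext_i);
      double ex_arg = (V[j] - VT[j]) / DT[j];
      if (ex_arg > 30.0) ex_arg = 30.0;
      V[j] += (dt / taum[j]) * (-(V[j] - EL[j]) + DT[j] * std::exp(ex_arg)) +
              dt * Isyn;
      if (V[j] >= Vth[j]) {
        spike_buf.push_back(j);
        V[j] = Vth[j];                 // clamp during refractory period
        refcnt[j] = refsteps[j];
      } else if (V[j] > 200.0 || V[j] < -200.0) {
        stop("numerical blow-up at step %d, neuron %d (V = %f)", step, j,
             V[j]);
      }
    }

    // spike bookkeeping + synaptic propagation (no transmission delay)
    for (int j : spike_buf) {
      sp_unit.push_back(j); sp_time.push_back(t);
      if (t >= burnin) ++counts[j];
      if (j < n_e) {
        for (int k = e_ptr[j]; k < e_ptr[j + 1]; ++k)
          xe[e_tgt[k]] += e_w[k] * ke.inv;
      } else {
        const int jj = j - n_e;
        for (int k = i_ptr[jj]; k < i_ptr[jj + 1]; ++k)
          xi[i_tgt[k]] += i_w[k] * ki.inv;
      }
    }
    for (int i : v1_buf) {
      if (t >= burnin) ++v1_counts[i];
      if (record_v1) { v1_unit.push_back(i); v1_time.push_back(t); }
      for (int k = f_ptr[i]; k < f_ptr[i + 1]; ++k) {
        const int tg = f_tgt[k];
        xf[tg] += f_w[k] * ke.inv;
        xs[tg] += f_w[k] * ks.inv;
      }
    }

    // current recording at the 10-ms cadence
    if (step % rec_every == 0 && t >= burnin - 1e-9) {
      for (int j = 0; j < n; ++j) {
        cur_mean(j, 0) += pf * sf[j] + ps * ss[j];
        cur_mean(j, 1) += se[j];
        cur_mean(j, 2) += si[j];
      }
      if (ntr > 0) {
        for (int q = 0; q < ntr; ++q) {
          const int j = trace_ids[q];
          traces(isamp, 3 * q + 0) = pf * sf[j] + ps * ss[j];
          traces(isamp, 3 * q + 1) = se[j];
          traces(isamp, 3 * q + 2) = si[j];
        }
        trace_t[isamp] = t;
      }
      ++nmean; ++isamp;
    }
    if (step % 20000 == 0) Rcpp::checkUserInterrupt();
  }

  if (nmean > 0)
    for (int j = 0; j < n; ++j)
      for (int c = 0; c < 3; ++c) cur_mean(j, c) /= nmean;

  return List::create(
      _["spike_unit"] = IntegerVector(sp_unit.begin(), sp_unit.end()),
      _["spike_time"] = NumericVector(sp_time.begin(), sp_time.end()),
      _["counts"] = counts,
      _["v1_counts"] = v1_counts,
      _["cur_mean"] = cur_mean,
      _["traces"] = traces,
      _["trace_times"] = trace_t,
      _["v1_unit"] = IntegerVector(v1_unit.begin(), v1_unit.end()),
      _["v1_time"] = NumericVector(v1_time.begin(), v1_time.end()),
      _["V"] = NumericVector(V.begin(), V.end()),
      _["n_mean_samples"] = nmean);
}
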