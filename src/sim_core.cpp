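#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step integration of the two-node distal-arm circuit:
//   C_art dPa/dt = Ps/Ra - Pa (1/Ra + 1/Rsys) + Pv/Rsys
//   C_ven dPv/dt = Pa/Rsys - Pv (1/Rsys + 1/Rven) + Pven_sys/Rven
// with Ra the Poiseuille resistance of the cuff-occluded brachial segment
// evaluated each step at the instantaneous transmural pressure
// (Ps - Pcuff, or (Ps+Pa)/2 - Pcuff), and Rven a log-space sigmoid law in
// cuff pressure. Compiled because the batch runs of the sensitivity
// analysis integrate thousands of inflations at sub-millisecond steps.

struct SimPars {
  double a, c, d;                 // tube law
  double sbp, pp, hr, pven_sys;   // systemic input
  double rate, t_start, p_max, hold; // cuff protocol
  double r_sys, c_art, c_ven, r_ven_open, ven_thresh, ven_width;
  double arm_len, cuff_len;       // m
  double eta;                     // mmHg s
  double a_min, r_max;            // clamps
  double pre_roll;
  int    method;                  // 0 = euler, 1 = rk4
  int    ptm_mode;                // 0 = proximal, 1 = midpoint, 2 = distal
};

static inline double tube_area(double ptm, const SimPars &p) {
  double u = p.a * ptm + 3.3;
  if (u <= 1.0) return p.a_min;
  double E = 1.0 + std::exp(-p.c * ptm);
  // log argument normalized to its zero-transmural value: A(0) = d exactly
  double A = p.d * std::pow(std::log(u) / std::log(3.3), E);
  if (!(A > p.a_min)) A = p.a_min;   // catches underflow and NaN
  return A;
}

static inline double art_resistance(double ptm, const SimPars &p) {
  double A = tube_area(ptm, p);
  if (A <= p.a_min) return p.r_max;
  double r2 = A / M_PI;              // r^2, cm^2
  double R = 8.0 * p.eta * (p.cuff_len * 100.0) / (M_PI * r2 * r2);
  return (R > p.r_max) ? p.r_max : R;
}

struct VenLaw {
  double lg_lo, lg_hi, thresh, width;
  double operator()(double pcuff) const {
    double s = 1.0 / (1.0 + std::exp(-(pcuff - thresh) / width));
    return std::exp(lg_lo + (lg_hi - lg_lo) * s);
  }
};

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(List pars, double dt, bool store_series) {
  SimPars p;
  p.a = pars["a"]; p.c = pars["c"]; p.d = pars["d"];
  p.sbp = pars["sbp"]; p.pp = pars["pp"]; p.hr = pars["hr"];
  p.pven_sys = pars["pven_sys"];
  p.rate = pars["rate"]; p.t_start = pars["t_start"];
  p.p_max = pars["p_max"]; p.hold = pars["hold"];
  p.r_sys = pars["r_sys"]; p.c_art = pars["c_art"]; p.c_ven = pars["c_ven"];
  p.r_ven_open = pars["r_ven_open"];
  p.ven_thresh = pars["ven_thresh"]; p.ven_width = pars["ven_width"];
  p.arm_len = pars["arm_len"]; p.cuff_len = pars["cuff_len"];
  p.eta = pars["eta"]; p.a_min = pars["a_min"]; p.r_max = pars["r_max"];
  p.pre_roll = pars["pre_roll"];
  p.method = as<int>(pars["method"]);
  p.ptm_mode = as<int>(pars["ptm_mode"]);

  const double dbp = p.sbp - p.pp;
  const double map_sys = 0.5 * (p.sbp + dbp);
  const double omega = 2.0 * M_PI * p.hr / 60.0;
  const double t_beat = 60.0 / p.hr;
  const double beat_off = 0.75 * t_beat;  // sinusoid trough at t = 0.75 T
  const double ramp = (p.rate > 0.0) ? p.p_max / p.rate : 0.0;
  const double t_end = p.t_start + ramp + p.hold;

  VenLaw ven{std::log(p.r_ven_open), std::log(p.r_max), p.ven_thresh,
             p.ven_width};

  const int n_pre = (int)std::lround(p.pre_roll / dt);
  const int n_out = (int)std::lround(t_end / dt) + 1;
  const int n_beat = std::max(0, (int)std::floor((t_end - beat_off) / t_beat));

  NumericVector st, sps, spc, spa, spv;
  if (store_series) {
    st = NumericVector(n_out); sps = NumericVector(n_out);
    spc = NumericVector(n_out); spa = NumericVector(n_out);
    spv = NumericVector(n_out);
  }
  NumericVector b_t(n_beat), b_min(n_beat), b_max(n_beat), b_sum(n_beat),
      b_pc(n_beat);
  IntegerVector b_n(n_beat);
  std::fill(b_min.begin(), b_min.end(), R_PosInf);
  std::fill(b_max.begin(), b_max.end(), R_NegInf);

  double pa = map_sys, pv = p.pven_sys;
  double pa_tail = NA_REAL;  // Pa at first sample in the final second
  double tail_min = R_PosInf, tail_max = R_NegInf;

  auto psys = [&](double t) { return map_sys + 0.5 * p.pp * std::sin(omega * t); };
  auto pcuff = [&](double t) {
    if (t < p.t_start) return 0.0;
    double x = p.rate * (t - p.t_start);
    return (x > p.p_max) ? p.p_max : x;
  };
  auto deriv = [&](double t, double a_, double v_, double &da, double &dv) {
    double ps = psys(t), pc = pcuff(t);
    double ptm = (p.ptm_mode == 2) ? a_ - pc
               : (p.ptm_mode == 1) ? 0.5 * (ps + a_) - pc : ps - pc;
    double Ra = art_resistance(ptm, p);
    double Rv = ven(pc);
    da = (ps / Ra - a_ * (1.0 / Ra + 1.0 / p.r_sys) + v_ / p.r_sys) / p.c_art;
    dv = (a_ / p.r_sys - v_ * (1.0 / p.r_sys + 1.0 / Rv) + p.pven_sys / Rv) /
         p.c_ven;
  };

  for (int i = -n_pre; i < n_out; ++i) {
    double t = i * dt;
    if (i >= 0) {
      if (store_series) {
        st[i] = t; sps[i] = psys(t); spc[i] = pcuff(t);
        spa[i] = pa; spv[i] = pv;
      }
      int k = (int)std::floor((t - beat_off) / t_beat);
      if (k >= 0 && k < n_beat) {
        if (b_n[k] == 0) b_t[k] = beat_off + k * t_beat;
        if (pa < b_min[k]) b_min[k] = pa;
        if (pa > b_max[k]) b_max[k] = pa;
        b_sum[k] += pa; b_pc[k] += pcuff(t); b_n[k]++;
      }
      if (t >= t_end - 1.0) {
        if (ISNA(pa_tail)) pa_tail = pa;
        if (pa < tail_min) tail_min = pa;
        if (pa > tail_max) tail_max = pa;
      }
    }
    if (i == n_out - 1) break;
    double k1a, k1v;
    deriv(t, pa, pv, k1a, k1v);
    if (p.method == 0) {
      pa += dt * k1a; pv += dt * k1v;
    } else {
      double k2a, k2v, k3a, k3v, k4a, k4v;
      deriv(t + 0.5 * dt, pa + 0.5 * dt * k1a, pv + 0.5 * dt * k1v, k2a, k2v);
      deriv(t + 0.5 * dt, pa + 0.5 * dt * k2a, pv + 0.5 * dt * k2v, k3a, k3v);
      deriv(t + dt, pa + dt * k3a, pv + dt * k3v, k4a, k4v);
      pa += dt / 6.0 * (k1a + 2.0 * k2a + 2.0 * k3a + k4a);
      pv += dt / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
    }
    if ((i & 1023) == 0 && !(std::isfinite(pa) && std::isfinite(pv)))
      stop("simulation diverged (non-finite state at t = %.3f s)", t);
  }
  if (!(std::isfinite(pa) && std::isfinite(pv)))
    stop("simulation diverged (non-finite final state)");

  NumericVector b_map(n_beat), b_pcm(n_beat);
  for (int k = 0; k < n_beat; ++k) {
    b_map[k] = (b_n[k] > 0) ? b_sum[k] / b_n[k] : NA_REAL;
    b_pcm[k] = (b_n[k] > 0) ? b_pc[k] / b_n[k] : NA_REAL;
  }

  List beats = List::create(
      _["t_start"] = b_t, _["dbp"] = b_min, _["sbp"] = b_max,
      _["map"] = b_map, _["p_cuff"] = b_pcm, _["n_samples"] = b_n);
  List out = List::create(
      _["beats"] = beats, _["p_end"] = pa, _["pv_end"] = pv,
      _["slope_end"] = (pa - pa_tail) / 1.0,
      _["pulse_end"] = tail_max - tail_min, _["t_end"] = t_end,
      _["t_occlusion"] = p.t_start + ramp, _["dt"] = dt);
  if (store_series)
    out["series"] = List::create(_["time"] = st, _["p_art_sys"] = sps,
                                 _["p_cuff"] = spc, _["p_art_distal"] = spa,
                                 _["p_ven_distal"] = spv);
  return out;
}
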