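// Simulation kernels for the bursting feedback loop and toggle switch.
// All randomness is drawn from R's RNG stream (unif_rand / exp_rand /
// norm_rand), so set.seed() on the R side gives full reproducibility.

#include <Rcpp.h>
#include <deque>
#include <vector>
#include <cmath>
using namespace Rcpp;

// (P/P0)^h evaluated in log space to survive extreme arguments
static inline double pow_ratio(double P, double P0, double h) {
  if (P <= 0.0) return 0.0;
  double lx = h * (std::log(P) - std::log(P0));
  if (lx > 600.0) return 1e260;
  return std::exp(lx);
}

static inline double hillf(double P, double P0, double h) {
  return 1.0 / (1.0 + pow_ratio(P, P0, h));
}

// ---------------------------------------------------------------------------
// Deterministic DDE (Heun, fixed step, ring-buffer delay)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List dde_kernel(double aM, double aP, double muM, double muP,
                double h, double P0, double tau,
                double T, double dt, double M0, double Pini,
                double M_hist, double P_hist) {
  int n = (int)std::lround(T / dt);
  int L = (int)std::lround(tau / dt);
  NumericVector tv(n + 1), Mv(n + 1), Pv(n + 1);
  Mv[0] = M0; Pv[0] = Pini;
  for (int i = 0; i <= n; ++i) tv[i] = i * dt;
  for (int i = 0; i < n; ++i) {
    double Pd0 = (i - L >= 0) ? Pv[i - L] : P_hist;
    double M = Mv[i], P = Pv[i];
    double k1M = aM * hillf(Pd0, P0, h) - muM * M;
    double k1P = aP * M - muP * P;
    double Mp = M + dt * k1M, Pp = P + dt * k1P;
    // with L >= 1 the corrector's delayed value is already on the grid;
    // the undelayed case (L == 0) uses the predictor
    double Pd1 = (L == 0) ? Pp : ((i + 1 - L >= 0) ? Pv[i + 1 - L] : P_hist);
    double k2M = aM * hillf(Pd1, P0, h) - muM * Mp;
    double k2P = aP * Mp - muP * Pp;
    Mv[i + 1] = M + 0.5 * dt * (k1M + k2M);
    Pv[i + 1] = P + 0.5 * dt * (k1P + k2P);
  }
  return List::create(_["time"] = tv, _["M"] = Mv, _["P"] = Pv);
}

// ---------------------------------------------------------------------------
// Full delayed SSA (telegraph promoter, scheduled mRNA arrivals)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List ssa_full_kernel(double aM, double aP, double muM, double muP,
                     double h, double P0, double tau,
                     double omega, double lam,
                     double T, double sample_dt,
                     double nM0, double nP0, int sigma0) {
  bool bursting = R_FINITE(lam);  // lam == Inf selects the Hill-rate reduction
  double nM = nM0, nP = nP0;
  int sigma = sigma0;
  double t = 0.0;
  std::deque<double> queue;  // scheduled arrival times; FIFO since tau is constant
  double n_init = 0.0, n_arr = 0.0;
  int n_out = (int)std::lround(std::floor(T / sample_dt + 1e-9)) + 1;
  NumericVector tv(n_out), Mv(n_out), Pv(n_out);
  IntegerVector sv(n_out);
  int gi = 0;
  long long iter = 0;
  while (gi < n_out) {
    if ((++iter & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    double a_tx;
    if (bursting) a_tx = sigma ? aM * omega : 0.0;
    else          a_tx = aM * omega * hillf(nP / omega, P0, h);
    double a_dM = muM * nM, a_tr = aP * nM, a_dP = muP * nP;
    double a_off = 0.0, a_on = 0.0;
    if (bursting) {
      if (sigma) a_off = lam * pow_ratio(nP / omega, P0, h);
      else       a_on = lam;
    }
    double a0 = a_tx + a_dM + a_tr + a_dP + a_off + a_on;
    if (!R_FINITE(a0) || a0 < 0.0)
      stop("non-finite total propensity at t = %f", t);
    double t_next = (a0 > 0.0) ? t + exp_rand() / a0 : R_PosInf;
    double t_arr = queue.empty() ? R_PosInf : queue.front();
    double t_ev = (t_arr < t_next) ? t_arr : t_next;
    while (gi < n_out && (double)gi * sample_dt < t_ev) {
      tv[gi] = (double)gi * sample_dt;
      Mv[gi] = nM / omega; Pv[gi] = nP / omega; sv[gi] = sigma;
      ++gi;
    }
    if (gi >= n_out) break;
    if (!R_FINITE(t_ev)) {
      // absorbing state: fill the rest of the grid
      while (gi < n_out) {
        tv[gi] = (double)gi * sample_dt;
        Mv[gi] = nM / omega; Pv[gi] = nP / omega; sv[gi] = sigma;
        ++gi;
      }
      break;
    }
    if (t_arr <= t_next) {
      // delayed transcript arrives first; redraw the exponential clock
      t = t_arr; queue.pop_front(); nM += 1.0; n_arr += 1.0;
      continue;
    }
    t = t_next;
    double u = unif_rand() * a0;
    if ((u -= a_tx) < 0.0) {
      n_init += 1.0;
      if (tau > 0.0) queue.push_back(t + tau);
      else { nM += 1.0; n_arr += 1.0; }
    } else if ((u -= a_dM) < 0.0) nM -= 1.0;
    else if ((u -= a_tr) < 0.0) nP += 1.0;
    else if ((u -= a_dP) < 0.0) nP -= 1.0;
    else if ((u -= a_off) < 0.0) sigma = 0;
    else sigma = 1;
  }
  return List::create(_["time"] = tv, _["M"] = Mv, _["P"] = Pv,
                      _["sigma"] = sv,
                      _["n_initiated"] = n_init, _["n_arrived"] = n_arr,
                      _["queue_residue"] = (double)queue.size());
}

// ---------------------------------------------------------------------------
// Toggle-switch SSA (two telegraph promoters, mutual repression, no delay)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List ssa_toggle_kernel(double alpha, double mu, double h, double P0,
                       double omega, double lam,
                       double T, double sample_dt,
                       double nA0, double nB0, int sA0, int sB0) {
  double nA = nA0, nB = nB0;
  int sA = sA0, sB = sB0;
  double t = 0.0;
  int n_out = (int)std::lround(std::floor(T / sample_dt + 1e-9)) + 1;
  NumericVector tv(n_out), Av(n_out), Bv(n_out);
  IntegerVector sAv(n_out), sBv(n_out);
  int gi = 0;
  long long iter = 0;
  while (gi < n_out) {
    if ((++iter & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    double a1 = alpha * omega * sA;           // A production
    double a2 = alpha * omega * sB;           // B production
    double a3 = mu * nA, a4 = mu * nB;        // degradation
    double a5 = sA ? lam * pow_ratio(nB / omega, P0, h) : 0.0;  // A promoter OFF
    double a6 = lam * (1 - sA);                                  // A promoter ON
    double a7 = sB ? lam * pow_ratio(nA / omega, P0, h) : 0.0;  // B promoter OFF
    double a8 = lam * (1 - sB);                                  // B promoter ON
    double a0 = a1 + a2 + a3 + a4 + a5 + a6 + a7 + a8;
    if (!R_FINITE(a0)) stop("non-finite total propensity at t = %f", t);
    double t_next = (a0 > 0.0) ? t + exp_rand() / a0 : R_PosInf;
    while (gi < n_out && (double)gi * sample_dt < t_next) {
      tv[gi] = (double)gi * sample_dt;
      Av[gi] = nA / omega; Bv[gi] = nB / omega;
      sAv[gi] = sA; sBv[gi] = sB;
      ++gi;
    }
    if (gi >= n_out || !R_FINITE(t_next)) {
      while (gi < n_out) {
        tv[gi] = (double)gi * sample_dt;
        Av[gi] = nA / omega; Bv[gi] = nB / omega;
        sAv[gi] = sA; sBv[gi] = sB;
        ++gi;
      }
      break;
    }
    t = t_next;
    double u = unif_rand() * a0;
    if ((u -= a1) < 0.0) nA += 1.0;
    else if ((u -= a2) < 0.0) nB += 1.0;
    else if ((u -= a3) < 0.0) nA -= 1.0;
    else if ((u -= a4) < 0.0) nB -= 1.0;
    else if ((u -= a5) < 0.0) sA = 0;
    else if ((u -= a6) < 0.0) sA = 1;
    else if ((u -= a7) < 0.0) sB = 0;
    else sB = 1;
  }
  return List::create(_["time"] = tv, _["A"] = Av, _["B"] = Bv,
                      _["sigma_A"] = sAv, _["sigma_B"] = sBv);
}

// ---------------------------------------------------------------------------
// Piecewise-deterministic process: Heun ODE flow between promoter switches,
// delayed sigma drive, hazard inversion for the ON->OFF jump time
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List pdmp_kernel(double aM, double aP, double muM, double muP,
                 double h, double P0, double tau, double lam,
                 double T, double sample_dt, double dt_int,
                 double M0, double Pini, int sigma0) {
  std::vector<double> sw_t; std::vector<int> sw_s;
  double t = 0.0, M = M0, P = Pini;
  int sigma = sigma0;
  double E = (sigma == 1) ? exp_rand() : 0.0;  // hazard threshold while ON
  double cum = 0.0;
  double t_on = (sigma == 0) ? t + exp_rand() / lam : R_PosInf;
  int n_out = (int)std::lround(std::floor(T / sample_dt + 1e-9)) + 1;
  NumericVector tv(n_out), Mv(n_out), Pv(n_out);
  IntegerVector sv(n_out);
  int gi = 0;
  tv[0] = 0.0; Mv[0] = M; Pv[0] = P; sv[0] = sigma; gi = 1;
  size_t jd = 0;  // index of next switch whose delayed effect is pending
  int sd = sigma0;  // delayed promoter state sigma(t - tau)
  long long iter = 0;
  while (gi < n_out) {
    if ((++iter & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    double t_grid = (double)gi * sample_dt;
    double t_end = t + dt_int;
    if (t_end > t_grid) t_end = t_grid;
    if (sigma == 0 && t_on < t_end) t_end = t_on;
    // split steps where the delayed sigma changes; the delayed state is
    // tracked incrementally with the identical fp expression sw_t[jd]+tau
    // used for the split, so the boundary comparison is exact (computing
    // sigma(t - tau) by subtraction would cancel catastrophically)
    while (jd < sw_t.size() && sw_t[jd] + tau <= t) { sd = sw_s[jd]; ++jd; }
    if (jd < sw_t.size() && sw_t[jd] + tau < t_end) t_end = sw_t[jd] + tau;
    double hstep = t_end - t;
    if (hstep > 0.0) {
      // Heun step with constant delayed drive
      double k1M = aM * sd - muM * M, k1P = aP * M - muP * P;
      double Mp = M + hstep * k1M, Pp = P + hstep * k1P;
      double k2M = aM * sd - muM * Mp, k2P = aP * Mp - muP * Pp;
      double Mn = M + 0.5 * hstep * (k1M + k2M);
      double Pn = P + 0.5 * hstep * (k1P + k2P);
      if (sigma == 1) {
        double r0 = lam * pow_ratio(P, P0, h);
        double r1 = lam * pow_ratio(Pn, P0, h);
        double dH = 0.5 * hstep * (r0 + r1);
        if (cum + dH >= E) {
          // hazard crosses inside the step: locate by linear interpolation
          double frac = (dH > 0.0) ? (E - cum) / dH : 0.0;
          double hs = frac * hstep;
          double Mp2 = M + hs * k1M, Pp2 = P + hs * k1P;
          M = M + 0.5 * hs * (k1M + (aM * sd - muM * Mp2));
          P = P + 0.5 * hs * (k1P + (aP * Mp2 - muP * Pp2));
          t = t + hs;
          sigma = 0;
          sw_t.push_back(t); sw_s.push_back(0);
          t_on = t + exp_rand() / lam;
          cum = 0.0;
          continue;
        }
        cum += dH;
      }
      M = Mn; P = Pn; t = t_end;
    } else {
      t = t_end;
    }
    if (sigma == 0 && t >= t_on) {
      sigma = 1;
      sw_t.push_back(t_on); sw_s.push_back(1);
      E = exp_rand(); cum = 0.0;
      t_on = R_PosInf;
    }
    if (t >= t_grid) {
      tv[gi] = t_grid; Mv[gi] = M; Pv[gi] = P; sv[gi] = sigma;
      ++gi;
    }
  }
  return List::create(_["time"] = tv, _["M"] = Mv, _["P"] = Pv,
                      _["sigma"] = sv,
                      _["switch_time"] = wrap(sw_t),
                      _["switch_sigma"] = wrap(sw_s));
}

// ---------------------------------------------------------------------------
// Extended chemical Langevin equation (Euler-Maruyama, delay ring buffer)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cle_kernel(double aM, double aP, double muM, double muP,
                double h, double P0, double tau,
                double omega, double lam, bool drift_alpha_m,
                double T, double dt, int thin,
                double M0, double Pini, double hist_fill) {
  bool burst_noise = R_FINITE(lam);
  bool copy_noise = R_FINITE(omega);
  int n = (int)std::lround(T / dt);
  int L = (int)std::lround(tau / dt);
  int n_out = n / thin + 1;
  NumericVector tv(n_out), Mv(n_out), Pv(n_out);
  std::vector<double> buf(L > 0 ? L : 1, hist_fill);
  int pos = 0;
  double M = M0, P = Pini;
  tv[0] = 0.0; Mv[0] = M; Pv[0] = P;
  int gi = 1;
  for (int i = 0; i < n; ++i) {
    if ((i & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    double Pd;
    if (L > 0) { Pd = buf[pos]; buf[pos] = P; pos = (pos + 1) % L; }
    else Pd = P;
    double xh = pow_ratio(Pd, P0, h);
    double fPd = 1.0 / (1.0 + xh);
    double varM = 0.0;
    if (burst_noise) varM += (aM * aM / lam) * 2.0 * xh / ((1.0 + xh) * (1.0 + xh) * (1.0 + xh));
    if (copy_noise) varM += (aM * fPd + muM * M) / omega;
    double varP = copy_noise ? (aP * M + muP * P) / omega : 0.0;
    double driftM = (drift_alpha_m ? aM : 1.0) * fPd - muM * M;
    double driftP = aP * M - muP * P;
    double Mn = M + driftM * dt + std::sqrt(varM * dt) * norm_rand();
    double Pn = P + driftP * dt + std::sqrt(varP * dt) * norm_rand();
    M = (Mn > 0.0) ? Mn : 0.0;
    P = (Pn > 0.0) ? Pn : 0.0;
    if (!R_FINITE(M) || !R_FINITE(P))
      stop("CLE state became non-finite at step %d (t = %f)", i + 1, (i + 1) * dt);
    if ((i + 1) % thin == 0) {
      tv[gi] = (double)(i + 1) * dt; Mv[gi] = M; Pv[gi] = P; ++gi;
    }
  }
  return List::create(_["time"] = tv, _["M"] = Mv, _["P"] = Pv);
}

// ---------------------------------------------------------------------------
// Linear-noise simulation: fluctuations about the fixed point, constant
// noise amplitudes, no clamping
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List lna_kernel(double gain, double aP, double muM, double muP, double tau,
                double sigM2, double sigP2,
                double T, double dt, int thin, double m0, double p0) {
  // gain = alpha_M * f'(P*)
  int n = (int)std::lround(T / dt);
  int L = (int)std::lround(tau / dt);
  int n_out = n / thin + 1;
  NumericVector tv(n_out), mv(n_out), pv(n_out);
  std::vector<double> buf(L > 0 ? L : 1, 0.0);
  int pos = 0;
  double m = m0, p = p0;
  double sM = std::sqrt(sigM2 * dt), sP = std::sqrt(sigP2 * dt);
  tv[0] = 0.0; mv[0] = m; pv[0] = p;
  int gi = 1;
  for (int i = 0; i < n; ++i) {
    if ((i & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    double pd;
    if (L > 0) { pd = buf[pos]; buf[pos] = p; pos = (pos + 1) % L; }
    else pd = p;
    double mn = m + (gain * pd - muM * m) * dt + sM * norm_rand();
    double pn = p + (aP * m - muP * p) * dt + sP * norm_rand();
    m = mn; p = pn;
    if (!R_FINITE(m) || !R_FINITE(p))
      stop("LNA state became non-finite at step %d", i + 1);
    if ((i + 1) % thin == 0) {
      tv[gi] = (double)(i + 1) * dt; mv[gi] = m; pv[gi] = p; ++gi;
    }
  }
  return List::create(_["time"] = tv, _["m"] = mv, _["p"] = pv);
}

// ---------------------------------------------------------------------------
// Toggle-switch CLE (two channels, mirror-symmetric noise, no delay)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cle_toggle_kernel(double alpha, double mu, double h, double P0,
                       double omega, double lam, bool drift_alpha,
                       double T, double dt, int thin,
                       double A0, double B0) {
  bool burst_noise = R_FINITE(lam);
  bool copy_noise = R_FINITE(omega);
  int n = (int)std::lround(T / dt);
  int n_out = n / thin + 1;
  NumericVector tv(n_out), Av(n_out), Bv(n_out);
  double A = A0, B = B0;
  tv[0] = 0.0; Av[0] = A; Bv[0] = B;
  int gi = 1;
  for (int i = 0; i < n; ++i) {
    if ((i & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    double xB = pow_ratio(B, P0, h), xA = pow_ratio(A, P0, h);
    double fB = 1.0 / (1.0 + xB), fA = 1.0 / (1.0 + xA);
    double varA = 0.0, varB = 0.0;
    if (burst_noise) {
      varA += (alpha * alpha / lam) * 2.0 * xB / ((1.0 + xB) * (1.0 + xB) * (1.0 + xB));
      varB += (alpha * alpha / lam) * 2.0 * xA / ((1.0 + xA) * (1.0 + xA) * (1.0 + xA));
    }
    if (copy_noise) {
      varA += (alpha * fB + mu * A) / omega;
      varB += (alpha * fA + mu * B) / omega;
    }
    double ca = drift_alpha ? alpha : 1.0;
    double An = A + (ca * fB - mu * A) * dt + std::sqrt(varA * dt) * norm_rand();
    double Bn = B + (ca * fA - mu * B) * dt + std::sqrt(varB * dt) * norm_rand();
    A = (An > 0.0) ? An : 0.0;
    B = (Bn > 0.0) ? Bn : 0.0;
    if (!R_FINITE(A) || !R_FINITE(B))
      stop("toggle CLE state became non-finite at step %d", i + 1);
    if ((i + 1) % thin == 0) {
      tv[gi] = (double)(i + 1) * dt; Av[gi] = A; Bv[gi] = B; ++gi;
    }
  }
  return List::create(_["time"] = tv, _["A"] = Av, _["B"] = Bv);
}
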