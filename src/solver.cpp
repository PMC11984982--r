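// Adaptive Dormand-Prince 5(4) integrator for the protest compartment model.
//
// State vector y = (S, I, C, R, D, A):
//   S susceptible, I novice protesters, C experienced protesters,
//   R retired, D detained; A is the auxiliary cumulative-arrest integral
//   dA/dt = eps1(t) I + eps2(t) C used to connect the detention flux to
//   arrest-count observations.
//
// The detention rates eps1(t), eps2(t) are piecewise constant with
// half-open intervals [t_k, t_{k+1}) (right-continuous). The integrator
// never steps across a breakpoint or a requested output time, so the
// constant pair used within a step is exact and output values are computed
// at the exact requested times (no interpolation).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

const int NSTATE = 6;

struct ModelParams {
  double beta1, beta2, gamma, chi, delta1, delta2, c0, n, eps3;
  double c0n;  // c0^n, precomputed
};

inline void deriv(const ModelParams& mp, double e1, double e2,
                  const double* y, double* dy) {
  const double S = y[0], I = y[1], C = y[2], R = y[3], D = y[4];
  const double N = I + C;
  // Hill-type collective withdrawal: decreases from delta1 (N=0) to delta2.
  const double w = mp.delta2 +
      (mp.delta1 - mp.delta2) * mp.c0n / (std::pow(N, mp.n) + mp.c0n);
  const double recruit = mp.beta1 * S * I + mp.beta2 * S * C;
  const double detained = e1 * I + e2 * C;
  dy[0] = -recruit + mp.gamma * R;
  dy[1] = recruit - (mp.chi + mp.delta1 + e1) * I;
  dy[2] = mp.chi * I - (w + e2) * C;
  dy[3] = mp.delta1 * I + w * C - mp.gamma * R + mp.eps3 * D;
  dy[4] = detained - mp.eps3 * D;
  dy[5] = detained;
}

// index of the schedule interval containing t under [t_k, t_{k+1})
inline int interval_index(const std::vector<double>& br, double t) {
  return static_cast<int>(std::upper_bound(br.begin(), br.end(), t) -
                          br.begin());
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix integrate_protest_cpp(NumericVector par, NumericVector breaks,
                                    NumericVector eps1v, NumericVector eps2v,
                                    NumericVector y0, NumericVector out_times,
                                    double t_end, double rtol, double atol) {
  ModelParams mp;
  mp.beta1 = par[0]; mp.beta2 = par[1]; mp.gamma = par[2]; mp.chi = par[3];
  mp.delta1 = par[4]; mp.delta2 = par[5]; mp.c0 = par[6]; mp.n = par[7];
  mp.eps3 = par[8];
  mp.c0n = std::pow(mp.c0, mp.n);

  std::vector<double> br(breaks.begin(), breaks.end());
  const int nout = out_times.size();
  NumericMatrix out(nout, NSTATE + 1);

  // mandatory stop times: schedule breakpoints and output times in (0, t_end]
  std::vector<double> stops;
  for (double b : br) if (b > 0.0 && b < t_end) stops.push_back(b);
  for (int i = 0; i < nout; ++i)
    if (out_times[i] > 0.0) stops.push_back(out_times[i]);
  stops.push_back(t_end);
  std::sort(stops.begin(), stops.end());
  stops.erase(std::unique(stops.begin(), stops.end(),
                          [](double a, double b) {
                            return std::fabs(a - b) < 1e-12;
                          }),
              stops.end());

  // Dormand-Prince 5(4) tableau
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695,
                      e4 = 393.0 / 640, e5 = -92097.0 / 339200,
                      e6 = 187.0 / 2100, e7 = 1.0 / 40;

  double y[NSTATE], ytmp[NSTATE], ynew[NSTATE], y4[NSTATE];
  double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], k5[NSTATE],
      k6[NSTATE], k7[NSTATE];
  for (int i = 0; i < NSTATE; ++i) y[i] = y0[i];

  double t = 0.0;
  int oi = 0;
  while (oi < nout && out_times[oi] <= 1e-12) {
    out(oi, 0) = out_times[oi];
    for (int i = 0; i < NSTATE; ++i) out(oi, i + 1) = y[i];
    ++oi;
  }
  if (t_end <= 0.0) return out;

  std::size_t si = 0;
  int idx = interval_index(br, t);
  double ce1 = eps1v[idx], ce2 = eps2v[idx];
  deriv(mp, ce1, ce2, y, k1);
  bool k1_fresh = true;

  double h = std::min(0.5, stops[0]);
  const double hmin = 1e-12;
  long nsteps = 0;
  const long max_steps = 5000000L;

  while (si < stops.size()) {
    const double target = stops[si];
    if (t >= target - 1e-9) {
      // arrived at a stop: record output / refresh schedule interval
      t = target;
      while (oi < nout && out_times[oi] <= t + 1e-9) {
        out(oi, 0) = out_times[oi];
        for (int i = 0; i < NSTATE; ++i) out(oi, i + 1) = y[i];
        ++oi;
      }
      ++si;
      int nidx = interval_index(br, t);
      if (nidx != idx) {
        idx = nidx;
        ce1 = eps1v[idx];
        ce2 = eps2v[idx];
        deriv(mp, ce1, ce2, y, k1);  // rates changed: refresh FSAL stage
        k1_fresh = true;
      }
      continue;
    }
    if (!k1_fresh) {
      deriv(mp, ce1, ce2, y, k1);
      k1_fresh = true;
    }
    double hstep = std::min(h, target - t);

    for (int i = 0; i < NSTATE; ++i) ytmp[i] = y[i] + hstep * a21 * k1[i];
    deriv(mp, ce1, ce2, ytmp, k2);
    for (int i = 0; i < NSTATE; ++i)
      ytmp[i] = y[i] + hstep * (a31 * k1[i] + a32 * k2[i]);
    deriv(mp, ce1, ce2, ytmp, k3);
    for (int i = 0; i < NSTATE; ++i)
      ytmp[i] = y[i] + hstep * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    deriv(mp, ce1, ce2, ytmp, k4);
    for (int i = 0; i < NSTATE; ++i)
      ytmp[i] = y[i] + hstep * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                                a54 * k4[i]);
    deriv(mp, ce1, ce2, ytmp, k5);
    for (int i = 0; i < NSTATE; ++i)
      ytmp[i] = y[i] + hstep * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                                a64 * k4[i] + a65 * k5[i]);
    deriv(mp, ce1, ce2, ytmp, k6);
    for (int i = 0; i < NSTATE; ++i)
      ynew[i] = y[i] + hstep * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                                b5 * k5[i] + b6 * k6[i]);
    deriv(mp, ce1, ce2, ynew, k7);
    for (int i = 0; i < NSTATE; ++i)
      y4[i] = y[i] + hstep * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                              e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);

    double errnorm = 0.0;
    for (int i = 0; i < NSTATE; ++i) {
      const double sk =
          atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      const double e = (ynew[i] - y4[i]) / sk;
      errnorm += e * e;
    }
    errnorm = std::sqrt(errnorm / NSTATE);

    if (errnorm <= 1.0) {
      t += hstep;
      for (int i = 0; i < NSTATE; ++i) {
        y[i] = ynew[i];
        k1[i] = k7[i];  // FSAL
      }
      k1_fresh = true;
    } else {
      k1_fresh = true;  // k1 still valid at unchanged y
    }
    const double fac = (errnorm <= 1e-30)
                           ? 5.0
                           : std::min(5.0, std::max(0.2, 0.9 * std::pow(
                                                             errnorm, -0.2)));
    h = std::max(hstep * fac, hmin);

    if (hstep < hmin && errnorm > 1.0)
      stop("step size underflow near t = %f (interval up to t = %f)", t,
           target);
    if (++nsteps > max_steps)
      stop("integrator exceeded %ld steps near t = %f", max_steps, t);
  }

  // trailing outputs exactly at t_end
  while (oi < nout && out_times[oi] <= t + 1e-9) {
    out(oi, 0) = out_times[oi];
    for (int i = 0; i < NSTATE; ++i) out(oi, i + 1) = y[i];
    ++oi;
  }
  if (oi < nout) stop("output time %f beyond integration horizon", out_times[oi]);
  return out;
}
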