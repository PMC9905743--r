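// Fixed-step 4th-order integrator for the six-variable DRN-VTA model with
// the quasi-steady threshold-linear rate system solved at every stage.
//
// State layout: 0 I_auto_5HT, 1 I_auto_DA, 2 I_mod_5HT, 3 I_mod_DA,
//               4 [5-HT], 5 [DA].
// Population layout: 0 HT5_DRN, 1 DA_VTA, 2 GLU_DRN, 3 GABA_DRN, 4 GABA_VTA.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Net {
  arma::vec gain, thr, bias;     // 5
  arma::mat Jf;                  // 5 x 5 (target x source), signed
  arma::mat Ws;                  // 5 x 4 (target x slow state), signed
  arma::vec tau, k, slope, off;  // 4 slow-current parameter sets
  arma::vec per, vmax, km, scl;  // 2 release parameter sets (5-HT, DA)
};

const double ACT_TOL = 1e-9;

// Active-set solve of F = G * [base + Jf * F - thr]_+ .
// `warm` carries the previous solution's active set between calls; the
// result is independent of the warm start (it only short-circuits the
// search), which the equivalence tests against the R solver confirm.
bool solve_rates_cpp(const Net& net, const arma::vec& base, arma::vec& F,
                     std::vector<bool>* warm = nullptr) {
  const int n = 5;
  std::vector<bool> active = (warm && warm->size() == 5)
                                 ? *warm
                                 : std::vector<bool>(n, true);
  auto attempt = [&](const std::vector<bool>& act, arma::vec& f,
                     arma::vec& cur) -> bool {
    arma::uvec idx(n);
    int m = 0;
    for (int i = 0; i < n; ++i) if (act[i]) idx[m++] = i;
    f.zeros(n);
    if (m > 0) {
      arma::uvec ia = idx.head(m);
      arma::mat A = arma::eye(m, m);
      for (int r = 0; r < m; ++r)
        for (int c = 0; c < m; ++c)
          A(r, c) -= net.gain[ia[r]] * net.Jf(ia[r], ia[c]);
      arma::vec rhs(m);
      for (int r = 0; r < m; ++r)
        rhs[r] = net.gain[ia[r]] * (base[ia[r]] - net.thr[ia[r]]);
      arma::vec sol;
      if (!arma::solve(sol, A, rhs, arma::solve_opts::no_approx)) return false;
      for (int r = 0; r < m; ++r) f[ia[r]] = sol[r];
    }
    cur = base + net.Jf * f;
    return true;
  };
  arma::vec f, cur;
  for (int iter = 0; iter < 20; ++iter) {
    if (!attempt(active, f, cur)) break;
    bool ok = true;
    std::vector<bool> nxt = active;
    for (int i = 0; i < n; ++i) {
      if (active[i] && f[i] < -ACT_TOL) { nxt[i] = false; ok = false; }
      if (!active[i] && cur[i] > net.thr[i] + ACT_TOL) { nxt[i] = true; ok = false; }
    }
    if (ok) {
      F = arma::clamp(f, 0.0, arma::datum::inf);
      if (warm) *warm = active;
      return true;
    }
    if (nxt == active) break;
    active = nxt;
  }
  // deterministic lexicographic fallback over all subsets
  for (int code = 0; code < 32; ++code) {
    std::vector<bool> act(n);
    for (int i = 0; i < n; ++i) act[i] = (code >> i) & 1;
    if (!attempt(act, f, cur)) continue;
    bool ok = true;
    for (int i = 0; i < n; ++i) {
      if (act[i] && f[i] < -ACT_TOL) ok = false;
      if (!act[i] && cur[i] > net.thr[i] + ACT_TOL) ok = false;
    }
    if (ok) {
      F = arma::clamp(f, 0.0, arma::datum::inf);
      if (warm) *warm = act;
      return true;
    }
  }
  return false;
}

// External inputs at time t. Event columns: target(0-based), sign,
// amplitude, onset, offset, smoothing tau (0 = unsmoothed).
void externals_at(const arma::mat& ev, double t, arma::vec& ext) {
  ext.zeros(5);
  for (arma::uword i = 0; i < ev.n_rows; ++i) {
    const int tgt = (int)ev(i, 0);
    const double sgn = ev(i, 1), amp = ev(i, 2), t0 = ev(i, 3), t1 = ev(i, 4),
                 stau = ev(i, 5);
    double v = 0.0;
    if (t >= t0) {
      if (stau <= 0.0) {
        v = (t <= t1) ? amp : 0.0;
      } else if (t <= t1) {
        v = amp * (1.0 - std::exp(-(t - t0) / stau));
      } else {
        const double peak = amp * (1.0 - std::exp(-(t1 - t0) / stau));
        v = peak * std::exp(-(t - t1) / stau);
      }
    }
    ext[tgt] += sgn * v;
  }
}

bool rhs(const Net& net, const arma::mat& ev, double t, const arma::vec& y,
         arma::vec& dy, arma::vec& F, std::vector<bool>* warm = nullptr) {
  arma::vec ext;
  externals_at(ev, t, ext);
  const double c5 = std::max(y[4], 0.0), cda = std::max(y[5], 0.0);
  arma::vec base = net.bias + ext + net.Ws * y.head(4);
  if (!solve_rates_cpp(net, base, F, warm)) return false;
  dy.set_size(6);
  for (int i = 0; i < 4; ++i) {
    const double c = (i == 1 || i == 3) ? cda : c5;
    const double ss = net.k[i] / (1.0 + std::exp(-net.slope[i] * (c - net.off[i])));
    dy[i] = (-y[i] + ss) / net.tau[i];
  }
  dy[4] = net.per[0] * F[0] / net.scl[0] - net.vmax[0] * c5 / (net.km[0] + c5);
  dy[5] = net.per[1] * F[1] / net.scl[1] - net.vmax[1] * cda / (net.km[1] + cda);
  return true;
}

Net unpack(const List& net) {
  Net n;
  n.gain = as<arma::vec>(net["gain"]);
  n.thr = as<arma::vec>(net["threshold"]);
  n.bias = as<arma::vec>(net["bias"]);
  n.Jf = as<arma::mat>(net["Jf"]);
  n.Ws = as<arma::mat>(net["Ws"]);
  n.tau = as<arma::vec>(net["slow_tau"]);
  n.k = as<arma::vec>(net["slow_k"]);
  n.slope = as<arma::vec>(net["slow_slope"]);
  n.off = as<arma::vec>(net["slow_offset"]);
  n.per = as<arma::vec>(net["rel_per"]);
  n.vmax = as<arma::vec>(net["rel_vmax"]);
  n.km = as<arma::vec>(net["rel_km"]);
  n.scl = as<arma::vec>(net["rel_scale"]);
  return n;
}

}  // namespace

// [[Rcpp::export]]
List cpp_solve_rates(List net, NumericVector slow_state, NumericVector ext) {
  Net n = unpack(net);
  arma::vec s = as<arma::vec>(slow_state);
  arma::vec base = n.bias + as<arma::vec>(ext) + n.Ws * s;
  arma::vec F;
  bool ok = solve_rates_cpp(n, base, F);
  return List::create(_["ok"] = ok,
                      _["rates"] = ok ? NumericVector(F.begin(), F.end())
                                      : NumericVector(5, NA_REAL));
}

// [[Rcpp::export]]
List cpp_integrate(List net, NumericMatrix events, NumericVector y0,
                   double dt, double horizon, int record_stride) {
  Net n = unpack(net);
  arma::mat ev = as<arma::mat>(events);
  arma::vec y = as<arma::vec>(y0);
  const int nstep = (int)std::round(horizon / dt);
  const int nrec = nstep / record_stride + 1;
  arma::mat states(nrec, 6), rates(nrec, 5);
  arma::vec times(nrec);
  arma::vec k1, k2, k3, k4, F, Frec;
  int irec = 0;
  std::string status = "ok";
  std::vector<bool> warm;

  for (int step = 0; step <= nstep; ++step) {
    const double t = step * dt;
    if (step % record_stride == 0) {
      arma::vec dy;
      if (!rhs(n, ev, t, y, dy, Frec, &warm)) { status = "rate_solver_failed"; break; }
      times[irec] = t;
      states.row(irec) = y.t();
      rates.row(irec) = Frec.t();
      ++irec;
    }
    if (step == nstep) break;
    bool ok = rhs(n, ev, t, y, k1, F, &warm) &&
              rhs(n, ev, t + 0.5 * dt, y + 0.5 * dt * k1, k2, F, &warm) &&
              rhs(n, ev, t + 0.5 * dt, y + 0.5 * dt * k2, k3, F, &warm) &&
              rhs(n, ev, t + dt, y + dt * k3, k4, F, &warm);
    if (!ok) { status = "rate_solver_failed"; break; }
    y += (dt / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (!y.is_finite()) { status = "nonfinite_state"; break; }
    for (int j = 4; j < 6; ++j) {
      if (y[j] < 0.0) {
        if (y[j] > -1e-9) y[j] = 0.0;
        else { status = "negative_concentration"; break; }
      }
    }
    if (status != "ok") break;
  }
  states.resize(irec, 6);
  rates.resize(irec, 5);
  times.resize(irec);
  return List::create(_["time"] = NumericVector(times.begin(), times.end()),
                      _["states"] = wrap(states), _["rates"] = wrap(rates),
                      _["status"] = status);
}
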