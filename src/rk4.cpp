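#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step classic RK4 integrator for the rate-model circuit.
// State layout: y = [s(1..nsyn), x(1..nsyn), u(1..nsyn), a(1..npop)].
// Rates are recomputed algebraically at every stage evaluation; plasticity
// pins (tau_r = 0 -> x == 1, tau_f = 0 -> u == U) are exact: the pinned
// coordinates carry zero derivative and keep their initial value.

static inline double stim_at(const double* col, double t) {
  int kind = (int)col[0];
  if (kind == 0) return col[1];                    // constant
  if (kind == 1) return t >= col[2] ? col[1] : 0;  // step(amp, onset)
  // square(mean, freq Hz, duty): active-phase amplitude mean/duty
  double period = 1000.0 / col[2];
  double phase = t - period * std::floor(t / period);
  return (phase / period) < col[3] ? col[1] / col[3] : 0.0;
}

struct Model {
  int npop, nsyn;
  const int* pre; const int* post;
  const double* g; const double* U;
  const double* tau_s; const double* tau_f; const double* tau_r;
  const double* sgn;
  const double* theta; const double* beta_t; // beta_tilde
  const int* adapt; const double* tau_a; const double* gbar_a;
  const double* stim; // 4 x npop column-major

  void rates(const double* y, double t, double* M) const {
    const double* s = y;
    const double* a = y + 3 * nsyn;
    for (int i = 0; i < npop; ++i) M[i] = stim_at(stim + 4 * i, t);
    for (int k = 0; k < nsyn; ++k) M[post[k]] += sgn[k] * g[k] * s[k];
    for (int i = 0; i < npop; ++i) {
      double d = M[i] - a[i] - theta[i];
      M[i] = d > 0 ? beta_t[i] * d : 0.0;
    }
  }

  void deriv(const double* y, double t, double* dy, double* M) const {
    rates(y, t, M);
    const double* s = y; const double* x = y + nsyn; const double* u = y + 2 * nsyn;
    const double* a = y + 3 * nsyn;
    double* ds = dy; double* dx = dy + nsyn; double* du = dy + 2 * nsyn;
    double* da = dy + 3 * nsyn;
    for (int k = 0; k < nsyn; ++k) {
      double Mj = M[pre[k]];
      double rel = u[k] * x[k] * Mj;
      ds[k] = -s[k] / tau_s[k] + rel;
      dx[k] = tau_r[k] > 0 ? (1.0 - x[k]) / tau_r[k] - rel : 0.0;
      du[k] = tau_f[k] > 0 ? (U[k] - u[k]) / tau_f[k] + U[k] * (1.0 - u[k]) * Mj
                           : 0.0;
    }
    for (int i = 0; i < npop; ++i)
      da[i] = adapt[i] ? (-a[i] + gbar_a[i] * M[i]) / tau_a[i] : 0.0;
  }
};

// [[Rcpp::export(name = ".sim_rk4")]]
List sim_rk4(IntegerVector pre, IntegerVector post, NumericVector g,
             NumericVector U, NumericVector tau_s, NumericVector tau_f,
             NumericVector tau_r, NumericVector sgn, NumericVector theta,
             NumericVector beta_t, IntegerVector adapt, NumericVector tau_a,
             NumericVector gbar_a, NumericMatrix stim, NumericVector y0,
             double t_end, double dt, int keep_every) {
  const int nsyn = pre.size();
  const int npop = theta.size();
  const int nvar = 3 * nsyn + npop;
  Model m;
  m.npop = npop; m.nsyn = nsyn;
  m.pre = pre.begin(); m.post = post.begin();
  m.g = g.begin(); m.U = U.begin();
  m.tau_s = tau_s.begin(); m.tau_f = tau_f.begin(); m.tau_r = tau_r.begin();
  m.sgn = sgn.begin(); m.theta = theta.begin(); m.beta_t = beta_t.begin();
  m.adapt = adapt.begin(); m.tau_a = tau_a.begin(); m.gbar_a = gbar_a.begin();
  m.stim = stim.begin();

  const int nsteps = (int)std::lround(t_end / dt);
  const int nrec = nsteps / keep_every + 1;

  NumericVector times(nrec);
  NumericMatrix rate_out(nrec, npop);
  NumericMatrix s_out(nrec, nsyn), x_out(nrec, nsyn), u_out(nrec, nsyn);
  NumericMatrix a_out(nrec, npop);

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(nvar), k2(nvar), k3(nvar), k4(nvar), tmp(nvar);
  std::vector<double> M(npop);

  int irec = 0;
  for (int step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    if (step % keep_every == 0) {
      m.rates(y.data(), t, M.data());
      times[irec] = t;
      for (int i = 0; i < npop; ++i) {
        rate_out(irec, i) = M[i];
        a_out(irec, i) = y[3 * nsyn + i];
      }
      for (int k = 0; k < nsyn; ++k) {
        s_out(irec, k) = y[k];
        x_out(irec, k) = y[nsyn + k];
        u_out(irec, k) = y[2 * nsyn + k];
      }
      ++irec;
    }
    if (step == nsteps) break;

    m.deriv(y.data(), t, k1.data(), M.data());
    for (int v = 0; v < nvar; ++v) tmp[v] = y[v] + 0.5 * dt * k1[v];
    m.deriv(tmp.data(), t + 0.5 * dt, k2.data(), M.data());
    for (int v = 0; v < nvar; ++v) tmp[v] = y[v] + 0.5 * dt * k2[v];
    m.deriv(tmp.data(), t + 0.5 * dt, k3.data(), M.data());
    for (int v = 0; v < nvar; ++v) tmp[v] = y[v] + dt * k3[v];
    m.deriv(tmp.data(), t + dt, k4.data(), M.data());
    for (int v = 0; v < nvar; ++v)
      y[v] += dt / 6.0 * (k1[v] + 2.0 * k2[v] + 2.0 * k3[v] + k4[v]);

    if (step % 1024 == 0) {
      for (int v = 0; v < nvar; ++v)
        if (!std::isfinite(y[v]))
          stop("non-finite state at t = %f (variable %d)", t + dt, v + 1);
    }
  }

  for (int v = 0; v < nvar; ++v)
    if (!std::isfinite(y[v]))
      stop("non-finite state at t = %f (variable %d)", t_end, v + 1);

  return List::create(_["time"] = times, _["rates"] = rate_out,
                      _["s"] = s_out, _["x"] = x_out, _["u"] = u_out,
                      _["a"] = a_out);
}
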