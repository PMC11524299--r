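#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Genotype-grouped logistic / SAD(1) likelihood core.
//
// Individuals are stored flattened: y and tt are concatenations of the
// per-individual observation and age vectors, off (length n+1, 0-based)
// delimits them.  cls[i] in {0,...,J-1} assigns individual i to a genotype
// class; cls[i] < 0 drops the individual (missing genotype at this marker).
//
// SAD(1): e_t = phi * e_{t-1} + eps_t, eps_t ~ N(0, nu2), e_0 = 0, with the
// lag index given by position in the individual's own grid.  Whitening the
// residual vector with the unit lower-bidiagonal inverse Cholesky factor
// gives log|Sigma| = T log nu2 and a quadratic form of the innovations, so
// each individual costs O(T).  When all individuals share one age grid the
// per-class mean curve is computed once per likelihood evaluation.

static const double BIG = 1e10;

struct Data {
  const double* y;
  const double* tt;
  const int* off;
  int n;
  bool shared;   // all individuals share an identical grid
  int T;         // grid length when shared
};

static Data make_data(const NumericVector& y, const NumericVector& tt,
                      const IntegerVector& off) {
  Data d;
  d.y = REAL(y);
  d.tt = REAL(tt);
  d.off = INTEGER(off);
  d.n = off.size() - 1;
  d.shared = true;
  d.T = d.n > 0 ? d.off[1] - d.off[0] : 0;
  for (int i = 1; i < d.n && d.shared; ++i) {
    if (d.off[i + 1] - d.off[i] != d.T) { d.shared = false; break; }
    for (int k = 0; k < d.T; ++k) {
      if (d.tt[d.off[i] + k] != d.tt[k]) { d.shared = false; break; }
    }
  }
  return d;
}

// Whitened residual cross-products: sfirst = sum of first-position r^2,
// s11/s01/s00 the lagged sums, Ttot the total observation count.
struct ResidStats {
  double sfirst, s11, s01, s00;
  int Ttot;
};

static ResidStats resid_stats(const Data& d, const int* cls,
                              const double* abr /* 3J raw a,b,r */, int J) {
  ResidStats st = {0.0, 0.0, 0.0, 0.0, 0};
  if (d.shared) {
    std::vector<double> mu(J * d.T);
    for (int j = 0; j < J; ++j) {
      double a = abr[3 * j], b = abr[3 * j + 1], r = abr[3 * j + 2];
      for (int k = 0; k < d.T; ++k) {
        mu[j * d.T + k] = a / (1.0 + b * std::exp(-r * d.tt[k]));
      }
    }
    for (int i = 0; i < d.n; ++i) {
      int j = cls[i];
      if (j < 0) continue;
      const double* yi = d.y + d.off[i];
      const double* mj = mu.data() + j * d.T;
      double rprev = yi[0] - mj[0];
      st.sfirst += rprev * rprev;
      for (int k = 1; k < d.T; ++k) {
        double res = yi[k] - mj[k];
        st.s11 += res * res;
        st.s01 += res * rprev;
        st.s00 += rprev * rprev;
        rprev = res;
      }
      st.Ttot += d.T;
    }
    return st;
  }
  for (int i = 0; i < d.n; ++i) {
    int j = cls[i];
    if (j < 0) continue;
    double a = abr[3 * j], b = abr[3 * j + 1], r = abr[3 * j + 2];
    double rprev = 0.0;
    for (int k = d.off[i]; k < d.off[i + 1]; ++k) {
      double mu = a / (1.0 + b * std::exp(-r * d.tt[k]));
      double res = d.y[k] - mu;
      if (k == d.off[i]) st.sfirst += res * res;
      else {
        st.s11 += res * res;
        st.s01 += res * rprev;
        st.s00 += rprev * rprev;
      }
      rprev = res;
      st.Ttot++;
    }
  }
  return st;
}

// Negative log-likelihood with (phi, nu2) profiled out in closed form.
// theta holds (log a_j, log b_j, log r_j) for each class j; phi is clamped
// to [-2, 2].
static double nll_profiled(const std::vector<double>& theta, const Data& d,
                           const int* cls, int J,
                           double* phi_out, double* nu2_out) {
  std::vector<double> abr(3 * J);
  for (int k = 0; k < 3 * J; ++k) {
    if (!std::isfinite(theta[k]) || theta[k] > 50.0 || theta[k] < -50.0)
      return BIG;
    abr[k] = std::exp(theta[k]);
  }
  ResidStats st = resid_stats(d, cls, abr.data(), J);
  if (st.Ttot == 0) return BIG;
  double phi = (st.s00 > 0.0) ? st.s01 / st.s00 : 0.0;
  if (phi > 2.0) phi = 2.0;
  if (phi < -2.0) phi = -2.0;
  double ss = st.sfirst + st.s11 - 2.0 * phi * st.s01 + phi * phi * st.s00;
  double nu2 = ss / st.Ttot;
  if (!(nu2 > 0.0) || !std::isfinite(nu2)) return BIG;
  if (phi_out) *phi_out = phi;
  if (nu2_out) *nu2_out = nu2;
  double nll = 0.5 * (st.Ttot * (std::log(2.0 * M_PI) + 1.0) +
                      st.Ttot * std::log(nu2));
  return std::isfinite(nll) ? nll : BIG;
}

// Plain Nelder-Mead simplex (reflection 1, expansion 2, contraction 0.5,
// shrink 0.5).
struct NMResult {
  std::vector<double> x;
  double fmin;
  int nev;
  bool converged;
};

template <typename F>
static NMResult nelder_mead(F f, const std::vector<double>& x0,
                            double step, int maxit, double reltol) {
  int p = (int)x0.size();
  int nv = p + 1;
  std::vector<std::vector<double> > vx(nv, x0);
  std::vector<double> fv(nv);
  for (int i = 1; i < nv; ++i) vx[i][i - 1] += step;
  int nev = 0;
  for (int i = 0; i < nv; ++i) { fv[i] = f(vx[i]); nev++; }
  std::vector<int> ord(nv);
  bool conv = false;
  while (nev < maxit) {
    for (int i = 0; i < nv; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return fv[a] < fv[b]; });
    int lo = ord[0], hi = ord[nv - 1], nh = ord[nv - 2];
    if (std::fabs(fv[hi] - fv[lo]) <=
        reltol * (std::fabs(fv[lo]) + reltol)) { conv = true; break; }
    std::vector<double> cen(p, 0.0);
    for (int i = 0; i < nv; ++i)
      if (i != hi) for (int k = 0; k < p; ++k) cen[k] += vx[i][k];
    for (int k = 0; k < p; ++k) cen[k] /= p;
    std::vector<double> xr(p), xe(p), xc(p);
    for (int k = 0; k < p; ++k) xr[k] = cen[k] + (cen[k] - vx[hi][k]);
    double fr = f(xr); nev++;
    if (fr < fv[lo]) {
      for (int k = 0; k < p; ++k) xe[k] = cen[k] + 2.0 * (cen[k] - vx[hi][k]);
      double fe = f(xe); nev++;
      if (fe < fr) { vx[hi] = xe; fv[hi] = fe; }
      else { vx[hi] = xr; fv[hi] = fr; }
    } else if (fr < fv[nh]) {
      vx[hi] = xr; fv[hi] = fr;
    } else {
      double fbase = std::min(fr, fv[hi]);
      const std::vector<double>& xbase = (fr < fv[hi]) ? xr : vx[hi];
      for (int k = 0; k < p; ++k) xc[k] = cen[k] + 0.5 * (xbase[k] - cen[k]);
      double fc = f(xc); nev++;
      if (fc < fbase) {
        vx[hi] = xc; fv[hi] = fc;
      } else {  // shrink toward best
        for (int i = 0; i < nv; ++i) {
          if (i == lo) continue;
          for (int k = 0; k < p; ++k)
            vx[i][k] = vx[lo][k] + 0.5 * (vx[i][k] - vx[lo][k]);
          fv[i] = f(vx[i]); nev++;
        }
      }
    }
  }
  int best = 0;
  for (int i = 1; i < nv; ++i) if (fv[i] < fv[best]) best = i;
  NMResult res;
  res.x = vx[best];
  res.fmin = fv[best];
  res.nev = nev;
  res.converged = conv;
  return res;
}

struct FitOut {
  std::vector<double> theta;
  double phi, nu2, loglik;
  bool converged;
};

static FitOut fit_groups(const Data& d, const int* cls, int J,
                         const std::vector<std::vector<double> >& starts,
                         int maxit, double reltol) {
  auto obj = [&](const std::vector<double>& th) {
    return nll_profiled(th, d, cls, J, NULL, NULL);
  };
  FitOut out;
  out.loglik = -std::numeric_limits<double>::infinity();
  out.converged = false;
  for (size_t s = 0; s < starts.size(); ++s) {
    NMResult nm = nelder_mead(obj, starts[s], 0.2, maxit, reltol);
    if (-nm.fmin > out.loglik) {
      out.theta = nm.x;
      out.loglik = -nm.fmin;
      out.converged = nm.converged;
    }
  }
  double phi = 0.0, nu2 = 1.0;
  nll_profiled(out.theta, d, cls, J, &phi, &nu2);
  out.phi = phi;
  out.nu2 = nu2;
  return out;
}

// [[Rcpp::export]]
double fm_loglik_cpp(NumericVector y, NumericVector tt, IntegerVector off,
                     IntegerVector cls, int J, NumericVector par,
                     double phi, double nu2) {
  if (!(nu2 > 0.0)) stop("innovation variance nu2 must be positive");
  if (par.size() != 3 * J) stop("par must have length 3*J (a, b, r per class)");
  Data d = make_data(y, tt, off);
  ResidStats st = resid_stats(d, INTEGER(cls), REAL(par), J);
  double ss = st.sfirst + st.s11 - 2.0 * phi * st.s01 + phi * phi * st.s00;
  return -0.5 * (st.Ttot * std::log(2.0 * M_PI) +
                 st.Ttot * std::log(nu2) + ss / nu2);
}

// [[Rcpp::export]]
List fm_fit_cpp(NumericVector y, NumericVector tt, IntegerVector off,
                IntegerVector cls, int J, NumericMatrix inits,
                int maxit = 2000, double reltol = 1e-8) {
  if (inits.ncol() != 3 * J) stop("inits must have 3*J columns");
  Data d = make_data(y, tt, off);
  std::vector<std::vector<double> > starts;
  for (int i = 0; i < inits.nrow(); ++i) {
    std::vector<double> s(3 * J);
    for (int k = 0; k < 3 * J; ++k) s[k] = inits(i, k);
    starts.push_back(s);
  }
  FitOut f = fit_groups(d, INTEGER(cls), J, starts, maxit, reltol);
  NumericVector th(3 * J), abr(3 * J);
  for (int k = 0; k < 3 * J; ++k) { th[k] = f.theta[k]; abr[k] = std::exp(f.theta[k]); }
  return List::create(_["par"] = abr, _["theta"] = th, _["phi"] = f.phi,
                      _["nu2"] = f.nu2, _["loglik"] = f.loglik,
                      _["converged"] = f.converged);
}

// Likelihood-ratio scan across markers.  cls is an m x n matrix of 0-based
// class codes (negative = drop individual at that marker), Jv the per-marker
// class count.  h0_init is a log-scale (a, b, r) start from a pooled fit;
// warm optionally holds per-marker log-scale H1 starts (m x 3*Jmax, NA pad)
// from a previous scan of the unpermuted data.  The H0 fit is shared across
// markers that drop no individuals (it does not depend on genotype).
// [[Rcpp::export]]
List fm_scan_cpp(NumericVector y, NumericVector tt, IntegerVector off,
                 IntegerMatrix cls, IntegerVector Jv,
                 NumericVector h0_init, Nullable<NumericMatrix> warm,
                 int nstart = 2, double jitter = 0.1,
                 int maxit = 1500, double reltol = 1e-8) {
  RNGScope scope;
  Data d = make_data(y, tt, off);
  int n = d.n, m = cls.nrow();
  if (cls.ncol() != n) stop("cls must be m x n");
  int Jmax = 0;
  for (int s = 0; s < m; ++s) if (Jv[s] > Jmax) Jmax = Jv[s];
  NumericVector logl0(m), logl1(m), lr(m), phi1(m), nu21(m);
  NumericMatrix par1(m, 3 * Jmax), par0(m, 3);
  std::fill(par1.begin(), par1.end(), NA_REAL);
  LogicalVector conv(m);
  NumericMatrix wm;
  bool have_warm = warm.isNotNull();
  if (have_warm) wm = NumericMatrix(warm);
  std::vector<int> cvec(n), c0(n);
  std::vector<double> b0(h0_init.begin(), h0_init.end());
  bool have_full_h0 = false;
  FitOut full_h0;

  for (int s = 0; s < m; ++s) {
    int J = Jv[s];
    bool complete = true;
    for (int i = 0; i < n; ++i) {
      cvec[i] = cls(s, i);
      if (cvec[i] < 0) complete = false;
      c0[i] = cvec[i] >= 0 ? 0 : -1;
    }

    // H0: one pooled class (cached across complete markers)
    FitOut f0;
    if (complete && have_full_h0) {
      f0 = full_h0;
    } else {
      std::vector<std::vector<double> > st0;
      st0.push_back(b0);
      for (int k = 1; k < nstart; ++k) {
        std::vector<double> bj = b0;
        for (size_t q = 0; q < bj.size(); ++q) bj[q] += R::rnorm(0.0, jitter);
        st0.push_back(bj);
      }
      f0 = fit_groups(d, c0.data(), 1, st0, maxit, reltol);
      if (complete) { full_h0 = f0; have_full_h0 = true; }
    }

    // H1: class-specific growth params, shared (phi, nu2)
    std::vector<std::vector<double> > st1;
    std::vector<double> rep0(3 * J);
    for (int j = 0; j < J; ++j)
      for (int k = 0; k < 3; ++k) rep0[3 * j + k] = f0.theta[k];
    st1.push_back(rep0);
    if (have_warm) {
      bool ok = true;
      std::vector<double> w(3 * J);
      for (int k = 0; k < 3 * J; ++k) {
        w[k] = wm(s, k);
        if (!std::isfinite(w[k])) { ok = false; break; }
      }
      if (ok) st1.push_back(w);
    }
    while ((int)st1.size() < nstart) {
      std::vector<double> bj = rep0;
      for (size_t q = 0; q < bj.size(); ++q) bj[q] += R::rnorm(0.0, jitter);
      st1.push_back(bj);
    }
    FitOut f1 = fit_groups(d, cvec.data(), J, st1, maxit, reltol);

    logl0[s] = f0.loglik;
    logl1[s] = f1.loglik;
    double diff = 2.0 * (f1.loglik - f0.loglik);
    lr[s] = diff > 0.0 ? diff : 0.0;
    phi1[s] = f1.phi;
    nu21[s] = f1.nu2;
    for (int k = 0; k < 3; ++k) par0(s, k) = std::exp(f0.theta[k]);
    for (int k = 0; k < 3 * J; ++k) par1(s, k) = std::exp(f1.theta[k]);
    conv[s] = f0.converged && f1.converged;
  }
  return List::create(_["logl0"] = logl0, _["logl1"] = logl1, _["lr"] = lr,
                      _["par0"] = par0, _["par1"] = par1, _["phi"] = phi1,
                      _["nu2"] = nu21, _["converged"] = conv);
}

// ---- Lotka-Volterra effect-dynamics RK4 kernels -------------------------
//
// One node's reduced ODE dz/dt = Q_s(z) + g(t), where Q_s is a Legendre
// expansion of the affinely mapped (and clamped) state and g(t) the summed
// regulator forcing.  Because g does not depend on the state, its values at
// all RK4 stage times are precomputed as a basis matrix Fb (rows = stage
// times t_0, t_0+h/2, t_0+h, ... shared between adjacent steps; columns =
// regulator basis functions), so each objective evaluation is one matvec
// plus a scalar RK4 sweep.  Stage layout: step k uses rows 2k, 2k+1, 2k+2.

static double q_legendre(double z, const double* th, int K,
                         double lo, double hi) {
  double x = 2.0 * (z - lo) / (hi - lo) - 1.0;
  if (x > 1.0) x = 1.0;
  if (x < -1.0) x = -1.0;
  double pkm1 = 1.0, pk = x, v = th[0];
  if (K >= 1) v += th[1] * x;
  for (int k = 1; k < K; ++k) {
    double pkp1 = ((2 * k + 1) * x * pk - k * pkm1) / (k + 1);
    v += th[k + 1] * pkp1;
    pkm1 = pk;
    pk = pkp1;
  }
  return v;
}

// Sum of squared deviations of the RK4-solved trajectory from obs; returns
// a large penalty if the trajectory leaves the finite range.
// [[Rcpp::export]]
double ode_rk4_sse_cpp(NumericVector th_self, NumericVector th_dep,
                       int K_ind, double lo, double hi,
                       NumericVector obs, NumericVector hsteps, int nsub,
                       Nullable<NumericMatrix> Fb_) {
  int T = obs.size();
  int S = (T - 1) * nsub;
  std::vector<double> g(2 * S + 1, 0.0);
  if (Fb_.isNotNull()) {
    NumericMatrix Fb(Fb_);
    if (Fb.nrow() != 2 * S + 1 || Fb.ncol() != th_dep.size())
      stop("forcing basis dimensions do not match");
    for (int j = 0; j < Fb.ncol(); ++j) {
      double c = th_dep[j];
      if (c == 0.0) continue;
      for (int i = 0; i < Fb.nrow(); ++i) g[i] += c * Fb(i, j);
    }
  }
  const double* th = REAL(th_self);
  int K = K_ind;
  double z = obs[0], sse = 0.0;
  int row = 0;
  for (int i = 1; i < T; ++i) {
    double h = hsteps[i - 1] / nsub;
    for (int s = 0; s < nsub; ++s) {
      double g1 = g[row], gm = g[row + 1], g2 = g[row + 2];
      double k1 = q_legendre(z, th, K, lo, hi) + g1;
      double k2 = q_legendre(z + 0.5 * h * k1, th, K, lo, hi) + gm;
      double k3 = q_legendre(z + 0.5 * h * k2, th, K, lo, hi) + gm;
      double k4 = q_legendre(z + h * k3, th, K, lo, hi) + g2;
      z += h / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      row += 2;
      if (!std::isfinite(z) || std::fabs(z) > 1e8) return 1e12;
    }
    double d = z - obs[i];
    sse += d * d;
  }
  return sse;
}

// Full trajectory plus the decomposition integrals, accumulated with the
// same RK4 stages (independent part) and the matching Simpson rule
// (state-free dependent parts), so independent + sum(dependent) equals the
// fitted net curve to rounding error.
// [[Rcpp::export]]
List ode_rk4_path_cpp(NumericVector th_self, NumericVector th_dep,
                      int K_ind, double lo, double hi,
                      double z0, int T, NumericVector hsteps, int nsub,
                      Nullable<NumericMatrix> Fb_, IntegerVector block_of) {
  int S = (T - 1) * nsub;
  int d = 0;
  for (int j = 0; j < block_of.size(); ++j)
    if (block_of[j] + 1 > d) d = block_of[j] + 1;
  NumericMatrix G(2 * S + 1, d > 0 ? d : 1);
  std::fill(G.begin(), G.end(), 0.0);
  if (Fb_.isNotNull() && d > 0) {
    NumericMatrix Fb(Fb_);
    for (int j = 0; j < Fb.ncol(); ++j) {
      double c = th_dep[j];
      int b = block_of[j];
      if (c == 0.0) continue;
      for (int i = 0; i < Fb.nrow(); ++i) G(i, b) += c * Fb(i, j);
    }
  }
  const double* th = REAL(th_self);
  NumericVector zout(T), Iout(T);
  NumericMatrix Dout(T, d > 0 ? d : 0);
  double z = z0, I = z0;
  std::vector<double> D(d, 0.0);
  zout[0] = z;
  Iout[0] = I;
  int row = 0;
  for (int i = 1; i < T; ++i) {
    double h = hsteps[i - 1] / nsub;
    for (int s = 0; s < nsub; ++s) {
      double gs1 = 0, gsm = 0, gs2 = 0;
      for (int b = 0; b < d; ++b) {
        gs1 += G(row, b); gsm += G(row + 1, b); gs2 += G(row + 2, b);
      }
      double q1 = q_legendre(z, th, K_ind, lo, hi);
      double k1 = q1 + gs1;
      double z2 = z + 0.5 * h * k1;
      double q2 = q_legendre(z2, th, K_ind, lo, hi);
      double k2 = q2 + gsm;
      double z3 = z + 0.5 * h * k2;
      double q3 = q_legendre(z3, th, K_ind, lo, hi);
      double k3 = q3 + gsm;
      double z4 = z + h * k3;
      double q4 = q_legendre(z4, th, K_ind, lo, hi);
      double k4 = q4 + gs2;
      z += h / 6.0 * (k1 + 2 * k2 + 2 * k3 + k4);
      I += h / 6.0 * (q1 + 2 * q2 + 2 * q3 + q4);
      for (int b = 0; b < d; ++b) {
        D[b] += h / 6.0 * (G(row, b) + 4.0 * G(row + 1, b) + G(row + 2, b));
      }
      row += 2;
    }
    zout[i] = z;
    Iout[i] = I;
    for (int b = 0; b < d; ++b) Dout(i, b) = D[b];
  }
  return List::create(_["z"] = zout, _["independent"] = Iout,
                      _["dependent"] = Dout);
}
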