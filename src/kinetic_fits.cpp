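#include <Rcpp.h>
using namespace Rcpp;

// Voxelwise fitting kernels for the DCE pipeline. Two hot loops live here:
// the three nested kinetic models (plasma-only / Patlak / extended Tofts)
// and the three-parameter Look-Locker T1 fit. Both use separable least
// squares: the linear amplitudes are profiled out in closed form and a
// bounded 1-D search (coarse log grid + golden section) handles the single
// nonlinear rate.

static const double GOLD = 0.6180339887498949;

// cumulative trapezoid of Cp on a uniform grid (dt in minutes)
static void cumtrapz(const std::vector<double>& cp, double dt,
                     std::vector<double>& out) {
  const int n = cp.size();
  out.assign(n, 0.0);
  for (int k = 1; k < n; ++k)
    out[k] = out[k - 1] + 0.5 * dt * (cp[k] + cp[k - 1]);
}

// convolution regressor int_0^t Cp(u) exp(-kep (t-u)) du, recursive trapezoid
static void expconv(const std::vector<double>& cp, double dt, double kep,
                    std::vector<double>& out) {
  const int n = cp.size();
  const double E = std::exp(-kep * dt);
  out.assign(n, 0.0);
  for (int k = 1; k < n; ++k)
    out[k] = E * out[k - 1] + 0.5 * dt * (cp[k] + E * cp[k - 1]);
}

// LS of y on a single regressor; nonnegative when nonneg is true
static double ls1(const double* x, const double* y, int n, double& beta,
                  bool nonneg) {
  double xx = 0.0, xy = 0.0, yy = 0.0;
  for (int i = 0; i < n; ++i) { xx += x[i] * x[i]; xy += x[i] * y[i]; yy += y[i] * y[i]; }
  beta = (xx > 0.0) ? xy / xx : 0.0;
  if (nonneg && beta < 0.0) beta = 0.0;
  double sse = yy - 2.0 * beta * xy + beta * beta * xx;
  return sse > 0.0 ? sse : 0.0;
}

static double nnls1(const double* x, const double* y, int n, double& beta) {
  return ls1(x, y, n, beta, true);
}

// LS of y on two regressors; active-set over the faces when nonneg
static double ls2(const double* x1, const double* x2, const double* y,
                  int n, double& b1, double& b2, bool nonneg) {
  double a11 = 0, a12 = 0, a22 = 0, c1 = 0, c2 = 0, yy = 0;
  for (int i = 0; i < n; ++i) {
    a11 += x1[i] * x1[i]; a12 += x1[i] * x2[i]; a22 += x2[i] * x2[i];
    c1  += x1[i] * y[i];  c2  += x2[i] * y[i];  yy  += y[i] * y[i];
  }
  double det = a11 * a22 - a12 * a12;
  if (det > 1e-300 * std::max(a11 * a22, 1.0)) {
    b1 = (c1 * a22 - c2 * a12) / det;
    b2 = (c2 * a11 - c1 * a12) / det;
    if (!nonneg || (b1 >= 0.0 && b2 >= 0.0)) {
      double sse = yy - b1 * c1 - b2 * c2;  // y'y - b'X'y at the LS solution
      return sse > 0.0 ? sse : 0.0;
    }
  } else if (!nonneg) {
    // singular design: fall back to the better single regressor
    double ba, bb;
    double ssea = ls1(x1, y, n, ba, false);
    double sseb = ls1(x2, y, n, bb, false);
    if (ssea <= sseb) { b1 = ba; b2 = 0.0; return ssea; }
    b1 = 0.0; b2 = bb; return sseb;
  }
  // constrained optimum lies on a boundary face
  double ba, bb;
  double ssea = nnls1(x1, y, n, ba);
  double sseb = nnls1(x2, y, n, bb);
  if (ssea <= sseb) { b1 = ba; b2 = 0.0; return ssea; }
  b1 = 0.0; b2 = bb; return sseb;
}

static double nnls2(const double* x1, const double* x2, const double* y,
                    int n, double& b1, double& b2) {
  return ls2(x1, x2, y, n, b1, b2, true);
}

struct ToftsEval {
  const std::vector<double>* cp;
  double dt;
  const double* y;   // already offset to the fit window
  int n;             // frames in the fit window
  int start;         // fit-window offset into the full grid
  bool nonneg;
  mutable std::vector<double> conv;
  double operator()(double log_kep, double& vp, double& kt) const {
    expconv(*cp, dt, std::exp(log_kep), conv);
    return ls2(cp->data() + start, conv.data() + start, y, n, vp, kt, nonneg);
  }
};

// golden-section minimisation of f over [lo, hi] (log-kep space)
template <typename F>
static double golden(const F& f, double lo, double hi, double tol,
                     double& xbest) {
  double a = lo, b = hi;
  double x1 = b - GOLD * (b - a), x2 = a + GOLD * (b - a);
  double d1, d2;
  double f1 = f(x1, d1, d2), f2 = f(x2, d1, d2);
  while (b - a > tol) {
    if (f1 <= f2) { b = x2; x2 = x1; f2 = f1; x1 = b - GOLD * (b - a); f1 = f(x1, d1, d2); }
    else          { a = x1; x1 = x2; f1 = f2; x2 = a + GOLD * (b - a); f2 = f(x2, d1, d2); }
  }
  xbest = 0.5 * (a + b);
  double v1, v2;
  return f(xbest, v1, v2);
}

//' @name pk_fit_batch
//' @title Batch nested kinetic-model fits (internal kernel)
//' @keywords internal
// [[Rcpp::export(name = ".pk_fit_batch")]]
NumericMatrix pk_fit_batch(NumericMatrix ct, NumericVector cp, double dt_min,
                           double kep_lo, double kep_hi, int n_grid = 25,
                           int start = 0) {
  // `start` (0-based) marks bolus arrival: regressors are built on the full
  // grid (the pre-arrival AIF is zero, so estimates are unaffected) but the
  // least-squares sums run over the post-arrival window only, keeping the
  // residual degrees of freedom consistent with the nested F-tests.
  const int n_t = ct.nrow(), n_vox = ct.ncol();
  if (cp.size() != n_t) stop("Cp and Ct grids differ in length");
  if (kep_lo <= 0 || kep_hi <= kep_lo) stop("invalid kep bounds");
  if (start < 0 || start >= n_t - 4) stop("invalid fit-window start");
  const int m = n_t - start;
  std::vector<double> cpv(cp.begin(), cp.end());
  std::vector<double> cum, conv;
  cumtrapz(cpv, dt_min, cum);

  const double llo = std::log(kep_lo), lhi = std::log(kep_hi);
  std::vector<double> lgrid(n_grid);
  for (int g = 0; g < n_grid; ++g)
    lgrid[g] = llo + (lhi - llo) * g / (n_grid - 1.0);

  // reported parameters come from bounded fits; the *_u columns are the
  // unconstrained nested linear SSEs used by the selection F-tests
  NumericMatrix out(n_vox, 12);
  colnames(out) = CharacterVector::create("vp1", "sse1", "vp2", "kt2", "sse2",
                                          "vp3", "kt3", "kep3", "sse3",
                                          "sse1u", "sse2u", "sse3u");
  std::vector<double> yv(n_t);
  const double* cpd = cpv.data() + start;
  const double* cumd = cum.data() + start;
  for (int v = 0; v < n_vox; ++v) {
    for (int i = 0; i < n_t; ++i) yv[i] = ct(i, v);
    const double* y = yv.data() + start;

    double vp1; double sse1 = nnls1(cpd, y, m, vp1);
    double vp2, kt2;
    double sse2 = nnls2(cpd, cumd, y, m, vp2, kt2);
    if (sse2 > sse1) { sse2 = sse1; vp2 = vp1; kt2 = 0.0; }
    double u1, u2;
    double sse1u = ls1(cpd, y, m, u1, false);
    double sse2u = ls2(cpd, cumd, y, m, u1, u2, false);
    if (sse2u > sse1u) sse2u = sse1u;

    // bounded separable fit: coarse scan brackets the kep minimum, golden
    // section refines it
    ToftsEval ev{&cpv, dt_min, y, m, start, true, conv};
    int gbest = 0; double fbest = R_PosInf, d1, d2;
    for (int g = 0; g < n_grid; ++g) {
      double f = ev(lgrid[g], d1, d2);
      if (f < fbest) { fbest = f; gbest = g; }
    }
    double a = lgrid[std::max(0, gbest - 1)];
    double b = lgrid[std::min(n_grid - 1, gbest + 1)];
    double lbest;
    golden(ev, a, b, 1e-7, lbest);
    double vp3, kt3;
    double sse3 = ev(lbest, vp3, kt3);
    double kep3 = std::exp(lbest);
    if (sse3 > sse2) {  // nesting guard: Tofts cannot beat Patlak here
      sse3 = sse2; vp3 = vp2; kt3 = kt2; kep3 = kep_lo;
    }

    ToftsEval evu{&cpv, dt_min, y, m, start, false, conv};
    gbest = 0; fbest = R_PosInf;
    for (int g = 0; g < n_grid; ++g) {
      double f = evu(lgrid[g], d1, d2);
      if (f < fbest) { fbest = f; gbest = g; }
    }
    a = lgrid[std::max(0, gbest - 1)];
    b = lgrid[std::min(n_grid - 1, gbest + 1)];
    golden(evu, a, b, 1e-7, lbest);
    double sse3u = evu(lbest, u1, u2);
    if (sse3u > sse2u) sse3u = sse2u;

    out(v, 0) = vp1; out(v, 1) = sse1;
    out(v, 2) = vp2; out(v, 3) = kt2; out(v, 4) = sse2;
    out(v, 5) = vp3; out(v, 6) = kt3; out(v, 7) = kep3; out(v, 8) = sse3;
    out(v, 9) = sse1u; out(v, 10) = sse2u; out(v, 11) = sse3u;
  }
  return out;
}

//' @name forward_tofts_conv
//' @title Exponential convolution regressor (internal kernel)
//' @keywords internal
// [[Rcpp::export(name = ".tofts_conv")]]
NumericVector forward_tofts_conv(NumericVector cp, double dt_min, double kep) {
  std::vector<double> cpv(cp.begin(), cp.end()), out;
  expconv(cpv, dt_min, kep, out);
  return wrap(out);
}

//' @name cum_trapz
//' @title Cumulative trapezoid (internal kernel)
//' @keywords internal
// [[Rcpp::export(name = ".cum_trapz")]]
NumericVector cum_trapz(NumericVector x, double dt) {
  std::vector<double> xv(x.begin(), x.end()), out;
  cumtrapz(xv, dt, out);
  return wrap(out);
}

struct LLEval {
  const double* ti;
  const double* s;     // signed signal
  int n;
  // profile A, B out of S = A - B exp(-TI/T1star); returns SSE
  double operator()(double log_t1s, double& A, double& B) const {
    double t1s = std::exp(log_t1s);
    double sx = 0, sxx = 0, sy = 0, sxy = 0, syy = 0;
    for (int i = 0; i < n; ++i) {
      double x = std::exp(-ti[i] / t1s);
      sx += x; sxx += x * x; sy += s[i]; sxy += x * s[i]; syy += s[i] * s[i];
    }
    double det = n * sxx - sx * sx;
    if (det <= 1e-30) { A = sy / n; B = 0.0; }
    else {
      // LS for y = A - B x
      A = (sy * sxx - sx * (sxy)) / det;
      B = -(n * sxy - sx * sy) / det;
    }
    double sse = 0;
    for (int i = 0; i < n; ++i) {
      double r = s[i] - (A - B * std::exp(-ti[i] / t1s));
      sse += r * r;
    }
    return sse;
  }
};

//' @name ll_fit_batch
//' @title Batch three-parameter Look-Locker fits (internal kernel)
//' @keywords internal
// [[Rcpp::export(name = ".ll_fit_batch")]]
NumericMatrix ll_fit_batch(NumericMatrix sig, NumericVector ti,
                           double t1s_lo = 0.02, double t1s_hi = 12.0) {
  const int n_ti = sig.nrow(), n_vox = sig.ncol();
  if (ti.size() != n_ti) stop("inversion-time grid does not match series");
  NumericMatrix out(n_vox, 6);
  colnames(out) = CharacterVector::create("A", "B", "t1_star", "t1", "sse",
                                          "converged");
  const double llo = std::log(t1s_lo), lhi = std::log(t1s_hi);
  std::vector<double> sv(n_ti);
  std::vector<int> ord(n_ti);
  for (int v = 0; v < n_vox; ++v) {
    // magnitude data: restore inversion polarity by searching the sign-flip
    // index around the signal minimum
    int imin = 0; double smin = R_PosInf; double smax = 0;
    for (int i = 0; i < n_ti; ++i) {
      double a = std::fabs(sig(i, v));
      if (a < smin) { smin = a; imin = i; }
      if (a > smax) smax = a;
    }
    if (smax <= 0.0) {  // all-zero voxel: undefined
      out(v, 0) = NA_REAL; out(v, 1) = NA_REAL; out(v, 2) = NA_REAL;
      out(v, 3) = NA_REAL; out(v, 4) = NA_REAL; out(v, 5) = 0;
      continue;
    }
    double best_sse = R_PosInf, bA = 0, bB = 0, bt1s = NA_REAL;
    for (int flip = std::max(0, imin - 1); flip <= std::min(n_ti, imin + 2); ++flip) {
      // samples with index < flip are negated
      for (int i = 0; i < n_ti; ++i)
        sv[i] = (i < flip) ? -sig(i, v) : sig(i, v);
      LLEval ev{REAL(ti), sv.data(), n_ti};
      // coarse scan + golden
      const int ng = 20;
      int gb = 0; double fb = R_PosInf, dA, dB;
      for (int g = 0; g < ng; ++g) {
        double lg = llo + (lhi - llo) * g / (ng - 1.0);
        double f = ev(lg, dA, dB);
        if (f < fb) { fb = f; gb = g; }
      }
      double a = llo + (lhi - llo) * std::max(0, gb - 1) / (ng - 1.0);
      double b = llo + (lhi - llo) * std::min(ng - 1, gb + 1) / (ng - 1.0);
      double lb;
      golden(ev, a, b, 1e-8, lb);
      double A, B;
      double sse = ev(lb, A, B);
      if (sse < best_sse) { best_sse = sse; bA = A; bB = B; bt1s = std::exp(lb); }
    }
    bool ok = (bA > 1e-12) && (bB / bA > 1.0 + 1e-9);
    out(v, 0) = bA; out(v, 1) = bB; out(v, 2) = bt1s;
    out(v, 3) = ok ? bt1s * (bB / bA - 1.0) : NA_REAL;
    out(v, 4) = best_sse;
    out(v, 5) = ok ? 1 : 0;
  }
  return out;
}
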