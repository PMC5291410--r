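#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sigmoid regulation-expression kinetics: phi(u) = (u/sqrt(u^2+1) + 1)/2.
static inline double phi(double u) {
  return 0.5 * (u / std::sqrt(u * u + 1.0) + 1.0);
}

// Linear interpolation of external regulator profiles in time.
// vals is a K x n x M array (column-major); out is n x M.
static void interp_ext(double t, const NumericVector& knots,
                       const NumericVector& vals, int n, int M,
                       std::vector<double>& out) {
  const int K = knots.size();
  if (K == 1) {
    for (int m = 0; m < M; ++m)
      for (int i = 0; i < n; ++i) out[i + n * m] = vals[i + n * m];
    return;
  }
  // clamp to span ends; callers guarantee t within span up to round-off
  int k = 0;
  if (t <= knots[0]) {
    k = 0;
  } else if (t >= knots[K - 1]) {
    k = K - 2;
  } else {
    int lo = 0, hi = K - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (knots[mid] <= t) lo = mid; else hi = mid;
    }
    k = lo;
  }
  double t0 = knots[k], t1 = knots[k + 1];
  double w = (t1 > t0) ? (t - t0) / (t1 - t0) : 0.0;
  if (w < 0.0) w = 0.0;
  if (w > 1.0) w = 1.0;
  for (int m = 0; m < M; ++m)
    for (int i = 0; i < n; ++i) {
      double v0 = vals[k + K * (i + n * m)];
      double v1 = vals[k + 1 + K * (i + n * m)];
      out[i + n * m] = v0 + w * (v1 - v0);
    }
}

// Circuit RHS: dy[i,a] = prod * R[a] * phi(u) + D[a]*(y[i-1,a]+y[i+1,a]-2y[i,a])
//              - lam[a]*y[i,a], zero-flux boundaries (mirrored ghost value).
// u = sum_b W[a,b] y[i,b] + sum_m E[a,m] ext[i,m] + h[a].
struct CircuitRHS {
  int n, G, M;
  const NumericVector R, D, lam, h;
  const NumericMatrix W, E;
  const NumericVector ext_t, ext_v;
  bool production;
  std::vector<double> ext;  // scratch n x M

  CircuitRHS(int n_, int G_, int M_, NumericVector R_, NumericVector D_,
             NumericVector lam_, NumericMatrix W_, NumericMatrix E_,
             NumericVector h_, NumericVector ext_t_, NumericVector ext_v_,
             bool production_)
      : n(n_), G(G_), M(M_), R(R_), D(D_), lam(lam_), h(h_), W(W_), E(E_),
        ext_t(ext_t_), ext_v(ext_v_), production(production_),
        ext(n_ * std::max(M_, 1)) {}

  void operator()(double t, const std::vector<double>& y,
                  std::vector<double>& dy) {
    if (M > 0) interp_ext(t, ext_t, ext_v, n, M, ext);
    for (int a = 0; a < G; ++a) {
      for (int i = 0; i < n; ++i) {
        double u = h[a];
        for (int b = 0; b < G; ++b) u += W(a, b) * y[i + n * b];
        for (int m = 0; m < M; ++m) u += E(a, m) * ext[i + n * m];
        double g = y[i + n * a];
        double gm = (i > 0) ? y[i - 1 + n * a] : g;
        double gp = (i < n - 1) ? y[i + 1 + n * a] : g;
        double d = production ? R[a] * phi(u) : 0.0;
        d += D[a] * (gm + gp - 2.0 * g) - lam[a] * g;
        dy[i + n * a] = d;
      }
    }
  }
};

// Cash-Karp embedded Runge-Kutta 4(5) tableau.
static const double CK_A[6] = {0.0, 1.0 / 5, 3.0 / 10, 3.0 / 5, 1.0, 7.0 / 8};
static const double CK_B[6][5] = {
    {0, 0, 0, 0, 0},
    {1.0 / 5, 0, 0, 0, 0},
    {3.0 / 40, 9.0 / 40, 0, 0, 0},
    {3.0 / 10, -9.0 / 10, 6.0 / 5, 0, 0},
    {-11.0 / 54, 5.0 / 2, -70.0 / 27, 35.0 / 27, 0},
    {1631.0 / 55296, 175.0 / 512, 575.0 / 13824, 44275.0 / 110592,
     253.0 / 4096}};
static const double CK_C[6] = {37.0 / 378, 0, 250.0 / 621, 125.0 / 594, 0,
                               512.0 / 1771};
static const double CK_DC[6] = {
    37.0 / 378 - 2825.0 / 27648, 0.0, 250.0 / 621 - 18575.0 / 48384,
    125.0 / 594 - 13525.0 / 55296, -277.0 / 14336, 512.0 / 1771 - 0.25};

// Integrate with adaptive Cash-Karp steps from t0, landing exactly on each
// entry of sample_times (strictly increasing, all > t0). Returns the states
// at the sample times plus a numerical-stability flag.
// [[Rcpp::export(name = ".ck_integrate")]]
List ck_integrate(NumericMatrix y0, double t0, NumericVector sample_times,
                  NumericVector R, NumericVector D, NumericVector lam,
                  NumericMatrix W, NumericMatrix E, NumericVector h,
                  NumericVector ext_t, NumericVector ext_v, bool production,
                  double rtol, double atol, double hinit, double hmin,
                  double max_steps_arg = -1) {
  const int n = y0.nrow(), G = y0.ncol(), M = E.ncol();
  const int ns = sample_times.size();
  const int len = n * G;
  CircuitRHS f(n, G, M, R, D, lam, W, E, h, ext_t, ext_v, production);

  std::vector<double> y(len), ytmp(len), yerr(len), ynew(len);
  std::vector<std::vector<double> > k(6, std::vector<double>(len));
  for (int j = 0; j < len; ++j) y[j] = y0[j];

  NumericVector out(len * ns, NA_REAL);
  out.attr("dim") = IntegerVector::create(n, G, ns);

  double t = t0;
  double tend = sample_times[ns - 1];
  double hstep = (hinit > 0) ? hinit : (tend - t0) / 100.0;
  if (hstep <= 0) hstep = 1e-3;
  double hfloor = (hmin > 0) ? hmin : 1e-12 * std::max(1.0, tend - t0);
  bool ok = true;
  long nsteps = 0;
  const long max_steps =
      (max_steps_arg > 0) ? (long)max_steps_arg : 2000000L;

  for (int s = 0; s < ns && ok; ++s) {
    double ts = sample_times[s];
    while (t < ts) {
      if (++nsteps > max_steps) { ok = false; break; }
      double hh = std::min(hstep, ts - t);
      bool land = (hh >= ts - t - 1e-14 * std::max(1.0, std::fabs(ts)));
      if (land) hh = ts - t;
      // stages
      f(t, y, k[0]);
      for (int st = 1; st < 6; ++st) {
        for (int j = 0; j < len; ++j) {
          double acc = y[j];
          for (int q = 0; q < st; ++q) acc += hh * CK_B[st][q] * k[q][j];
          ytmp[j] = acc;
        }
        f(t + CK_A[st] * hh, ytmp, k[st]);
      }
      double errmax = 0.0;
      bool finite = true;
      for (int j = 0; j < len; ++j) {
        double dy5 = 0.0, de = 0.0;
        for (int st = 0; st < 6; ++st) {
          dy5 += CK_C[st] * k[st][j];
          de += CK_DC[st] * k[st][j];
        }
        ynew[j] = y[j] + hh * dy5;
        yerr[j] = hh * de;
        if (!std::isfinite(ynew[j])) finite = false;
        double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(ynew[j]));
        double e = std::fabs(yerr[j]) / sc;
        if (e > errmax) errmax = e;
      }
      if (!finite || !std::isfinite(errmax)) {
        // halve and retry; give up at the floor
        hstep = hh * 0.1;
        if (hstep < hfloor) { ok = false; break; }
        continue;
      }
      if (errmax <= 1.0) {
        t = land ? ts : t + hh;
        y.swap(ynew);
        double fac = (errmax > 0) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
        if (fac > 5.0) fac = 5.0;
        if (fac < 0.2) fac = 0.2;
        hstep = hh * fac;
        if (hstep < hfloor) hstep = hfloor;
      } else {
        double fac = 0.9 * std::pow(errmax, -0.25);
        if (fac < 0.1) fac = 0.1;
        hstep = hh * fac;
        if (hstep < hfloor) { ok = false; break; }
      }
    }
    if (ok) {
      for (int j = 0; j < len; ++j) out[j + len * s] = y[j];
    }
  }

  return List::create(_["states"] = out, _["ok"] = ok,
                      _["nsteps"] = (double)nsteps, _["t_end"] = t);
}
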