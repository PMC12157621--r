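#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// EM for K-component mixtures. One function per family; both return the final
// parameter set, the log-likelihood trace and convergence/degeneracy flags.
// Densities are inlined and responsibilities kept internal, so the hot path
// (nested bootstrap refits) never allocates an n x K matrix on the R side.

static const double LOG_SQRT_2PI = 0.9189385332046727;

// [[Rcpp::export]]
List em_normal_cpp(NumericVector x, NumericVector w0, NumericVector mu0,
                   NumericVector sd0, double tol, int max_iter, double sd_floor) {
  const int n = x.size(), K = w0.size();
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sd(sd0.begin(), sd0.end());
  std::vector<double> resp(static_cast<size_t>(n) * K);
  std::vector<double> lw(K), lc(K), inv2(K), lp(K);
  std::vector<double> trace;
  trace.reserve(64);
  double ll = R_NegInf, ll_old = R_NegInf;
  bool converged = false, degenerate = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    for (int k = 0; k < K; ++k) {
      lw[k] = std::log(w[k]);
      lc[k] = -std::log(sd[k]) - LOG_SQRT_2PI;
      inv2[k] = 0.5 / (sd[k] * sd[k]);
    }
    ll = 0.0;
    if (K == 2) {
      // logistic form: one exp per observation
      const double lw0 = lw[0] + lc[0], lw1 = lw[1] + lc[1];
      const double m0 = mu[0], m1 = mu[1], i0 = inv2[0], i1 = inv2[1];
      double* r0 = &resp[0];
      double* r1 = &resp[static_cast<size_t>(n)];
      for (int i = 0; i < n; ++i) {
        double d0 = x[i] - m0, d1 = x[i] - m1;
        double lp0 = lw0 - d0 * d0 * i0;
        double lp1 = lw1 - d1 * d1 * i1;
        if (lp0 >= lp1) {
          double e = std::exp(lp1 - lp0);
          ll += lp0 + std::log1p(e);
          double r = e / (1.0 + e);
          r0[i] = 1.0 - r;
          r1[i] = r;
        } else {
          double e = std::exp(lp0 - lp1);
          ll += lp1 + std::log1p(e);
          double r = e / (1.0 + e);
          r0[i] = r;
          r1[i] = 1.0 - r;
        }
      }
    } else {
      for (int i = 0; i < n; ++i) {
        double m = R_NegInf;
        for (int k = 0; k < K; ++k) {
          double d = x[i] - mu[k];
          lp[k] = lw[k] + lc[k] - d * d * inv2[k];
          if (lp[k] > m) m = lp[k];
        }
        double s = 0.0;
        for (int k = 0; k < K; ++k) {
          double e = std::exp(lp[k] - m);
          resp[static_cast<size_t>(n) * k + i] = e;
          s += e;
        }
        double inv_s = 1.0 / s;
        for (int k = 0; k < K; ++k) resp[static_cast<size_t>(n) * k + i] *= inv_s;
        ll += m + std::log(s);
      }
    }
    trace.push_back(ll);
    if (iter > 1 && std::fabs(ll - ll_old) <= tol * (std::fabs(ll_old) + 1e-300)) {
      converged = true;
      break;
    }
    ll_old = ll;
    for (int k = 0; k < K; ++k) {
      const double* r = &resp[static_cast<size_t>(n) * k];
      double sw = 0.0, sm = 0.0;
      for (int i = 0; i < n; ++i) { sw += r[i]; sm += r[i] * x[i]; }
      if (sw < 1e-4 * n) { degenerate = true; break; }
      double m = sm / sw, sv = 0.0;
      for (int i = 0; i < n; ++i) { double d = x[i] - m; sv += r[i] * d * d; }
      double s = std::sqrt(sv / sw);
      if (s < sd_floor) { degenerate = true; break; }
      w[k] = sw / n; mu[k] = m; sd[k] = s;
    }
    if (degenerate) break;
  }
  if (iter > max_iter) iter = max_iter;

  return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                      _["p1"] = NumericVector(mu.begin(), mu.end()),
                      _["p2"] = NumericVector(sd.begin(), sd.end()),
                      _["loglik"] = ll,
                      _["n_iter"] = iter,
                      _["converged"] = converged,
                      _["degenerate"] = degenerate,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}

// Weighted Weibull MLE via safeguarded Newton on the profile shape equation
//   g(k) = sum(r * x^k * log x)/sum(r * x^k) - 1/k - sum(r * log x)/sum(r) = 0
// g is strictly increasing in k, so Newton steps fall back to bisection on a
// maintained bracket. Values are rescaled by max(x) to avoid overflow.
static bool weibull_wmle(const double* lx, const double* r, int n,
                         double& shape, double& scale) {
  const double klo = 1e-3, khi = 1e3;
  double lxmax = R_NegInf, sw = 0.0, slx = 0.0;
  for (int i = 0; i < n; ++i) {
    if (lx[i] > lxmax) lxmax = lx[i];
    sw += r[i];
    slx += r[i] * lx[i];
  }
  if (sw <= 0.0 || !R_FINITE(lxmax)) return false;
  const double C = slx / sw;

  double k = (shape > klo && shape < khi) ? shape : 1.0;
  double lo = klo, hi = khi;
  double g = 0.0;
  bool have_root = false;
  for (int it = 0; it < 100; ++it) {
    double S0 = 0.0, S1 = 0.0, S2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double yk = std::exp(k * (lx[i] - lxmax));
      double t = r[i] * yk;
      S0 += t; S1 += t * lx[i]; S2 += t * lx[i] * lx[i];
    }
    if (S0 <= 0.0) return false;
    double A = S1 / S0;
    g = A - 1.0 / k - C;
    if (std::fabs(g) < 1e-12) { have_root = true; break; }
    if (g > 0) hi = k; else lo = k;
    double gp = (S2 / S0 - A * A) + 1.0 / (k * k);
    double knew = k - g / gp;
    if (!(knew > lo && knew < hi)) knew = 0.5 * (lo + hi);
    if (std::fabs(knew - k) < 1e-12 * k) { k = knew; have_root = true; break; }
    k = knew;
  }
  if (!have_root && std::fabs(g) > 1e-6) {
    // no interior root: shape pinned at a bound means a degenerate component
    if (hi >= khi - 1e-9 || lo <= klo + 1e-9) return false;
  }
  shape = k;
  // scale^k = sum(r x^k)/sum(r) = exp(k*lxmax) * S0/sw (S0 at final k)
  double S0f = 0.0;
  for (int i = 0; i < n; ++i) S0f += r[i] * std::exp(k * (lx[i] - lxmax));
  scale = std::exp(lxmax + std::log(S0f / sw) / k);
  return R_FINITE(shape) && R_FINITE(scale) && shape > 0 && scale > 0;
}

// [[Rcpp::export]]
List em_weibull_cpp(NumericVector x, NumericVector w0, NumericVector shape0,
                    NumericVector scale0, double tol, int max_iter) {
  const int n = x.size(), K = w0.size();
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> sh(shape0.begin(), shape0.end());
  std::vector<double> sc(scale0.begin(), scale0.end());
  std::vector<double> resp(static_cast<size_t>(n) * K);
  std::vector<double> lx(n);
  for (int i = 0; i < n; ++i) lx[i] = std::log(x[i]);
  std::vector<double> lp(K), cons(K), km1(K), lsc(K);
  std::vector<double> trace;
  trace.reserve(64);
  double ll = R_NegInf, ll_old = R_NegInf;
  bool converged = false, degenerate = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    for (int k = 0; k < K; ++k) {
      lsc[k] = std::log(sc[k]);
      cons[k] = std::log(w[k]) + std::log(sh[k]) - sh[k] * lsc[k];
      km1[k] = sh[k] - 1.0;
    }
    ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) {
        // log w + log dweibull: c + (k-1) log x - (x/scale)^k
        lp[k] = cons[k] + km1[k] * lx[i] - std::exp(sh[k] * (lx[i] - lsc[k]));
        if (lp[k] > m) m = lp[k];
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        double e = std::exp(lp[k] - m);
        resp[static_cast<size_t>(n) * k + i] = e;
        s += e;
      }
      double inv_s = 1.0 / s;
      for (int k = 0; k < K; ++k) resp[static_cast<size_t>(n) * k + i] *= inv_s;
      ll += m + std::log(s);
    }
    trace.push_back(ll);
    if (iter > 1 && std::fabs(ll - ll_old) <= tol * (std::fabs(ll_old) + 1e-300)) {
      converged = true;
      break;
    }
    ll_old = ll;
    for (int k = 0; k < K; ++k) {
      const double* r = &resp[static_cast<size_t>(n) * k];
      double sw = 0.0;
      for (int i = 0; i < n; ++i) sw += r[i];
      if (sw < 1e-4 * n) { degenerate = true; break; }
      if (!weibull_wmle(&lx[0], r, n, sh[k], sc[k])) { degenerate = true; break; }
      w[k] = sw / n;
    }
    if (degenerate) break;
  }
  if (iter > max_iter) iter = max_iter;

  return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                      _["p1"] = NumericVector(sh.begin(), sh.end()),
                      _["p2"] = NumericVector(sc.begin(), sc.end()),
                      _["loglik"] = ll,
                      _["n_iter"] = iter,
                      _["converged"] = converged,
                      _["degenerate"] = degenerate,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}

// [[Rcpp::export]]
List weibull_wmle_cpp(NumericVector x, NumericVector r, double shape_init) {
  const int n = x.size();
  std::vector<double> lx(n);
  for (int i = 0; i < n; ++i) lx[i] = std::log(x[i]);
  double shape = shape_init, scale = 1.0;
  bool ok = weibull_wmle(&lx[0], &r[0], n, shape, scale);
  return List::create(_["shape"] = shape, _["scale"] = scale, _["ok"] = ok);
}
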