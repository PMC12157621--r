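#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Hartigan-Hartigan dip statistic:
//   dip = min over unimodal CDFs G of sup_x |Fn(x) - G(x)|
//
// Computed by bisection on t with an exact feasibility check. A unimodal G
// within sup-distance t of the ECDF exists iff for some placement of the mode
// between adjacent distinct order statistics (split s) there are values
// g_1..g_s (convex part) and h_{s+1}..h_m (concave part), nondecreasing
// across the junction, inside the band
//   l_i = max(b_i - t, 0),  u_i = min(a_i + t, 1)
// where a_i / b_i are the ECDF levels just below / at distinct value v_i.
//
// Convex-side feasibility and the minimal attainable junction value use a
// support-line argument: a convex nondecreasing g with l <= g <= u exists and
// has minimal endpoint
//   gmin_s = max(0, max_{i<=s} [ l_i + sig_i * (v_s - v_i) ])
// where sig_i = max(0, max_{j<i} (l_i - u_j)/(v_i - v_j)) is the smallest
// admissible support-line slope at obstacle i; the side is feasible iff each
// such line stays <= u at every later point of the prefix. The concave side
// is the same problem after the point reflection (v, y) -> (-v, -y).

struct SideResult {
  std::vector<double> gmin;   // gmin[s], s = 1..m (index 0 unused)
  std::vector<int> ok_upto;   // largest prefix length that is feasible
  int max_ok;
};

static void side_check(const std::vector<double>& v, const std::vector<double>& l,
                       const std::vector<double>& u, std::vector<double>& sig,
                       std::vector<double>& gmin, int& max_ok) {
  const int m = v.size();
  sig.assign(m, 0.0);
  gmin.assign(m + 1, 0.0);
  max_ok = m;
  for (int i = 0; i < m; ++i) {
    double s = 0.0;
    for (int j = 0; j < i; ++j) {
      double cand = (l[i] - u[j]) / (v[i] - v[j]);
      if (cand > s) s = cand;
    }
    sig[i] = s;
  }
  for (int s = 0; s < m; ++s) {
    // lines evaluated at v_s; prefix s+1 feasible iff no line exceeds u_s here
    double mx = -1e300;
    for (int i = 0; i <= s; ++i) {
      double val = l[i] + sig[i] * (v[s] - v[i]);
      if (val > mx) mx = val;
    }
    if (mx > u[s] + 1e-12 && s + 1 <= max_ok) { max_ok = s; }
    gmin[s + 1] = mx;
  }
}

static bool feasible(const std::vector<double>& v, const std::vector<double>& a,
                     const std::vector<double>& b, double t,
                     std::vector<double>& sig, std::vector<double>& gmin,
                     std::vector<double>& rv, std::vector<double>& rl,
                     std::vector<double>& ru, std::vector<double>& rsig,
                     std::vector<double>& rgmin, std::vector<double>& l,
                     std::vector<double>& u) {
  const int m = v.size();
  l.resize(m); u.resize(m);
  for (int i = 0; i < m; ++i) {
    l[i] = std::max(b[i] - t, 0.0);
    u[i] = std::min(a[i] + t, 1.0);
    if (l[i] > u[i] + 1e-12) return false;   // band empty (t < 1/(2n))
  }
  int ok_left;
  side_check(v, l, u, sig, gmin, ok_left);

  // reflected problem for the concave side: suffix of length k maps to prefix
  // of length k of the reflected arrays; hmax(suffix start s+1) = -rgmin[k]
  rv.resize(m); rl.resize(m); ru.resize(m);
  for (int i = 0; i < m; ++i) {
    rv[i] = -v[m - 1 - i];
    rl[i] = -u[m - 1 - i];   // reflected lower = -(original upper)
    ru[i] = -l[m - 1 - i];
  }
  int ok_right;
  side_check(rv, rl, ru, rsig, rgmin, ok_right);

  for (int s = 0; s <= m; ++s) {
    if (s > ok_left) break;
    int k = m - s;                      // concave suffix length
    if (k > ok_right) continue;
    double left_end = (s == 0) ? 0.0 : gmin[s];
    double right_start = (k == 0) ? 1.0 : -rgmin[k];
    if (left_end <= right_start + 1e-12) return true;
  }
  return false;
}

// [[Rcpp::export]]
double dip_cpp(NumericVector xs) {
  const int n = xs.size();
  if (n < 1) stop("empty sample");
  std::vector<double> v, a, b;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && xs[j + 1] == xs[i]) ++j;
    v.push_back(xs[i]);
    a.push_back(static_cast<double>(i) / n);
    b.push_back(static_cast<double>(j + 1) / n);
    i = j + 1;
  }
  const int m = v.size();
  if (m == 1) return 0.5;

  std::vector<double> sig, gmin, rv, rl, ru, rsig, rgmin, l, u;
  double lo = 0.5 / n, hi = 0.5;
  if (feasible(v, a, b, lo, sig, gmin, rv, rl, ru, rsig, rgmin, l, u)) return lo;
  for (int it = 0; it < 60 && hi - lo > 1e-13; ++it) {
    double mid = 0.5 * (lo + hi);
    if (feasible(v, a, b, mid, sig, gmin, rv, rl, ru, rsig, rgmin, l, u))
      hi = mid;
    else
      lo = mid;
  }
  return hi;
}
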