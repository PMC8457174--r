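#include <Rcpp.h>
using namespace Rcpp;

// ---- Gauss-Legendre nodes on [-1,1], computed once by Newton iteration ----
static const int GLN = 32;
static double gl_x[GLN], gl_w[GLN];
static bool gl_ready = false;

static void gl_init() {
  if (gl_ready) return;
  int m = (GLN + 1) / 2;
  for (int i = 0; i < m; ++i) {
    double x = std::cos(M_PI * (i + 0.75) / (GLN + 0.5));
    double pp = 0.0;
    for (int it = 0; it < 100; ++it) {
      double p0 = 1.0, p1 = 0.0;
      for (int j = 0; j < GLN; ++j) {
        double p2 = p1; p1 = p0;
        p0 = ((2.0 * j + 1.0) * x * p1 - j * p2) / (j + 1.0);
      }
      pp = GLN * (x * p0 - p1) / (x * x - 1.0);
      double x1 = x;
      x = x1 - p0 / pp;
      if (std::fabs(x - x1) < 1e-15) break;
    }
    gl_x[i] = -x;
    gl_x[GLN - 1 - i] = x;
    gl_w[i] = 2.0 / ((1.0 - x * x) * pp * pp);
    gl_w[GLN - 1 - i] = gl_w[i];
  }
  gl_ready = true;
}

// ---- bivariate normal CDF P(X<=h, Y<=k; rho) via Plackett's identity ----
// Phi2(h,k,rho) = Phi(h)Phi(k) + (1/2pi) Int_0^rho phi2(h,k;r) dr
static double phi2_cdf(double h, double k, double rho) {
  if (h <= -37.0 || k <= -37.0) return 0.0;
  if (h >= 37.0) return R::pnorm(k, 0.0, 1.0, 1, 0);
  if (k >= 37.0) return R::pnorm(h, 0.0, 1.0, 1, 0);
  gl_init();
  double base = R::pnorm(h, 0.0, 1.0, 1, 0) * R::pnorm(k, 0.0, 1.0, 1, 0);
  if (rho == 0.0) return base;
  double acc = 0.0;
  double c = rho / 2.0;  // map [-1,1] -> [0,rho]
  for (int i = 0; i < GLN; ++i) {
    double r = c * (gl_x[i] + 1.0);
    double omr2 = 1.0 - r * r;
    double e = std::exp(-(h * h - 2.0 * r * h * k + k * k) / (2.0 * omr2));
    acc += gl_w[i] * e / std::sqrt(omr2);
  }
  double val = base + c * acc / (2.0 * M_PI);
  if (val < 0.0) val = 0.0;
  if (val > 1.0) val = 1.0;
  return val;
}

// [[Rcpp::export(name = ".pbivnorm_cpp")]]
NumericVector pbivnorm_cpp(NumericVector h, NumericVector k, double rho) {
  int n = h.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = phi2_cdf(h[i], k[i], rho);
  return out;
}

// negative log-likelihood of a two-way ordinal table under the bivariate
// normal model with fixed thresholds
static double pair_nll(const IntegerMatrix& tab,
                       const std::vector<double>& a,
                       const std::vector<double>& b, double rho) {
  int r = tab.nrow(), s = tab.ncol();
  // cumulative CDF grid, thresholds a has r+1 entries (with +-Inf)
  std::vector<double> F((r + 1) * (s + 1));
  for (int i = 0; i <= r; ++i)
    for (int j = 0; j <= s; ++j)
      F[i * (s + 1) + j] = phi2_cdf(a[i], b[j], rho);
  double nll = 0.0;
  for (int i = 1; i <= r; ++i)
    for (int j = 1; j <= s; ++j) {
      int n_ij = tab(i - 1, j - 1);
      if (n_ij == 0) continue;
      double pij = F[i * (s + 1) + j] - F[(i - 1) * (s + 1) + j]
                 - F[i * (s + 1) + (j - 1)] + F[(i - 1) * (s + 1) + (j - 1)];
      if (pij < 1e-12) pij = 1e-12;
      nll -= n_ij * std::log(pij);
    }
  return nll;
}

// Brent's local minimizer on [lo, hi]
template <typename F>
static double brent_min(F f, double lo, double hi, double tol) {
  const double gold = 0.3819660112501051;
  double a = lo, b = hi;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int it = 0; it < 100; ++it) {
    double xm = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-10, tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool parab = false;
    if (std::fabs(e) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etmp = e; e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etmp) &&
          p > q * (a - x) && p < q * (b - x)) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        parab = true;
      }
    }
    if (!parab) { e = (x >= xm) ? a - x : b - x; d = gold * e; }
    double u = (std::fabs(d) >= tol1) ? x + d : x + (d > 0 ? tol1 : -tol1);
    double fu = f(u);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  return x;
}

// [[Rcpp::export(name = ".polychoric_pair_cpp")]]
double polychoric_pair_cpp(IntegerMatrix tab, NumericVector thr_a,
                           NumericVector thr_b) {
  std::vector<double> a(tab.nrow() + 1), b(tab.ncol() + 1);
  a[0] = -100.0; a[tab.nrow()] = 100.0;
  for (int i = 1; i < tab.nrow(); ++i) a[i] = thr_a[i - 1];
  b[0] = -100.0; b[tab.ncol()] = 100.0;
  for (int j = 1; j < tab.ncol(); ++j) b[j] = thr_b[j - 1];
  auto f = [&](double rho) { return pair_nll(tab, a, b, rho); };
  return brent_min(f, -0.995, 0.995, 1e-5);
}

// [[Rcpp::export(name = ".polychoric_all_cpp")]]
NumericMatrix polychoric_all_cpp(IntegerMatrix X, List thresholds,
                                 IntegerVector n_levels) {
  int N = X.nrow(), P = X.ncol();
  NumericMatrix R(P, P);
  std::vector<std::vector<double>> thr(P);
  for (int p = 0; p < P; ++p) {
    NumericVector tp = thresholds[p];
    thr[p] = std::vector<double>(tp.begin(), tp.end());
  }
  for (int p = 0; p < P; ++p) R(p, p) = 1.0;
  for (int p = 0; p < P; ++p) {
    for (int q = p + 1; q < P; ++q) {
      int r = n_levels[p], s = n_levels[q];
      IntegerMatrix tab(r, s);
      for (int i = 0; i < N; ++i) tab(X(i, p) - 1, X(i, q) - 1)++;
      std::vector<double> a(r + 1), b(s + 1);
      a[0] = -100.0; a[r] = 100.0;
      for (int i = 1; i < r; ++i) a[i] = thr[p][i - 1];
      b[0] = -100.0; b[s] = 100.0;
      for (int j = 1; j < s; ++j) b[j] = thr[q][j - 1];
      auto f = [&](double rho) { return pair_nll(tab, a, b, rho); };
      double rho = brent_min(f, -0.995, 0.995, 1e-5);
      R(p, q) = rho;
      R(q, p) = rho;
    }
  }
  return R;
}
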