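#include <Rcpp.h>
#include <cfloat>
#include <cmath>
using namespace Rcpp;

// Generalized Gauss-Laguerre rules for the weight t^alpha e^{-t} on (0, Inf),
// built by the Golub-Welsch method: nodes are eigenvalues of the Jacobi
// matrix of the monic generalized Laguerre recurrence, weights come from the
// first components of the eigenvectors.  The symmetric-tridiagonal QL
// iteration below tracks only those first components, so the whole rule is
// O(order^2) and cheap enough to rebuild at every likelihood evaluation
// (alpha depends on the burst-frequency parameter being optimized).

static inline double log1pexp_c(double u) {
  // log(1 + e^u), stable for large |u|
  if (u > 0.0)
    return u + std::log1p(std::exp(-u));
  return std::log1p(std::exp(u));
}

static inline double fast_hypot(double x, double y) {
  // entries of the Jacobi matrices here are O(1e3); no overflow guard needed
  return std::sqrt(x * x + y * y);
}

static inline double logsumexp_vec(const std::vector<double>& v) {
  double m = -DBL_MAX;
  for (double x : v) if (x > m) m = x;
  if (m == -DBL_MAX || !R_FINITE(m)) return m;
  double s = 0.0;
  for (double x : v) s += std::exp(x - m);
  return m + std::log(s);
}

// Implicit-shift QL on a symmetric tridiagonal matrix, rotating a single
// vector z along (initialized to e1); on exit d holds eigenvalues and z the
// first eigenvector components.
static void ql_first_components(std::vector<double>& d,
                                std::vector<double>& e,
                                std::vector<double>& z) {
  const int n = static_cast<int>(d.size());
  const int max_iter = 60;
  if (n == 1) return;
  e[n - 1] = 0.0;
  for (int l = 0; l < n; ++l) {
    int iter = 0;
    for (;;) {
      int m;
      for (m = l; m < n - 1; ++m) {
        double dd = std::fabs(d[m]) + std::fabs(d[m + 1]);
        if (std::fabs(e[m]) <= DBL_EPSILON * dd) break;
      }
      if (m == l) break;
      if (++iter > max_iter)
        stop("Gauss-Laguerre eigenvalue iteration failed to converge");
      double g = (d[l + 1] - d[l]) / (2.0 * e[l]);
      double r = fast_hypot(g, 1.0);
      g = d[m] - d[l] + e[l] / (g + (g >= 0.0 ? std::fabs(r) : -std::fabs(r)));
      double s = 1.0, c = 1.0, p = 0.0;
      bool underflow = false;
      for (int i = m - 1; i >= l; --i) {
        double f = s * e[i];
        double bb = c * e[i];
        r = fast_hypot(f, g);
        e[i + 1] = r;
        if (r == 0.0) {
          d[i + 1] -= p;
          e[m] = 0.0;
          underflow = true;
          break;
        }
        s = f / r;
        c = g / r;
        g = d[i + 1] - p;
        r = (d[i] - g) * s + 2.0 * c * bb;
        p = s * r;
        d[i + 1] = g + p;
        g = c * r - bb;
        f = z[i + 1];
        z[i + 1] = s * z[i] + c * f;
        z[i] = c * z[i] - s * f;
      }
      if (underflow) continue;
      d[l] -= p;
      e[l] = g;
      e[m] = 0.0;
    }
  }
  // insertion sort of eigenvalues, carrying z
  for (int i = 1; i < n; ++i) {
    double dk = d[i], zk = z[i];
    int j = i - 1;
    while (j >= 0 && d[j] > dk) {
      d[j + 1] = d[j];
      z[j + 1] = z[j];
      --j;
    }
    d[j + 1] = dk;
    z[j + 1] = zk;
  }
}

static void gl_rule_compute(int order, double alpha,
                            std::vector<double>& nodes,
                            std::vector<double>& logw) {
  if (order < 1) stop("quadrature order must be >= 1");
  if (alpha <= -1.0) stop("generalized Laguerre exponent must exceed -1");
  std::vector<double> d(order), e(order), z(order, 0.0);
  for (int j = 0; j < order; ++j) {
    d[j] = 2.0 * j + alpha + 1.0;
    e[j] = std::sqrt((j + 1.0) * (j + 1.0 + alpha));  // subdiagonal j -> j+1
  }
  z[0] = 1.0;
  ql_first_components(d, e, z);
  nodes = d;
  logw.resize(order);
  const double lmu0 = R::lgammafn(alpha + 1.0);  // total weight-function mass
  for (int i = 0; i < order; ++i) {
    double az = std::fabs(z[i]);
    logw[i] = (az > 0.0) ? lmu0 + 2.0 * std::log(az) : R_NegInf;
  }
}

// Tiny LRU cache of recently used rules.  During a bounded quasi-Newton fit
// the finite-difference gradient perturbs b, k and h without changing alpha,
// so most likelihood evaluations can reuse the previous node set.
struct GLRule {
  int order = -1;
  double alpha = 0.0;
  std::vector<double> nodes, logw;
};

static const GLRule& gl_rule(int order, double alpha) {
  static GLRule cache[16];
  static int next = 0;
  for (int i = 0; i < 16; ++i)
    if (cache[i].order == order && cache[i].alpha == alpha) return cache[i];
  GLRule& slot = cache[next];
  next = (next + 1) % 16;
  slot.order = order;
  slot.alpha = alpha;
  gl_rule_compute(order, alpha, slot.nodes, slot.logw);
  return slot;
}

//' @noRd
// [[Rcpp::export(name = ".gl_rule_cpp")]]
List gl_rule_cpp(int order, double alpha) {
  const GLRule& r = gl_rule(order, alpha);
  return List::create(_["nodes"] = r.nodes, _["logw"] = r.logw);
}

// The unnormalized kernel x^{a(1+eps)-1} e^{-x/b} H(x) with Hill factor
// H(x) = (1 + (x/k)^h)^{-a/h} is integrated against a generalized Laguerre
// weight t^alpha e^{-t}.  For negative feedback (h > 0) H is bounded on
// (0, Inf) and alpha = a(1+eps) - 1.  For positive feedback (h < 0) H
// diverges like (x/k)^{-a} at the origin, so that power is moved into the
// weight instead: alpha = a eps - 1 and the bounded remainder
// G(x) = x^a H(x) stays in the smooth part.  The kernel is then integrable
// only when a*eps > 0, which the promoter leakiness guarantees.

static inline double weight_exponent(double a, double eps, double h) {
  if (h == 0.0) return a - 1.0;            // pure Gamma kernel
  if (h > 0.0) return a * (1.0 + eps) - 1.0;
  return a * eps - 1.0;
}

// log of the smooth (non-weight) part of the kernel at log(x):
// h > 0: log H(x);  h < 0: log G(x) = a log x + log H(x);  h == 0: 0.
static inline double log_smooth(double logx, double a, double k, double h) {
  if (h == 0.0) return 0.0;
  double u = h * (logx - std::log(k));
  double lH = -(a / h) * log1pexp_c(u);
  return (h > 0.0) ? lH : a * logx + lH;
}

// Log normalizing constant of the unnormalized kernel, evaluated with the
// same generalized rule (substitution t = x/b).  A finite alpha_rule
// evaluates with the rule for that exponent instead of the kernel's own,
// folding the residual power t^(alpha - alpha_rule) into the smooth part;
// this lets derivative evaluations that perturb `a` reuse a cached rule.
static double kernel_log_norm(double a, double b, double eps, double k,
                              double h, int order, double alpha_rule) {
  if (h == 0.0) return -(R::lgammafn(a) + a * std::log(b));
  const double alpha = weight_exponent(a, eps, h);
  const double ar = R_FINITE(alpha_rule) ? alpha_rule : alpha;
  const double da = alpha - ar;
  const GLRule& r = gl_rule(order, ar);
  std::vector<double> terms(order);
  const double lb = std::log(b);
  for (int i = 0; i < order; ++i) {
    const double lt = std::log(r.nodes[i]);
    terms[i] = r.logw[i] + da * lt + log_smooth(lt + lb, a, k, h);
  }
  return -((alpha + 1.0) * lb + logsumexp_vec(terms));
}

//' @noRd
// [[Rcpp::export(name = ".kernel_log_norm_cpp")]]
double kernel_log_norm_cpp(double a, double b, double eps, double k,
                           double h, int order) {
  return kernel_log_norm(a, b, eps, k, h, order, NA_REAL);
}

// Log pmf of the observed (Binomial-thinned) count for y = 0..ymax, via
// generalized Gauss-Laguerre quadrature after the substitution
// t = x (lambda + 1/b):
//   P(y) = N lambda^y / (y! s^{alpha+y+1}) * sum_i w_i t_i^y S(t_i/s)
// with s = lambda + 1/b, the weight exponent alpha fixed across y, the
// Poisson factor folded into the smooth part S, and all node contributions
// accumulated with log-sum-exp.  lambda = 1 gives the latent gene-level pmf.
//' @noRd
// [[Rcpp::export(name = ".observed_logpmf_cpp")]]
NumericVector observed_logpmf_cpp(int ymax, double a, double b, double eps,
                                  double k, double h, double lambda,
                                  int order,
                                  double alpha_rule = NA_REAL) {
  if (ymax < 0) stop("ymax must be >= 0");
  const double alpha = weight_exponent(a, eps, h);
  const double ar = R_FINITE(alpha_rule) && h != 0.0 ? alpha_rule : alpha;
  const double da = alpha - ar;
  const double s = lambda + 1.0 / b;
  const double ls = std::log(s);
  const GLRule& r = gl_rule(order, ar);
  const int n = order;

  // Node contributions at y = 0; the per-node factor t_i^y is then built
  // incrementally by multiplication.  All terms are positive, so plain
  // summation with a shared log-scale shift (renormalized whenever the sum
  // leaves a safe magnitude window) is exactly equivalent to log-sum-exp
  // and avoids an exp() per node and count value.
  std::vector<double> v(n);
  double m0 = -DBL_MAX;
  for (int i = 0; i < n; ++i) {
    const double lt = std::log(r.nodes[i]);
    v[i] = r.logw[i] + da * lt + log_smooth(lt - ls, a, k, h);
    if (v[i] > m0) m0 = v[i];
  }
  NumericVector out(ymax + 1);
  if (!R_FINITE(m0)) {
    std::fill(out.begin(), out.end(), R_NegInf);
    return out;
  }
  for (int i = 0; i < n; ++i) v[i] = std::exp(v[i] - m0);

  const double logN = kernel_log_norm(a, b, eps, k, h, order,
                                      h != 0.0 ? ar : NA_REAL);
  const double llam = std::log(lambda);
  double shift = m0;
  for (int y = 0; y <= ymax; ++y) {
    double sum = 0.0;
    if (y > 0)
      for (int i = 0; i < n; ++i) {
        v[i] *= r.nodes[i];
        sum += v[i];
      }
    else
      for (int i = 0; i < n; ++i) sum += v[i];
    double lse = (sum > 0.0) ? shift + std::log(sum) : R_NegInf;
    out[y] = logN + y * llam - R::lgammafn(y + 1.0) -
             (alpha + y + 1.0) * ls + lse;
    if (sum > 1e250 || (sum > 0.0 && sum < 1e-250)) {
      const double c = 1.0 / sum;
      for (int i = 0; i < n; ++i) v[i] *= c;
      shift += std::log(sum);
    }
  }
  return out;
}

// Negative log-likelihood for tabulated counts: sum_j n_j * (-log P(y_j)),
// with a log-probability floor so boundary parameter values stay finite.
//' @noRd
// [[Rcpp::export(name = ".nll_quadrature_cpp")]]
double nll_quadrature_cpp(IntegerVector yvals, NumericVector ncells,
                          double a, double b, double eps, double k, double h,
                          double lambda, int order,
                          double alpha_rule = NA_REAL) {
  int ymax = 0;
  for (int j = 0; j < yvals.size(); ++j) if (yvals[j] > ymax) ymax = yvals[j];
  NumericVector lp = observed_logpmf_cpp(ymax, a, b, eps, k, h, lambda, order,
                                         alpha_rule);
  const double floor_lp = std::log(1e-300);
  double nll = 0.0;
  for (int j = 0; j < yvals.size(); ++j) {
    double l = lp[yvals[j]];
    if (!R_FINITE(l) || l < floor_lp) l = floor_lp;
    nll -= ncells[j] * l;
  }
  return nll;
}
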