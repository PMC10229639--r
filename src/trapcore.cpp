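#include <Rcpp.h>
using namespace Rcpp;

// Exact-discretization Ornstein-Uhlenbeck path with piecewise-constant
// mean and stiffness. mu and keff are per-sample vectors (nm, pN/nm);
// z is a vector of standard normal draws supplied by the caller so that
// all randomness flows through R's RNG.
// x_{i} = mu_i + (x_{i-1} - mu_i) * rho_i + sqrt(kT/keff_i * (1 - rho_i^2)) z_i
// with rho_i = exp(-keff_i * dt / gamma).
// [[Rcpp::export]]
NumericVector ou_paint(NumericVector mu, NumericVector keff, double x0,
                       double kT, double dt, double gamma_drag,
                       NumericVector z) {
  int n = mu.size();
  if (keff.size() != n || z.size() != n)
    stop("mu, keff and z must have equal length");
  NumericVector x(n);
  double prev = x0;
  double last_k = -1.0, rho = 0.0, sd = 0.0;
  for (int i = 0; i < n; i++) {
    double k = keff[i];
    if (k != last_k) {
      rho = std::exp(-k * dt / gamma_drag);
      sd = std::sqrt(kT / k * (1.0 - rho * rho));
      last_k = k;
    }
    prev = mu[i] + (prev - mu[i]) * rho + sd * z[i];
    x[i] = prev;
  }
  return x;
}

// Scaled forward-backward pass for a K-state HMM given per-observation
// log emission densities. Returns the log-likelihood, posterior state
// probabilities gamma (T x K) and summed transition responsibilities
// xi (K x K).
// [[Rcpp::export]]
List hmm_forward_backward(NumericMatrix logdens, NumericMatrix trans,
                          NumericVector init) {
  int T = logdens.nrow(), K = logdens.ncol();
  if (trans.nrow() != K || trans.ncol() != K || init.size() != K)
    stop("dimension mismatch");
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector scale(T);
  // stabilise emissions per observation
  NumericMatrix dens(T, K);
  for (int t = 0; t < T; t++) {
    double m = logdens(t, 0);
    for (int k = 1; k < K; k++) m = std::max(m, logdens(t, k));
    for (int k = 0; k < K; k++) dens(t, k) = std::exp(logdens(t, k) - m);
    scale[t] = m;  // temporarily store the shift
  }
  double loglik = 0.0;
  NumericVector c(T);
  for (int k = 0; k < K; k++) alpha(0, k) = init[k] * dens(0, k);
  double s0 = 0.0;
  for (int k = 0; k < K; k++) s0 += alpha(0, k);
  if (s0 <= 0) stop("zero forward probability at t=0");
  for (int k = 0; k < K; k++) alpha(0, k) /= s0;
  c[0] = s0;
  for (int t = 1; t < T; t++) {
    double st = 0.0;
    for (int k = 0; k < K; k++) {
      double a = 0.0;
      for (int j = 0; j < K; j++) a += alpha(t - 1, j) * trans(j, k);
      a *= dens(t, k);
      alpha(t, k) = a;
      st += a;
    }
    if (st <= 0) stop("zero forward probability");
    for (int k = 0; k < K; k++) alpha(t, k) /= st;
    c[t] = st;
  }
  for (int t = 0; t < T; t++) loglik += std::log(c[t]) + scale[t];

  for (int k = 0; k < K; k++) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; t--) {
    for (int k = 0; k < K; k++) {
      double b = 0.0;
      for (int j = 0; j < K; j++)
        b += trans(k, j) * dens(t + 1, j) * beta(t + 1, j);
      beta(t, k) = b / c[t + 1];
    }
  }
  for (int t = 0; t < T; t++) {
    double g = 0.0;
    for (int k = 0; k < K; k++) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      g += gamma(t, k);
    }
    for (int k = 0; k < K; k++) gamma(t, k) /= g;
  }
  NumericMatrix xi(K, K);
  for (int t = 0; t < T - 1; t++) {
    double denom = 0.0;
    for (int j = 0; j < K; j++)
      for (int k = 0; k < K; k++)
        denom += alpha(t, j) * trans(j, k) * dens(t + 1, k) * beta(t + 1, k);
    if (denom <= 0) continue;
    for (int j = 0; j < K; j++)
      for (int k = 0; k < K; k++)
        xi(j, k) += alpha(t, j) * trans(j, k) * dens(t + 1, k) *
                    beta(t + 1, k) / denom;
  }
  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi"] = xi);
}

// Viterbi decoding; returns 1-based state indices.
// [[Rcpp::export]]
IntegerVector hmm_viterbi(NumericMatrix logdens, NumericMatrix trans,
                          NumericVector init) {
  int T = logdens.nrow(), K = logdens.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; k++)
    delta(0, k) = std::log(init[k]) + logdens(0, k);
  for (int t = 1; t < T; t++) {
    for (int k = 0; k < K; k++) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < K; j++) {
        double v = delta(t - 1, j) + std::log(trans(j, k));
        if (v > best) { best = v; arg = j; }
      }
      delta(t, k) = best + logdens(t, k);
      psi(t, k) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf;
  int arg = 0;
  for (int k = 0; k < K; k++)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; t--) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; t++) path[t] += 1;
  return path;
}

// Nearest-neighbour Euclidean distances, brute force O(n^2) but cheap
// for the point counts produced by localization microscopy fields.
// [[Rcpp::export]]
NumericVector nn_distances(NumericVector x, NumericVector y) {
  int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (n < 2) stop("need at least 2 points");
  NumericVector d(n);
  for (int i = 0; i < n; i++) {
    double best = R_PosInf;
    for (int j = 0; j < n; j++) {
      if (j == i) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double dd = dx * dx + dy * dy;
      if (dd < best) best = dd;
    }
    d[i] = std::sqrt(best);
  }
  return d;
}
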