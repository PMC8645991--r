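// Kernel SVM dual solver (SMO, maximal-violating-pair working set) and the
// SimpleMKL alternating scheme: SVM solve on the beta-combined kernel plus a
// reduced-gradient step on the probability simplex with golden-section line
// search. Kept in compiled code because nested LOOCV refits these thousands
// of times.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct SvmFit {
  vec alpha;
  double b;
  double obj;       // dual objective (maximized form)
  bool converged;
  int iter;
};

// Solves max_a  sum(a) - 0.5 sum_ij a_i a_j y_i y_j K_ij
// s.t. 0 <= a_i <= C, sum a_i y_i = 0.
static SvmFit smo_solve(const mat& K, const vec& y, double C,
                        double eps = 1e-6, int max_iter = 500000) {
  const int n = K.n_rows;
  vec a(n, fill::zeros);
  vec G(n, fill::ones);
  G *= -1.0;                      // gradient of 0.5 a'Qa - e'a at a = 0
  int it = 0;
  bool conv = false;
  double m_up = 0, m_low = 0;
  for (; it < max_iter; ++it) {
    // working set: maximal violating pair
    int i = -1, j = -1;
    m_up = -datum::inf; m_low = datum::inf;
    for (int t = 0; t < n; ++t) {
      double v = -y(t) * G(t);
      bool in_up  = (y(t) > 0 && a(t) < C) || (y(t) < 0 && a(t) > 0);
      bool in_low = (y(t) > 0 && a(t) > 0) || (y(t) < 0 && a(t) < C);
      if (in_up && v > m_up)  { m_up = v;  i = t; }
      if (in_low && v < m_low) { m_low = v; j = t; }
    }
    if (i < 0 || j < 0 || m_up - m_low < eps) { conv = true; break; }
    double s = y(i) * y(j);
    double eta = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (eta < 1e-12) eta = 1e-12;
    double t_step = -(G(i) - s * G(j)) / eta;
    // box bounds on t (a_i + t, a_j - s t must stay in [0, C])
    double lo = -a(i), hi = C - a(i);
    if (s > 0) { lo = std::max(lo, a(j) - C); hi = std::min(hi, a(j)); }
    else       { lo = std::max(lo, -a(j));    hi = std::min(hi, C - a(j)); }
    if (t_step < lo) t_step = lo;
    if (t_step > hi) t_step = hi;
    if (std::abs(t_step) < 1e-16) { conv = false; break; }
    // snap to the box so bound membership stays exact for pair selection;
    // the gradient update uses the deltas actually applied
    const double snap = 1e-12 * C;
    double ai_new = a(i) + t_step;
    double aj_new = a(j) - s * t_step;
    if (ai_new < snap) ai_new = 0; else if (ai_new > C - snap) ai_new = C;
    if (aj_new < snap) aj_new = 0; else if (aj_new > C - snap) aj_new = C;
    double d_i = ai_new - a(i), d_j = aj_new - a(j);
    a(i) = ai_new;
    a(j) = aj_new;
    for (int t2 = 0; t2 < n; ++t2)
      G(t2) += y(t2) * (y(i) * K(t2, i) * d_i + y(j) * K(t2, j) * d_j);
  }
  // bias from free support vectors, midpoint of KKT interval otherwise
  double bsum = 0; int nfree = 0;
  for (int t = 0; t < n; ++t)
    if (a(t) > 1e-10 && a(t) < C - 1e-10) { bsum += -y(t) * G(t); ++nfree; }
  double b;
  if (nfree > 0) b = bsum / nfree;
  else b = 0.5 * (m_up + m_low);
  double obj = 0.5 * (accu(a) - dot(a, G));  // = sum(a) - 0.5 a'Qa
  SvmFit fit;
  fit.alpha = a; fit.b = b; fit.obj = obj; fit.converged = conv; fit.iter = it;
  return fit;
}

static mat combine(const cube& Ks, const vec& beta) {
  mat Kc(Ks.n_rows, Ks.n_cols, fill::zeros);
  for (uword m = 0; m < Ks.n_slices; ++m)
    if (beta(m) > 0) Kc += beta(m) * Ks.slice(m);
  return Kc;
}

// dual objective J(beta) = max_alpha of the combined-kernel SVM dual
static double J_of_beta(const cube& Ks, const vec& y, double C,
                        const vec& beta, double eps, SvmFit* out = nullptr) {
  SvmFit f = smo_solve(combine(Ks, beta), y, C, eps);
  if (out) *out = f;
  return f.obj;
}

struct MklFit {
  vec alpha; double b; vec beta;
  std::vector<double> obj_trace;
  bool svm_converged; int n_outer;
};

static MklFit simplemkl(const cube& Ks, const vec& y, double C,
                        double outer_tol, int max_outer, double svm_eps,
                        vec beta0) {
  const uword M = Ks.n_slices;
  vec beta = beta0;
  SvmFit fit;
  double J = J_of_beta(Ks, y, C, beta, svm_eps, &fit);
  MklFit res;
  res.obj_trace.push_back(J);
  int outer = 0;
  for (; outer < max_outer && M > 1; ++outer) {
    // gradient of J wrt beta at the current alpha optimum (Danskin)
    vec v = fit.alpha % y;
    vec grad(M);
    for (uword m = 0; m < M; ++m)
      grad(m) = -0.5 * as_scalar(v.t() * Ks.slice(m) * v);
    uword mu = beta.index_max();
    vec d(M, fill::zeros);
    for (uword m = 0; m < M; ++m) {
      if (m == mu) continue;
      double red = grad(m) - grad(mu);
      if (beta(m) < 1e-12 && red > 0) d(m) = 0;
      else d(m) = -red;
    }
    d(mu) = -accu(d);
    if (norm(d, "inf") < 1e-12) break;
    // maximal admissible step on the simplex
    double gmax = datum::inf;
    for (uword m = 0; m < M; ++m)
      if (d(m) < 0) gmax = std::min(gmax, -beta(m) / d(m));
    if (!std::isfinite(gmax) || gmax < 1e-14) break;
    // golden-section search on [0, gmax], tracking the best evaluated point
    const double gr = 0.6180339887498949;
    double lo = 0, hi = gmax;
    double best_g = 0, best_J = J;
    SvmFit best_fit = fit;
    auto eval = [&](double g) {
      SvmFit f2;
      double Jg = J_of_beta(Ks, y, C, beta + g * d, svm_eps, &f2);
      if (Jg < best_J) { best_J = Jg; best_g = g; best_fit = f2; }
      return Jg;
    };
    double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
    double f1 = eval(x1), f2v = eval(x2);
    eval(gmax);
    for (int ls = 0; ls < 8; ++ls) {
      if (f1 < f2v) { hi = x2; x2 = x1; f2v = f1; x1 = hi - gr * (hi - lo); f1 = eval(x1); }
      else          { lo = x1; x1 = x2; f1 = f2v; x2 = lo + gr * (hi - lo); f2v = eval(x2); }
      if (hi - lo < 1e-4 * gmax) break;
    }
    if (best_g <= 0 || best_J >= J - 1e-12) { res.obj_trace.push_back(J); break; }
    vec beta_new = beta + best_g * d;
    beta_new.transform([](double x) { return x < 1e-12 ? 0.0 : x; });
    beta_new /= accu(beta_new);
    double dbeta = norm(beta_new - beta, "inf");
    beta = beta_new;
    J = best_J; fit = best_fit;
    res.obj_trace.push_back(J);
    if (dbeta < outer_tol) break;
  }
  res.alpha = fit.alpha; res.b = fit.b; res.beta = beta;
  res.svm_converged = fit.converged; res.n_outer = outer;
  return res;
}

// [[Rcpp::export(name = ".smo_solve_cpp")]]
Rcpp::List smo_solve_cpp(const arma::mat& K, const arma::vec& y, double C,
                         double eps = 1e-6, int max_iter = 500000) {
  SvmFit f = smo_solve(K, y, C, eps, max_iter);
  return Rcpp::List::create(
    Rcpp::Named("alpha") = f.alpha, Rcpp::Named("b") = f.b,
    Rcpp::Named("objective") = f.obj, Rcpp::Named("converged") = f.converged,
    Rcpp::Named("iterations") = f.iter);
}

// [[Rcpp::export(name = ".simplemkl_cpp")]]
Rcpp::List simplemkl_cpp(const arma::cube& Ks, const arma::vec& y, double C,
                         double outer_tol = 1e-4, int max_outer = 100,
                         double svm_eps = 1e-6,
                         Rcpp::Nullable<Rcpp::NumericVector> beta_init = R_NilValue) {
  vec beta0(Ks.n_slices);
  if (beta_init.isNotNull()) beta0 = Rcpp::as<vec>(beta_init.get());
  else beta0.fill(1.0 / Ks.n_slices);
  MklFit f = simplemkl(Ks, y, C, outer_tol, max_outer, svm_eps, beta0);
  return Rcpp::List::create(
    Rcpp::Named("alpha") = f.alpha, Rcpp::Named("b") = f.b,
    Rcpp::Named("beta") = f.beta,
    Rcpp::Named("objective_trace") = f.obj_trace,
    Rcpp::Named("svm_converged") = f.svm_converged,
    Rcpp::Named("n_outer") = f.n_outer);
}

// Leave-one-out accuracy over a C grid on precomputed kernels. For M > 1 and
// learn_beta, beta is learned once per C on all n samples' kernels (warm
// started along the grid), then each fold refits only the SVM dual.
// [[Rcpp::export(name = ".mkl_inner_loocv_cpp")]]
Rcpp::List mkl_inner_loocv_cpp(const arma::cube& Ks, const arma::vec& y,
                               const arma::vec& Cgrid, bool learn_beta = true,
                               double svm_eps = 1e-6, double outer_tol = 1e-3,
                               int max_outer = 40) {
  const uword n = Ks.n_rows, M = Ks.n_slices, nC = Cgrid.n_elem;
  vec acc(nC, fill::zeros);
  mat betas(M, nC);
  vec beta(M); beta.fill(1.0 / M);
  for (uword ci = 0; ci < nC; ++ci) {
    double C = Cgrid(ci);
    if (learn_beta && M > 1) {
      MklFit f = simplemkl(Ks, y, C, outer_tol, max_outer, svm_eps, beta);
      beta = f.beta;
    }
    betas.col(ci) = beta;
    mat Kc = combine(Ks, beta);
    uvec allidx = regspace<uvec>(0, n - 1);
    int ncorrect = 0;
    for (uword k = 0; k < n; ++k) {
      uvec idx = find(allidx != k);
      vec ysub = y(idx);
      if (ysub.min() > 0 || ysub.max() < 0) continue;  // one-class fold scores 0
      SvmFit f = smo_solve(Kc(idx, idx), ysub, C, svm_eps);
      double dec = dot(f.alpha % ysub, Kc(idx, uvec{k})) + f.b;
      double pred = dec >= 0 ? 1.0 : -1.0;
      if (pred == y(k)) ++ncorrect;
    }
    acc(ci) = double(ncorrect) / n;
  }
  return Rcpp::List::create(Rcpp::Named("accuracy") = acc,
                            Rcpp::Named("beta") = betas);
}
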