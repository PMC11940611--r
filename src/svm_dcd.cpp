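#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L1-loss (hinge) linear SVM,
//   min_w 0.5 w'w + C sum_i max(0, 1 - y_i w'x_i),
// after Hsieh et al. (2008), with the liblinear shrinking heuristic:
// variables pinned at their bounds with sufficiently violating gradients
// are dropped from the sweep until the active set converges, then one full
// pass verifies optimality. Samples arrive as the columns of a dgCMatrix
// (features x samples), so per-sample work is proportional to the nonzero
// count. An implicit constant feature of value bias_scale carries the
// bias (so the effective intercept is bias_scale times the returned last
// weight and its ridge penalty is (b/bias_scale)^2, negligible for a
// large enough scale, as in liblinear's -B option). Uses R's RNG for
// the per-epoch permutation so set.seed() on the R side fixes the
// iteration order.
// [[Rcpp::export(name = ".dcd_svm")]]
List dcd_svm(S4 Xt, NumericVector y, double C, double eps, int max_iter,
             double bias_scale) {
  const IntegerVector dim = Xt.slot("Dim");
  const int d = dim[0], n = dim[1];
  const IntegerVector p = Xt.slot("p"), ri = Xt.slot("i");
  const NumericVector xv = Xt.slot("x");
  std::vector<double> w(d + 1, 0.0), alpha(n, 0.0), qii(n);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) {
    double s = bias_scale * bias_scale;  // scaled bias feature
    for (int k = p[i]; k < p[i + 1]; ++k) s += xv[k] * xv[k];
    qii[i] = s;
    idx[i] = i;
  }
  int active = n, iter = 0;
  bool converged = false;
  double Mbar = R_PosInf, mbar = R_NegInf;
  for (iter = 0; iter < max_iter; ++iter) {
    for (int i = active - 1; i > 0; --i) {  // Fisher-Yates over active set
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    double pg_max = R_NegInf, pg_min = R_PosInf;
    for (int s = 0; s < active; ++s) {
      const int i = idx[s];
      double g = w[d] * bias_scale;
      for (int k = p[i]; k < p[i + 1]; ++k) g += w[ri[k]] * xv[k];
      g = y[i] * g - 1.0;
      double pg = 0.0;
      if (alpha[i] <= 0.0) {
        if (g > Mbar) { std::swap(idx[s], idx[--active]); --s; continue; }
        if (g < 0.0) pg = g;
      } else if (alpha[i] >= C) {
        if (g < mbar) { std::swap(idx[s], idx[--active]); --s; continue; }
        if (g > 0.0) pg = g;
      } else {
        pg = g;
      }
      if (pg > pg_max) pg_max = pg;
      if (pg < pg_min) pg_min = pg;
      if (std::fabs(pg) > 1e-12) {
        double a_old = alpha[i];
        double a_new = std::min(std::max(a_old - g / qii[i], 0.0), C);
        alpha[i] = a_new;
        double delta = (a_new - a_old) * y[i];
        if (delta != 0.0) {
          for (int k = p[i]; k < p[i + 1]; ++k) w[ri[k]] += delta * xv[k];
          w[d] += delta * bias_scale;
        }
      }
    }
    if (pg_max - pg_min <= eps) {
      if (active == n) { converged = true; break; }
      active = n;  // verify optimality over the shrunken variables
      Mbar = R_PosInf; mbar = R_NegInf;
      continue;
    }
    Mbar = (pg_max <= 0.0) ? R_PosInf : pg_max;
    mbar = (pg_min >= 0.0) ? R_NegInf : pg_min;
    if (iter % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["iter"] = iter + 1, _["converged"] = converged);
}
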