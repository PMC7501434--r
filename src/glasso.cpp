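#include <Rcpp.h>
using namespace Rcpp;

// Graphical lasso by block coordinate descent (Friedman/Hastie/Tibshirani style).
//
// Maximizes  log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |Theta_ij|
// over positive-definite Theta; the diagonal is unpenalized, so the working
// covariance W keeps diag(W) = diag(S).  Each outer sweep solves, for one
// column, the lasso problem
//     min_b 0.5 b' W11 b - s12' b + lambda ||b||_1
// by cyclic coordinate descent with soft-thresholding.

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// [[Rcpp::export]]
List glasso_cpp(NumericMatrix S, double lambda,
                double tol = 1e-7, int maxIter = 200,
                Nullable<NumericMatrix> wInit = R_NilValue,
                Nullable<NumericMatrix> bInit = R_NilValue) {
  const int p = S.nrow();
  if (S.ncol() != p) stop("S must be square");
  if (lambda < 0) stop("lambda must be nonnegative");

  NumericMatrix W(p, p);   // working covariance estimate
  NumericMatrix B(p, p);   // column j holds the lasso coefficients for node j
  if (wInit.isNotNull()) {
    NumericMatrix w0(wInit);
    for (int i = 0; i < p * p; ++i) W[i] = w0[i];
    for (int j = 0; j < p; ++j) W(j, j) = S(j, j);  // diagonal unpenalized
  } else {
    for (int i = 0; i < p * p; ++i) W[i] = S[i];
  }
  if (bInit.isNotNull()) {
    NumericMatrix b0(bInit);
    for (int i = 0; i < p * p; ++i) B[i] = b0[i];
  }

  // convergence scale: mean |off-diagonal of S|
  double sbar = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) sbar += std::fabs(S(i, j));
  sbar /= std::max(1, p * (p - 1));
  const double thr = tol * std::max(sbar, 1e-12);

  std::vector<double> beta(p), grad(p);
  int iter = 0;
  bool converged = false;

  for (iter = 1; iter <= maxIter; ++iter) {
    double maxDelta = 0.0;
    for (int j = 0; j < p; ++j) {
      for (int k = 0; k < p; ++k) beta[k] = B(k, j);
      beta[j] = 0.0;
      // inner cyclic coordinate descent on the p-1 free coordinates
      for (int inner = 0; inner < 200; ++inner) {
        double innerDelta = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          double r = S(k, j);
          for (int m = 0; m < p; ++m) {
            if (m == j || m == k) continue;
            r -= W(k, m) * beta[m];
          }
          double bNew = soft(r, lambda) / W(k, k);
          double d = std::fabs(bNew - beta[k]);
          if (d > innerDelta) innerDelta = d;
          beta[k] = bNew;
        }
        if (innerDelta < thr * 0.1) break;
      }
      // update column j of W: w12 = W11 beta
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        double w = 0.0;
        for (int m = 0; m < p; ++m) {
          if (m == j) continue;
          w += W(k, m) * beta[m];
        }
        double d = std::fabs(w - W(k, j));
        if (d > maxDelta) maxDelta = d;
        W(k, j) = w;
        W(j, k) = w;
        B(k, j) = beta[k];
      }
    }
    if (maxDelta < thr) { converged = true; break; }
  }
  if (iter > maxIter) iter = maxIter;

  // recover Theta from W and the regression coefficients
  NumericMatrix Theta(p, p);
  for (int j = 0; j < p; ++j) {
    double dot = 0.0;
    for (int k = 0; k < p; ++k)
      if (k != j) dot += W(k, j) * B(k, j);
    double tjj = 1.0 / (W(j, j) - dot);
    Theta(j, j) = tjj;
    for (int k = 0; k < p; ++k)
      if (k != j) Theta(k, j) = -B(k, j) * tjj;
  }
  // symmetrize (columns are solved separately)
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) {
      double v = 0.5 * (Theta(i, j) + Theta(j, i));
      Theta(i, j) = v;
      Theta(j, i) = v;
    }

  return List::create(_["theta"] = Theta, _["w"] = W, _["B"] = B,
                      _["iterations"] = iter, _["converged"] = converged);
}
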