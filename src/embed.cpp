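#include <Rcpp.h>
using namespace Rcpp;

// Penalty energy for the distance-geometry embedding: harmonic springs
// on bonds (weight 10) and a quadratic repulsion floor at 2.0 A for
// non-bonded pairs.
// [[Rcpp::export]]
double embed_energy_cpp(NumericVector par, IntegerVector b1,
                        IntegerVector b2, NumericVector r0,
                        IntegerVector nb1, IntegerVector nb2, int n,
                        IntegerVector rs1, IntegerVector rs2,
                        NumericVector rtarget, NumericVector rweight) {
  double e = 0.0;
  const double *x = par.begin();
  for (int k = 0; k < rs1.size(); ++k) {
    int i = rs1[k] - 1, j = rs2[k] - 1;
    double dx = x[i] - x[j];
    double dy = x[i + n] - x[j + n];
    double dz = x[i + 2 * n] - x[j + 2 * n];
    double d = sqrt(dx * dx + dy * dy + dz * dz);
    double diff = d - rtarget[k];
    e += rweight[k] * diff * diff;
  }
  for (int k = 0; k < b1.size(); ++k) {
    int i = b1[k] - 1, j = b2[k] - 1;
    double dx = x[i] - x[j];
    double dy = x[i + n] - x[j + n];
    double dz = x[i + 2 * n] - x[j + 2 * n];
    double d = sqrt(dx * dx + dy * dy + dz * dz);
    double diff = d - r0[k];
    e += 10.0 * diff * diff;
  }
  for (int k = 0; k < nb1.size(); ++k) {
    int i = nb1[k] - 1, j = nb2[k] - 1;
    double dx = x[i] - x[j];
    double dy = x[i + n] - x[j + n];
    double dz = x[i + 2 * n] - x[j + 2 * n];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < 4.0) {
      double d = sqrt(d2);
      double v = 2.0 - d;
      e += v * v;
    }
  }
  return e;
}

// [[Rcpp::export]]
NumericVector embed_gradient_cpp(NumericVector par, IntegerVector b1,
                                 IntegerVector b2, NumericVector r0,
                                 IntegerVector nb1, IntegerVector nb2,
                                 int n, IntegerVector rs1,
                                 IntegerVector rs2, NumericVector rtarget,
                                 NumericVector rweight) {
  NumericVector grad(3 * n);
  const double *x = par.begin();
  double *g = grad.begin();
  for (int k = 0; k < rs1.size(); ++k) {
    int i = rs1[k] - 1, j = rs2[k] - 1;
    double dx = x[i] - x[j];
    double dy = x[i + n] - x[j + n];
    double dz = x[i + 2 * n] - x[j + 2 * n];
    double d = sqrt(dx * dx + dy * dy + dz * dz);
    if (d < 1e-9) d = 1e-9;
    double f = 2.0 * rweight[k] * (d - rtarget[k]) / d;
    g[i] += f * dx;         g[j] -= f * dx;
    g[i + n] += f * dy;     g[j + n] -= f * dy;
    g[i + 2 * n] += f * dz; g[j + 2 * n] -= f * dz;
  }
  for (int k = 0; k < b1.size(); ++k) {
    int i = b1[k] - 1, j = b2[k] - 1;
    double dx = x[i] - x[j];
    double dy = x[i + n] - x[j + n];
    double dz = x[i + 2 * n] - x[j + 2 * n];
    double d = sqrt(dx * dx + dy * dy + dz * dz);
    if (d < 1e-9) d = 1e-9;
    double f = 20.0 * (d - r0[k]) / d;
    g[i] += f * dx;         g[j] -= f * dx;
    g[i + n] += f * dy;     g[j + n] -= f * dy;
    g[i + 2 * n] += f * dz; g[j + 2 * n] -= f * dz;
  }
  for (int k = 0; k < nb1.size(); ++k) {
    int i = nb1[k] - 1, j = nb2[k] - 1;
    double dx = x[i] - x[j];
    double dy = x[i + n] - x[j + n];
    double dz = x[i + 2 * n] - x[j + 2 * n];
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < 4.0) {
      double d = sqrt(d2);
      if (d < 1e-9) d = 1e-9;
      double f = -2.0 * (2.0 - d) / d;
      g[i] += f * dx;         g[j] -= f * dx;
      g[i + n] += f * dy;     g[j + n] -= f * dy;
      g[i + 2 * n] += f * dz; g[j + 2 * n] -= f * dz;
    }
  }
  return grad;
}
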