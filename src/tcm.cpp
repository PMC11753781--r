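// Inner loops of the two-tissue-compartment forward model: exact
// convolution of a piecewise-linear plasma input with the exponential
// kernel, and trapezoidal frame averaging. Called per voxel and per
// fit iteration, so these live in compiled code.

#include <Rcpp.h>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

// Convolution of piecewise-linear cp (uniform grid, step dt) with
// exp(-alpha t): y_j = E y_{j-1} + I0 cp_j + I1 cp_{j-1}. Exact for a
// piecewise-linear input; series branch avoids cancellation as alpha -> 0.
static void conv_exp(const double* cp, int n, double dt, double alpha,
                     double* y) {
  double x = alpha * dt;
  double E = std::exp(-x);
  double I0, I1;
  if (x < 1e-4) {
    I1 = dt * (0.5 - x / 3.0 + x * x / 8.0);
    I0 = dt * (0.5 - x / 6.0 + x * x / 24.0);
  } else {
    double J1 = (1.0 - E * (1.0 + x)) / (alpha * alpha);
    I1 = J1 / dt;
    I0 = (1.0 - E) / alpha - I1;
  }
  y[0] = 0.0;
  for (int j = 1; j < n; ++j)
    y[j] = E * y[j - 1] + I0 * cp[j] + I1 * cp[j - 1];
}

// Convolution with t exp(-alpha t) (confluent eigenrate case), given the
// plain exponential convolution y of the same input.
static void conv_texp(const double* cp, const double* y, int n, double dt,
                      double alpha, double* w) {
  double x = alpha * dt;
  double E = std::exp(-x);
  double J1, J2;
  if (x < 1e-4) {
    J1 = dt * dt * (0.5 - x / 3.0 + x * x / 8.0);
    J2 = dt * dt * dt * (1.0 / 3.0 - x / 4.0 + x * x / 10.0);
  } else {
    J1 = (1.0 - E * (1.0 + x)) / (alpha * alpha);
    J2 = (2.0 - E * (x * x + 2.0 * x + 2.0)) / (alpha * alpha * alpha);
  }
  double c0 = J1 - J2 / dt;
  double c1 = J2 / dt;
  w[0] = 0.0;
  for (int j = 1; j < n; ++j)
    w[j] = E * w[j - 1] + dt * E * y[j - 1] + c0 * cp[j] + c1 * cp[j - 1];
}

// [[Rcpp::export(name = ".tcm_tissue_curve")]]
NumericVector tcm_tissue_curve(NumericVector cp, double dt, double K1,
                               double k2, double k3, double k4) {
  int n = cp.size();
  NumericVector ct(n);
  double s = k2 + k3 + k4;
  double disc = s * s - 4.0 * k2 * k4;
  if (disc < 0.0) disc = 0.0;
  double rt = std::sqrt(disc);
  double scale = s > 1.0 ? s : 1.0;
  std::vector<double> y1(n);
  if (rt <= std::sqrt(DBL_EPSILON) * scale) {
    // repeated eigenrate: h(t) = K1 e^(-a t) (1 + (k3 + k4 - a) t)
    double a = s / 2.0;
    double slope = K1 * (k3 + k4 - a);
    conv_exp(cp.begin(), n, dt, a, y1.data());
    if (slope != 0.0) {
      std::vector<double> w(n);
      conv_texp(cp.begin(), y1.data(), n, dt, a, w.data());
      for (int j = 0; j < n; ++j) ct[j] = K1 * y1[j] + slope * w[j];
    } else {
      for (int j = 0; j < n; ++j) ct[j] = K1 * y1[j];
    }
  } else {
    double a1 = (s - rt) / 2.0;
    double a2 = (s + rt) / 2.0;
    double A1 = K1 * (k3 + k4 - a1) / (a2 - a1);
    double A2 = K1 * (a2 - (k3 + k4)) / (a2 - a1);
    std::vector<double> y2(n);
    conv_exp(cp.begin(), n, dt, a1, y1.data());
    conv_exp(cp.begin(), n, dt, a2, y2.data());
    for (int j = 0; j < n; ++j) ct[j] = A1 * y1[j] + A2 * y2[j];
  }
  return ct;
}

// Fused path for the fit inner loop: parameters -> frame means in one call.
// [[Rcpp::export(name = ".tcm_frame_tac")]]
NumericVector tcm_frame_tac(NumericVector cp, double dt,
                            IntegerVector starts, IntegerVector ends,
                            double K1, double k2, double k3, double k4) {
  NumericVector ct = tcm_tissue_curve(cp, dt, K1, k2, k3, k4);
  int nf = starts.size();
  NumericVector out(nf);
  for (int i = 0; i < nf; ++i) {
    int a = starts[i] - 1, b = ends[i] - 1;
    double sum = 0.0;
    for (int j = a; j <= b; ++j) sum += ct[j];
    sum -= 0.5 * (ct[a] + ct[b]);
    out[i] = sum / (b - a);
  }
  return out;
}

// Trapezoidal mean of ct over each frame [starts_i, ends_i] (1-based,
// inclusive fine-grid indices aligned with frame boundaries).
// [[Rcpp::export(name = ".tcm_frame_means")]]
NumericVector tcm_frame_means(NumericVector ct, IntegerVector starts,
                              IntegerVector ends) {
  int nf = starts.size();
  NumericVector out(nf);
  for (int i = 0; i < nf; ++i) {
    int a = starts[i] - 1, b = ends[i] - 1;
    double sum = 0.0;
    for (int j = a; j <= b; ++j) sum += ct[j];
    sum -= 0.5 * (ct[a] + ct[b]);
    out[i] = sum / (b - a);
  }
  return out;
}
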