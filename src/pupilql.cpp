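#include <Rcpp.h>
using namespace Rcpp;

// Sequential Q-learning recursion shared by the likelihood and the
// trajectory extractor. Options are 0-based indices into the Q vector;
// Q is initialised at 0.5 for every option. Only the chosen option is
// updated, and only on trials that carry an outcome (outcome >= 0).

// [[Rcpp::export]]
double ql_nll_cpp(IntegerVector opt_a, IntegerVector opt_b,
                  IntegerVector choice, IntegerVector outcome,
                  LogicalVector include,
                  double alpha_gain, double alpha_loss, double beta,
                  int n_options) {
  int n = opt_a.size();
  std::vector<double> q(n_options, 0.5);
  double nll = 0.0;
  for (int t = 0; t < n; ++t) {
    int a = opt_a[t], b = opt_b[t], c = choice[t];
    double qa = q[a], qb = q[b];
    if (include[t]) {
      // log softmax, stabilised by subtracting the max exponent
      double xa = beta * qa, xb = beta * qb;
      double m = xa > xb ? xa : xb;
      double lse = m + std::log(std::exp(xa - m) + std::exp(xb - m));
      double lp = (c == a ? xa : xb) - lse;
      nll -= lp;
    }
    int r = outcome[t];
    if (r >= 0) {
      double alpha = (r == 1) ? alpha_gain : alpha_loss;
      q[c] += alpha * ((double)r - q[c]);
    }
  }
  return nll;
}

// [[Rcpp::export]]
List ql_traj_cpp(IntegerVector opt_a, IntegerVector opt_b,
                 IntegerVector choice, IntegerVector outcome,
                 double alpha_gain, double alpha_loss,
                 int n_options) {
  int n = opt_a.size();
  std::vector<double> q(n_options, 0.5);
  NumericVector q_chosen(n), q_unchosen(n), rpe(n);
  NumericMatrix q_by_option(n, n_options);
  for (int t = 0; t < n; ++t) {
    int a = opt_a[t], b = opt_b[t], c = choice[t];
    for (int j = 0; j < n_options; ++j) q_by_option(t, j) = q[j];
    int u = (c == a) ? b : a;
    q_chosen[t] = q[c];
    q_unchosen[t] = q[u];
    int r = outcome[t];
    if (r >= 0) {
      rpe[t] = (double)r - q[c];
      double alpha = (r == 1) ? alpha_gain : alpha_loss;
      q[c] += alpha * ((double)r - q[c]);
    } else {
      rpe[t] = NA_REAL;
    }
  }
  NumericVector final_q(n_options);
  for (int j = 0; j < n_options; ++j) final_q[j] = q[j];
  return List::create(_["q_chosen"] = q_chosen, _["q_unchosen"] = q_unchosen,
                      _["rpe"] = rpe, _["q_by_option"] = q_by_option,
                      _["final_q"] = final_q);
}

// Cascade of biquads in direct form II transposed. sos has one section
// per row: b0 b1 b2 a0 a1 a2, with a0 == 1.

// [[Rcpp::export]]
NumericVector sosfilt_cpp(NumericMatrix sos, NumericVector x) {
  int ns = sos.nrow(), n = x.size();
  NumericVector y = clone(x);
  for (int s = 0; s < ns; ++s) {
    double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = 0.0, z2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double xi = y[i];
      double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}
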