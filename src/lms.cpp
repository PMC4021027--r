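#include <Rcpp.h>
using namespace Rcpp;

// LMS recursion with a tapped-delay-line input:
//   y(n) = w(n)' u(n),  e(n) = d(n) - y(n),  w(n+1) = w(n) + mu e(n) u(n)
// where u(n) = [u(n), u(n-1), ..., u(n-L+1)] with zero pre-history.
// With normalize = true the step is
//   mu / (max(L * P(n), ||u(n)||^2) + delta),
// where P(n) is an exponentially smoothed input-power estimate:
//   P(n) = (1 - beta) P(n-1) + beta u(n)^2,  P(0) = p_init.
// The smoothed floor keeps the step bounded when a periodic input
// crosses zero; the instantaneous term retains the classic NLMS
// stability guarantee (mu <= 1) during input bursts.
// Also accumulates the running average of w over the pass (Polyak
// averaging), returned as w_avg. mu = 0 freezes the taps at w_init.
// [[Rcpp::export]]
List lms_core(NumericVector u, NumericVector d, int order, double mu,
              bool normalize, NumericVector w_init, double delta,
              double beta, double p_init, bool keep_trace) {
  const int n = u.size();
  NumericVector y(n), e(n);
  std::vector<double> w(w_init.begin(), w_init.end());
  std::vector<double> wsum(order, 0.0);
  std::vector<double> buf(order, 0.0); // buf[k] = u(i - k)
  NumericMatrix trace = keep_trace ? NumericMatrix(order, n)
                                   : NumericMatrix(0, 0);

  double w0 = 0.0;
  for (int k = 0; k < order; ++k) w0 += w[k] * w[k];
  const double cap2 = 1e12 * std::max(1.0, w0); // ||w|| > 1e6 * scale
  bool diverged = false;
  double P = p_init;

  for (int i = 0; i < n; ++i) {
    for (int k = order - 1; k > 0; --k) buf[k] = buf[k - 1];
    buf[0] = u[i];

    double yi = 0.0;
    for (int k = 0; k < order; ++k) yi += w[k] * buf[k];
    y[i] = yi;
    const double ei = d[i] - yi;
    e[i] = ei;

    double step = mu;
    if (normalize) {
      P = (1.0 - beta) * P + beta * u[i] * u[i];
      double p_inst = 0.0;
      for (int k = 0; k < order; ++k) p_inst += buf[k] * buf[k];
      step = mu / (std::max(order * P, p_inst) + delta);
    }
    double wn = 0.0;
    for (int k = 0; k < order; ++k) {
      w[k] += step * ei * buf[k];
      wsum[k] += w[k];
      wn += w[k] * w[k];
    }
    if (wn > cap2) diverged = true;
    if (keep_trace)
      for (int k = 0; k < order; ++k) trace(k, i) = w[k];
  }

  NumericVector wavg(order);
  for (int k = 0; k < order; ++k) wavg[k] = wsum[k] / n;

  return List::create(_["y"] = y, _["e"] = e,
                      _["w_final"] = NumericVector(w.begin(), w.end()),
                      _["w_avg"] = wavg, _["w_trace"] = trace,
                      _["diverged"] = diverged);
}
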