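#include <Rcpp.h>
using namespace Rcpp;

// Online value-RNN training loop over a concatenated observation stream.
//
// Dynamics: x(t+1) = sigmoid(A x(t) + B o(t)); v(t) = w.x(t);
// delta(t) = r(t) + gamma v(t+1) - v(t).
// Per time-step order: RNN step -> delta -> value-weight update (clamped
// non-negative) -> value-weight decay (toward zero) -> recurrent/feedforward
// update with random feedback gains c and the "monotonic + saturation"
// postsynaptic factor: x(1-x) for x <= 0.5, constant 0.25 for x > 0.5.
// The A/B update for delta(t) uses presynaptic activities at t-1 and
// postsynaptic activity at t, so it starts from the second step.
//
// Learning is continuous across trials including ITIs. Inner loops run
// column-major over raw pointers; no RNG is used here (all initial weights
// and the stream are drawn by the caller in R).
// [[Rcpp::export]]
List ovrnn_core(NumericMatrix A0, NumericMatrix B0, NumericVector w0,
                NumericVector c, NumericVector x0, NumericMatrix obs,
                NumericVector rew, double gamma, double a_value,
                double a_rnn, double dr) {
  const int N = A0.nrow();           // recurrent units
  const int K = B0.ncol();           // observation units
  const int T = obs.nrow();          // stream length
  NumericMatrix A = clone(A0), B = clone(B0);
  NumericVector w = clone(w0);
  double *a = A.begin(), *b = B.begin(), *wp = w.begin();
  const double *op = obs.begin();    // T x K, column-major
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> x_prev(N, 0.0), x_new(N, 0.0), z(N, 0.0),
      o_prev(K, 0.0), gain(N, 0.0);
  NumericVector delta(T - 1), value(T - 1);

  for (int t = 0; t < T - 1; ++t) {
    // z = A x(t) + B o(t), column-major accumulation
    std::fill(z.begin(), z.end(), 0.0);
    for (int j = 0; j < N; ++j) {
      const double xj = x[j];
      if (xj == 0.0) continue;
      const double *col = a + (size_t)j * N;
      for (int i = 0; i < N; ++i) z[i] += col[i] * xj;
    }
    for (int k = 0; k < K; ++k) {
      const double ok = op[(size_t)k * T + t];
      if (ok == 0.0) continue;
      const double *col = b + (size_t)k * N;
      for (int i = 0; i < N; ++i) z[i] += col[i] * ok;
    }
    double v_t = 0.0, v_t1 = 0.0;
    for (int i = 0; i < N; ++i) {
      x_new[i] = 1.0 / (1.0 + std::exp(-z[i]));
      v_t += wp[i] * x[i];
      v_t1 += wp[i] * x_new[i];
    }
    const double d = rew[t] + gamma * v_t1 - v_t;
    delta[t] = d;
    value[t] = v_t;
    // value-weight update with x(t), then decay toward zero
    for (int i = 0; i < N; ++i) {
      double wi = wp[i] + a_value * d * x[i];
      if (wi < 0.0) wi = 0.0;
      wp[i] = (1.0 - dr) * wi;
    }
    // recurrent/feedforward update with (t-1, t) activities
    if (t > 0) {
      for (int i = 0; i < N; ++i) {
        const double post = (x[i] <= 0.5) ? x[i] * (1.0 - x[i]) : 0.25;
        gain[i] = a_rnn * d * post * c[i];
      }
      for (int j = 0; j < N; ++j) {
        const double xp = x_prev[j];
        if (xp == 0.0) continue;
        double *col = a + (size_t)j * N;
        for (int i = 0; i < N; ++i) col[i] += gain[i] * xp;
      }
      for (int k = 0; k < K; ++k) {
        const double okp = o_prev[k];
        if (okp == 0.0) continue;
        double *col = b + (size_t)k * N;
        for (int i = 0; i < N; ++i) col[i] += gain[i] * okp;
      }
    }
    x_prev = x;
    for (int k = 0; k < K; ++k) o_prev[k] = op[(size_t)k * T + t];
    x = x_new;
  }
  return List::create(
    _["delta"] = delta, _["value"] = value,
    _["A"] = A, _["B"] = B, _["w"] = w,
    _["x"] = NumericVector(x.begin(), x.end()));
}
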