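// Euler integration of the delayed linear rate model with output noise:
//
//   y_i(t) = r_i(t) + x_i(t)
//   r_i(t) = sum_c  integral  kern_c(t - s) y_{j(c)}(s) ds
//
// where the per-connection kernels kern_c already contain the anatomical
// weight, the population impulse response and the (delay-distribution
// averaged) delay kernel, sampled on the simulation grid. The convolution
// uses lags >= 1 step, so the update is explicit; x_i is white noise of
// spectral density D_ii discretised as sd_i = sqrt(D_ii / dt).

#include <Rcpp.h>
using namespace Rcpp;

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_simulate_rates(NumericMatrix kern, IntegerVector conn_i,
                                 IntegerVector conn_j, int n_pop,
                                 NumericVector noise_sd, double dt,
                                 int n_steps) {
    int n_conn = kern.ncol();
    int n_taps = kern.nrow();
    if (conn_i.size() != n_conn || conn_j.size() != n_conn)
        stop("connection index length mismatch");
    NumericMatrix y(n_steps, n_pop);
    std::vector<double> r(n_pop);
    for (int t = 0; t < n_steps; ++t) {
        std::fill(r.begin(), r.end(), 0.0);
        for (int c = 0; c < n_conn; ++c) {
            int i = conn_i[c], j = conn_j[c];
            const double* kc = &kern(0, c);
            const double* yj = &y(0, j);
            int mmax = std::min(n_taps, t);  // lags 1 .. t
            double acc = 0.0;
            for (int m = 0; m < mmax; ++m) acc += kc[m] * yj[t - 1 - m];
            r[i] += acc * dt;
        }
        for (int i = 0; i < n_pop; ++i)
            y(t, i) = r[i] + noise_sd[i] * norm_rand();
    }
    return y;
}
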