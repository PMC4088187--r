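#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward pass. obs is 0-based; returns log-likelihood of the
// sequence under (pi, A, B). Emission columns index symbols.
// [[Rcpp::export]]
double hmm_loglik_cpp(NumericVector pi, NumericMatrix A, NumericMatrix B,
                      IntegerVector obs) {
  const int k = pi.size();
  const int T = obs.size();
  if (T == 0) return 0.0;
  std::vector<double> alpha(k), tmp(k);
  double ll = 0.0, c = 0.0;
  for (int i = 0; i < k; ++i) { alpha[i] = pi[i] * B(i, obs[0]); c += alpha[i]; }
  if (c <= 0.0) return R_NegInf;
  for (int i = 0; i < k; ++i) alpha[i] /= c;
  ll = std::log(c);
  for (int t = 1; t < T; ++t) {
    c = 0.0;
    for (int j = 0; j < k; ++j) {
      double s = 0.0;
      for (int i = 0; i < k; ++i) s += alpha[i] * A(i, j);
      tmp[j] = s * B(j, obs[t]);
      c += tmp[j];
    }
    if (c <= 0.0) return R_NegInf;
    for (int j = 0; j < k; ++j) alpha[j] = tmp[j] / c;
    ll += std::log(c);
  }
  return ll;
}

// Baum-Welch EM for a discrete-emission HMM over multiple sequences.
// obs holds all sequences concatenated (0-based symbols); lengths gives the
// per-sequence lengths. Rows of A and B are renormalised each M-step with a
// tiny floor so that states that momentarily lose all mass stay valid.
// [[Rcpp::export]]
List hmm_baum_welch_cpp(NumericVector pi0, NumericMatrix A0, NumericMatrix B0,
                        IntegerVector obs, IntegerVector lengths,
                        int max_iter, double tol) {
  const int k = pi0.size();
  const int M = B0.ncol();
  const int S = lengths.size();
  const double floor_eps = 1e-300;

  NumericVector pi = clone(pi0);
  NumericMatrix A = clone(A0);
  NumericMatrix B = clone(B0);

  int Tmax = 0;
  for (int s = 0; s < S; ++s) if (lengths[s] > Tmax) Tmax = lengths[s];
  std::vector<double> alpha((size_t)Tmax * k), beta((size_t)Tmax * k),
      cs(Tmax), gamma(k);

  std::vector<double> ll_trace;
  double prev_ll = R_NegInf, ll = R_NegInf;

  for (int iter = 0; iter < max_iter; ++iter) {
    std::vector<double> pi_acc(k, 0.0), A_acc((size_t)k * k, 0.0),
        B_acc((size_t)k * M, 0.0);
    ll = 0.0;
    int off = 0;
    bool dead = false;
    for (int s = 0; s < S; ++s) {
      const int T = lengths[s];
      if (T == 0) continue;
      // forward (scaled)
      double c = 0.0;
      for (int i = 0; i < k; ++i) {
        alpha[i] = pi[i] * B(i, obs[off]);
        c += alpha[i];
      }
      if (c <= floor_eps) { dead = true; break; }
      for (int i = 0; i < k; ++i) alpha[i] /= c;
      cs[0] = c; ll += std::log(c);
      for (int t = 1; t < T; ++t) {
        c = 0.0;
        for (int j = 0; j < k; ++j) {
          double su = 0.0;
          for (int i = 0; i < k; ++i) su += alpha[(size_t)(t - 1) * k + i] * A(i, j);
          double v = su * B(j, obs[off + t]);
          alpha[(size_t)t * k + j] = v;
          c += v;
        }
        if (c <= floor_eps) { dead = true; break; }
        for (int j = 0; j < k; ++j) alpha[(size_t)t * k + j] /= c;
        cs[t] = c; ll += std::log(c);
      }
      if (dead) break;
      // backward (same scaling)
      for (int i = 0; i < k; ++i) beta[(size_t)(T - 1) * k + i] = 1.0;
      for (int t = T - 2; t >= 0; --t) {
        for (int i = 0; i < k; ++i) {
          double su = 0.0;
          for (int j = 0; j < k; ++j)
            su += A(i, j) * B(j, obs[off + t + 1]) * beta[(size_t)(t + 1) * k + j];
          beta[(size_t)t * k + i] = su / cs[t + 1];
        }
      }
      // accumulate expected counts
      for (int t = 0; t < T; ++t) {
        double norm = 0.0;
        for (int i = 0; i < k; ++i) {
          gamma[i] = alpha[(size_t)t * k + i] * beta[(size_t)t * k + i];
          norm += gamma[i];
        }
        if (norm <= 0.0) continue;
        for (int i = 0; i < k; ++i) {
          double g = gamma[i] / norm;
          B_acc[(size_t)i * M + obs[off + t]] += g;
          if (t == 0) pi_acc[i] += g;
        }
      }
      for (int t = 0; t < T - 1; ++t) {
        for (int i = 0; i < k; ++i) {
          const double ai = alpha[(size_t)t * k + i];
          if (ai == 0.0) continue;
          for (int j = 0; j < k; ++j) {
            double x = ai * A(i, j) * B(j, obs[off + t + 1]) *
                       beta[(size_t)(t + 1) * k + j] / cs[t + 1];
            A_acc[(size_t)i * k + j] += x;
          }
        }
      }
      off += T;
    }
    if (dead) break;  // degenerate parameters; keep last valid estimates
    ll_trace.push_back(ll);
    // M-step
    double psum = 0.0;
    for (int i = 0; i < k; ++i) psum += pi_acc[i];
    if (psum > 0.0) for (int i = 0; i < k; ++i) pi[i] = pi_acc[i] / psum;
    for (int i = 0; i < k; ++i) {
      double ra = 0.0, rb = 0.0;
      for (int j = 0; j < k; ++j) ra += A_acc[(size_t)i * k + j];
      for (int m = 0; m < M; ++m) rb += B_acc[(size_t)i * M + m];
      if (ra > 0.0) for (int j = 0; j < k; ++j) A(i, j) = A_acc[(size_t)i * k + j] / ra;
      if (rb > 0.0) for (int m = 0; m < M; ++m) B(i, m) = B_acc[(size_t)i * M + m] / rb;
    }
    if (iter > 0 && std::abs(ll - prev_ll) < tol) break;
    prev_ll = ll;
  }

  return List::create(_["pi"] = pi, _["A"] = A, _["B"] = B,
                      _["loglik"] = ll, _["ll_trace"] = wrap(ll_trace));
}
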