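#include <Rcpp.h>
using namespace Rcpp;

// One explicit-Euler pass over the coupled EPG-rate / ER-weight system.
//
// Rate update (per neuron n, circular indexing):
//   tau df_n/dt = -f_n + [ alpha f_n + D (f_{n-1} + f_{n+1})
//                          + (v/v_rel) * 0.5 * (f_{n+1} - f_{n-1})
//                          - beta sum_l f_l + I_{n,1} + I_{n,2} + drive ]_+
// with inhibitory cue input I_k = -W_k g_k and ER activity
//   g_{k,m} = eps + A_k exp[kappa_k (cos(theta_k - theta_m) - 1)],
//   eps ~ uniform(0, noise_bound), drawn independently per neuron and step.
//
// Weight update (postsynaptically gated, velocity gated):
//   dW_{k,nm}/dt = eta |v| f_n (w_max (1 - g_{k,m}/g0) - W_{k,nm})
// followed by clipping at zero when clip is true.
//
// Uses R's RNG stream (so set.seed() in R governs the ER noise draws).
//
// [[Rcpp::export]]
List sim_core(NumericVector v,            // angular velocity per step (rad/s)
              NumericMatrix theta_in,     // T x K tuning argument per cue (rad)
              NumericMatrix A,            // T x K ER amplitude per step
              NumericVector kappa_cue,    // K
              NumericMatrix theta_pref,   // M x K preferred directions
              double noise_bound,         // b_ER * sum(f_ss); 0 disables noise
              double tau, double alpha, double D, double beta,
              double v_rel, double drive, double dt,
              double eta, double w_max, double g0, bool clip,
              NumericVector f0, List W0,
              int record_every, int w_record_every) {
  const int T = v.size();
  const int K = A.ncol();
  const int N = f0.size();
  const int M = theta_pref.nrow();
  if (theta_in.nrow() != T || A.nrow() != T)
    stop("schedule arrays must have one row per time step");
  if (W0.size() != K)
    stop("need one initial weight matrix per cue");

  std::vector<std::vector<double>> W(K);
  for (int k = 0; k < K; ++k) {
    NumericMatrix Wk = W0[k];
    if (Wk.nrow() != N || Wk.ncol() != M) stop("weight matrix dimension mismatch");
    W[k].assign(Wk.begin(), Wk.end());  // column-major N x M
  }

  std::vector<double> f(f0.begin(), f0.end());
  std::vector<double> fnew(N), g(K * M), I(N);

  const int n_rec  = record_every > 0 ? T / record_every : 0;
  const int n_wrec = w_record_every > 0 ? T / w_record_every : 0;
  NumericMatrix f_rec(n_rec, N);
  NumericVector t_rec(n_rec), t_wrec(n_wrec);
  List W_rec(K);
  for (int k = 0; k < K; ++k)
    W_rec[k] = NumericVector(Dimension(N, M, std::max(n_wrec, 0)));

  int ir = 0, iw = 0;
  for (int t = 0; t < T; ++t) {
    // ER activity for this step
    for (int k = 0; k < K; ++k) {
      const double Ak = A(t, k), th = theta_in(t, k), kap = kappa_cue[k];
      for (int m = 0; m < M; ++m) {
        double eps = noise_bound > 0.0 ? unif_rand() * noise_bound : 0.0;
        g[k * M + m] = eps + Ak * std::exp(kap * (std::cos(th - theta_pref(m, k)) - 1.0));
      }
    }
    // inhibitory cue input I_n = -sum_k (W_k g_k)_n
    std::fill(I.begin(), I.end(), 0.0);
    for (int k = 0; k < K; ++k) {
      const double* Wk = W[k].data();
      for (int m = 0; m < M; ++m) {
        const double gm = g[k * M + m];
        if (gm == 0.0) continue;
        const double* col = Wk + (size_t)m * N;
        for (int n = 0; n < N; ++n) I[n] -= col[n] * gm;
      }
    }
    // rate update (synchronous, from the old state)
    double sumf = 0.0;
    for (int n = 0; n < N; ++n) sumf += f[n];
    const double vt = v[t], adv = 0.5 * vt / v_rel;
    for (int n = 0; n < N; ++n) {
      const double fm = f[(n + N - 1) % N], fp = f[(n + 1) % N];
      double inp = alpha * f[n] + D * (fm + fp) + adv * (fp - fm)
                   - beta * sumf + I[n] + drive;
      if (inp < 0.0) inp = 0.0;
      fnew[n] = f[n] + dt / tau * (-f[n] + inp);
      if (!std::isfinite(fnew[n])) stop("EPG rates became non-finite (blow-up)");
    }
    // weight update from the pre-step rates, then clip
    const double coef = eta * std::fabs(vt) * dt;
    if (coef > 0.0) {
      for (int k = 0; k < K; ++k) {
        double* Wk = W[k].data();
        for (int m = 0; m < M; ++m) {
          const double target = w_max * (1.0 - g[k * M + m] / g0);
          double* col = Wk + (size_t)m * N;
          for (int n = 0; n < N; ++n) {
            double w = col[n] + coef * f[n] * (target - col[n]);
            if (clip && w < 0.0) w = 0.0;
            col[n] = w;
          }
        }
      }
    }
    std::copy(fnew.begin(), fnew.end(), f.begin());

    if (record_every > 0 && (t + 1) % record_every == 0 && ir < n_rec) {
      for (int n = 0; n < N; ++n) f_rec(ir, n) = f[n];
      t_rec[ir] = (t + 1) * dt;
      ++ir;
    }
    if (w_record_every > 0 && (t + 1) % w_record_every == 0 && iw < n_wrec) {
      for (int k = 0; k < K; ++k) {
        NumericVector Wr = W_rec[k];
        std::copy(W[k].begin(), W[k].end(), Wr.begin() + (size_t)iw * N * M);
      }
      t_wrec[iw] = (t + 1) * dt;
      ++iw;
    }
  }

  List W_final(K);
  for (int k = 0; k < K; ++k) {
    NumericMatrix Wk(N, M);
    std::copy(W[k].begin(), W[k].end(), Wk.begin());
    W_final[k] = Wk;
  }
  return List::create(_["f_rec"] = f_rec, _["t_rec"] = t_rec,
                      _["W_rec"] = W_rec, _["t_wrec"] = t_wrec,
                      _["f_final"] = NumericVector(f.begin(), f.end()),
                      _["W_final"] = W_final);
}
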