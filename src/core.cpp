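#include <Rcpp.h>
using namespace Rcpp;

// Explicit Euler integration of the slow-learning mean-field weight dynamics
// in rescaled time s = lambda * t:
//   dw/ds = F_d + w_bar * F_0 + w_tilde * F_1
// with
//   F_d = w (D/N) (f+ K+(d) - f- K-(d))          (finite-N delay atom)
//   F_0 = D^2 (Kbar+ f+ - Kbar- f-)              (Kbar = 1, normalized kernels)
//   F_1 = D^2 (g^2/2) (Kt+ f+ cos(phi - Om+ - nu d - psi)
//                      - Kt- f- cos(phi - Om- - nu d - psi))
// Weights are clamped to [0, 1] after every step. State is recorded every
// `record_every` steps, including step 0.
// [[Rcpp::export]]
List mf_euler_core(NumericVector w0, NumericVector phases,
                   int n_steps, double ds,
                   double D, double gamma_mod, double nu, double delay,
                   double mu, double alpha,
                   double kt_plus, double om_plus,
                   double kt_minus, double om_minus,
                   double kp_d, double km_d,
                   bool include_fd, int record_every, bool snapshots) {
  const int N = w0.size();
  std::vector<double> w(w0.begin(), w0.end());
  const int n_rec = n_steps / record_every + 1;
  NumericVector rec_t(n_rec), rec_wb(n_rec), rec_wt(n_rec), rec_psi(n_rec);
  NumericMatrix snap(snapshots ? n_rec : 1, snapshots ? N : 1);
  int irec = 0;

  const double nud = nu * delay;
  const double c1 = D * D;
  const double c2 = D * D * gamma_mod * gamma_mod / 2.0;
  const double cfd = D / (double)N;

  for (int step = 0; step <= n_steps; ++step) {
    double wb = 0.0, zr = 0.0, zi = 0.0;
    for (int k = 0; k < N; ++k) {
      wb += w[k];
      zr += w[k] * std::cos(phases[k]);
      zi += w[k] * std::sin(phases[k]);
    }
    wb /= N; zr /= N; zi /= N;
    double wt = std::sqrt(zr * zr + zi * zi);
    double psi = (wt > 1e-12) ? std::atan2(zi, zr) : 0.0;

    if (step % record_every == 0) {
      rec_t[irec] = step * ds;
      rec_wb[irec] = wb;
      rec_wt[irec] = wt;
      rec_psi[irec] = (wt > 1e-12) ? psi : NA_REAL;
      if (snapshots)
        for (int k = 0; k < N; ++k) snap(irec, k) = w[k];
      ++irec;
    }
    if (step == n_steps) break;

    for (int k = 0; k < N; ++k) {
      double fp = (mu == 0.0) ? 1.0 : std::pow(1.0 - w[k], mu);
      double fm = (mu == 0.0) ? alpha : alpha * std::pow(w[k], mu);
      double F0 = c1 * (fp - fm);
      double F1 = c2 * (kt_plus * fp * std::cos(phases[k] - om_plus - nud - psi)
                        - kt_minus * fm * std::cos(phases[k] - om_minus - nud - psi));
      double Fd = include_fd ? w[k] * cfd * (fp * kp_d - fm * km_d) : 0.0;
      double wn = w[k] + ds * (Fd + wb * F0 + wt * F1);
      if (!std::isfinite(wn))
        stop("non-finite weight at step %d, synapse %d", step + 1, k + 1);
      w[k] = std::min(1.0, std::max(0.0, wn));
    }
  }

  NumericVector w_final(w.begin(), w.end());
  List out = List::create(_["time"] = rec_t, _["w_bar"] = rec_wb,
                          _["w_tilde"] = rec_wt, _["psi"] = rec_psi,
                          _["w_final"] = w_final);
  if (snapshots) out["snapshots"] = snap;
  return out;
}

// All-pairs kernel sums between each pre-synaptic train and the post train,
// truncated at |dt| > trunc. Returns an n_neurons x 2 matrix: column 0 the
// summed K+(dt) over pairs, column 1 the summed K-(dt). dt = t_post - t_pre.
// Pre spike times are passed concatenated and sorted within neuron, with
// 1-based neuron ids.
// [[Rcpp::export]]
NumericMatrix stdp_pair_sums(NumericVector pre_times, IntegerVector pre_id,
                             int n_neurons, NumericVector post_times,
                             double tau_plus, double tau_minus,
                             bool symmetric, double trunc) {
  NumericMatrix out(n_neurons, 2);
  const int n_post = post_times.size();
  const double gp = 1.0 / (tau_plus * std::sqrt(2.0 * M_PI));
  const double gm = 1.0 / (tau_minus * std::sqrt(2.0 * M_PI));
  for (int i = 0; i < pre_times.size(); ++i) {
    const double tp = pre_times[i];
    const int k = pre_id[i] - 1;
    // post spikes within [tp - trunc, tp + trunc]
    int lo = std::lower_bound(post_times.begin(), post_times.end(), tp - trunc)
             - post_times.begin();
    for (int j = lo; j < n_post && post_times[j] <= tp + trunc; ++j) {
      const double dt = post_times[j] - tp;
      if (symmetric) {
        out(k, 0) += gp * std::exp(-0.5 * dt * dt / (tau_plus * tau_plus));
        out(k, 1) += gm * std::exp(-0.5 * dt * dt / (tau_minus * tau_minus));
      } else {
        if (dt > 0)      out(k, 0) += std::exp(-dt / tau_plus) / tau_plus;
        else if (dt < 0) out(k, 1) += std::exp(dt / tau_minus) / tau_minus;
      }
    }
  }
  return out;
}

// Full event-level spiking STDP run. Same scheme as the R-level composition
// (thinned inhomogeneous Poisson thalamic trains, linear-Poisson downstream
// thinning, batched all-pairs STDP with exact cross-window bookkeeping) in
// one compiled loop so the slow-learning regime (small lambda, long real
// time) stays affordable. Draws from R's RNG stream, so results are
// reproducible under set.seed().
// [[Rcpp::export]]
List spiking_run_core(NumericVector w0, NumericVector phases,
                      double D, double gamma_mod, double nu, double delay,
                      double tau_plus, double tau_minus, double mu,
                      double alpha, double lambda, bool symmetric,
                      int n_windows, double t_window, double trunc) {
  const int N = w0.size();
  std::vector<double> w(w0.begin(), w0.end());
  NumericVector rec_t(n_windows + 1), rec_wb(n_windows + 1),
      rec_wt(n_windows + 1), rec_psi(n_windows + 1);
  std::vector<double> cph(N), sph(N);
  for (int k = 0; k < N; ++k) { cph[k] = std::cos(phases[k]); sph[k] = std::sin(phases[k]); }

  auto record = [&](int i) {
    double wb = 0, zr = 0, zi = 0;
    for (int k = 0; k < N; ++k) { wb += w[k]; zr += w[k] * cph[k]; zi += w[k] * sph[k]; }
    wb /= N; zr /= N; zi /= N;
    double wt = std::sqrt(zr * zr + zi * zi);
    rec_t[i] = i * lambda * t_window;
    rec_wb[i] = wb; rec_wt[i] = wt;
    rec_psi[i] = (wt > 1e-12) ? std::atan2(zi, zr) : NA_REAL;
  };
  record(0);

  const double bound = D * (1.0 + gamma_mod);
  std::vector<std::vector<double>> pre(N), tail_pre(N);
  std::vector<double> post, tail_post;
  std::vector<double> sum_p(N), sum_m(N);
  const double gp = 1.0 / (tau_plus * std::sqrt(2.0 * M_PI));
  const double gm = 1.0 / (tau_minus * std::sqrt(2.0 * M_PI));

  // all-pairs kernel sums of one pre train against the post train,
  // restricted to pairs whose LATER spike lies at or after t_min
  auto accum = [&](const std::vector<double>& pk, const std::vector<double>& po,
                   double t_min, double& sp, double& sm) {
    std::size_t lo = 0;
    for (std::size_t i = 0; i < pk.size(); ++i) {
      const double tp = pk[i];
      while (lo < po.size() && po[lo] < tp - trunc) ++lo;
      for (std::size_t j = lo; j < po.size() && po[j] <= tp + trunc; ++j) {
        const double dt = po[j] - tp;
        if (std::max(tp, po[j]) < t_min) continue;  // counted last window
        if (symmetric) {
          sp += gp * std::exp(-0.5 * dt * dt / (tau_plus * tau_plus));
          sm += gm * std::exp(-0.5 * dt * dt / (tau_minus * tau_minus));
        } else if (dt > 0) {
          sp += std::exp(-dt / tau_plus) / tau_plus;
        } else if (dt < 0) {
          sm += std::exp(dt / tau_minus) / tau_minus;
        }
      }
    }
  };

  for (int iw = 0; iw < n_windows; ++iw) {
    const double t0 = iw * t_window;
    post.clear();
    for (int k = 0; k < N; ++k) {
      pre[k].clear();
      int n_prop = (int)R::rpois(bound * t_window);
      for (int i = 0; i < n_prop; ++i)
        pre[k].push_back(t0 + R::runif(0.0, t_window));
      std::sort(pre[k].begin(), pre[k].end());
      std::size_t m = 0;
      for (std::size_t i = 0; i < pre[k].size(); ++i) {
        const double t = pre[k][i];
        if (R::unif_rand() <
            (1.0 + gamma_mod * std::cos(nu * t - phases[k])) / (1.0 + gamma_mod)) {
          pre[k][m++] = t;
        }
      }
      pre[k].resize(m);
      for (std::size_t i = 0; i < m; ++i)
        if (R::unif_rand() < w[k] / N) post.push_back(pre[k][i] + delay);
    }
    std::sort(post.begin(), post.end());

    // merge the carried tails so boundary-straddling pairs count once
    std::vector<double> post_all(tail_post);
    post_all.insert(post_all.end(), post.begin(), post.end());
    for (int k = 0; k < N; ++k) {
      sum_p[k] = 0.0; sum_m[k] = 0.0;
      std::vector<double> pre_all(tail_pre[k]);
      pre_all.insert(pre_all.end(), pre[k].begin(), pre[k].end());
      accum(pre_all, post_all, t0, sum_p[k], sum_m[k]);
    }

    for (int k = 0; k < N; ++k) {
      const double fp = (mu == 0.0) ? 1.0 : std::pow(1.0 - w[k], mu);
      const double fm = (mu == 0.0) ? alpha : alpha * std::pow(w[k], mu);
      w[k] = std::min(1.0, std::max(0.0, w[k] + lambda * (fp * sum_p[k] - fm * sum_m[k])));
    }
    record(iw + 1);

    const double cut = t0 + t_window - trunc;
    for (int k = 0; k < N; ++k) {
      tail_pre[k].assign(
          std::lower_bound(pre[k].begin(), pre[k].end(), cut), pre[k].end());
    }
    tail_post.assign(
        std::lower_bound(post.begin(), post.end(), cut), post.end());
  }

  return List::create(_["time"] = rec_t, _["w_bar"] = rec_wb,
                      _["w_tilde"] = rec_wt, _["psi"] = rec_psi,
                      _["w_final"] = NumericVector(w.begin(), w.end()));
}
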