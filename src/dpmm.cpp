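#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Collapsed Gibbs sampler for a Dirichlet-process mixture of independent
// Bernoulli features with Beta(1,1) priors. Cluster parameters are
// marginalised: an existing cluster k attracts patient x with weight
// n_k * prod_j ((c_kj + 1)/(n_k + 2))^x_j * ((n_k - c_kj + 1)/(n_k + 2))^(1-x_j)
// and a new cluster with weight alpha * (1/2)^d. The concentration alpha is
// resampled by the standard Beta auxiliary-variable (Gamma-mixture) update.
// Uses R's RNG, so results are reproducible under set.seed().

struct Cluster {
  int n = 0;
  std::vector<int> c;            // per-feature presence counts
  std::vector<double> lp1, lp0;  // cached log predictive probs
  bool fresh = false;
  explicit Cluster(int d) : c(d, 0), lp1(d), lp0(d) {}
  void refresh() {
    const double denom = std::log(n + 2.0);
    for (size_t j = 0; j < c.size(); ++j) {
      lp1[j] = std::log(c[j] + 1.0) - denom;
      lp0[j] = std::log(n - c[j] + 1.0) - denom;
    }
    fresh = true;
  }
};

static int sample_index(const std::vector<double>& logw) {
  double m = logw[0];
  for (double w : logw) if (w > m) m = w;
  double tot = 0.0;
  std::vector<double> w(logw.size());
  for (size_t k = 0; k < logw.size(); ++k) { w[k] = std::exp(logw[k] - m); tot += w[k]; }
  double u = unif_rand() * tot;
  double acc = 0.0;
  for (size_t k = 0; k < logw.size(); ++k) {
    acc += w[k];
    if (u <= acc) return (int)k;
  }
  return (int)logw.size() - 1;
}

// [[Rcpp::export(name = ".dpmm_gibbs_cpp")]]
List dpmm_gibbs_cpp(IntegerMatrix X, IntegerVector z_init,
                    int iterations, int burn_in, int thin,
                    double alpha_a, double alpha_b, double alpha_init,
                    bool resample_alpha, bool prior_only) {
  const int n = X.nrow(), d = X.ncol();
  const double lhalf = std::log(0.5);
  double alpha = alpha_init;

  // z_init: 0-based compact cluster labels (0..K0-1)
  std::vector<int> z(n);
  int K0 = 0;
  for (int i = 0; i < n; ++i) {
    z[i] = z_init[i];
    if (z[i] + 1 > K0) K0 = z[i] + 1;
  }
  std::vector<Cluster> clusters(K0, Cluster(d));
  for (int i = 0; i < n; ++i) {
    Cluster& cl = clusters[z[i]];
    cl.n += 1;
    for (int j = 0; j < d; ++j) cl.c[j] += X(i, j);
  }

  int n_keep = 0;
  for (int it = burn_in; it < iterations; ++it)
    if ((it - burn_in) % thin == 0) ++n_keep;
  IntegerMatrix kept(n_keep, n);
  NumericVector kept_alpha(n_keep);
  IntegerVector kept_k(n_keep);
  IntegerVector trace_k(iterations);

  std::vector<double> logw;
  int keep_row = 0;
  for (int it = 0; it < iterations; ++it) {
    for (int i = 0; i < n; ++i) {
      // remove patient i from its cluster
      Cluster& cur = clusters[z[i]];
      cur.n -= 1;
      for (int j = 0; j < d; ++j) cur.c[j] -= X(i, j);
      cur.fresh = false;
      if (cur.n == 0) {
        int last = (int)clusters.size() - 1;
        if (z[i] != last) {
          clusters[z[i]] = clusters[last];
          for (int t = 0; t < n; ++t) if (z[t] == last) z[t] = z[i];
        }
        clusters.pop_back();
      }
      const int K = (int)clusters.size();
      logw.assign(K + 1, 0.0);
      for (int k = 0; k < K; ++k) {
        Cluster& cl = clusters[k];
        double lw = std::log((double)cl.n);
        if (!prior_only) {
          if (!cl.fresh) cl.refresh();
          for (int j = 0; j < d; ++j)
            lw += X(i, j) ? cl.lp1[j] : cl.lp0[j];
        }
        logw[k] = lw;
      }
      logw[K] = std::log(alpha) + (prior_only ? 0.0 : d * lhalf);
      int pick = sample_index(logw);
      if (pick == K) {
        clusters.emplace_back(d);
      }
      Cluster& dst = clusters[pick];
      dst.n += 1;
      for (int j = 0; j < d; ++j) dst.c[j] += X(i, j);
      dst.fresh = false;
      z[i] = pick;
    }
    const int K = (int)clusters.size();
    trace_k[it] = K;
    if (resample_alpha) {
      // Escobar-West auxiliary update: eta ~ Beta(alpha+1, n), then a
      // two-component Gamma mixture for alpha | eta, K
      double eta = R::rbeta(alpha + 1.0, (double)n);
      double rate = alpha_b - std::log(eta);
      double odds = (alpha_a + K - 1.0) / ((double)n * rate);
      double shape = (unif_rand() < odds / (1.0 + odds))
                       ? alpha_a + K : alpha_a + K - 1.0;
      alpha = R::rgamma(shape, 1.0 / rate);
      if (alpha < 1e-8) alpha = 1e-8;
    }
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (int i = 0; i < n; ++i) kept(keep_row, i) = z[i] + 1;
      kept_alpha[keep_row] = alpha;
      kept_k[keep_row] = K;
      ++keep_row;
    }
  }
  return List::create(_["assignments"] = kept,
                      _["alpha"] = kept_alpha,
                      _["n_clusters"] = kept_k,
                      _["trace_n_clusters"] = trace_k);
}

// [[Rcpp::export(name = ".psm_cpp")]]
NumericMatrix psm_cpp(IntegerMatrix assignments) {
  const int m = assignments.nrow(), n = assignments.ncol();
  NumericMatrix psm(n, n);
  for (int s = 0; s < m; ++s)
    for (int i = 0; i < n; ++i) {
      const int zi = assignments(s, i);
      for (int j = i; j < n; ++j)
        if (assignments(s, j) == zi) psm(i, j) += 1.0;
    }
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double v = psm(i, j) / m;
      psm(i, j) = v;
      psm(j, i) = v;
    }
  return psm;
}

// Dahl's least-squares criterion: squared deviation of each sampled
// partition's co-clustering indicator from the posterior similarity matrix.
// [[Rcpp::export(name = ".dahl_scores_cpp")]]
NumericVector dahl_scores_cpp(IntegerMatrix assignments, NumericMatrix psm) {
  const int m = assignments.nrow(), n = assignments.ncol();
  NumericVector score(m);
  for (int s = 0; s < m; ++s) {
    double tot = 0.0;
    for (int i = 0; i < n; ++i) {
      const int zi = assignments(s, i);
      for (int j = i + 1; j < n; ++j) {
        double diff = (assignments(s, j) == zi ? 1.0 : 0.0) - psm(i, j);
        tot += diff * diff;
      }
    }
    score[s] = tot;
  }
  return score;
}
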