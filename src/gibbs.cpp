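#include <Rcpp.h>
using namespace Rcpp;

// Log marginal likelihood of one (module, sample-block) cell under a
// Normal-Gamma prior, from sufficient statistics (n, sum, sum of squares).
// Empty cells contribute 0 (the marginal of no data is 1).
static double cell_logml(double n, double s1, double s2,
                         double mu0, double lambda0,
                         double alpha0, double beta0) {
  if (n <= 0.0) return 0.0;
  double ybar = s1 / n;
  double ss = s2 - n * ybar * ybar;
  if (ss < 0.0) ss = 0.0; // numerical guard
  double lambda_n = lambda0 + n;
  double alpha_n = alpha0 + 0.5 * n;
  double beta_n = beta0 + 0.5 * ss +
    0.5 * lambda0 * n * (ybar - mu0) * (ybar - mu0) / lambda_n;
  return lgamma(alpha_n) - lgamma(alpha0) +
    alpha0 * std::log(beta0) - alpha_n * std::log(beta_n) +
    0.5 * (std::log(lambda0) - std::log(lambda_n)) -
    0.5 * n * std::log(2.0 * M_PI);
}

// [[Rcpp::export(name = ".ng_cell_logml")]]
double ng_cell_logml(double n, double s1, double s2,
                     double mu0, double lambda0,
                     double alpha0, double beta0) {
  return cell_logml(n, s1, s2, mu0, lambda0, alpha0, beta0);
}

// Total log score of a two-way partition: product over (module, block)
// cells of the Normal-Gamma marginal likelihood of the cell's values.
// z: gene -> module (0-based), w: K x S sample-block assignment (0-based).
// [[Rcpp::export(name = ".partition_log_score_cpp")]]
double partition_log_score_cpp(NumericMatrix X, IntegerVector z,
                               IntegerMatrix w, int K, int B,
                               double mu0, double lambda0,
                               double alpha0, double beta0) {
  int G = X.nrow(), S = X.ncol();
  std::vector<double> cnt(K * B, 0.0), s1(K * B, 0.0), s2(K * B, 0.0);
  for (int g = 0; g < G; ++g) {
    int m = z[g];
    for (int s = 0; s < S; ++s) {
      int b = w(m, s);
      double v = X(g, s);
      cnt[m * B + b] += 1.0;
      s1[m * B + b] += v;
      s2[m * B + b] += v * v;
    }
  }
  double total = 0.0;
  for (int i = 0; i < K * B; ++i)
    total += cell_logml(cnt[i], s1[i], s2[i], mu0, lambda0, alpha0, beta0);
  return total;
}

static int sample_from_logw(const std::vector<double>& logw) {
  int n = logw.size();
  double mx = logw[0];
  for (int i = 1; i < n; ++i) if (logw[i] > mx) mx = logw[i];
  std::vector<double> p(n);
  double tot = 0.0;
  for (int i = 0; i < n; ++i) { p[i] = std::exp(logw[i] - mx); tot += p[i]; }
  double u = R::runif(0.0, tot), acc = 0.0;
  for (int i = 0; i < n; ++i) { acc += p[i]; if (u <= acc) return i; }
  return n - 1;
}

// One Gibbs chain over gene-module and sample-block assignments.
// Returns the best-scoring sweep (assignments + score) and the per-sweep
// best-so-far log-score trace.
// [[Rcpp::export(name = ".gibbs_chain_cpp")]]
List gibbs_chain_cpp(NumericMatrix X, int K, int B, int n_iter,
                     double mu0, double lambda0,
                     double alpha0, double beta0) {
  int G = X.nrow(), S = X.ncol();
  // random initialisation from R's RNG
  IntegerVector z(G);
  for (int g = 0; g < G; ++g) z[g] = (int)std::floor(R::runif(0.0, 1.0) * K);
  IntegerMatrix w(K, S);
  for (int m = 0; m < K; ++m)
    for (int s = 0; s < S; ++s)
      w(m, s) = (int)std::floor(R::runif(0.0, 1.0) * B);

  // sufficient statistics per (module, block)
  std::vector<double> cnt(K * B), s1(K * B), s2(K * B);
  std::vector<double> bsize(K * B); // samples per block
  auto rebuild = [&]() {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    std::fill(s1.begin(), s1.end(), 0.0);
    std::fill(s2.begin(), s2.end(), 0.0);
    std::fill(bsize.begin(), bsize.end(), 0.0);
    for (int m = 0; m < K; ++m)
      for (int s = 0; s < S; ++s) bsize[m * B + w(m, s)] += 1.0;
    for (int g = 0; g < G; ++g) {
      int m = z[g];
      for (int s = 0; s < S; ++s) {
        int b = w(m, s);
        double v = X(g, s);
        cnt[m * B + b] += 1.0; s1[m * B + b] += v; s2[m * B + b] += v * v;
      }
    }
  };
  rebuild();

  auto total_score = [&]() {
    double t = 0.0;
    for (int i = 0; i < K * B; ++i)
      t += cell_logml(cnt[i], s1[i], s2[i], mu0, lambda0, alpha0, beta0);
    return t;
  };

  double best = R_NegInf;
  IntegerVector best_z(G);
  IntegerMatrix best_w(K, S);
  NumericVector trace(n_iter);

  std::vector<double> gs1(K * B), gs2(K * B); // gene row sums per module layout
  std::vector<double> logw_m(K), logw_b(B);
  std::vector<double> c1(B), c2(B);

  for (int it = 0; it < n_iter; ++it) {
    // --- gene reassignment sweep ---
    for (int g = 0; g < G; ++g) {
      std::fill(gs1.begin(), gs1.end(), 0.0);
      std::fill(gs2.begin(), gs2.end(), 0.0);
      for (int m = 0; m < K; ++m)
        for (int s = 0; s < S; ++s) {
          int b = w(m, s);
          double v = X(g, s);
          gs1[m * B + b] += v; gs2[m * B + b] += v * v;
        }
      int mold = z[g];
      for (int b = 0; b < B; ++b) {
        cnt[mold * B + b] -= bsize[mold * B + b];
        s1[mold * B + b] -= gs1[mold * B + b];
        s2[mold * B + b] -= gs2[mold * B + b];
      }
      for (int m = 0; m < K; ++m) {
        double d = 0.0;
        for (int b = 0; b < B; ++b) {
          int i = m * B + b;
          d += cell_logml(cnt[i] + bsize[i], s1[i] + gs1[i], s2[i] + gs2[i],
                          mu0, lambda0, alpha0, beta0) -
               cell_logml(cnt[i], s1[i], s2[i], mu0, lambda0, alpha0, beta0);
        }
        logw_m[m] = d;
      }
      int mnew = sample_from_logw(logw_m);
      z[g] = mnew;
      for (int b = 0; b < B; ++b) {
        cnt[mnew * B + b] += bsize[mnew * B + b];
        s1[mnew * B + b] += gs1[mnew * B + b];
        s2[mnew * B + b] += gs2[mnew * B + b];
      }
    }
    // --- sample-block reassignment sweep, per module ---
    for (int m = 0; m < K; ++m) {
      // genes currently in module m
      double ng = 0.0;
      for (int g = 0; g < G; ++g) if (z[g] == m) ng += 1.0;
      for (int s = 0; s < S; ++s) {
        double v1 = 0.0, v2 = 0.0;
        for (int g = 0; g < G; ++g)
          if (z[g] == m) { double v = X(g, s); v1 += v; v2 += v * v; }
        int bold = w(m, s);
        cnt[m * B + bold] -= ng; s1[m * B + bold] -= v1; s2[m * B + bold] -= v2;
        bsize[m * B + bold] -= 1.0;
        for (int b = 0; b < B; ++b) {
          int i = m * B + b;
          logw_b[b] = cell_logml(cnt[i] + ng, s1[i] + v1, s2[i] + v2,
                                 mu0, lambda0, alpha0, beta0) -
                      cell_logml(cnt[i], s1[i], s2[i],
                                 mu0, lambda0, alpha0, beta0);
        }
        int bnew = sample_from_logw(logw_b);
        w(m, s) = bnew;
        cnt[m * B + bnew] += ng; s1[m * B + bnew] += v1; s2[m * B + bnew] += v2;
        bsize[m * B + bnew] += 1.0;
      }
    }
    double sc = total_score();
    if (sc > best) {
      best = sc;
      best_z = clone(z);
      best_w = clone(w);
    }
    trace[it] = best; // best-so-far, non-decreasing by construction
  }

  return List::create(_["module"] = best_z, _["blocks"] = best_w,
                      _["log_score"] = best, _["trace"] = trace);
}
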