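#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// One binary collision between species a and b. All draws use the
// pre-collision copy numbers and are applied simultaneously:
//   gains_a ~ Binomial(V_b, p_h)                 (transfers in from partner)
//   (loss_a, dup_a, rest) ~ Multinomial(V_a; p_l, p_d, 1 - p_l - p_d)
// sampled as loss ~ Bin(V, p_l), dup | loss ~ Bin(V - loss, p_d / (1 - p_l)).
// Gains are copies: the donor keeps its genes, so with p_h + p_d = p_l the
// expected change of V_a + V_b is exactly zero.
static inline void one_collision(std::vector<int>& V, int a, int b,
                                 double ph, double pd, double pl) {
  const int Va = V[a], Vb = V[b];
  int gain_a = 0, gain_b = 0, loss_a = 0, loss_b = 0, dup_a = 0, dup_b = 0;
  if (ph > 0.0) {
    if (Vb > 0) gain_a = (int) R::rbinom((double) Vb, ph);
    if (Va > 0) gain_b = (int) R::rbinom((double) Va, ph);
  }
  if (Va > 0 && pl > 0.0) loss_a = (int) R::rbinom((double) Va, pl);
  if (Vb > 0 && pl > 0.0) loss_b = (int) R::rbinom((double) Vb, pl);
  if (pd > 0.0 && pl < 1.0) {
    const double pcond = pd / (1.0 - pl);
    if (Va - loss_a > 0) dup_a = (int) R::rbinom((double) (Va - loss_a), pcond);
    if (Vb - loss_b > 0) dup_b = (int) R::rbinom((double) (Vb - loss_b), pcond);
  }
  V[a] = Va + gain_a + dup_a - loss_a;
  V[b] = Vb + gain_b + dup_b - loss_b;
}

// Ensemble moments of V: mean, sample variance (n - 1), and the moment
// skewness m3 / m2^(3/2) (population moments; NaN when m2 == 0).
static inline void moments(const std::vector<int>& V,
                           double& mean, double& var, double& skew) {
  const int n = (int) V.size();
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += V[i];
  mean = s / n;
  double m2 = 0.0, m3 = 0.0;
  for (int i = 0; i < n; ++i) {
    const double d = V[i] - mean;
    m2 += d * d;
    m3 += d * d * d;
  }
  var  = (n > 1) ? m2 / (n - 1) : 0.0;
  m2 /= n; m3 /= n;
  skew = (m2 > 0.0) ? m3 / std::pow(m2, 1.5) : R_NaReal;
}

// [[Rcpp::export]]
IntegerVector cpp_collide_pair(IntegerVector V, int i, int j,
                               double ph, double pd, double pl) {
  std::vector<int> W(V.begin(), V.end());
  one_collision(W, i - 1, j - 1, ph, pd, pl);  // 1-based indices from R
  return IntegerVector(W.begin(), W.end());
}

// Run n_sweeps * N collisions, recording ensemble moments every
// record_interval sweeps (including the initial state at t = 0).
// Pair choice is uniform over unordered pairs, or proportional to the
// off-diagonal weights of `kernel` when supplied.
// [[Rcpp::export]]
List cpp_run_simulation(IntegerVector init, double ph, double pd, double pl,
                        int n_sweeps, int record_interval,
                        Nullable<NumericMatrix> kernel) {
  const int N = init.size();
  std::vector<int> V(init.begin(), init.end());

  // cumulative pair weights for the biased kernel
  bool biased = kernel.isNotNull();
  std::vector<double> cumw;
  std::vector<int> pi, pj;
  if (biased) {
    NumericMatrix W(kernel.get());
    if (W.nrow() != N || W.ncol() != N)
      stop("collision kernel must be %d x %d", N, N);
    double tot = 0.0;
    cumw.reserve((size_t) N * (N - 1) / 2);
    pi.reserve(cumw.capacity());
    pj.reserve(cumw.capacity());
    for (int a = 0; a < N - 1; ++a)
      for (int b = a + 1; b < N; ++b) {
        const double w = W(a, b);
        if (w < 0.0 || !R_finite(w)) stop("kernel weights must be finite and >= 0");
        if (w > 0.0) {
          tot += w;
          cumw.push_back(tot);
          pi.push_back(a);
          pj.push_back(b);
        }
      }
    if (cumw.empty()) stop("kernel has no positive off-diagonal weight");
  }

  const int n_rec = n_sweeps / record_interval + 1;
  NumericVector times(n_rec), means(n_rec), vars(n_rec), skews(n_rec);
  int r = 0;
  double mean, var, skew;
  moments(V, mean, var, skew);
  times[r] = 0.0; means[r] = mean; vars[r] = var; skews[r] = skew; ++r;

  for (int sweep = 1; sweep <= n_sweeps; ++sweep) {
    for (int c = 0; c < N; ++c) {
      int a, b;
      if (biased) {
        const double u = unif_rand() * cumw.back();
        const int k = (int) (std::upper_bound(cumw.begin(), cumw.end(), u) -
                             cumw.begin());
        const int kk = std::min(k, (int) cumw.size() - 1);
        a = pi[kk]; b = pj[kk];
      } else {
        a = (int) (unif_rand() * N); if (a >= N) a = N - 1;
        do { b = (int) (unif_rand() * N); if (b >= N) b = N - 1; } while (b == a);
      }
      one_collision(V, a, b, ph, pd, pl);
    }
    if (sweep % record_interval == 0) {
      moments(V, mean, var, skew);
      times[r] = (double) sweep;
      means[r] = mean; vars[r] = var; skews[r] = skew; ++r;
    }
  }

  return List::create(_["times"] = times, _["means"] = means,
                      _["variances"] = vars, _["skewnesses"] = skews,
                      _["final_V"] = IntegerVector(V.begin(), V.end()));
}
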