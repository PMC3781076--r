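// Metropolis-within-Gibbs sampler for the latent-radius spatial link models.
// Each sweep: (1) joint zero-reflected random-walk update of the global
// scalars (alpha, beta and, when communities are on, gamma), (2) per-node
// reflected random-walk updates of the radii, (3) per-node exact Gibbs
// resampling of community labels from their full conditionals.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double log1pexp_c(double x) {
  if (x > 33.3) return x;
  if (x > 18.0) return x + std::exp(-x);
  return std::log1p(std::exp(x));
}

// Bernoulli log-mass of pair indicator a at logit l
static inline double pair_ll(int a, double l) {
  return a * l - log1pexp_c(l);
}

// sign of the community offset: +1 same non-zero label, -1 different
// non-zero labels, 0 if either node is don't-care
static inline double off_sign(int ci, int cj) {
  if (ci == 0 || cj == 0) return 0.0;
  return ci == cj ? 1.0 : -1.0;
}

// log density of N(m, s) truncated to (0, Inf)
static inline double ltnorm(double x, double m, double s) {
  if (x <= 0.0) return R_NegInf;
  return R::dnorm(x, m, s, 1) - R::pnorm(0.0, m, s, 0, 1);
}

static double full_ll(const NumericMatrix& D, const IntegerMatrix& A,
                      const NumericMatrix& KC,
                      double alpha, double beta, double gamma,
                      const std::vector<double>& r, const std::vector<int>& c) {
  const int n = D.nrow();
  double s = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double l = alpha * (r[i] + r[j] - D(i, j)) + beta * KC(i, j)
               + gamma * off_sign(c[i], c[j]);
      s += pair_ll(A(i, j), l);
    }
  return s;
}

struct Sampler {
  const NumericMatrix& D;
  const IntegerMatrix& A;
  const NumericMatrix& KC;
  int n, K;
  double alpha, beta, gamma;
  std::vector<double> r;
  std::vector<int> c;
  // prior: alpha (m, s), beta, gamma, radius
  double am, as_, bm, bs, gm, gs, rm, rs;
  double s_a, s_b, s_g, s_r;      // random-walk step sizes
  double cur_ll;
  // adaptation window counters: alpha, beta, gamma, radius
  long acc[4], tries[4];
  long tot_acc[4], tot_try[4];    // reporting counters

  Sampler(const NumericMatrix& D_, const IntegerMatrix& A_,
          const NumericMatrix& KC_, int K_)
    : D(D_), A(A_), KC(KC_), n(D_.nrow()), K(K_) {
    for (int g = 0; g < 4; ++g) acc[g] = tries[g] = tot_acc[g] = tot_try[g] = 0;
  }

  void reset_counters() {
    for (int g = 0; g < 4; ++g) { acc[g] = tries[g] = 0; tot_acc[g] = tot_try[g] = 0; }
  }

  double prior_terms() const {
    double lp = ltnorm(alpha, am, as_) + ltnorm(beta, bm, bs);
    if (K > 0) lp += ltnorm(gamma, gm, gs) - n * std::log((double)(K + 1));
    for (int i = 0; i < n; ++i) lp += ltnorm(r[i], rm, rs);
    return lp;
  }

  // single-scalar Metropolis step; which: 0 alpha, 1 beta, 2 gamma
  void scalar_update(int which) {
    double* tgt = which == 0 ? &alpha : (which == 1 ? &beta : &gamma);
    double step = which == 0 ? s_a : (which == 1 ? s_b : s_g);
    double pm = which == 0 ? am : (which == 1 ? bm : gm);
    double ps = which == 0 ? as_ : (which == 1 ? bs : gs);
    double old = *tgt;
    double prop = std::fabs(old + norm_rand() * step);
    *tgt = prop;
    double ll_new = full_ll(D, A, KC, alpha, beta, gamma, r, c);
    double dpr = ltnorm(prop, pm, ps) - ltnorm(old, pm, ps);
    ++tries[which]; ++tot_try[which];
    if (std::log(unif_rand()) < (ll_new - cur_ll) + dpr) {
      cur_ll = ll_new;
      ++acc[which]; ++tot_acc[which];
    } else {
      *tgt = old;
    }
  }

  void radius_update(int i) {
    double rp = std::fabs(r[i] + norm_rand() * s_r);
    double dll = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double base = beta * KC(i, j) + gamma * off_sign(c[i], c[j]);
      double rest = alpha * (r[j] - D(i, j)) + base;
      dll += pair_ll(A(i, j), alpha * rp + rest)
           - pair_ll(A(i, j), alpha * r[i] + rest);
    }
    double dpr = ltnorm(rp, rm, rs) - ltnorm(r[i], rm, rs);
    ++tries[3]; ++tot_try[3];
    if (std::log(unif_rand()) < dll + dpr) {
      r[i] = rp; cur_ll += dll;
      ++acc[3]; ++tot_acc[3];
    }
  }

  // exact Gibbs draw of c[i] over {0..K}; uniform label prior cancels
  void comm_update(int i) {
    std::vector<double> W(K + 1, 0.0);
    double Sall0 = 0.0, S0 = 0.0, T = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double b = alpha * (r[i] + r[j] - D(i, j)) + beta * KC(i, j);
      int a = A(i, j);
      double f0 = pair_ll(a, b);
      Sall0 += f0;
      if (c[j] == 0) {
        S0 += f0;
      } else {
        double fp = pair_ll(a, b + gamma);
        double fm = pair_ll(a, b - gamma);
        T += fm;
        W[c[j]] += fp - fm;
      }
    }
    std::vector<double> logw(K + 1);
    logw[0] = Sall0;
    for (int k = 1; k <= K; ++k) logw[k] = S0 + T + W[k];
    double mx = logw[0];
    for (int k = 1; k <= K; ++k) if (logw[k] > mx) mx = logw[k];
    std::vector<double> w(K + 1);
    double tot = 0.0;
    for (int k = 0; k <= K; ++k) { w[k] = std::exp(logw[k] - mx); tot += w[k]; }
    double u = unif_rand() * tot, cum = 0.0;
    int newc = K;
    for (int k = 0; k <= K; ++k) {
      cum += w[k];
      if (u <= cum) { newc = k; break; }
    }
    cur_ll += logw[newc] - logw[c[i]];
    c[i] = newc;
  }

  void sweep() {
    cur_ll = full_ll(D, A, KC, alpha, beta, gamma, r, c); // resync, no drift
    scalar_update(0);
    scalar_update(1);
    if (K > 0) scalar_update(2);
    for (int i = 0; i < n; ++i) radius_update(i);
    if (K > 0) for (int i = 0; i < n; ++i) comm_update(i);
  }

  // steer each group toward ~30% acceptance; the multiplicative factor
  // grows with the distance from target so badly-scaled initial steps
  // (set from the weakly-informative prior sds) correct within a burn-in
  void adapt_window() {
    for (int g = 0; g < 4; ++g) {
      if (tries[g] == 0) continue;
      double rate = (double)acc[g] / tries[g];
      double f = std::exp(2.0 * (rate - 0.30));
      if (f < 0.5) f = 0.5; else if (f > 2.0) f = 2.0;
      if (g == 0) s_a *= f; else if (g == 1) s_b *= f;
      else if (g == 2) s_g *= f; else s_r *= f;
      acc[g] = tries[g] = 0;
    }
  }
};

// [[Rcpp::export]]
List run_sampler_cpp(NumericMatrix D, IntegerMatrix A, NumericMatrix KC,
                     int n_comms,
                     double alpha0, double beta0, double gamma0,
                     NumericVector r0, IntegerVector c0,
                     NumericVector prior,
                     int n_iter, int burn, int thin,
                     NumericVector steps, bool adapt, int init_iter) {
  const int n = D.nrow();
  Sampler S(D, A, KC, n_comms);
  S.alpha = alpha0; S.beta = beta0; S.gamma = gamma0;
  S.r.assign(r0.begin(), r0.end());
  S.c.assign(c0.begin(), c0.end());
  S.am = prior[0]; S.as_ = prior[1]; S.bm = prior[2]; S.bs = prior[3];
  S.gm = prior[4]; S.gs = prior[5]; S.rm = prior[6]; S.rs = prior[7];
  S.s_a = steps[0]; S.s_b = steps[1]; S.s_g = steps[2]; S.s_r = steps[3];

  const int ADAPT_WIN = 25;

  // initialisation chain: keep the best-scoring state seen, restart from it
  double best_lp = R_NegInf;
  double b_alpha = S.alpha, b_beta = S.beta, b_gamma = S.gamma;
  std::vector<double> b_r = S.r;
  std::vector<int> b_c = S.c;
  for (int s = 0; s < init_iter; ++s) {
    S.sweep();
    double lp = S.cur_ll + S.prior_terms();
    if (lp > best_lp) {
      best_lp = lp;
      b_alpha = S.alpha; b_beta = S.beta; b_gamma = S.gamma;
      b_r = S.r; b_c = S.c;
    }
    if (adapt && (s + 1) % ADAPT_WIN == 0) S.adapt_window();
  }
  S.alpha = b_alpha; S.beta = b_beta; S.gamma = b_gamma;
  S.r = b_r; S.c = b_c;
  S.reset_counters();

  const int n_ret = (n_iter - burn) / thin;
  NumericVector out_a(n_ret), out_b(n_ret), out_g(n_ret), out_lp(n_ret);
  NumericMatrix out_r(n_ret, n);
  IntegerMatrix out_c(n_ret, n);

  int k = 0;
  for (int s = 0; s < n_iter; ++s) {
    S.sweep();
    if (s < burn) {
      if (adapt && (s + 1) % ADAPT_WIN == 0) S.adapt_window();
      if (s == burn - 1) { // freeze; start post-burn-in acceptance accounting
        for (int g = 0; g < 4; ++g) S.tot_acc[g] = S.tot_try[g] = 0;
      }
    }
    if (s >= burn && (s - burn + 1) % thin == 0 && k < n_ret) {
      out_a[k] = S.alpha; out_b[k] = S.beta; out_g[k] = S.gamma;
      out_lp[k] = S.cur_ll + S.prior_terms();
      for (int i = 0; i < n; ++i) { out_r(k, i) = S.r[i]; out_c(k, i) = S.c[i]; }
      ++k;
    }
  }
  long gacc = S.tot_acc[0] + S.tot_acc[1] + S.tot_acc[2];
  long gtry = S.tot_try[0] + S.tot_try[1] + S.tot_try[2];
  return List::create(
    _["alpha"] = out_a, _["beta"] = out_b, _["gamma"] = out_g,
    _["log_posterior"] = out_lp, _["radii"] = out_r, _["comms"] = out_c,
    _["acceptance"] = List::create(
      _["global"] = gtry > 0 ? (double)gacc / gtry : NA_REAL,
      _["alpha"] = S.tot_try[0] > 0 ? (double)S.tot_acc[0] / S.tot_try[0] : NA_REAL,
      _["beta"] = S.tot_try[1] > 0 ? (double)S.tot_acc[1] / S.tot_try[1] : NA_REAL,
      _["gamma"] = S.tot_try[2] > 0 ? (double)S.tot_acc[2] / S.tot_try[2] : NA_REAL,
      _["radius"] = S.tot_try[3] > 0 ? (double)S.tot_acc[3] / S.tot_try[3] : NA_REAL),
    _["steps_final"] = NumericVector::create(
      _["alpha"] = S.s_a, _["beta"] = S.s_b, _["gamma"] = S.s_g,
      _["radius"] = S.s_r));
}
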