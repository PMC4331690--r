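// Linear-chain CRF internals: log-space forward-backward, Viterbi,
// penalized negative log-likelihood with analytic gradient, and
// constrained-path log-probability.
//
// Parameter layout (length n_feat * n_tags + n_tags * n_tags):
//   state weight (feature f, tag y)      at f * n_tags + y
//   transition weight (y_prev -> y_cur)  at n_feat * n_tags + y_prev * n_tags + y_cur
// Feature and tag indices are 0-based. Each sequence is a list of integer
// vectors of active feature indices, one per position.
//
// The recursions are kept in log space for stability, but the inner
// logsumexp over previous tags is computed as a max-shifted product with
// the exponentiated transition matrix (precomputed once per call), which
// avoids n_tags^2 exp() evaluations per position.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Per-position log potentials psi[t * n_tags + y] = sum_{f active} w[f, y].
static std::vector<double> log_potentials(const NumericVector &par,
                                          const List &seq, int n_tags) {
  int T = seq.size();
  std::vector<double> psi((size_t)T * n_tags, 0.0);
  for (int t = 0; t < T; ++t) {
    IntegerVector xs = seq[t];
    double *row = &psi[(size_t)t * n_tags];
    for (int k = 0; k < xs.size(); ++k) {
      const double *w = &par[(size_t)xs[k] * n_tags];
      for (int y = 0; y < n_tags; ++y) row[y] += w[y];
    }
  }
  return psi;
}

static std::vector<double> exp_trans(const double *trans, int n_tags) {
  std::vector<double> e((size_t)n_tags * n_tags);
  for (int i = 0; i < n_tags * n_tags; ++i) e[i] = std::exp(trans[i]);
  return e;
}

static double vec_max(const double *x, int n) {
  double m = x[0];
  for (int i = 1; i < n; ++i)
    if (x[i] > m) m = x[i];
  return m;
}

// logsumexp of a finished alpha row.
static double logsumexp(const double *x, int n) {
  double m = vec_max(x, n);
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(x[i] - m);
  return m + std::log(s);
}

// Forward recursion over exp-shifted products; optional per-position tag
// constraint (-1 = free). Returns logZ; fills alpha (T x n_tags).
static double forward(const std::vector<double> &psi,
                      const std::vector<double> &etrans, int T, int n_tags,
                      const int *constraint, std::vector<double> &alpha) {
  std::vector<double> u(n_tags);
  for (int y = 0; y < n_tags; ++y) {
    bool ok = constraint == nullptr || constraint[0] < 0 || constraint[0] == y;
    alpha[y] = ok ? psi[y] : NEG_INF;
  }
  for (int t = 1; t < T; ++t) {
    const double *ap = &alpha[(size_t)(t - 1) * n_tags];
    double *ac = &alpha[(size_t)t * n_tags];
    double m = vec_max(ap, n_tags);
    if (!std::isfinite(m)) {
      for (int y = 0; y < n_tags; ++y) ac[y] = NEG_INF;
      continue;
    }
    for (int yp = 0; yp < n_tags; ++yp) u[yp] = std::exp(ap[yp] - m);
    for (int y = 0; y < n_tags; ++y) {
      if (constraint != nullptr && constraint[t] >= 0 && constraint[t] != y) {
        ac[y] = NEG_INF;
        continue;
      }
      double s = 0.0;
      for (int yp = 0; yp < n_tags; ++yp) s += u[yp] * etrans[yp * n_tags + y];
      ac[y] = psi[(size_t)t * n_tags + y] + m + std::log(s);
    }
  }
  return logsumexp(&alpha[(size_t)(T - 1) * n_tags], n_tags);
}

// Backward recursion; fills beta (T x n_tags).
static void backward(const std::vector<double> &psi,
                     const std::vector<double> &etrans, int T, int n_tags,
                     std::vector<double> &beta) {
  std::vector<double> w(n_tags), v(n_tags);
  for (int y = 0; y < n_tags; ++y) beta[(size_t)(T - 1) * n_tags + y] = 0.0;
  for (int t = T - 2; t >= 0; --t) {
    const double *bn = &beta[(size_t)(t + 1) * n_tags];
    double *bc = &beta[(size_t)t * n_tags];
    for (int yc = 0; yc < n_tags; ++yc)
      w[yc] = psi[(size_t)(t + 1) * n_tags + yc] + bn[yc];
    double m = vec_max(w.data(), n_tags);
    for (int yc = 0; yc < n_tags; ++yc) v[yc] = std::exp(w[yc] - m);
    for (int y = 0; y < n_tags; ++y) {
      double s = 0.0;
      for (int yc = 0; yc < n_tags; ++yc) s += etrans[y * n_tags + yc] * v[yc];
      bc[y] = m + std::log(s);
    }
  }
}

// [[Rcpp::export]]
List crf_nll_grad_cpp(NumericVector par, List feats, List tags, int n_feat,
                      int n_tags, double inv_sigma2) {
  const double *trans = &par[(size_t)n_feat * n_tags];
  std::vector<double> etrans = exp_trans(trans, n_tags);
  NumericVector grad(par.size());
  double *gtrans = &grad[(size_t)n_feat * n_tags];
  double loglik = 0.0;
  std::vector<double> marg, u, v;

  for (int s = 0; s < feats.size(); ++s) {
    List seq = feats[s];
    IntegerVector y = tags[s];
    int T = seq.size();
    if (T == 0) continue;
    std::vector<double> psi = log_potentials(par, seq, n_tags);
    std::vector<double> alpha((size_t)T * n_tags), beta((size_t)T * n_tags);
    double logZ = forward(psi, etrans, T, n_tags, nullptr, alpha);
    backward(psi, etrans, T, n_tags, beta);

    // empirical score
    double score = psi[(size_t)0 * n_tags + y[0]];
    for (int t = 1; t < T; ++t)
      score += trans[y[t - 1] * n_tags + y[t]] + psi[(size_t)t * n_tags + y[t]];
    loglik += score - logZ;

    // state gradient: expected - empirical counts
    marg.assign(n_tags, 0.0);
    for (int t = 0; t < T; ++t) {
      for (int yy = 0; yy < n_tags; ++yy)
        marg[yy] = std::exp(alpha[(size_t)t * n_tags + yy] +
                            beta[(size_t)t * n_tags + yy] - logZ);
      IntegerVector xs = seq[t];
      for (int k = 0; k < xs.size(); ++k) {
        double *g = &grad[(size_t)xs[k] * n_tags];
        for (int yy = 0; yy < n_tags; ++yy) g[yy] += marg[yy];
        g[y[t]] -= 1.0;
      }
    }
    // transition gradient: pairwise expectations via shifted products
    u.assign(n_tags, 0.0);
    v.assign(n_tags, 0.0);
    for (int t = 1; t < T; ++t) {
      const double *ap = &alpha[(size_t)(t - 1) * n_tags];
      const double *bc = &beta[(size_t)t * n_tags];
      const double *ps = &psi[(size_t)t * n_tags];
      double ma = vec_max(ap, n_tags);
      double mb = NEG_INF;
      for (int yc = 0; yc < n_tags; ++yc) {
        double w = ps[yc] + bc[yc];
        if (w > mb) mb = w;
        v[yc] = w;
      }
      for (int yc = 0; yc < n_tags; ++yc) v[yc] = std::exp(v[yc] - mb);
      for (int yp = 0; yp < n_tags; ++yp) u[yp] = std::exp(ap[yp] - ma);
      double scale = std::exp(ma + mb - logZ);
      for (int yp = 0; yp < n_tags; ++yp) {
        double uy = u[yp] * scale;
        if (uy == 0.0) continue;
        const double *e = &etrans[(size_t)yp * n_tags];
        double *g = &gtrans[(size_t)yp * n_tags];
        for (int yc = 0; yc < n_tags; ++yc) g[yc] += uy * e[yc] * v[yc];
      }
      gtrans[y[t - 1] * n_tags + y[t]] -= 1.0;
    }
  }

  double penalty = 0.0;
  for (R_xlen_t i = 0; i < par.size(); ++i) {
    penalty += 0.5 * inv_sigma2 * par[i] * par[i];
    grad[i] += inv_sigma2 * par[i];
  }
  return List::create(Named("nll") = -loglik + penalty, Named("grad") = grad);
}

// [[Rcpp::export]]
IntegerVector crf_viterbi_cpp(NumericVector par, List seq, int n_feat,
                              int n_tags) {
  int T = seq.size();
  IntegerVector path(T);
  if (T == 0) return path;
  const double *trans = &par[(size_t)n_feat * n_tags];
  std::vector<double> psi = log_potentials(par, seq, n_tags);
  std::vector<double> delta((size_t)T * n_tags);
  std::vector<int> back((size_t)T * n_tags, 0);
  for (int y = 0; y < n_tags; ++y) delta[y] = psi[y];
  for (int t = 1; t < T; ++t) {
    const double *dp = &delta[(size_t)(t - 1) * n_tags];
    for (int y = 0; y < n_tags; ++y) {
      // strict > keeps the lowest previous-tag index on ties; tags are
      // supplied in lexicographic order, so ties break lexicographically
      double best = dp[0] + trans[0 * n_tags + y];
      int arg = 0;
      for (int yp = 1; yp < n_tags; ++yp) {
        double v = dp[yp] + trans[yp * n_tags + y];
        if (v > best) {
          best = v;
          arg = yp;
        }
      }
      delta[(size_t)t * n_tags + y] = best + psi[(size_t)t * n_tags + y];
      back[(size_t)t * n_tags + y] = arg;
    }
  }
  const double *dl = &delta[(size_t)(T - 1) * n_tags];
  int arg = 0;
  for (int y = 1; y < n_tags; ++y)
    if (dl[y] > dl[arg]) arg = y;
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) {
    arg = back[(size_t)t * n_tags + arg];
    path[t - 1] = arg;
  }
  return path;
}

// [[Rcpp::export]]
NumericMatrix crf_marginals_cpp(NumericVector par, List seq, int n_feat,
                                int n_tags) {
  int T = seq.size();
  NumericMatrix out(T, n_tags);
  if (T == 0) return out;
  const double *trans = &par[(size_t)n_feat * n_tags];
  std::vector<double> etrans = exp_trans(trans, n_tags);
  std::vector<double> psi = log_potentials(par, seq, n_tags);
  std::vector<double> alpha((size_t)T * n_tags), beta((size_t)T * n_tags);
  double logZ = forward(psi, etrans, T, n_tags, nullptr, alpha);
  backward(psi, etrans, T, n_tags, beta);
  for (int t = 0; t < T; ++t)
    for (int y = 0; y < n_tags; ++y)
      out(t, y) = std::exp(alpha[(size_t)t * n_tags + y] +
                           beta[(size_t)t * n_tags + y] - logZ);
  return out;
}

// Log of the summed unnormalized score over paths agreeing with
// `constraint` (-1 = position free, otherwise the required 0-based tag).
// With an all-free constraint this is logZ.
// [[Rcpp::export]]
double crf_constrained_logz_cpp(NumericVector par, List seq,
                                IntegerVector constraint, int n_feat,
                                int n_tags) {
  int T = seq.size();
  if (T == 0) return 0.0;
  const double *trans = &par[(size_t)n_feat * n_tags];
  std::vector<double> etrans = exp_trans(trans, n_tags);
  std::vector<double> psi = log_potentials(par, seq, n_tags);
  std::vector<double> alpha((size_t)T * n_tags);
  return forward(psi, etrans, T, n_tags, &constraint[0], alpha);
}
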