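// Metropolis-within-Gibbs sampler for the two-class latent class model
// with additive within-class covariances for disjoint dependent pairs.
//
// Parameter vector layout: [prev, se_1..K, sp_1..K, covd_1..P, covn_1..P].
// Probability parameters move by random-walk proposals on the logit scale
// (with the implied Jacobian correction); covariances by random walks
// scaled to the width of their current admissible interval. Step sizes
// adapt toward a target acceptance rate during burn-in, then freeze.
// All randomness comes from R's RNG, so set.seed() governs the chain.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Model {
  NumericVector counts;
  IntegerMatrix pat;     // C x K, 0/1
  IntegerMatrix pairs;   // P x 2, 0-based column indices
  NumericVector prev_ab, se_a, se_b, sp_a, sp_b, cov_lower, cov_upper;
  bool constrain;        // optional identifiability constraint Se + Sp > 1
  int C, K, P;
  std::vector<bool> in_pair;

  void init_dims() {
    C = pat.nrow();
    K = pat.ncol();
    P = pairs.nrow();
    in_pair.assign(K, false);
    for (int p = 0; p < P; ++p) {
      in_pair[pairs(p, 0)] = true;
      in_pair[pairs(p, 1)] = true;
    }
  }

  double logpost(const std::vector<double>& th) const {
    const double pi = th[0];
    const double* se = &th[1];
    const double* sp = &th[1 + K];
    const double* cd = P ? &th[1 + 2 * K] : NULL;
    const double* cn = P ? &th[1 + 2 * K + P] : NULL;

    if (constrain)
      for (int k = 0; k < K; ++k)
        if (se[k] + sp[k] <= 1.0) return R_NegInf;

    double lp = 0.0;
    for (int p = 0; p < P; ++p) {
      const int i = pairs(p, 0), j = pairs(p, 1);
      const double lod = std::max(-se[i] * se[j], -(1 - se[i]) * (1 - se[j]));
      const double hid = std::min(se[i] * (1 - se[j]), (1 - se[i]) * se[j]);
      const double lon = std::max(-sp[i] * sp[j], -(1 - sp[i]) * (1 - sp[j]));
      const double hin = std::min(sp[i] * (1 - sp[j]), (1 - sp[i]) * sp[j]);
      if (cd[p] < std::max(lod, (double)cov_lower[p]) ||
          cd[p] > std::min(hid, (double)cov_upper[p]) ||
          cn[p] < std::max(lon, (double)cov_lower[p]) ||
          cn[p] > std::min(hin, (double)cov_upper[p]))
        return R_NegInf;
      lp -= 2.0 * std::log(cov_upper[p] - cov_lower[p]);
    }

    lp += ::Rf_dbeta(pi, prev_ab[0], prev_ab[1], 1);
    for (int k = 0; k < K; ++k) {
      lp += ::Rf_dbeta(se[k], se_a[k], se_b[k], 1);
      lp += ::Rf_dbeta(sp[k], sp_a[k], sp_b[k], 1);
    }
    if (!std::isfinite(lp)) return R_NegInf;

    for (int c = 0; c < C; ++c) {
      if (counts[c] == 0.0) continue;
      double pd = 1.0, pn = 1.0;
      for (int k = 0; k < K; ++k) {
        if (in_pair[k]) continue;
        const int t = pat(c, k);
        pd *= t ? se[k] : 1.0 - se[k];
        pn *= t ? 1.0 - sp[k] : sp[k];
      }
      for (int p = 0; p < P; ++p) {
        const int i = pairs(p, 0), j = pairs(p, 1);
        const int ti = pat(c, i), tj = pat(c, j);
        const double s = (ti == tj) ? 1.0 : -1.0;
        const double ai = ti ? se[i] : 1.0 - se[i];
        const double aj = tj ? se[j] : 1.0 - se[j];
        const double bi = ti ? 1.0 - sp[i] : sp[i];
        const double bj = tj ? 1.0 - sp[j] : sp[j];
        pd *= ai * aj + s * cd[p];
        pn *= bi * bj + s * cn[p];
      }
      const double pc = pi * pd + (1.0 - pi) * pn;
      if (pc <= 0.0) return R_NegInf;
      lp += counts[c] * std::log(pc);
    }
    return lp;
  }
};

}  // namespace

// [[Rcpp::export]]
List blcda_mcmc_cpp(NumericVector counts, IntegerMatrix pat,
                    IntegerMatrix pairs, NumericVector prev_ab,
                    NumericVector se_a, NumericVector se_b,
                    NumericVector sp_a, NumericVector sp_b,
                    NumericVector cov_lower, NumericVector cov_upper,
                    NumericVector init, int iterations, int burn_in,
                    int thin, int adapt_batch, double target_accept,
                    bool constrain) {
  Model m;
  m.counts = counts; m.pat = pat; m.pairs = pairs;
  m.prev_ab = prev_ab; m.se_a = se_a; m.se_b = se_b;
  m.sp_a = sp_a; m.sp_b = sp_b;
  m.cov_lower = cov_lower; m.cov_upper = cov_upper;
  m.constrain = constrain;
  m.init_dims();

  const int K = m.K, P = m.P;
  const int npar = 1 + 2 * K + 2 * P;
  if (init.size() != npar) stop("init has wrong length");

  std::vector<double> th(init.begin(), init.end());
  double lp = m.logpost(th);
  if (!std::isfinite(lp)) stop("non-finite log-posterior at the initial state");

  // step sizes on the log scale: logit-units for probabilities,
  // fraction of the admissible width for covariances
  std::vector<double> lstep(npar, std::log(0.5));
  for (int j = 1 + 2 * K; j < npar; ++j) lstep[j] = std::log(0.2);

  const int ndraw = (iterations - burn_in) / thin;
  NumericMatrix draws(ndraw, npar);
  NumericVector draw_lp(ndraw);
  std::vector<int> acc_batch(npar, 0);
  std::vector<double> acc_post(npar, 0.0);
  int stored = 0, batch = 0, post_iters = 0;

  RNGScope scope;
  for (int it = 1; it <= iterations; ++it) {
    for (int j = 0; j < npar; ++j) {
      const double old = th[j];
      double prop, lqdiff = 0.0;
      if (j < 1 + 2 * K) {
        const double l = std::log(old / (1.0 - old)) +
                         std::exp(lstep[j]) * norm_rand();
        prop = 1.0 / (1.0 + std::exp(-l));
        if (prop <= 0.0 || prop >= 1.0) continue;  // numeric under/overflow
        lqdiff = std::log(prop * (1.0 - prop)) - std::log(old * (1.0 - old));
      } else {
        const int idx = j - (1 + 2 * K);
        const bool diseased = idx < P;
        const int p = diseased ? idx : idx - P;
        const int i = m.pairs(p, 0), jj = m.pairs(p, 1);
        const double* mar = diseased ? &th[1] : &th[1 + K];
        const double lo = std::max(-mar[i] * mar[jj],
                                   -(1 - mar[i]) * (1 - mar[jj]));
        const double hi = std::min(mar[i] * (1 - mar[jj]),
                                   (1 - mar[i]) * mar[jj]);
        double width = hi - lo;
        if (width < 1e-8) width = 1e-8;
        prop = old + std::exp(lstep[j]) * width * norm_rand();
      }
      th[j] = prop;
      const double lpn = m.logpost(th);
      const double la = lpn - lp + lqdiff;
      if (std::isfinite(lpn) && (la >= 0.0 || std::log(unif_rand()) < la)) {
        lp = lpn;
        ++acc_batch[j];
        if (it > burn_in) acc_post[j] += 1.0;
      } else {
        th[j] = old;
      }
    }
    if (it <= burn_in && it % adapt_batch == 0) {
      ++batch;
      const double gain = std::min(0.5, 5.0 / std::sqrt((double)batch));
      for (int j = 0; j < npar; ++j) {
        const double rate = (double)acc_batch[j] / adapt_batch;
        lstep[j] += (rate - target_accept) * gain;
        if (lstep[j] < -8.0) lstep[j] = -8.0;
        if (lstep[j] > 3.0) lstep[j] = 3.0;
        acc_batch[j] = 0;
      }
    }
    if (it > burn_in) {
      ++post_iters;
      if ((it - burn_in) % thin == 0 && stored < ndraw) {
        for (int j = 0; j < npar; ++j) draws(stored, j) = th[j];
        draw_lp[stored] = lp;
        ++stored;
      }
    }
  }

  NumericVector acc(npar), steps(npar);
  for (int j = 0; j < npar; ++j) {
    acc[j] = post_iters ? acc_post[j] / post_iters : NA_REAL;
    steps[j] = std::exp(lstep[j]);
  }
  return List::create(_["draws"] = draws, _["logpost"] = draw_lp,
                      _["acceptance"] = acc, _["steps"] = steps);
}

// Log posterior of a single parameter point, shared with the sampler —
// exposed so the R-level density can be cross-checked against it.
// [[Rcpp::export]]
double blcda_logpost_cpp(NumericVector counts, IntegerMatrix pat,
                         IntegerMatrix pairs, NumericVector prev_ab,
                         NumericVector se_a, NumericVector se_b,
                         NumericVector sp_a, NumericVector sp_b,
                         NumericVector cov_lower, NumericVector cov_upper,
                         NumericVector theta, bool constrain) {
  Model m;
  m.counts = counts; m.pat = pat; m.pairs = pairs;
  m.prev_ab = prev_ab; m.se_a = se_a; m.se_b = se_b;
  m.sp_a = sp_a; m.sp_b = sp_b;
  m.cov_lower = cov_lower; m.cov_upper = cov_upper;
  m.constrain = constrain;
  m.init_dims();
  std::vector<double> th(theta.begin(), theta.end());
  return m.logpost(th);
}
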