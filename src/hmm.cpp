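// Core HMM recursions. Emissions arrive as a site x state matrix of
// log-likelihoods; transitions as an S x S x (n-1) cube of per-gap matrices,
// or a single-slice cube when the chain is homogeneous. Scaling (per-site
// normalization of the forward variables) keeps everything in linear space
// without underflow; the log-likelihood is recovered from the scale factors.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline const arma::mat slice_at(const arma::cube& trans, bool homog,
                                       arma::uword t) {
  return homog ? trans.slice(0) : trans.slice(t);
}

// Forward-backward with per-site scaling.
// logem: n x S; trans: S x S x (n-1) (or x 1 if homogeneous); pi: S.
// xi_by_gap: return xi as an S x S x (n-1) cube instead of the sum over gaps.
// [[Rcpp::export(name = ".hmm_fb")]]
List hmm_fb(const arma::mat& logem, const arma::cube& trans,
            const arma::vec& pi, bool homogeneous, bool xi_by_gap) {
  const arma::uword n = logem.n_rows, S = logem.n_cols;
  if (pi.n_elem != S) stop("pi length does not match state count");
  if (!homogeneous && n > 1 && trans.n_slices != n - 1)
    stop("need one transition matrix per gap");

  // shift each row by its max before exponentiating
  arma::vec shift(n);
  arma::mat em(n, S);
  for (arma::uword t = 0; t < n; ++t) {
    double m = logem.row(t).max();
    if (!std::isfinite(m))
      stop("all emission probabilities are zero at site " +
           std::to_string(t + 1));
    shift(t) = m;
    em.row(t) = arma::exp(logem.row(t) - m);
  }

  arma::mat alpha(n, S), beta(n, S);
  arma::vec cvec(n);

  alpha.row(0) = (pi % em.row(0).t()).t();
  cvec(0) = arma::accu(alpha.row(0));
  if (cvec(0) <= 0) stop("zero forward probability at site 1");
  alpha.row(0) /= cvec(0);
  for (arma::uword t = 1; t < n; ++t) {
    alpha.row(t) = (alpha.row(t - 1) * slice_at(trans, homogeneous, t - 1)) %
                   em.row(t);
    cvec(t) = arma::accu(alpha.row(t));
    if (cvec(t) <= 0)
      stop("zero forward probability at site " + std::to_string(t + 1));
    alpha.row(t) /= cvec(t);
  }

  beta.row(n - 1).ones();
  for (arma::uword t = n - 1; t-- > 0;) {
    beta.row(t) = (slice_at(trans, homogeneous, t) *
                   (em.row(t + 1).t() % beta.row(t + 1).t())).t() /
                  cvec(t + 1);
  }

  arma::mat gamma = alpha % beta;
  for (arma::uword t = 0; t < n; ++t) gamma.row(t) /= arma::accu(gamma.row(t));

  double loglik = arma::accu(arma::log(cvec)) + arma::accu(shift);

  arma::cube xic;
  arma::mat xis(S, S, arma::fill::zeros);
  if (xi_by_gap) xic.set_size(S, S, n > 1 ? n - 1 : 0);
  for (arma::uword t = 0; t + 1 < n; ++t) {
    arma::mat x = (alpha.row(t).t() *
                   (em.row(t + 1) % beta.row(t + 1) / cvec(t + 1))) %
                  slice_at(trans, homogeneous, t);
    double s = arma::accu(x);
    if (s > 0) x /= s;
    if (xi_by_gap) xic.slice(t) = x; else xis += x;
  }

  if (xi_by_gap)
    return List::create(_["gamma"] = gamma, _["xi"] = xic,
                        _["loglik"] = loglik);
  return List::create(_["gamma"] = gamma, _["xi"] = xis,
                      _["loglik"] = loglik);
}

// Viterbi in log space; ties broken toward the lower state index.
// [[Rcpp::export(name = ".hmm_viterbi")]]
List hmm_viterbi(const arma::mat& logem, const arma::cube& logtrans,
                 const arma::vec& logpi, bool homogeneous) {
  const arma::uword n = logem.n_rows, S = logem.n_cols;
  arma::mat delta(n, S);
  arma::umat psi(n, S, arma::fill::zeros);

  delta.row(0) = (logpi + logem.row(0).t()).t();
  for (arma::uword t = 1; t < n; ++t) {
    const arma::mat lt = homogeneous ? logtrans.slice(0)
                                     : logtrans.slice(t - 1);
    for (arma::uword s = 0; s < S; ++s) {
      double best = -arma::datum::inf;
      arma::uword arg = 0;
      for (arma::uword r = 0; r < S; ++r) {
        double v = delta(t - 1, r) + lt(r, s);
        if (v > best) { best = v; arg = r; }
      }
      delta(t, s) = best + logem(t, s);
      psi(t, s) = arg;
    }
  }

  IntegerVector path(n);
  arma::uword last = 0;
  double best = -arma::datum::inf;
  for (arma::uword s = 0; s < S; ++s)
    if (delta(n - 1, s) > best) { best = delta(n - 1, s); last = s; }
  path[n - 1] = last + 1;
  for (arma::uword t = n - 1; t-- > 0;) {
    last = psi(t + 1, last);
    path[t] = last + 1;
  }
  return List::create(_["path"] = path, _["logprob"] = best);
}

// Greedy acceptance pass for the Z-score window assignment. Windows arrive
// already sorted by (|Z| desc, start asc, length asc); a window is accepted
// iff none of its sites has been assigned yet. Returns, per site, the index
// (1-based, into the sorted window list) of the window it was assigned to.
// [[Rcpp::export(name = ".greedy_accept")]]
IntegerVector greedy_accept(const IntegerVector& start,
                            const IntegerVector& len, int n_sites) {
  IntegerVector assigned(n_sites, 0);
  int n_assigned = 0;
  for (int w = 0; w < start.size() && n_assigned < n_sites; ++w) {
    int a = start[w] - 1, b = a + len[w];
    bool free = true;
    for (int i = a; i < b; ++i)
      if (assigned[i] != 0) { free = false; break; }
    if (free) {
      for (int i = a; i < b; ++i) assigned[i] = w + 1;
      n_assigned += len[w];
    }
  }
  return assigned;
}

// Joint E-step for the left-to-right model: runs forward-backward for every
// individual (slices of logems) under the shared per-gap transitions and
// returns the xi accumulator summed over individuals plus the joint
// log-likelihood.  Keeping the per-individual loop here avoids allocating
// one S x S x (n-1) cube per individual per EM iteration in R.
// [[Rcpp::export(name = ".ltr_estep")]]
List ltr_estep(const arma::cube& logems,  // n x S x J
               const arma::cube& trans,   // S x S x (n-1)
               const arma::vec& pi) {
  const arma::uword n = logems.n_rows, S = logems.n_cols,
                    J = logems.n_slices;
  arma::cube xiAcc(S, S, n > 1 ? n - 1 : 0, arma::fill::zeros);
  double total = 0;
  arma::mat alpha(n, S), beta(n, S), em(n, S);
  arma::vec cvec(n), shift(n);
  for (arma::uword j = 0; j < J; ++j) {
    const arma::mat logem = logems.slice(j);
    for (arma::uword t = 0; t < n; ++t) {
      double m = logem.row(t).max();
      if (!std::isfinite(m))
        stop("all emission probabilities are zero at site " +
             std::to_string(t + 1));
      shift(t) = m;
      em.row(t) = arma::exp(logem.row(t) - m);
    }
    alpha.row(0) = (pi % em.row(0).t()).t();
    cvec(0) = arma::accu(alpha.row(0));
    if (cvec(0) <= 0) stop("zero forward probability at site 1");
    alpha.row(0) /= cvec(0);
    for (arma::uword t = 1; t < n; ++t) {
      alpha.row(t) = (alpha.row(t - 1) * trans.slice(t - 1)) % em.row(t);
      cvec(t) = arma::accu(alpha.row(t));
      if (cvec(t) <= 0)
        stop("zero forward probability at site " + std::to_string(t + 1));
      alpha.row(t) /= cvec(t);
    }
    beta.row(n - 1).ones();
    for (arma::uword t = n - 1; t-- > 0;)
      beta.row(t) = (trans.slice(t) *
                     (em.row(t + 1).t() % beta.row(t + 1).t())).t() /
                    cvec(t + 1);
    total += arma::accu(arma::log(cvec)) + arma::accu(shift);
    for (arma::uword t = 0; t + 1 < n; ++t) {
      arma::mat x = (alpha.row(t).t() *
                     (em.row(t + 1) % beta.row(t + 1) / cvec(t + 1))) %
                    trans.slice(t);
      double s = arma::accu(x);
      if (s > 0) x /= s;
      xiAcc.slice(t) += x;
    }
  }
  return List::create(_["xiAcc"] = xiAcc, _["loglik"] = total);
}
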