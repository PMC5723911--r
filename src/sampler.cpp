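// Metropolis-within-Gibbs core for the BYM gamma regression.
//
// Parameterization: fixed effects are updated on an internally standardized
// covariate scale (columns of Xs are (x - m)/s, intercept untouched); the
// prior is evaluated on the original scale after back-transformation.
// Conjugate Gibbs draws for the random-effect precisions; random-walk
// Metropolis for everything else; exact Gibbs "sweep" moves along the
// likelihood-invariant translation directions (all v vs intercept, all b vs
// exposure slope) to break the posterior ridges; per-component recentering
// of the ICAR effect with the offset absorbed into the intercept.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double gamma_loglik_sum(const NumericVector& y,
                                      const NumericVector& logy,
                                      const NumericVector& eta,
                                      double alpha) {
  const int N = y.size();
  double s = 0.0;
  const double la = std::log(alpha);
  for (int k = 0; k < N; ++k)
    s += alpha * (la - eta[k]) - alpha * y[k] * std::exp(-eta[k]);
  s += (alpha - 1.0) * Rcpp::sum(logy) - N * R::lgammafn(alpha);
  return s;
}

// change in log likelihood when eta[k] += d for k in idx
static inline double dloglik(const NumericVector& y, const NumericVector& eta,
                             double alpha, const std::vector<int>& idx,
                             double d) {
  double s = 0.0;
  for (size_t t = 0; t < idx.size(); ++t) {
    const int k = idx[t];
    s += -alpha * d - alpha * y[k] *
      (std::exp(-eta[k] - d) - std::exp(-eta[k]));
  }
  return s;
}

struct Adapt {
  std::vector<double> ls;      // log proposal scales
  std::vector<int> acc, tot;
  double target;
  explicit Adapt(int n, double init_ls, double target_) :
    ls(n, init_ls), acc(n, 0), tot(n, 0), target(target_) {}
  void update(int batch_index) {
    const double step = std::min(0.1, 1.0 / std::sqrt((double)batch_index));
    for (size_t i = 0; i < ls.size(); ++i) {
      if (tot[i] > 0) {
        const double rate = (double)acc[i] / tot[i];
        ls[i] += (rate > target) ? step : -step;
        if (ls[i] < -10.0) ls[i] = -10.0;
        if (ls[i] > 6.0) ls[i] = 6.0;
      }
      acc[i] = 0; tot[i] = 0;
    }
  }
};

// [[Rcpp::export(name = ".run_chain_cpp")]]
List run_chain_cpp(NumericVector y, NumericMatrix Xs, NumericVector colM,
                   NumericVector colS, NumericVector xexp,
                   IntegerVector region, List nbrs, IntegerMatrix edges,
                   IntegerVector comp, int exposureCol,
                   bool useU, bool useV, bool useB,
                   double priorFixedPrec, double precShape, double precRate,
                   double shapeShape, double shapeRate,
                   NumericVector fixedVals,  // alpha, tau_u, tau_v, tau_b (NA = sample)
                   NumericVector betaInit, double alphaInit,
                   int nIter, int nBurnin, int thin, int adaptBatch,
                   double targetAccept) {
  RNGScope scope;
  const int N = y.size(), p = Xs.ncol(), n = nbrs.size();
  const int ncomp = Rcpp::unique(comp).size();
  const int icar_rank = n - ncomp;

  NumericVector logy(N);
  for (int k = 0; k < N; ++k) logy[k] = std::log(y[k]);

  // per-region observation index
  std::vector< std::vector<int> > obs(n);
  for (int k = 0; k < N; ++k) obs[region[k]].push_back(k);
  // neighbour lists
  std::vector< std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = nbrs[i];
    nb[i].assign(v.begin(), v.end());
  }
  // component sizes
  std::vector<int> csize(ncomp, 0);
  for (int i = 0; i < n; ++i) csize[comp[i]]++;

  // Spectral decomposition of the ICAR precision, used by the partially
  // collapsed (tau_u, tau_v, u | u+v) update that breaks the BYM ridge.
  arma::mat Evec;
  arma::vec lam;
  if (useU && useV) {
    arma::mat Q(n, n, arma::fill::zeros);
    for (int e = 0; e < edges.nrow(); ++e) {
      const int i = edges(e, 0), j = edges(e, 1);
      Q(i, j) -= 1.0; Q(j, i) -= 1.0;
      Q(i, i) += 1.0; Q(j, j) += 1.0;
    }
    arma::eig_sym(lam, Evec, Q);
    for (int k = 0; k < n; ++k) if (lam[k] < 1e-9) lam[k] = 0.0;
  }
  // geometric-mean positive eigenvalue: scale factor for the u/v role swap
  double loglambar = 0.0;
  if (useU && useV && icar_rank > 0) {
    for (int k = 0; k < n; ++k)
      if (lam[k] > 0.0) loglambar += std::log(lam[k]);
    loglambar /= icar_rank;
  }
  const int interweave = 1;  // cadence of the collapsed u|u+v redraw

  // state
  NumericVector bs = clone(betaInit);                // std-scale fixed effects
  NumericVector u(n, 0.0), v(n, 0.0), b(n, 0.0);
  const bool fixA = R_finite(fixedVals[0]), fixTu = R_finite(fixedVals[1]),
             fixTv = R_finite(fixedVals[2]), fixTb = R_finite(fixedVals[3]);
  double alpha = fixA ? fixedVals[0] : alphaInit;
  double tauU = fixTu ? fixedVals[1] : 1.0;
  double tauV = fixTv ? fixedVals[2] : 1.0;
  double tauB = fixTb ? fixedVals[3] : 1.0;

  NumericVector eta(N);
  for (int k = 0; k < N; ++k) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += Xs(k, j) * bs[j];
    eta[k] = e;  // u=v=b=0 at init
  }

  // original-scale beta from std-scale
  NumericVector bo(p);
  auto to_orig = [&](const NumericVector& s) {
    bo[0] = s[0];
    for (int j = 1; j < p; ++j) {
      bo[j] = s[j] / colS[j];
      bo[0] -= s[j] * colM[j] / colS[j];
    }
  };
  auto beta_logprior = [&](const NumericVector& s) {
    to_orig(s);
    double q = 0.0;
    for (int j = 0; j < p; ++j) q += bo[j] * bo[j];
    return -0.5 * priorFixedPrec * q;
  };

  Adapt adBeta(p, std::log(0.1), targetAccept);
  Adapt adU(n, std::log(0.1), targetAccept);
  Adapt adV(n, std::log(0.1), targetAccept);
  Adapt adB(n, std::log(0.02), targetAccept);
  Adapt adA(1, std::log(0.3), targetAccept);

  long accBeta = 0, totBeta = 0, accU = 0, totU = 0, accV = 0, totV = 0,
       accB = 0, totB = 0, accA = 0, totA = 0;

  const int nKeep = (nIter - nBurnin) / thin;
  const int ncols = p + 3 * n + 5;
  NumericMatrix out(nKeep, ncols);
  int stored = 0, batch_index = 0;

  std::vector<int> allobs(N);
  for (int k = 0; k < N; ++k) allobs[k] = k;

  for (int it = 1; it <= nIter; ++it) {
    const bool adapting = it <= nBurnin;

    // ---- fixed effects, componentwise RW on std scale ----
    for (int j = 0; j < p; ++j) {
      const double d = std::exp(adBeta.ls[j]) * R::norm_rand();
      double dll = 0.0;
      for (int k = 0; k < N; ++k)
        dll += -alpha * d * Xs(k, j) - alpha * y[k] *
          (std::exp(-eta[k] - d * Xs(k, j)) - std::exp(-eta[k]));
      const double lp0 = beta_logprior(bs);
      bs[j] += d;
      const double lp1 = beta_logprior(bs);
      bs[j] -= d;
      const double lr = dll + lp1 - lp0;
      adBeta.tot[j]++;
      if (!adapting) totBeta++;
      if (R_finite(lr) && std::log(R::unif_rand()) < lr) {
        bs[j] += d;
        for (int k = 0; k < N; ++k) eta[k] += d * Xs(k, j);
        adBeta.acc[j]++;
        if (!adapting) accBeta++;
      }
    }

    // ---- structured intercept u, single site ----
    if (useU) {
      for (int i = 0; i < n; ++i) {
        const double d = std::exp(adU.ls[i]) * R::norm_rand();
        double dpr = 0.0;
        for (size_t t = 0; t < nb[i].size(); ++t) {
          const double diff = u[i] - u[nb[i][t]];
          dpr += -0.5 * tauU * ((diff + d) * (diff + d) - diff * diff);
        }
        const double lr = dloglik(y, eta, alpha, obs[i], d) + dpr;
        adU.tot[i]++;
        if (!adapting) totU++;
        if (R_finite(lr) && std::log(R::unif_rand()) < lr) {
          u[i] += d;
          for (size_t t = 0; t < obs[i].size(); ++t) eta[obs[i][t]] += d;
          adU.acc[i]++;
          if (!adapting) accU++;
        }
      }
      // per-component recentering; overall (size-weighted) offset into the
      // intercept so eta is unchanged on connected graphs
      std::vector<double> cm(ncomp, 0.0);
      for (int i = 0; i < n; ++i) cm[comp[i]] += u[i];
      for (int c = 0; c < ncomp; ++c) cm[c] /= csize[c];
      double shift = 0.0;
      for (int c = 0; c < ncomp; ++c) shift += cm[c] * csize[c];
      shift /= n;
      for (int i = 0; i < n; ++i) u[i] -= cm[comp[i]];
      bs[0] += shift;
      if (ncomp > 1) {
        for (int k = 0; k < N; ++k)
          eta[k] += shift - cm[comp[region[k]]];
      }
    }

    // ---- unstructured intercept v, single site ----
    if (useV) {
      for (int i = 0; i < n; ++i) {
        const double d = std::exp(adV.ls[i]) * R::norm_rand();
        const double dpr = -0.5 * tauV * ((v[i] + d) * (v[i] + d) - v[i] * v[i]);
        const double lr = dloglik(y, eta, alpha, obs[i], d) + dpr;
        adV.tot[i]++;
        if (!adapting) totV++;
        if (R_finite(lr) && std::log(R::unif_rand()) < lr) {
          v[i] += d;
          for (size_t t = 0; t < obs[i].size(); ++t) eta[obs[i][t]] += d;
          adV.acc[i]++;
          if (!adapting) accV++;
        }
      }
      // sweep: v + delta, intercept - delta (likelihood-invariant)
      to_orig(bs);
      double sv = 0.0;
      for (int i = 0; i < n; ++i) sv += v[i];
      const double P = n * tauV + priorFixedPrec;
      const double mean = (-tauV * sv + priorFixedPrec * bo[0]) / P;
      const double delta = mean + R::norm_rand() / std::sqrt(P);
      for (int i = 0; i < n; ++i) v[i] += delta;
      bs[0] -= delta;
    }

    // ---- partially collapsed update of (tau_u, tau_v, u) given s = u+v ----
    // The likelihood sees u and v only through s. In the ICAR eigenbasis,
    // s_k ~ N(0, 1/(tau_u*lam_k) + 1/tau_v) for lam_k > 0 and
    // s_k ~ N(0, 1/tau_v) on the null space (u is constrained there), so
    // (tau_u, tau_v) can be updated against this marginal with u integrated
    // out, then u redrawn exactly from its conditional. This breaks the
    // near-absorbing BYM regime where one component swallows the other.
    if (useU && useV && it % interweave == 0) {
      arma::vec s(n);
      for (int i = 0; i < n; ++i) s[i] = u[i] + v[i];
      arma::vec st = Evec.t() * s;
      auto marg = [&](double tu, double tv) {
        double ll = 0.0;
        for (int k = 0; k < n; ++k) {
          const double var = (lam[k] > 0.0 ? 1.0 / (tu * lam[k]) : 0.0) +
            1.0 / tv;
          ll += -0.5 * std::log(var) - 0.5 * st[k] * st[k] / var;
        }
        return ll;
      };
      if (!fixTu && !fixTv) {
        // joint random-walk MH on (log tau_u, log tau_v) against the
        // marginal; Gamma(a, c) priors plus log-scale Jacobians
        double lt_u = std::log(tauU), lt_v = std::log(tauV);
        double cur = marg(tauU, tauV) +
          precShape * lt_u - precRate * tauU +
          precShape * lt_v - precRate * tauV;
        for (int rep = 0; rep < 6; ++rep) {
          double pu, pv;
          if (rep == 0) {
            // symmetric role-swap proposal: exchange the per-region variance
            // contributions of the two components (jumps between the "mostly
            // structured" and "mostly unstructured" labelings)
            pu = lt_v - loglambar + 0.1 * R::norm_rand();
            pv = lt_u + loglambar + 0.1 * R::norm_rand();
          } else {
            pu = lt_u + 0.6 * R::norm_rand();
            pv = lt_v + 0.6 * R::norm_rand();
          }
          const double prop = marg(std::exp(pu), std::exp(pv)) +
            precShape * pu - precRate * std::exp(pu) +
            precShape * pv - precRate * std::exp(pv);
          if (R_finite(prop) && std::log(R::unif_rand()) < prop - cur) {
            lt_u = pu; lt_v = pv; cur = prop;
          }
        }
        tauU = std::exp(lt_u);
        tauV = std::exp(lt_v);
      }
      // exact conditional redraw of the split: u_k | s_k is normal with
      // shrinkage weight a_k / (a_k + b), a_k = 1/(tau_u*lam_k), b = 1/tau_v
      arma::vec ut(n);
      const double bvar = 1.0 / tauV;
      for (int k = 0; k < n; ++k) {
        if (lam[k] <= 0.0) { ut[k] = 0.0; continue; }
        const double ak = 1.0 / (tauU * lam[k]);
        const double w = ak / (ak + bvar);
        ut[k] = w * st[k] + std::sqrt(w * bvar) * R::norm_rand();
      }
      arma::vec un = Evec * ut;
      // per-component centering keeps the constraint; v absorbs the offset
      std::vector<double> cm(ncomp, 0.0);
      for (int i = 0; i < n; ++i) cm[comp[i]] += un[i];
      for (int c = 0; c < ncomp; ++c) cm[c] /= csize[c];
      for (int i = 0; i < n; ++i) {
        u[i] = un[i] - cm[comp[i]];
        v[i] = s[i] - u[i];
      }
    }

    // ---- random slopes b, single site ----
    if (useB) {
      for (int i = 0; i < n; ++i) {
        const double d = std::exp(adB.ls[i]) * R::norm_rand();
        double dll = 0.0;
        for (size_t t = 0; t < obs[i].size(); ++t) {
          const int k = obs[i][t];
          const double dk = d * xexp[k];
          dll += -alpha * dk - alpha * y[k] *
            (std::exp(-eta[k] - dk) - std::exp(-eta[k]));
        }
        const double dpr = -0.5 * tauB * ((b[i] + d) * (b[i] + d) - b[i] * b[i]);
        const double lr = dll + dpr;
        adB.tot[i]++;
        if (!adapting) totB++;
        if (R_finite(lr) && std::log(R::unif_rand()) < lr) {
          b[i] += d;
          for (size_t t = 0; t < obs[i].size(); ++t)
            eta[obs[i][t]] += d * xexp[obs[i][t]];
          adB.acc[i]++;
          if (!adapting) accB++;
        }
      }
      // sweep: b + delta, exposure slope - delta (likelihood-invariant)
      if (exposureCol >= 1) {
        to_orig(bs);
        double sb = 0.0;
        for (int i = 0; i < n; ++i) sb += b[i];
        const double P = n * tauB + priorFixedPrec;
        const double mean = (-tauB * sb + priorFixedPrec * bo[exposureCol]) / P;
        const double delta = mean + R::norm_rand() / std::sqrt(P);
        for (int i = 0; i < n; ++i) b[i] += delta;
        bs[exposureCol] -= delta * colS[exposureCol];
        bs[0] -= delta * colM[exposureCol];
      }
    }

    // ---- conjugate precision updates ----
    if (useU && !fixTu) {
      double S = 0.0;
      for (int e = 0; e < edges.nrow(); ++e) {
        const double diff = u[edges(e, 0)] - u[edges(e, 1)];
        S += diff * diff;
      }
      tauU = R::rgamma(precShape + 0.5 * icar_rank,
                       1.0 / (precRate + 0.5 * S));
    }
    if (useV && !fixTv) {
      double S = 0.0;
      for (int i = 0; i < n; ++i) S += v[i] * v[i];
      tauV = R::rgamma(precShape + 0.5 * n, 1.0 / (precRate + 0.5 * S));
    }
    if (useB && !fixTb) {
      double S = 0.0;
      for (int i = 0; i < n; ++i) S += b[i] * b[i];
      tauB = R::rgamma(precShape + 0.5 * n, 1.0 / (precRate + 0.5 * S));
    }

    // ---- likelihood shape alpha, RW on log scale ----
    if (!fixA) {
      const double d = std::exp(adA.ls[0]) * R::norm_rand();
      const double a1 = alpha * std::exp(d);
      const double ll0 = gamma_loglik_sum(y, logy, eta, alpha);
      const double ll1 = gamma_loglik_sum(y, logy, eta, a1);
      // Gamma(shapeShape, shapeRate) prior + log Jacobian of the log scale
      const double lr = ll1 - ll0 +
        shapeShape * (std::log(a1) - std::log(alpha)) -
        shapeRate * (a1 - alpha);
      adA.tot[0]++;
      if (!adapting) totA++;
      if (R_finite(lr) && std::log(R::unif_rand()) < lr) {
        alpha = a1;
        adA.acc[0]++;
        if (!adapting) accA++;
      }
    }

    if (adapting && it % adaptBatch == 0) {
      ++batch_index;
      adBeta.update(batch_index);
      adU.update(batch_index);
      adV.update(batch_index);
      adB.update(batch_index);
      adA.update(batch_index);
    }

    // ---- store ----
    if (it > nBurnin && (it - nBurnin) % thin == 0) {
      to_orig(bs);
      int c = 0;
      for (int j = 0; j < p; ++j) out(stored, c++) = bo[j];
      for (int i = 0; i < n; ++i) out(stored, c++) = u[i];
      for (int i = 0; i < n; ++i) out(stored, c++) = v[i];
      for (int i = 0; i < n; ++i) out(stored, c++) = b[i];
      out(stored, c++) = tauU;
      out(stored, c++) = tauV;
      out(stored, c++) = tauB;
      out(stored, c++) = alpha;
      // joint log posterior (up to additive constants shared across draws)
      double lp = gamma_loglik_sum(y, logy, eta, alpha);
      double q = 0.0;
      for (int j = 0; j < p; ++j) q += bo[j] * bo[j];
      lp += -0.5 * priorFixedPrec * q;
      if (useU) {
        double S = 0.0;
        for (int e = 0; e < edges.nrow(); ++e) {
          const double diff = u[edges(e, 0)] - u[edges(e, 1)];
          S += diff * diff;
        }
        lp += 0.5 * icar_rank * std::log(tauU) - 0.5 * tauU * S;
        lp += (precShape - 1.0) * std::log(tauU) - precRate * tauU;
      }
      if (useV) {
        double S = 0.0;
        for (int i = 0; i < n; ++i) S += v[i] * v[i];
        lp += 0.5 * n * std::log(tauV) - 0.5 * tauV * S;
        lp += (precShape - 1.0) * std::log(tauV) - precRate * tauV;
      }
      if (useB) {
        double S = 0.0;
        for (int i = 0; i < n; ++i) S += b[i] * b[i];
        lp += 0.5 * n * std::log(tauB) - 0.5 * tauB * S;
        lp += (precShape - 1.0) * std::log(tauB) - precRate * tauB;
      }
      lp += (shapeShape - 1.0) * std::log(alpha) - shapeRate * alpha;
      out(stored, c++) = lp;
      ++stored;
    }
  }

  NumericVector accept = NumericVector::create(
    Named("beta") = totBeta ? (double)accBeta / totBeta : NA_REAL,
    Named("u") = totU ? (double)accU / totU : NA_REAL,
    Named("v") = totV ? (double)accV / totV : NA_REAL,
    Named("b") = totB ? (double)accB / totB : NA_REAL,
    Named("alpha") = totA ? (double)accA / totA : NA_REAL);
  return List::create(Named("draws") = out, Named("accept") = accept);
}
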