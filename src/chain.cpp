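// Metropolis-within-Gibbs chain for the multi-species occupancy model.
// Faithful port of the reference R implementation (runChainR): identical
// update order and identical R-RNG call sequence, so for a given seed the
// two engines produce the same draws.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double ETA_CLIP = 35.0;

static inline double clipEta(double x) {
  if (x > ETA_CLIP) return ETA_CLIP;
  if (x < -ETA_CLIP) return -ETA_CLIP;
  return x;
}

// log(1 + exp(x)) on a clipped linear predictor
static inline double log1pexpClip(double x) {
  return log1p(std::exp(clipEta(x)));
}

// [[Rcpp::export(name = ".chainCpp")]]
List chainCpp(NumericMatrix x,        // N x M detections (0 on unobserved cells)
              NumericVector maskv,    // M survey mask, site-fastest
              NumericMatrix detAny,   // N x J any-detection indicator
              NumericMatrix X,        // J x Cocc occupancy design
              NumericMatrix W,        // M x Cdet detection design
              NumericVector uInit, NumericVector vInit,
              NumericVector hyperMuInit, NumericVector hyperSdInit,
              LogicalVector famFixed, // per family: u, v, alpha..., beta...
              double tau, double sdUpper,
              int iterations, int burnin, int thin, int adaptUntil,
              bool storeZ) {
  const int N = x.nrow(), M = x.ncol();
  const int J = X.nrow(), Cocc = X.ncol(), Cdet = W.ncol();
  const int K = M / J;
  const int F = 2 + Cocc + Cdet;
  const int nRet = (iterations - burnin) / thin;

  NumericVector u = clone(uInit), v = clone(vInit);
  NumericMatrix alpha(N, Cocc), beta(N, Cdet);
  NumericVector hyperMu = clone(hyperMuInit), hyperSd = clone(hyperSdInit);
  NumericMatrix etaPsi(N, J), etaP(N, M), z(N, J);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < N; ++i) { etaPsi(i, j) = u[i]; z(i, j) = 1.0; }
  for (int m = 0; m < M; ++m)
    for (int i = 0; i < N; ++i) etaP(i, m) = v[i];

  NumericMatrix scales(N, F);
  std::fill(scales.begin(), scales.end(), 0.5);
  NumericVector sdScales(F, 0.5);

  NumericVector llPsiCur(N), llDetCur(N), llNew(N), delta(N);
  NumericMatrix O(N, M);
  NumericMatrix draws(nRet, 2 * N + N * Cocc + N * Cdet + 2 * F);
  NumericVector zDraws(storeZ ? (double)N * J * nRet : 1);
  NumericVector accCount(2 * F), accTotal(2 * F);

  RNGScope scope;

  for (int t = 1; t <= iterations; ++t) {
    const bool adapting = t <= adaptUntil;
    const double gamma = adapting ? std::min(0.25, 1.0 / std::sqrt((double)t)) : 0.0;
    const bool tracking = t > burnin;

    // ---- z: exact Bernoulli full conditional ------------------------------
    for (int j = 0; j < J; ++j) {
      for (int i = 0; i < N; ++i) {
        long double logNoDet = 0.0;
        for (int k = 0; k < K; ++k) {
          const int m = k * J + j;
          if (maskv[m] != 0.0) logNoDet -= log1pexpClip(etaP(i, m));
        }
        const double psi = R::plogis(clipEta(etaPsi(i, j)), 0.0, 1.0, 1, 0);
        const double q = psi * std::exp((double)logNoDet);
        const double probZ = q / (q + 1.0 - psi);
        const double uu = unif_rand();
        z(i, j) = (detAny(i, j) != 0.0 || uu < probZ) ? 1.0 : 0.0;
      }
    }

    // ---- occupancy effects -------------------------------------------------
    for (int i = 0; i < N; ++i) {
      long double ll = 0.0;
      for (int j = 0; j < J; ++j) {
        const double e = clipEta(etaPsi(i, j));
        ll += z(i, j) * e - log1p(std::exp(e));
      }
      llPsiCur[i] = (double)ll;
    }
    for (int fam = 0; fam < 1 + Cocc; ++fam) {
      // fam 0: intercept u; fam c: alpha column c-1
      const int fidx = (fam == 0) ? 0 : 1 + fam;   // family index: u=0, alpha_c=2+c
      const int ci = fam - 1;
      for (int i = 0; i < N; ++i) delta[i] = norm_rand() * scales(i, fidx);
      for (int i = 0; i < N; ++i) {
        long double ll = 0.0;
        for (int j = 0; j < J; ++j) {
          const double mult = (fam == 0) ? 1.0 : X(j, ci);
          const double e = clipEta(etaPsi(i, j) + delta[i] * mult);
          ll += z(i, j) * e - log1p(std::exp(e));
        }
        llNew[i] = (double)ll;
      }
      double accSum = 0.0;
      for (int i = 0; i < N; ++i) {
        const double cur = (fam == 0) ? u[i] : alpha(i, ci);
        const double lpDiff =
          R::dnorm(cur + delta[i], hyperMu[fidx], hyperSd[fidx], 1) -
          R::dnorm(cur, hyperMu[fidx], hyperSd[fidx], 1);
        const bool acc = std::log(unif_rand()) < (llNew[i] - llPsiCur[i] + lpDiff);
        if (acc) {
          for (int j = 0; j < J; ++j) {
            const double mult = (fam == 0) ? 1.0 : X(j, ci);
            etaPsi(i, j) += delta[i] * mult;
          }
          llPsiCur[i] = llNew[i];
          if (fam == 0) u[i] += delta[i]; else alpha(i, ci) += delta[i];
          accSum += 1.0;
        }
        if (adapting)
          scales(i, fidx) *= std::exp(gamma * ((acc ? 1.0 : 0.0) - 0.44));
      }
      if (tracking) { accCount[fidx] += accSum; accTotal[fidx] += N; }
    }

    // ---- detection effects -------------------------------------------------
    for (int m = 0; m < M; ++m) {
      const int j = m % J;
      for (int i = 0; i < N; ++i) O(i, m) = maskv[m] * z(i, j);
    }
    for (int i = 0; i < N; ++i) {
      long double ll = 0.0;
      for (int m = 0; m < M; ++m)
        if (O(i, m) != 0.0) {
          const double e = clipEta(etaP(i, m));
          ll += x(i, m) * e - log1p(std::exp(e));
        }
      llDetCur[i] = (double)ll;
    }
    for (int fam = 0; fam < 1 + Cdet; ++fam) {
      const int fidx = (fam == 0) ? 1 : 1 + Cocc + fam;  // v=1, beta_c=2+Cocc+c
      const int ci = fam - 1;
      for (int i = 0; i < N; ++i) delta[i] = norm_rand() * scales(i, fidx);
      for (int i = 0; i < N; ++i) {
        long double ll = 0.0;
        for (int m = 0; m < M; ++m) {
          if (O(i, m) == 0.0) continue;
          const double mult = (fam == 0) ? 1.0 : W(m, ci);
          const double e = clipEta(etaP(i, m) + delta[i] * mult);
          ll += x(i, m) * e - log1p(std::exp(e));
        }
        llNew[i] = (double)ll;
      }
      double accSum = 0.0;
      for (int i = 0; i < N; ++i) {
        const double cur = (fam == 0) ? v[i] : beta(i, ci);
        const double lpDiff =
          R::dnorm(cur + delta[i], hyperMu[fidx], hyperSd[fidx], 1) -
          R::dnorm(cur, hyperMu[fidx], hyperSd[fidx], 1);
        const bool acc = std::log(unif_rand()) < (llNew[i] - llDetCur[i] + lpDiff);
        if (acc) {
          for (int m = 0; m < M; ++m) {
            const double mult = (fam == 0) ? 1.0 : W(m, ci);
            etaP(i, m) += delta[i] * mult;
          }
          llDetCur[i] = llNew[i];
          if (fam == 0) v[i] += delta[i]; else beta(i, ci) += delta[i];
          accSum += 1.0;
        }
        if (adapting)
          scales(i, fidx) *= std::exp(gamma * ((acc ? 1.0 : 0.0) - 0.44));
      }
      if (tracking) { accCount[fidx] += accSum; accTotal[fidx] += N; }
    }

    // ---- hyper-parameters --------------------------------------------------
    for (int f = 0; f < F; ++f) {
      if (famFixed[f]) continue;
      const double *vals;
      if (f == 0) vals = &u[0];
      else if (f == 1) vals = &v[0];
      else if (f < 2 + Cocc) vals = &alpha(0, f - 2);
      else vals = &beta(0, f - 2 - Cocc);
      long double sum = 0.0;
      for (int i = 0; i < N; ++i) sum += vals[i];
      const double sd2 = hyperSd[f] * hyperSd[f];
      const double prec = N / sd2 + 1.0 / (tau * tau);
      hyperMu[f] = ((double)sum / sd2) / prec + std::sqrt(1.0 / prec) * norm_rand();
      const double sNew = hyperSd[f] * std::exp(norm_rand() * sdScales[f]);
      bool accepted = false;
      if (sNew < sdUpper) {
        long double sumNew = 0.0, sumOld = 0.0;
        for (int i = 0; i < N; ++i) {
          sumNew += R::dnorm(vals[i], hyperMu[f], sNew, 1);
          sumOld += R::dnorm(vals[i], hyperMu[f], hyperSd[f], 1);
        }
        const double logr = (double)sumNew - (double)sumOld +
          std::log(sNew) - std::log(hyperSd[f]);
        if (std::log(unif_rand()) < logr) {
          hyperSd[f] = sNew;
          accepted = true;
        }
      } else {
        unif_rand();   // keep the RNG stream aligned across accept paths
      }
      if (adapting)
        sdScales[f] *= std::exp(gamma * ((accepted ? 1.0 : 0.0) - 0.44));
      if (tracking) {
        accCount[F + f] += accepted ? 1.0 : 0.0;
        accTotal[F + f] += 1.0;
      }
    }

    // ---- record ------------------------------------------------------------
    if (t > burnin && (t - burnin) % thin == 0) {
      const int r = (t - burnin) / thin - 1;
      int c = 0;
      for (int i = 0; i < N; ++i) draws(r, c++) = u[i];
      for (int i = 0; i < N; ++i) draws(r, c++) = v[i];
      for (int ci = 0; ci < Cocc; ++ci)
        for (int i = 0; i < N; ++i) draws(r, c++) = alpha(i, ci);
      for (int ci = 0; ci < Cdet; ++ci)
        for (int i = 0; i < N; ++i) draws(r, c++) = beta(i, ci);
      for (int f = 0; f < F; ++f) draws(r, c++) = hyperMu[f];
      for (int f = 0; f < F; ++f) draws(r, c++) = hyperSd[f];
      if (storeZ) {
        double *zd = &zDraws[0] + (R_xlen_t)r * N * J;
        for (int j = 0; j < J; ++j)
          for (int i = 0; i < N; ++i) zd[j * N + i] = z(i, j);
      }
    }
  }

  return List::create(
    _["draws"] = draws,
    _["z"] = zDraws,
    _["accCount"] = accCount,
    _["accTotal"] = accTotal
  );
}
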