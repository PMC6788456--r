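// Gibbs sampler for the multi-trait (multi-parity) reaction-norm
// repeatability test-day model:
//   y = HTD + DIMclass + a + pe + f*(v + q) + e
// with per-animal coefficient pairs (a_l, v_l) under precision
// Kinv (x) Phi^-1, per-cow pairs (pe_l, q_l) under I (x) Psi^-1, and
// heterogeneous residual variance by parity. Location effects are updated
// blockwise (scalar for fixed levels, 2P-vector per animal/cow); Phi and Psi
// from inverse-Wishart full conditionals, residual variances from scaled
// inverse chi-square. All randomness comes from R's RNG so chains are
// reproducible under set.seed(). The block updates run on small fixed-size
// stack buffers (2P <= 6) to keep the per-iteration cost allocation-free.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int PMAX = 6;  // max 2P supported by the stack kernels

// in-place lower Cholesky of col-major p x p matrix; false on failure
static bool cholInPlace(double* A, int p) {
  for (int j = 0; j < p; ++j) {
    double d = A[j + j * p];
    for (int k = 0; k < j; ++k) d -= A[j + k * p] * A[j + k * p];
    if (d <= 0.0 || !std::isfinite(d)) return false;
    d = std::sqrt(d);
    A[j + j * p] = d;
    for (int i = j + 1; i < p; ++i) {
      double s = A[i + j * p];
      for (int k = 0; k < j; ++k) s -= A[i + k * p] * A[j + k * p];
      A[i + j * p] = s / d;
    }
  }
  return true;
}

static void forwardSolve(const double* L, const double* b, double* y, int p) {
  for (int i = 0; i < p; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i + k * p] * y[k];
    y[i] = s / L[i + i * p];
  }
}

static void backSolve(const double* L, const double* z, double* x, int p) {
  for (int i = p - 1; i >= 0; --i) {
    double s = z[i];
    for (int k = i + 1; k < p; ++k) s -= L[k + i * p] * x[k];
    x[i] = s / L[i + i * p];
  }
}

// chol with diagonal jitter fallback on a stack copy
static void cholJitter(double* A, int p, int& jitter) {
  double save[PMAX * PMAX];
  std::copy(A, A + p * p, save);
  if (cholInPlace(A, p)) return;
  double tr = 0.0;
  for (int j = 0; j < p; ++j) tr += save[j + j * p];
  double ridge = 1e-8 * (tr / p + 1.0);
  for (int k = 0; k < 12; ++k) {
    ++jitter;
    std::copy(save, save + p * p, A);
    for (int j = 0; j < p; ++j) A[j + j * p] += ridge;
    if (cholInPlace(A, p)) return;
    ridge *= 10.0;
  }
  stop("conditional precision not positive definite after jitter");
}

static arma::mat rwishart(double df, const arma::mat& Sinv) {
  const int p = Sinv.n_rows;
  arma::mat L = arma::chol(Sinv, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat X = L * A;
  return X * X.t();
}

static arma::mat invSympdJitter(arma::mat M, int& jitter) {
  arma::mat R;
  double ridge = 1e-8 * (arma::trace(M) / M.n_rows + 1.0);
  for (int k = 0; k < 13; ++k) {
    if (arma::inv_sympd(R, M)) return R;
    ++jitter;
    M.diag() += ridge;
    ridge *= 10.0;
  }
  stop("covariance matrix not invertible after jitter");
  return R;
}

// [[Rcpp::export]]
List gibbs_rrm_cpp(const arma::vec& y, const IntegerVector& parity,
                   const arma::vec& f, const IntegerVector& htd, int nHtd,
                   const IntegerVector& dimcl, int nDim,
                   const IntegerVector& animal, int nAnim,
                   const IntegerVector& cow, int nCow,
                   const IntegerVector& Ki, const IntegerVector& Kp,
                   const arma::vec& Kx,
                   const arma::mat& Phi0, const arma::mat& Psi0,
                   const arma::vec& R0,
                   const arma::mat& SPhi, double nuPhi,
                   const arma::mat& SPsi, double nuPsi,
                   const arma::vec& s2E, double nuE,
                   int total, int burnin, int thin,
                   bool updatePhi, bool updatePsi, bool updateR) {
  const int nrec = y.n_elem;
  const int p2 = Phi0.n_rows;          // 2 * nParities
  const int P = p2 / 2;
  if (p2 > PMAX) stop("at most %d parities supported", PMAX / 2);

  // record index lists per level / animal / cow (counting sort, flat CSR)
  auto buildIndex = [nrec](const IntegerVector& key, int nkey,
                           std::vector<int>& start, std::vector<int>& item) {
    start.assign(nkey + 1, 0);
    for (int i = 0; i < nrec; ++i)
      if (key[i] > 0) ++start[key[i]];
    for (int k = 0; k < nkey; ++k) start[k + 1] += start[k];
    item.assign(start[nkey], 0);
    std::vector<int> pos(start.begin(), start.end() - 1);
    for (int i = 0; i < nrec; ++i)
      if (key[i] > 0) item[pos[key[i] - 1]++] = i;
  };
  std::vector<int> hS, hI, dS, dI, aS, aI, cS, cI, pS, pI;
  buildIndex(htd, nHtd, hS, hI);
  buildIndex(dimcl, nDim, dS, dI);
  buildIndex(animal, nAnim, aS, aI);
  buildIndex(cow, nCow, cS, cI);
  buildIndex(parity, P, pS, pI);

  arma::vec bH(nHtd, arma::fill::zeros), bD(nDim, arma::fill::zeros);
  arma::mat U(p2, nAnim, arma::fill::zeros), W(p2, nCow, arma::fill::zeros);
  arma::mat Phi = Phi0, Psi = Psi0;
  arma::vec Rv = R0;
  arma::vec e = y;                     // residuals (all effects start at 0)
  int jitter = 0;
  arma::mat PhiInv = invSympdJitter(Phi, jitter);
  arma::mat PsiInv = invSympdJitter(Psi, jitter);

  const int nv = p2 * (p2 + 1) / 2;
  const int keep = (total - burnin) / thin;
  arma::mat out(keep, 2 * nv + P);
  int row = 0;

  double rinv[3];
  double Prec[PMAX * PMAX], Lbuf[PMAX * PMAX];
  double r[PMAX], acc[PMAX], z[PMAX], mu[PMAX], tmp[PMAX], un[PMAX];

  for (int it = 1; it <= total; ++it) {
    for (int l = 0; l < P; ++l) rinv[l] = 1.0 / Rv(l);

    // ---- fixed effects (flat prior, scalar updates) ----
    for (int j = 0; j < nHtd; ++j) {
      double sw = 0, sr = 0;
      for (int k = hS[j]; k < hS[j + 1]; ++k) {
        int i = hI[k];
        double wgt = rinv[parity[i] - 1];
        sr += (e[i] + bH(j)) * wgt;
        sw += wgt;
      }
      double bn = sr / sw + R::norm_rand() / std::sqrt(sw);
      double dlt = bn - bH(j);
      bH(j) = bn;
      for (int k = hS[j]; k < hS[j + 1]; ++k) e[hI[k]] -= dlt;
    }
    for (int j = 0; j < nDim; ++j) {
      double sw = 0, sr = 0;
      for (int k = dS[j]; k < dS[j + 1]; ++k) {
        int i = dI[k];
        double wgt = rinv[parity[i] - 1];
        sr += (e[i] + bD(j)) * wgt;
        sw += wgt;
      }
      double bn = sr / sw + R::norm_rand() / std::sqrt(sw);
      double dlt = bn - bD(j);
      bD(j) = bn;
      for (int k = dS[j]; k < dS[j + 1]; ++k) e[dI[k]] -= dlt;
    }

    // ---- additive animal blocks ----
    const double* Pi = PhiInv.memptr();
    for (int n = 0; n < nAnim; ++n) {
      double ann = 0;
      std::fill(acc, acc + p2, 0.0);
      for (int k = Kp[n]; k < Kp[n + 1]; ++k) {
        int m = Ki[k];
        if (m == n) { ann = Kx[k]; continue; }
        const double* um = U.colptr(m);
        double a = Kx[k];
        for (int q = 0; q < p2; ++q) acc[q] += a * um[q];
      }
      for (int cjj = 0; cjj < p2; ++cjj) {
        double s = 0;
        for (int q = 0; q < p2; ++q) s += Pi[cjj + q * p2] * acc[q];
        r[cjj] = -s;
        for (int cii = 0; cii < p2; ++cii)
          Prec[cii + cjj * p2] = ann * Pi[cii + cjj * p2];
      }
      double* ucol = U.colptr(n);
      for (int k = aS[n]; k < aS[n + 1]; ++k) {
        int i = aI[k];
        int l = parity[i] - 1;
        double wgt = rinv[l], fi = f[i];
        double ystar = e[i] + ucol[2 * l] + fi * ucol[2 * l + 1];
        r[2 * l] += ystar * wgt;
        r[2 * l + 1] += ystar * fi * wgt;
        Prec[2 * l + 2 * l * p2] += wgt;
        Prec[2 * l + (2 * l + 1) * p2] += fi * wgt;
        Prec[2 * l + 1 + 2 * l * p2] += fi * wgt;
        Prec[2 * l + 1 + (2 * l + 1) * p2] += fi * fi * wgt;
      }
      std::copy(Prec, Prec + p2 * p2, Lbuf);
      cholJitter(Lbuf, p2, jitter);
      forwardSolve(Lbuf, r, tmp, p2);
      backSolve(Lbuf, tmp, mu, p2);
      for (int q = 0; q < p2; ++q) z[q] = R::norm_rand();
      backSolve(Lbuf, z, un, p2);
      for (int q = 0; q < p2; ++q) un[q] += mu[q];
      for (int k = aS[n]; k < aS[n + 1]; ++k) {
        int i = aI[k];
        int l = parity[i] - 1;
        e[i] -= (un[2 * l] - ucol[2 * l]) +
                f[i] * (un[2 * l + 1] - ucol[2 * l + 1]);
      }
      std::copy(un, un + p2, ucol);
    }

    // ---- permanent-environment cow blocks ----
    const double* Qi = PsiInv.memptr();
    for (int c = 0; c < nCow; ++c) {
      std::copy(Qi, Qi + p2 * p2, Prec);
      std::fill(r, r + p2, 0.0);
      double* wcol = W.colptr(c);
      for (int k = cS[c]; k < cS[c + 1]; ++k) {
        int i = cI[k];
        int l = parity[i] - 1;
        double wgt = rinv[l], fi = f[i];
        double ystar = e[i] + wcol[2 * l] + fi * wcol[2 * l + 1];
        r[2 * l] += ystar * wgt;
        r[2 * l + 1] += ystar * fi * wgt;
        Prec[2 * l + 2 * l * p2] += wgt;
        Prec[2 * l + (2 * l + 1) * p2] += fi * wgt;
        Prec[2 * l + 1 + 2 * l * p2] += fi * wgt;
        Prec[2 * l + 1 + (2 * l + 1) * p2] += fi * fi * wgt;
      }
      std::copy(Prec, Prec + p2 * p2, Lbuf);
      cholJitter(Lbuf, p2, jitter);
      forwardSolve(Lbuf, r, tmp, p2);
      backSolve(Lbuf, tmp, mu, p2);
      for (int q = 0; q < p2; ++q) z[q] = R::norm_rand();
      backSolve(Lbuf, z, un, p2);
      for (int q = 0; q < p2; ++q) un[q] += mu[q];
      for (int k = cS[c]; k < cS[c + 1]; ++k) {
        int i = cI[k];
        int l = parity[i] - 1;
        e[i] -= (un[2 * l] - wcol[2 * l]) +
                f[i] * (un[2 * l + 1] - wcol[2 * l + 1]);
      }
      std::copy(un, un + p2, wcol);
    }

    // ---- Phi | U : inverse-Wishart with scale SPhi + U Kinv U' ----
    if (updatePhi) {
      arma::mat S = SPhi;
      double* Sp = S.memptr();
      for (int m = 0; m < nAnim; ++m) {
        const double* um = U.colptr(m);
        for (int k = Kp[m]; k < Kp[m + 1]; ++k) {
          const double* un2 = U.colptr(Ki[k]);
          double a = Kx[k];
          for (int cjj = 0; cjj < p2; ++cjj) {
            double aum = a * um[cjj];
            for (int cii = 0; cii < p2; ++cii)
              Sp[cii + cjj * p2] += aum * un2[cii];
          }
        }
      }
      S = 0.5 * (S + S.t());
      arma::mat Wd = rwishart(nuPhi + nAnim, invSympdJitter(S, jitter));
      PhiInv = Wd;
      Phi = invSympdJitter(Wd, jitter);
    }

    // ---- Psi | W ----
    if (updatePsi) {
      arma::mat S = SPsi + W * W.t();
      S = 0.5 * (S + S.t());
      arma::mat Wd = rwishart(nuPsi + nCow, invSympdJitter(S, jitter));
      PsiInv = Wd;
      Psi = invSympdJitter(Wd, jitter);
    }

    // ---- residual variances by parity: scaled inverse chi-square ----
    if (updateR) {
      for (int l = 0; l < P; ++l) {
        double sse = 0;
        for (int k = pS[l]; k < pS[l + 1]; ++k) sse += e[pI[k]] * e[pI[k]];
        Rv(l) = (nuE * s2E(l) + sse) /
                R::rchisq(nuE + (double)(pS[l + 1] - pS[l]));
      }
    }

    if (it > burnin && (it - burnin) % thin == 0) {
      int col = 0;
      for (int j = 0; j < p2; ++j)
        for (int i = j; i < p2; ++i) out(row, col++) = Phi(i, j);
      for (int j = 0; j < p2; ++j)
        for (int i = j; i < p2; ++i) out(row, col++) = Psi(i, j);
      for (int l = 0; l < P; ++l) out(row, col++) = Rv(l);
      ++row;
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["samples"] = out, _["jitter"] = jitter,
                      _["U"] = U.t(), _["W"] = W.t());
}
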