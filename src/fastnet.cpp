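// Numerical core: bivariate normal rectangle probabilities, two-step
// polychoric maximum likelihood, graphical-lasso coordinate descent with
// EBIC path selection, and a Gibbs sampler for the Ising model.
// Kept in C++ because bootstrap / permutation procedures re-estimate the
// network tens of thousands of times.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double TWOPI = 6.283185307179586;

static inline double phid(double x) { return R::pnorm(x, 0.0, 1.0, 1, 0); }

// Gauss-Legendre abscissae/weights (6-, 12-, 20-point rules) for the
// Drezner & Wesolowsky / Genz algorithm.
static const double GL_X[3][10] = {
  {-0.9324695142031521, -0.6612093864662645, -0.2386191860831969,
    0, 0, 0, 0, 0, 0, 0},
  {-0.9815606342467192, -0.9041172563704749, -0.7699026741943047,
   -0.5873179542866175, -0.3678314989981802, -0.1252334085114689,
    0, 0, 0, 0},
  {-0.9931285991850949, -0.9639719272779138, -0.9122344282513259,
   -0.8391169718222188, -0.7463319064601508, -0.6360536807265150,
   -0.5108670019508271, -0.3737060887154196, -0.2277858511416451,
   -0.07652652113349733}
};
static const double GL_W[3][10] = {
  {0.1713244923791704, 0.3607615730481386, 0.4679139345726910,
   0, 0, 0, 0, 0, 0, 0},
  {0.04717533638651183, 0.1069393259953184, 0.1600783285433462,
   0.2031674267230659, 0.2334925365383548, 0.2491470458134028,
   0, 0, 0, 0},
  {0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
   0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
   0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
   0.1527533871307259}
};

// P(X > dh, Y > dk) for a standard bivariate normal with correlation r.
static double bvnu(double dh, double dk, double r) {
  int ng, lg;
  double ar = std::fabs(r);
  if (ar < 0.3)       { ng = 0; lg = 3; }
  else if (ar < 0.75) { ng = 1; lg = 6; }
  else                { ng = 2; lg = 10; }

  double h = dh, k = dk, hk = h * k, bvn = 0.0;
  if (ar < 0.925) {
    if (ar > 0.0) {
      double hs = (h * h + k * k) / 2.0;
      double asr = std::asin(r);
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double sn = std::sin(asr * (is * GL_X[ng][i] + 1.0) / 2.0);
          bvn += GL_W[ng][i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
        }
      }
      bvn = bvn * asr / (2.0 * TWOPI);
    }
    bvn += phid(-h) * phid(-k);
  } else {
    if (r < 0.0) { k = -k; hk = -hk; }
    if (ar < 1.0) {
      double as_ = (1.0 - r) * (1.0 + r);
      double a = std::sqrt(as_);
      double bs = (h - k) * (h - k);
      double c = (4.0 - hk) / 8.0;
      double d = (12.0 - hk) / 16.0;
      double asr = -(bs / as_ + hk) / 2.0;
      if (asr > -100.0)
        bvn = a * std::exp(asr) *
          (1.0 - c * (bs - as_) * (1.0 - d * bs / 5.0) / 3.0 +
           c * d * as_ * as_ / 5.0);
      if (-hk < 100.0) {
        double b = std::sqrt(bs);
        bvn -= std::exp(-hk / 2.0) * std::sqrt(TWOPI) * phid(-b / a) * b *
          (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
      }
      a /= 2.0;
      for (int i = 0; i < lg; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double x = a * (is * GL_X[ng][i] + 1.0);
          double xs = x * x;
          double rs = std::sqrt(1.0 - xs);
          double asr2 = -(bs / xs + hk) / 2.0;
          if (asr2 > -100.0)
            bvn += a * GL_W[ng][i] * std::exp(asr2) *
              (std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs -
               (1.0 + c * xs * (1.0 + d * xs)));
        }
      }
      bvn = -bvn / TWOPI;
    }
    if (r > 0.0) {
      bvn += phid(-std::max(h, k));
    } else {
      bvn = -bvn;
      if (k > h) bvn += phid(k) - phid(h);
    }
  }
  return std::min(1.0, std::max(0.0, bvn));
}

// P(X <= h, Y <= k); thresholds may be +/- infinity.
// [[Rcpp::export]]
double bvn_prob_cpp(double h, double k, double rho) {
  if (ISNAN(h) || ISNAN(k) || ISNAN(rho)) return NA_REAL;
  if (h == R_NegInf || k == R_NegInf) return 0.0;
  if (h == R_PosInf && k == R_PosInf) return 1.0;
  if (h == R_PosInf) return phid(k);
  if (k == R_PosInf) return phid(h);
  return bvnu(-h, -k, rho);
}

// Bivariate normal log-likelihood of an ordinal contingency table, given
// latent thresholds (length nrow-1 / ncol-1, extended by +/-inf).
static double poly_loglik(const arma::mat& counts,
                          const std::vector<double>& tx,
                          const std::vector<double>& ty,
                          double rho) {
  const int a = counts.n_rows, b = counts.n_cols;
  std::vector<double> ex(a + 1), ey(b + 1);
  ex[0] = R_NegInf; ex[a] = R_PosInf;
  for (int i = 1; i < a; i++) ex[i] = tx[i - 1];
  ey[0] = R_NegInf; ey[b] = R_PosInf;
  for (int j = 1; j < b; j++) ey[j] = ty[j - 1];

  arma::mat C(a + 1, b + 1);
  for (int i = 0; i <= a; i++)
    for (int j = 0; j <= b; j++)
      C(i, j) = bvn_prob_cpp(ex[i], ey[j], rho);

  double ll = 0.0;
  for (int i = 0; i < a; i++) {
    for (int j = 0; j < b; j++) {
      if (counts(i, j) > 0) {
        double p = C(i + 1, j + 1) - C(i, j + 1) - C(i + 1, j) + C(i, j);
        if (p < 1e-12) p = 1e-12;
        ll += counts(i, j) * std::log(p);
      }
    }
  }
  return ll;
}

// [[Rcpp::export]]
double polychoric_loglik_cpp(const arma::mat& counts,
                             const arma::vec& tx, const arma::vec& ty,
                             double rho) {
  std::vector<double> vx(tx.begin(), tx.end()), vy(ty.begin(), ty.end());
  return poly_loglik(counts, vx, vy, rho);
}

// Golden-section maximization of the profile likelihood over rho.
static double poly_opt_rho(const arma::mat& counts,
                           const std::vector<double>& tx,
                           const std::vector<double>& ty,
                           double tol) {
  const double gr = 0.6180339887498949;
  double lo = -0.999, hi = 0.999;
  double x1 = hi - gr * (hi - lo);
  double x2 = lo + gr * (hi - lo);
  double f1 = poly_loglik(counts, tx, ty, x1);
  double f2 = poly_loglik(counts, tx, ty, x2);
  while (hi - lo > tol) {
    if (f1 < f2) {
      lo = x1; x1 = x2; f1 = f2;
      x2 = lo + gr * (hi - lo);
      f2 = poly_loglik(counts, tx, ty, x2);
    } else {
      hi = x2; x2 = x1; f2 = f1;
      x1 = hi - gr * (hi - lo);
      f1 = poly_loglik(counts, tx, ty, x1);
    }
  }
  return (lo + hi) / 2.0;
}

// Thresholds from marginal cumulative proportions (two-step estimator).
static std::vector<double> marginal_thresholds(const arma::vec& margin) {
  const int L = margin.n_elem;
  const double n = arma::accu(margin);
  std::vector<double> thr(L - 1);
  double cum = 0.0;
  for (int i = 0; i < L - 1; i++) {
    cum += margin(i);
    thr[i] = R::qnorm(cum / n, 0.0, 1.0, 1, 0);
  }
  return thr;
}

// [[Rcpp::export]]
List polychoric_pair_cpp(const arma::mat& counts, double tol) {
  arma::vec rowm = arma::sum(counts, 1);
  arma::vec colm = arma::sum(counts, 0).t();
  std::vector<double> tx = marginal_thresholds(rowm);
  std::vector<double> ty = marginal_thresholds(colm);
  double rho = poly_opt_rho(counts, tx, ty, tol);
  return List::create(_["rho"] = rho,
                      _["x_thresholds"] = NumericVector(tx.begin(), tx.end()),
                      _["y_thresholds"] = NumericVector(ty.begin(), ty.end()));
}

// Full polychoric correlation matrix for an integer-coded data matrix.
// Columns must each have >= 2 observed categories (checked in R).
// [[Rcpp::export]]
List polychoric_matrix_cpp(const IntegerMatrix& X, double tol) {
  const int n = X.nrow(), p = X.ncol();
  // recode each column to 0..L-1
  std::vector< std::vector<int> > code(p, std::vector<int>(n));
  std::vector<int> nlev(p);
  std::vector< std::vector<double> > thr(p);
  for (int j = 0; j < p; j++) {
    std::vector<int> vals(n);
    for (int i = 0; i < n; i++) vals[i] = X(i, j);
    std::vector<int> uq(vals);
    std::sort(uq.begin(), uq.end());
    uq.erase(std::unique(uq.begin(), uq.end()), uq.end());
    nlev[j] = uq.size();
    for (int i = 0; i < n; i++)
      code[j][i] = std::lower_bound(uq.begin(), uq.end(), vals[i]) - uq.begin();
    arma::vec margin(nlev[j], arma::fill::zeros);
    for (int i = 0; i < n; i++) margin(code[j][i]) += 1.0;
    thr[j] = marginal_thresholds(margin);
  }
  arma::mat R(p, p, arma::fill::eye);
  for (int a = 0; a < p - 1; a++) {
    for (int b = a + 1; b < p; b++) {
      arma::mat counts(nlev[a], nlev[b], arma::fill::zeros);
      for (int i = 0; i < n; i++) counts(code[a][i], code[b][i]) += 1.0;
      double rho = poly_opt_rho(counts, thr[a], thr[b], tol);
      R(a, b) = rho;
      R(b, a) = rho;
    }
  }
  List th(p);
  for (int j = 0; j < p; j++)
    th[j] = NumericVector(thr[j].begin(), thr[j].end());
  return List::create(_["rho"] = R, _["thresholds"] = th);
}

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One graphical-lasso fit (Friedman et al. block coordinate descent).
// W (estimated covariance) and B (column regression coefficients) are
// modified in place so the lambda path can warm-start.
static int glasso_core(const arma::mat& S, double lambda,
                       arma::mat& W, arma::mat& B,
                       double tol, int maxit) {
  // Off-diagonal penalty only: at the optimum diag(W) = diag(S).
  const int p = S.n_rows;
  for (int j = 0; j < p; j++) W(j, j) = S(j, j);
  double offsum = 0.0; int offn = 0;
  for (int i = 0; i < p; i++)
    for (int j = 0; j < p; j++)
      if (i != j) { offsum += std::fabs(S(i, j)); offn++; }
  double thr = tol * std::max(offsum / std::max(offn, 1), 1e-8);

  const int q = p - 1;
  std::vector<double> W11(q * q), s12(q), beta(q), v(q);
  std::vector<int> idx(q);
  int it = 0;
  for (; it < maxit; it++) {
    double maxdiff = 0.0;
    for (int j = 0; j < p; j++) {
      int m = 0;
      for (int k = 0; k < p; k++) if (k != j) idx[m++] = k;
      for (int c = 0; c < q; c++) {
        const double* wc = W.colptr(idx[c]);
        for (int r = 0; r < q; r++) W11[c * q + r] = wc[idx[r]];
      }
      for (int k = 0; k < q; k++) {
        s12[k] = S(idx[k], j);
        beta[k] = B(idx[k], j);
      }
      // lasso coordinate descent on 0.5 b'W11 b - s12'b + lambda|b|_1,
      // keeping the residual v = W11 b incrementally (inactive
      // coordinates cost O(1))
      std::fill(v.begin(), v.end(), 0.0);
      for (int k = 0; k < q; k++) {
        if (beta[k] != 0.0) {
          const double bk = beta[k];
          const double* col = &W11[k * q];
          for (int r = 0; r < q; r++) v[r] += col[r] * bk;
        }
      }
      for (int inner = 0; inner < 100; inner++) {
        double del = 0.0;
        for (int k = 0; k < q; k++) {
          const double old = beta[k];
          const double wkk = W11[k * q + k];
          const double r = s12[k] - v[k] + wkk * old;
          const double nb = soft(r, lambda) / wkk;
          if (nb != old) {
            const double d = nb - old;
            beta[k] = nb;
            const double* col = &W11[k * q];
            for (int rr = 0; rr < q; rr++) v[rr] += col[rr] * d;
            if (std::fabs(d) > del) del = std::fabs(d);
          }
        }
        if (del < thr * 0.1) break;
      }
      for (int k = 0; k < q; k++) {
        const double d = std::fabs(W(idx[k], j) - v[k]);
        if (d > maxdiff) maxdiff = d;
        W(idx[k], j) = v[k];
        W(j, idx[k]) = v[k];
        B(idx[k], j) = beta[k];
      }
    }
    if (maxdiff < thr) { it++; break; }
  }
  return it;
}

// Precision matrix from converged (W, B).
static arma::mat theta_from_wb(const arma::mat& W, const arma::mat& B) {
  const int p = W.n_rows;
  arma::mat Theta(p, p, arma::fill::zeros);
  arma::uvec all = arma::regspace<arma::uvec>(0, p - 1);
  for (int j = 0; j < p; j++) {
    arma::uvec idx = arma::find(all != (unsigned) j);
    arma::vec beta = B.col(j); beta = beta(idx);
    arma::vec w12 = W.col(j); w12 = w12(idx);
    double tjj = 1.0 / (W(j, j) - arma::dot(w12, beta));
    Theta(j, j) = tjj;
    for (int k = 0; k < p - 1; k++) Theta(idx(k), j) = -beta(k) * tjj;
  }
  return 0.5 * (Theta + Theta.t());
}

// [[Rcpp::export]]
List glasso_cpp(const arma::mat& S, double lambda, double tol, int maxit) {
  const int p = S.n_rows;
  arma::mat W = S;
  arma::mat B(p, p, arma::fill::zeros);
  int it = glasso_core(S, lambda, W, B, tol, maxit);
  arma::mat Theta = theta_from_wb(W, B);
  return List::create(_["theta"] = Theta, _["w"] = W,
                      _["iterations"] = it,
                      _["converged"] = it < maxit);
}

// Graphical-lasso lambda path (descending) with EBIC selection.
// EBIC = -2 * (n/2)(logdet K - tr(SK)) + E log n + 4 E gamma log p.
// [[Rcpp::export]]
List ebic_path_cpp(const arma::mat& S, int n, double gamma,
                   const arma::vec& lambdas, double tol, int maxit) {
  const int p = S.n_rows, nl = lambdas.n_elem;
  arma::mat W = S;
  arma::mat B(p, p, arma::fill::zeros);
  arma::vec ebic(nl), lls(nl);
  arma::ivec ecount(nl), iters(nl);
  arma::mat bestTheta;
  double best = R_PosInf;
  int besti = -1;
  for (int l = 0; l < nl; l++) {
    double lam = lambdas(l);
    iters(l) = glasso_core(S, lam, W, B, tol, maxit);
    arma::mat Theta = theta_from_wb(W, B);
    int E = 0;
    for (int i = 0; i < p - 1; i++)
      for (int j = i + 1; j < p; j++)
        if (std::fabs(Theta(i, j)) > 1e-8) E++;
    double ld, sign;
    arma::log_det(ld, sign, Theta);
    double ll = 0.5 * n * (ld - arma::accu(S % Theta));
    lls(l) = ll;
    ecount(l) = E;
    ebic(l) = -2.0 * ll + E * std::log((double) n) +
      4.0 * E * gamma * std::log((double) p);
    if (ebic(l) < best) { best = ebic(l); besti = l; bestTheta = Theta; }
  }
  // partial correlations of the selected precision matrix
  arma::mat Wt(p, p, arma::fill::zeros);
  for (int i = 0; i < p; i++)
    for (int j = 0; j < p; j++)
      if (i != j) {
        double v = -bestTheta(i, j) /
          std::sqrt(bestTheta(i, i) * bestTheta(j, j));
        if (std::fabs(v) < 1e-10) v = 0.0;
        Wt(i, j) = std::min(1.0, std::max(-1.0, v));
      }
  return List::create(_["theta"] = bestTheta, _["weights"] = Wt,
                      _["lambda_index"] = besti + 1,
                      _["lambda"] = lambdas(besti),
                      _["ebic"] = ebic, _["loglik"] = lls,
                      _["n_edges"] = ecount, _["iterations"] = iters);
}

// Spearman correlation: average ranks per column, Pearson on the ranks.
// [[Rcpp::export]]
arma::mat spearman_cor_cpp(const arma::mat& X) {
  const int n = X.n_rows, p = X.n_cols;
  arma::mat Rk(n, p);
  std::vector<int> ord(n);
  for (int j = 0; j < p; j++) {
    const double* col = X.colptr(j);
    for (int i = 0; i < n; i++) ord[i] = i;
    std::sort(ord.begin(), ord.end(),
              [col](int a, int b) { return col[a] < col[b]; });
    int i = 0;
    while (i < n) {
      int k = i;
      while (k + 1 < n && col[ord[k + 1]] == col[ord[i]]) k++;
      const double avg = (i + k) / 2.0 + 1.0;
      for (int t = i; t <= k; t++) Rk(ord[t], j) = avg;
      i = k + 1;
    }
  }
  return arma::cor(Rk);
}

// Gibbs sampler for a binary (0/1) Ising model with conditional logit
// tau_i + sum_j beta_ij x_j. Uses R's RNG stream for reproducibility.
// [[Rcpp::export]]
IntegerMatrix ising_gibbs_cpp(const arma::vec& tau, const arma::mat& beta,
                              int n, int burn_in, int thin) {
  const int p = tau.n_elem;
  std::vector<int> x(p);
  for (int j = 0; j < p; j++) x[j] = unif_rand() < 0.5 ? 1 : 0;
  IntegerMatrix out(n, p);
  int row = 0;
  const int total = burn_in + n * thin;
  for (int s = 0; s < total && row < n; s++) {
    for (int j = 0; j < p; j++) {
      double eta = tau(j);
      for (int k = 0; k < p; k++)
        if (k != j && x[k]) eta += beta(j, k);
      double pr = 1.0 / (1.0 + std::exp(-eta));
      x[j] = unif_rand() < pr ? 1 : 0;
    }
    if (s >= burn_in && (s - burn_in) % thin == 0) {
      for (int j = 0; j < p; j++) out(row, j) = x[j];
      row++;
    }
  }
  return out;
}
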