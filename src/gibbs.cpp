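// Data-augmentation Gibbs sampler for ordinal-probit confirmatory factor
// models (theta parameterization: residual and factor variances fixed at 1),
// plus the compiled pieces of the posterior-predictive check: bivariate
// normal rectangle probabilities and pairwise G^2 discrepancies.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double POS_INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// Truncated standard normal on (a, b).  Inverse-CDF where the interval has
// usable probability mass; tail rejection (Robert 1995 exponential proposal
// for one-sided, uniform proposal for narrow two-sided intervals) otherwise.
static double rtnorm_std(double a, double b) {
  double pa = std::isfinite(a) ? R::pnorm(a, 0.0, 1.0, 1, 0) : 0.0;
  double pb = std::isfinite(b) ? R::pnorm(b, 0.0, 1.0, 1, 0) : 1.0;
  if (pb - pa > 1e-9) {
    double u = R::runif(pa, pb);
    if (u <= 0.0) u = 1e-300;
    if (u >= 1.0) u = 1.0 - 1e-16;
    double z = R::qnorm(u, 0.0, 1.0, 1, 0);
    if (z < a) z = a; else if (z > b) z = b;
    return z;
  }
  bool flip = false;
  if (std::isfinite(b) && b <= 0.0) { // both bounds in lower tail: mirror
    double t = a; a = -b; b = std::isfinite(t) ? -t : POS_INF; flip = true;
  }
  if (!std::isfinite(b)) {
    // one-sided [a, inf) with a in the far upper tail
    double alpha = (a + std::sqrt(a * a + 4.0)) / 2.0;
    for (int it = 0; it < 10000; ++it) {
      double z = a + R::rexp(1.0 / alpha);
      double d = z - alpha;
      if (std::log(R::runif(0.0, 1.0)) <= -d * d / 2.0)
        return flip ? -z : z;
    }
    return flip ? -a : a;
  }
  // two-sided interval in the upper tail: uniform proposal, density peak at a
  for (int it = 0; it < 100000; ++it) {
    double z = R::runif(a, b);
    if (std::log(R::runif(0.0, 1.0)) <= (a * a - z * z) / 2.0)
      return flip ? -z : z;
  }
  double m = (a + b) / 2.0;
  return flip ? -m : m;
}

static double rtnorm(double mu, double sd, double lo, double hi) {
  double a = std::isfinite(lo) ? (lo - mu) / sd : NEG_INF;
  double b = std::isfinite(hi) ? (hi - mu) / sd : POS_INF;
  return mu + sd * rtnorm_std(a, b);
}

// [[Rcpp::export]]
double rtnorm_cpp(double mu, double sd, double lo, double hi) {
  return rtnorm(mu, sd, lo, hi);
}

// ---------------------------------------------------------------------------
// One MCMC chain.  Y holds categories 0..ncat[j]-1, NA for missing.
// pattern (J x F) marks free loadings; fixed entries stay at lambda0.
// Missing cells are imputed in the augmentation step each iteration.
// [[Rcpp::export]]
List gibbs_chain(const IntegerMatrix& Y, const IntegerVector& ncat,
                 const IntegerMatrix& pattern,
                 int n_iter, int n_burn, int thin,
                 double pv_load, double pv_thresh,
                 const arma::mat& lambda0, const List& tau0,
                 bool update_lambda, bool update_tau, bool store_eta) {
  const int n = Y.nrow(), J = Y.ncol(), F = pattern.ncol();

  arma::mat Lambda = lambda0;            // J x F
  std::vector<arma::vec> tau(J);
  int ntau = 0, nfree = 0;
  for (int j = 0; j < J; ++j) {
    tau[j] = as<arma::vec>(tau0[j]);     // length ncat[j] - 1, increasing
    ntau += ncat[j] - 1;
    for (int f = 0; f < F; ++f) if (pattern(j, f)) ++nfree;
  }

  arma::mat Eta(n, F, arma::fill::zeros);
  arma::mat Ystar(n, J, arma::fill::zeros);

  const int n_keep = (n_iter - n_burn + thin - 1) / thin;
  arma::mat Ldraws(n_keep, nfree);
  arma::mat Tdraws(n_keep, ntau);
  arma::mat Edraws;
  if (store_eta) Edraws.set_size(n_keep, n * F);

  int keep = 0;
  for (int iter = 0; iter < n_iter; ++iter) {
    // -- 1. latent responses y* | eta, lambda, tau, data ---------------------
    for (int j = 0; j < J; ++j) {
      const int K = ncat[j];
      for (int i = 0; i < n; ++i) {
        double mu = arma::dot(Lambda.row(j), Eta.row(i));
        int c = Y(i, j);
        if (c == NA_INTEGER) {
          Ystar(i, j) = R::rnorm(mu, 1.0);
        } else {
          double lo = (c == 0) ? NEG_INF : tau[j](c - 1);
          double hi = (c == K - 1) ? POS_INF : tau[j](c);
          Ystar(i, j) = rtnorm(mu, 1.0, lo, hi);
        }
      }
    }

    // -- 2. factor scores eta | y*, lambda ----------------------------------
    arma::mat P = arma::eye(F, F) + Lambda.t() * Lambda;
    arma::mat U = arma::chol(P);                  // P = U'U, U upper
    arma::mat M = arma::solve(P, Lambda.t() * Ystar.t()).t(); // n x F means
    arma::mat Z(n, F);
    for (int i = 0; i < n; ++i)
      for (int f = 0; f < F; ++f) Z(i, f) = R::norm_rand();
    // rows of Z * inv(U)' have covariance P^{-1}
    Eta = M + arma::solve(arma::trimatu(U), Z.t()).t();

    // -- 3. loadings lambda_j | y*, eta -------------------------------------
    if (update_lambda) {
      for (int j = 0; j < J; ++j) {
        std::vector<unsigned int> idx;
        for (int f = 0; f < F; ++f) if (pattern(j, f)) idx.push_back(f);
        if (idx.empty()) continue;
        arma::uvec S(idx);
        arma::mat X = Eta.cols(S);
        arma::mat A = X.t() * X + arma::eye(S.n_elem, S.n_elem) / pv_load;
        arma::vec m = arma::solve(A, X.t() * Ystar.col(j));
        arma::mat Ua = arma::chol(A);
        arma::vec z(S.n_elem);
        for (unsigned int u = 0; u < S.n_elem; ++u) z(u) = R::norm_rand();
        arma::vec lam = m + arma::solve(arma::trimatu(Ua), z);
        for (unsigned int u = 0; u < S.n_elem; ++u) Lambda(j, S(u)) = lam(u);
      }
    }

    // -- 4. thresholds tau_j | y*, data -------------------------------------
    if (update_tau) {
      double psd = std::sqrt(pv_thresh);
      for (int j = 0; j < J; ++j) {
        const int K = ncat[j];
        for (int m = 0; m < K - 1; ++m) {
          double lo = (m > 0) ? tau[j](m - 1) : NEG_INF;
          double hi = (m < K - 2) ? tau[j](m + 1) : POS_INF;
          for (int i = 0; i < n; ++i) {
            int c = Y(i, j);
            if (c == NA_INTEGER) continue;
            if (c == m && Ystar(i, j) > lo) lo = Ystar(i, j);
            else if (c == m + 1 && Ystar(i, j) < hi) hi = Ystar(i, j);
          }
          if (lo < hi) tau[j](m) = rtnorm(0.0, psd, lo, hi);
          // lo >= hi cannot occur with consistent augmentation; keep value
        }
      }
    }

    // -- store ---------------------------------------------------------------
    if (iter >= n_burn && (iter - n_burn) % thin == 0) {
      int p = 0;
      for (int j = 0; j < J; ++j)
        for (int f = 0; f < F; ++f)
          if (pattern(j, f)) Ldraws(keep, p++) = Lambda(j, f);
      p = 0;
      for (int j = 0; j < J; ++j)
        for (int m = 0; m < ncat[j] - 1; ++m) Tdraws(keep, p++) = tau[j](m);
      if (store_eta) {
        p = 0;
        for (int f = 0; f < F; ++f)
          for (int i = 0; i < n; ++i) Edraws(keep, p++) = Eta(i, f);
      }
      ++keep;
    }
  }

  return List::create(_["lambda"] = Ldraws, _["tau"] = Tdraws,
                      _["eta"] = Edraws);
}

// ---------------------------------------------------------------------------
// Bivariate standard normal upper-tail probability P(X > dh, Y > dk),
// correlation r.  Drezner & Wesolowsky / Genz algorithm with adaptive
// Gauss-Legendre order.
static double bvnu(double dh, double dk, double r) {
  if (dh == POS_INF || dk == POS_INF) return 0.0;
  if (dh == NEG_INF)
    return (dk == NEG_INF) ? 1.0 : R::pnorm(-dk, 0.0, 1.0, 1, 0);
  if (dk == NEG_INF) return R::pnorm(-dh, 0.0, 1.0, 1, 0);
  if (r >= 1.0) return R::pnorm(-std::max(dh, dk), 0.0, 1.0, 1, 0);
  if (r <= -1.0) {
    double v = R::pnorm(-dh, 0.0, 1.0, 1, 0) - R::pnorm(dk, 0.0, 1.0, 1, 0);
    return v > 0.0 ? v : 0.0;
  }
  if (r == 0.0)
    return R::pnorm(-dh, 0.0, 1.0, 1, 0) * R::pnorm(-dk, 0.0, 1.0, 1, 0);

  static const double w6[] = {0.1713244923791705, 0.3607615730481384,
                              0.4679139345726904};
  static const double x6[] = {0.9324695142031522, 0.6612093864662647,
                              0.2386191860831970};
  static const double w12[] = {0.04717533638651177, 0.1069393259953183,
                               0.1600783285433464,  0.2031674267230659,
                               0.2334925365383547,  0.2491470458134029};
  static const double x12[] = {0.9815606342467191, 0.9041172563704750,
                               0.7699026741943050, 0.5873179542866171,
                               0.3678314989981802, 0.1252334085114692};
  static const double w20[] = {0.01761400713915212, 0.04060142980038694,
                               0.06267204833410906, 0.08327674157670475,
                               0.1019301198172404,  0.1181945319615184,
                               0.1316886384491766,  0.1420961093183821,
                               0.1491729864726037,  0.1527533871307259};
  static const double x20[] = {0.9931285991850949,  0.9639719272779138,
                               0.9122344282513259,  0.8391169718222188,
                               0.7463319064601508,  0.6360536807265150,
                               0.5108670019508271,  0.3737060887154196,
                               0.2277858511416451,  0.07652652113349733};
  const double* w; const double* x; int ng;
  double ar = std::fabs(r);
  if (ar < 0.3)       { w = w6;  x = x6;  ng = 3; }
  else if (ar < 0.75) { w = w12; x = x12; ng = 6; }
  else                { w = w20; x = x20; ng = 10; }

  const double tp = 2.0 * M_PI;
  double h = dh, k = dk, hk = h * k, bvn = 0.0;

  if (ar < 0.925) {
    double hs = (h * h + k * k) / 2.0;
    double asr = std::asin(r) / 2.0;
    for (int i = 0; i < ng; ++i) {
      double sn = std::sin(asr * (1.0 - x[i]));
      bvn += w[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
      sn = std::sin(asr * (1.0 + x[i]));
      bvn += w[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
    }
    bvn = bvn * asr / tp +
          R::pnorm(-h, 0.0, 1.0, 1, 0) * R::pnorm(-k, 0.0, 1.0, 1, 0);
    return std::max(0.0, std::min(1.0, bvn));
  }

  // |r| >= 0.925: tail expansion
  if (r < 0.0) { k = -k; hk = -hk; }
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
    bvn -= std::exp(-hk / 2.0) * std::sqrt(tp) *
           R::pnorm(-b / a, 0.0, 1.0, 1, 0) * b *
           (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
  }
  a /= 2.0;
  for (int i = 0; i < ng; ++i) {
    for (int s = -1; s <= 1; s += 2) {
      double xs = a * (1.0 + s * x[i]);
      xs = xs * xs;
      double rs = std::sqrt(1.0 - xs);
      double asr2 = -(bs / xs + hk) / 2.0;
      if (asr2 > -100.0)
        bvn += a * w[i] * std::exp(asr2) *
               (std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs -
                (1.0 + c * xs * (1.0 + d * xs)));
    }
  }
  bvn = -bvn / tp;
  if (r > 0.0) {
    bvn += R::pnorm(-std::max(h, k), 0.0, 1.0, 1, 0);
  } else {
    bvn = -bvn;
    if (k > h)
      bvn += R::pnorm(k, 0.0, 1.0, 1, 0) - R::pnorm(h, 0.0, 1.0, 1, 0);
  }
  return std::max(0.0, std::min(1.0, bvn));
}

// [[Rcpp::export]]
double bvn_upper_cpp(double dh, double dk, double r) { return bvnu(dh, dk, r); }

// Rectangle probability P(x1 < X <= x2, y1 < Y <= y2)
static double bvn_rect(double x1, double x2, double y1, double y2, double r) {
  double p = bvnu(x1, y1, r) - bvnu(x1, y2, r) - bvnu(x2, y1, r) +
             bvnu(x2, y2, r);
  return p > 0.0 ? p : 0.0;
}

// [[Rcpp::export]]
double bvn_rect_cpp(double x1, double x2, double y1, double y2, double r) {
  return bvn_rect(x1, x2, y1, y2, r);
}

static double g2_stat(const arma::mat& obs, const arma::mat& expd) {
  double g = 0.0;
  for (arma::uword i = 0; i < obs.n_rows; ++i)
    for (arma::uword j = 0; j < obs.n_cols; ++j)
      if (obs(i, j) > 0.0)
        g += obs(i, j) * std::log(obs(i, j) / std::max(expd(i, j), 1e-300));
  return 2.0 * g;
}

// ---------------------------------------------------------------------------
// Posterior-predictive discrepancies: limited-information G^2 over all
// pairwise two-way indicator tables, model-implied probabilities from each
// draw's parameters, replicates simulated under the same draw with the
// observed missingness mask.
// [[Rcpp::export]]
List ppc_cpp(const IntegerMatrix& Y, const IntegerVector& ncat,
             const IntegerMatrix& pattern,
             const arma::mat& Ldraws, const arma::mat& Tdraws) {
  const int n = Y.nrow(), J = Y.ncol(), F = pattern.ncol();
  const int ndraw = Ldraws.n_rows;

  // observed pairwise tables
  std::vector<arma::mat> obs_tab;
  std::vector<std::pair<int, int>> pairs;
  std::vector<double> pair_n;
  for (int j = 0; j < J - 1; ++j)
    for (int k = j + 1; k < J; ++k) {
      arma::mat tab(ncat[j], ncat[k], arma::fill::zeros);
      for (int i = 0; i < n; ++i)
        if (Y(i, j) != NA_INTEGER && Y(i, k) != NA_INTEGER)
          tab(Y(i, j), Y(i, k)) += 1.0;
      pairs.push_back(std::make_pair(j, k));
      obs_tab.push_back(tab);
      pair_n.push_back(arma::accu(tab));
    }

  arma::vec f_obs(ndraw), f_rep(ndraw);
  arma::mat Lambda(J, F);
  IntegerMatrix Yrep(n, J);

  for (int d = 0; d < ndraw; ++d) {
    // unpack draw
    int p = 0;
    for (int j = 0; j < J; ++j)
      for (int f = 0; f < F; ++f)
        Lambda(j, f) = pattern(j, f) ? Ldraws(d, p++) : 0.0;
    std::vector<arma::vec> cuts(J);   // standardized cuts with +-inf ends
    std::vector<arma::vec> tau(J);
    std::vector<double> sj(J);
    p = 0;
    for (int j = 0; j < J; ++j) {
      sj[j] = std::sqrt(1.0 + arma::dot(Lambda.row(j), Lambda.row(j)));
      arma::vec tj(ncat[j] - 1);
      for (int m = 0; m < ncat[j] - 1; ++m) tj(m) = Tdraws(d, p++);
      tau[j] = tj;
      arma::vec cj(ncat[j] + 1);
      cj(0) = NEG_INF; cj(ncat[j]) = POS_INF;
      for (int m = 0; m < ncat[j] - 1; ++m) cj(m + 1) = tj(m) / sj[j];
      cuts[j] = cj;
    }

    // replicate data under this draw, observed missingness mask kept
    arma::mat EtaR(n, F);
    for (int i = 0; i < n; ++i)
      for (int f = 0; f < F; ++f) EtaR(i, f) = R::norm_rand();
    for (int j = 0; j < J; ++j) {
      for (int i = 0; i < n; ++i) {
        if (Y(i, j) == NA_INTEGER) { Yrep(i, j) = NA_INTEGER; continue; }
        double ys = arma::dot(Lambda.row(j), EtaR.row(i)) + R::norm_rand();
        int c = 0;
        while (c < ncat[j] - 1 && ys > tau[j](c)) ++c;
        Yrep(i, j) = c;
      }
    }

    double fo = 0.0, fr = 0.0;
    for (size_t q = 0; q < pairs.size(); ++q) {
      int j = pairs[q].first, k = pairs[q].second;
      if (pair_n[q] <= 0.0) continue;
      double rho = arma::dot(Lambda.row(j), Lambda.row(k)) / (sj[j] * sj[k]);
      arma::mat prob(ncat[j], ncat[k]);
      for (int aa = 0; aa < ncat[j]; ++aa)
        for (int bb = 0; bb < ncat[k]; ++bb)
          prob(aa, bb) = bvn_rect(cuts[j](aa), cuts[j](aa + 1),
                                  cuts[k](bb), cuts[k](bb + 1), rho);
      double tot = arma::accu(prob);
      if (tot <= 0.0) continue;
      prob /= tot;
      arma::mat expd = pair_n[q] * prob;
      arma::mat rep_tab(ncat[j], ncat[k], arma::fill::zeros);
      for (int i = 0; i < n; ++i)
        if (Yrep(i, j) != NA_INTEGER && Yrep(i, k) != NA_INTEGER)
          rep_tab(Yrep(i, j), Yrep(i, k)) += 1.0;
      fo += g2_stat(obs_tab[q], expd);
      fr += g2_stat(rep_tab, expd);
    }
    f_obs(d) = fo;
    f_rep(d) = fr;
  }

  return List::create(_["f_obs"] = f_obs, _["f_rep"] = f_rep);
}

// ---------------------------------------------------------------------------
// Covariance likelihood-ratio discrepancy on the augmented continuous
// responses: for each draw, latent responses y* are sampled conditional on
// the draw's parameters, scores and the observed categories (missing cells
// from the unconditional normal), and the discrepancy is
//   f = n * (log|Sigma| - log|S| + tr(S Sigma^{-1}) - J),
// with Sigma = Lambda Lambda' + I the model-implied second-moment matrix
// and S the empirical second-moment matrix of y*.  The replicate draws
// fresh scores and continuous responses from the same parameters.
// [[Rcpp::export]]
List ppc_lr_cpp(const IntegerMatrix& Y, const IntegerVector& ncat,
                const IntegerMatrix& pattern,
                const arma::mat& Ldraws, const arma::mat& Tdraws,
                const arma::mat& Edraws) {
  const int n = Y.nrow(), J = Y.ncol(), F = pattern.ncol();
  const int ndraw = Ldraws.n_rows;
  arma::vec f_obs(ndraw), f_rep(ndraw);
  arma::mat Lambda(J, F), Eta(n, F), Ystar(n, J), YstarR(n, J);

  for (int d = 0; d < ndraw; ++d) {
    int p = 0;
    for (int j = 0; j < J; ++j)
      for (int f = 0; f < F; ++f)
        Lambda(j, f) = pattern(j, f) ? Ldraws(d, p++) : 0.0;
    std::vector<arma::vec> tau(J);
    p = 0;
    for (int j = 0; j < J; ++j) {
      arma::vec tj(ncat[j] - 1);
      for (int m = 0; m < ncat[j] - 1; ++m) tj(m) = Tdraws(d, p++);
      tau[j] = tj;
    }
    p = 0;
    for (int f = 0; f < F; ++f)
      for (int i = 0; i < n; ++i) Eta(i, f) = Edraws(d, p++);

    // augment observed data
    for (int j = 0; j < J; ++j) {
      const int K = ncat[j];
      for (int i = 0; i < n; ++i) {
        double mu = arma::dot(Lambda.row(j), Eta.row(i));
        int c = Y(i, j);
        if (c == NA_INTEGER) Ystar(i, j) = R::rnorm(mu, 1.0);
        else {
          double lo = (c == 0) ? NEG_INF : tau[j](c - 1);
          double hi = (c == K - 1) ? POS_INF : tau[j](c);
          Ystar(i, j) = rtnorm(mu, 1.0, lo, hi);
        }
      }
    }
    // replicate: fresh scores and continuous responses
    arma::mat EtaR(n, F);
    for (int i = 0; i < n; ++i)
      for (int f = 0; f < F; ++f) EtaR(i, f) = R::norm_rand();
    for (int j = 0; j < J; ++j)
      for (int i = 0; i < n; ++i)
        YstarR(i, j) = arma::dot(Lambda.row(j), EtaR.row(i)) + R::norm_rand();

    arma::mat Sigma = Lambda * Lambda.t() + arma::eye(J, J);
    arma::mat Sinv = arma::inv_sympd(Sigma);
    double ldS;
    double sign;
    arma::log_det(ldS, sign, Sigma);
    auto lr = [&](const arma::mat& Ys) {
      arma::mat S = Ys.t() * Ys / (double)n;
      double ld, sg;
      arma::log_det(ld, sg, S);
      return n * (ldS - ld + arma::trace(S * Sinv) - (double)J);
    };
    f_obs(d) = lr(Ystar);
    f_rep(d) = lr(YstarR);
  }
  return List::create(_["f_obs"] = f_obs, _["f_rep"] = f_rep);
}
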