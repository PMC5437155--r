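// Iterative solver cores: Infomax ICA, IVA with Gaussian / Laplace SCV
// models, and the reference-guided per-subject component ascent.
// All callers pass whitened data; convergence tolerances are supplied from R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// numerically safe log(cosh(u))
static inline double safe_logcosh(double u) {
  double a = std::fabs(u);
  return a + std::log1p(std::exp(-2.0 * a)) - M_LN2;
}

static mat logcosh_mat(const mat& U) {
  mat out(U.n_rows, U.n_cols);
  for (uword i = 0; i < U.n_elem; ++i) out(i) = safe_logcosh(U(i));
  return out;
}

// Natural-gradient Infomax with logistic nonlinearity, minibatch updates
// over a random permutation of samples per epoch (the canonical runica
// scheme). The learning rate anneals by 0.98 when the update direction turns
// by more than 60 degrees between epochs; weight blow-up restarts from the
// initial weights at 0.9 of the rate. X: k x V whitened; W: k x k initial.
// The full-data log-likelihood under the logistic prior is recorded per
// epoch.
// [[Rcpp::export]]
Rcpp::List cpp_infomax(const arma::mat& X, const arma::mat& W0, double lr,
                       double tol, int maxit, int block, int rng_seed) {
  const uword k = X.n_rows;
  const uword V = X.n_cols;
  mat I = eye<mat>(k, k);
  if (block <= 0) {
    block = (int)std::ceil(std::min(5.0 * std::log((double)V), 0.3 * V));
  }
  std::mt19937 rng((unsigned)rng_seed);

  auto loglik = [&](const mat& Wm) {
    mat U = Wm * X;
    double s = 0.0;
    for (uword i = 0; i < U.n_elem; ++i) {
      double u = U(i);
      double l1pe = (u > 0) ? (u + std::log1p(std::exp(-u)))
                            : std::log1p(std::exp(u));
      s += -u - 2.0 * l1pe;
    }
    double val, sign;
    log_det(val, sign, Wm);
    return val + s / (double)V;
  };

  mat W = W0;
  std::vector<double> trace;
  trace.push_back(loglik(W));
  uvec perm(V);
  for (uword i = 0; i < V; ++i) perm(i) = i;
  mat oldW = W, old_dW(k, k, fill::zeros);
  bool have_old_dw = false;
  bool converged = false;
  int it;
  mat BI = (double)block * I;
  for (it = 0; it < maxit; ++it) {
    std::shuffle(perm.begin(), perm.end(), rng);
    bool blowup = false;
    for (uword start = 0; start + block <= V; start += block) {
      mat Xb = X.cols(perm.subvec(start, start + block - 1));
      mat U = W * Xb;
      mat Y = 1.0 / (1.0 + exp(-U));
      W += lr * (BI + (1.0 - 2.0 * Y) * U.t()) * W;
      if (!W.is_finite() || abs(W).max() > 1e8) { blowup = true; break; }
    }
    if (blowup) {
      lr *= 0.9;
      W = W0;
      oldW = W0;
      have_old_dw = false;
      if (lr < 1e-12) break;
      continue;
    }
    mat dW = W - oldW;
    double wchange = accu(square(dW));
    if (have_old_dw) {
      double denom = std::sqrt(accu(square(dW)) * accu(square(old_dW)));
      double cosang = denom > 0 ? accu(dW % old_dW) / denom : 1.0;
      if (cosang < 0.5) lr *= 0.98;  // direction turned by > 60 degrees
    }
    old_dW = dW;
    have_old_dw = true;
    oldW = W;
    trace.push_back(loglik(W));
    if (wchange < tol) { converged = true; break; }
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("loglik") = trace,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("iterations") = it + 1);
}

// cost and score matrices for one IVA iteration.
// Y: cube k x V x M. Fills Phi (same shape) and returns the cost.
static double iva_cost_phi(const cube& Y, cube& Phi, bool laplace,
                           double ridge, bool want_phi) {
  const uword k = Y.n_rows, M = Y.n_slices;
  const double V = (double)Y.n_cols;
  double cost = 0.0;
  mat Yl(M, Y.n_cols);
  for (uword l = 0; l < k; ++l) {
    for (uword m = 0; m < M; ++m) Yl.row(m) = Y.slice(m).row(l);
    if (laplace) {
      rowvec nrm = sqrt(sum(square(Yl), 0)) + 1e-12;
      cost += accu(nrm) / V;
      if (want_phi) {
        mat P = Yl.each_row() / nrm;
        for (uword m = 0; m < M; ++m) Phi.slice(m).row(l) = P.row(m);
      }
    } else {
      mat S = (Yl * Yl.t()) / V;
      double dval, dsign;
      if (!log_det(dval, dsign, S) || dsign <= 0 || !std::isfinite(dval)) {
        S += ridge * eye<mat>(M, M);
        log_det(dval, dsign, S);
      }
      cost += 0.5 * dval;
      if (want_phi) {
        mat P = solve(S + ridge * eye<mat>(M, M), Yl);
        for (uword m = 0; m < M; ++m) Phi.slice(m).row(l) = P.row(m);
      }
    }
  }
  return cost;
}

// IVA with multivariate Gaussian (laplace = false) or multivariate Laplace
// (laplace = true) source-component-vector model, relative-gradient descent
// with step halving on cost increase.
// Xs: list of k x V whitened matrices; W0: list of k x k initial unmixings.
// [[Rcpp::export]]
Rcpp::List cpp_iva(const Rcpp::List& Xs, const Rcpp::List& W0, bool laplace,
                   double step0, double tol, int maxit, double ridge,
                   double stall_tol) {
  const int M = Xs.size();
  std::vector<mat> X(M);
  std::vector<mat> W(M);
  for (int m = 0; m < M; ++m) {
    X[m] = Rcpp::as<mat>(Xs[m]);
    W[m] = Rcpp::as<mat>(W0[m]);
  }
  const uword k = X[0].n_rows;
  const uword V = X[0].n_cols;
  cube Y(k, V, M), Phi(k, V, M);
  mat I = eye<mat>(k, k);

  auto fill_Y = [&](const std::vector<mat>& Wc) {
    for (int m = 0; m < M; ++m) Y.slice(m) = Wc[m] * X[m];
  };
  auto logdet_sum = [&](const std::vector<mat>& Wc) {
    double s = 0.0, val, sign;
    for (int m = 0; m < M; ++m) { log_det(val, sign, Wc[m]); s += val; }
    return s;
  };

  double step = step0;
  std::vector<double> trace;
  fill_Y(W);
  double cost = iva_cost_phi(Y, Phi, laplace, ridge, true) - logdet_sum(W);
  trace.push_back(cost);
  bool converged = false;
  int stall = 0;
  int it;
  for (it = 0; it < maxit; ++it) {
    // candidate relative-gradient step from the current score functions
    std::vector<mat> Wn(M);
    double dw = 0.0, wmax = 0.0;
    for (int m = 0; m < M; ++m) {
      mat G = (I - (Phi.slice(m) * Y.slice(m).t()) / (double)V) * W[m];
      Wn[m] = W[m] + step * G;
      dw = std::max(dw, abs(Wn[m] - W[m]).max());
      wmax = std::max(wmax, abs(W[m]).max());
    }
    bool finite = true;
    for (int m = 0; m < M; ++m) if (!Wn[m].is_finite()) finite = false;
    if (!finite) { step *= 0.5; if (step < 1e-12) break; continue; }
    fill_Y(Wn);
    cube Phin(k, V, M);
    double costn = iva_cost_phi(Y, Phin, laplace, ridge, true)
      - logdet_sum(Wn);
    if (!std::isfinite(costn) || costn > cost + 1e-12) {
      step *= 0.5;
      if (step < 1e-12) break;
      continue;
    }
    double impr = cost - costn;
    W = Wn;
    Phi = Phin;
    cost = costn;
    trace.push_back(cost);
    if (dw < tol * std::max(wmax, 1.0)) { converged = true; break; }
    // cost plateau: stop after 10 consecutive near-zero improvements
    stall = (impr < stall_tol * (1.0 + std::fabs(cost))) ? stall + 1 : 0;
    if (stall >= 10) { converged = true; break; }
    step = std::min(step * 1.2, step0);  // recover from transient halvings
  }
  Rcpp::List Wout(M);
  for (int m = 0; m < M; ++m) Wout[m] = W[m];
  return Rcpp::List::create(
    Rcpp::Named("W") = Wout,
    Rcpp::Named("cost_trace") = trace,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("iterations") = it + 1);
}

// Reference-guided estimation of one subject's components.
// X: k x V whitened data with zero-mean unit-variance rows (population
// convention); R: n_ref x V standardized references. For each reference the
// demixing vector w maximizes
//   F(w) = lambda * (E log cosh(y) - EGnu)^2 + (1 - lambda) * corr(y, ref)
// on the unit sphere, orthogonal (deflation) to previously accepted vectors.
// [[Rcpp::export]]
Rcpp::List cpp_gigica_subject(const arma::mat& X, const arma::mat& R,
                              double lambda, double EGnu, double tol,
                              int maxit, double step0, double corr_floor) {
  const uword k = X.n_rows;
  const double V = (double)X.n_cols;
  const uword n_ref = R.n_rows;
  mat Wout(n_ref, k, fill::zeros);
  mat Yout(n_ref, X.n_cols, fill::zeros);
  mat U(k, 0);  // accepted demixing vectors, columns orthonormal
  Rcpp::List traces(n_ref);
  Rcpp::NumericVector ref_corr(n_ref);
  Rcpp::LogicalVector flagged(n_ref);

  for (uword c = 0; c < n_ref; ++c) {
    vec rho = X * R.row(c).t() / V;  // corr(w'X, ref) = w . rho
    vec w = rho;
    if (U.n_cols > 0) w -= U * (U.t() * w);
    if (norm(w) < 1e-10) {
      // degenerate reference: fall back to the least-used basis direction
      vec cand(k, fill::zeros);
      for (uword j = 0; j < k; ++j) {
        vec e(k, fill::zeros); e(j) = 1.0;
        if (U.n_cols > 0) e -= U * (U.t() * e);
        if (norm(e) > norm(cand)) cand = e;
      }
      w = cand;
    }
    w /= norm(w);

    auto fval = [&](const vec& wv, rowvec& y) {
      y = wv.t() * X;
      double eg = accu(logcosh_mat(y)) / V;
      double corr = dot(wv, rho);
      return lambda * (eg - EGnu) * (eg - EGnu) + (1.0 - lambda) * corr;
    };

    rowvec y;
    double F = fval(w, y);
    std::vector<double> trace;
    trace.push_back(F);
    double step = step0;
    for (int it = 0; it < maxit; ++it) {
      double eg = accu(logcosh_mat(y)) / V;
      vec g = lambda * 2.0 * (eg - EGnu) * (X * tanh(y).t() / V)
        + (1.0 - lambda) * rho;
      g -= dot(w, g) * w;  // tangent projection on the sphere
      double gn = norm(g);
      if (gn < 1e-14) break;
      g /= gn;  // scale-free ascent direction
      bool accepted = false;
      double moved = 0.0;
      for (int h = 0; h < 60; ++h) {
        vec wn = w + step * g;
        wn /= norm(wn);
        rowvec yn;
        double Fn = fval(wn, yn);
        if (Fn >= F + 1e-14) {
          moved = norm(wn - w);
          w = wn; y = yn; F = Fn;
          trace.push_back(F);
          accepted = true;
          step = std::min(step * 2.0, step0);
          break;
        }
        step *= 0.5;
        if (step < 1e-10) break;
      }
      if (!accepted || moved < tol) break;
    }
    double corr = dot(w, rho);
    if (corr < 0) { w = -w; y = -y; corr = -corr; }  // sign-align to reference
    ref_corr[c] = corr;
    flagged[c] = corr < corr_floor;
    Wout.row(c) = w.t();
    Yout.row(c) = y;
    traces[c] = trace;
    // grow the deflation basis
    vec wo = w;
    if (U.n_cols > 0) wo -= U * (U.t() * wo);
    if (norm(wo) > 1e-10) U = join_rows(U, wo / norm(wo));
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = Wout,
    Rcpp::Named("Y") = Yout,
    Rcpp::Named("traces") = traces,
    Rcpp::Named("ref_corr") = ref_corr,
    Rcpp::Named("flagged") = flagged);
}

// IVA-G on sufficient statistics: the Gaussian-SCV cost depends on the data
// only through the cross-subject covariance blocks C_{mn} = X_m X_n' / V, so
// iterations run in O(k^3 M^2) regardless of the number of voxels.
// C: cube (k x k x M*M), slice m*M + n holding C_{mn}; W0: list of k x k.
// [[Rcpp::export]]
Rcpp::List cpp_iva_g_cov(const arma::cube& C, const Rcpp::List& W0,
                         double step0, double tol, int maxit, double ridge,
                         double stall_tol) {
  const int M = W0.size();
  const uword k = C.n_rows;
  std::vector<mat> W(M);
  for (int m = 0; m < M; ++m) W[m] = Rcpp::as<mat>(W0[m]);
  mat I = eye<mat>(k, k);

  // Sig[l]: M x M covariance of SCV l; also returns the cost
  auto eval_cost = [&](const std::vector<mat>& Wc, std::vector<mat>& Sig) {
    double cost = 0.0;
    Sig.assign(k, mat(M, M));
    // Ct[m][n] = Wc[m] * C_{mn} * Wc[n]'
    std::vector<std::vector<mat>> Ct(M, std::vector<mat>(M));
    for (int m = 0; m < M; ++m) {
      for (int n = m; n < M; ++n) {
        Ct[m][n] = Wc[m] * C.slice(m * M + n) * Wc[n].t();
        if (n > m) Ct[n][m] = Ct[m][n].t();
      }
    }
    for (uword l = 0; l < k; ++l) {
      mat S(M, M);
      for (int m = 0; m < M; ++m)
        for (int n = 0; n < M; ++n) S(m, n) = Ct[m][n](l, l);
      double dval, dsign;
      if (!log_det(dval, dsign, S) || dsign <= 0 || !std::isfinite(dval)) {
        S += ridge * eye<mat>(M, M);
        log_det(dval, dsign, S);
      }
      cost += 0.5 * dval;
      Sig[l] = S + ridge * eye<mat>(M, M);
    }
    double val, sign, ld = 0.0;
    for (int m = 0; m < M; ++m) { log_det(val, sign, Wc[m]); ld += val; }
    return cost - ld;
  };

  std::vector<mat> Sig;
  double cost = eval_cost(W, Sig);
  std::vector<double> trace;
  trace.push_back(cost);
  double step = step0;
  bool converged = false;
  int total_it = 0;

  // Discrete descent on the same cost: swapping two rows of one subject's
  // unmixing moves that subject's component between SCVs. Gradient flow
  // cannot cross these permutation barriers, so after each gradient phase we
  // accept any row swap that lowers the cost and, if one was found, resume
  // the gradient phase from the realigned solution.
  auto swap_polish = [&]() {
    bool any = false;
    bool improved = true;
    while (improved) {
      improved = false;
      for (int m = 0; m < M; ++m) {
        for (uword i = 0; i + 1 < k; ++i) {
          for (uword j = i + 1; j < k; ++j) {
            std::vector<mat> Wc = W;
            Wc[m].swap_rows(i, j);
            std::vector<mat> Sigc;
            double costc = eval_cost(Wc, Sigc);
            if (costc < cost - 1e-10) {
              W = Wc;
              Sig = Sigc;
              cost = costc;
              trace.push_back(cost);
              improved = true;
              any = true;
            }
          }
        }
      }
    }
    return any;
  };

  for (int round = 0; round < 4; ++round) {
  int stall = 0;
  int it;
  for (it = 0; it < maxit; ++it) {
    // relative-gradient: D_m[l, l2] = sum_n inv(Sig_l)[m,n] * (w_nl' C_nm w_ml2)
    std::vector<mat> Sinv(k);
    for (uword l = 0; l < k; ++l) Sinv[l] = inv_sympd(Sig[l]);
    std::vector<mat> Wn(M);
    double dw = 0.0, wmax = 0.0;
    for (int m = 0; m < M; ++m) {
      mat D(k, k, fill::zeros);
      for (int n = 0; n < M; ++n) {
        // B = Wc[n] * C_{nm} * Wc[m]' : rows l (subject n comp l), cols l2
        mat B = W[n] * C.slice(n * M + m) * W[m].t();
        for (uword l = 0; l < k; ++l) D.row(l) += Sinv[l](m, n) * B.row(l);
      }
      Wn[m] = W[m] + step * (I - D) * W[m];
      dw = std::max(dw, abs(Wn[m] - W[m]).max());
      wmax = std::max(wmax, abs(W[m]).max());
    }
    bool finite = true;
    for (int m = 0; m < M; ++m) if (!Wn[m].is_finite()) finite = false;
    std::vector<mat> Sign;
    double costn = finite ? eval_cost(Wn, Sign) : datum::inf;
    if (!std::isfinite(costn) || costn > cost + 1e-12) {
      step *= 0.5;
      if (step < 1e-12) break;
      continue;
    }
    double impr = cost - costn;
    W = Wn;
    Sig = Sign;
    cost = costn;
    trace.push_back(cost);
    if (dw < tol * std::max(wmax, 1.0)) { converged = true; break; }
    stall = (impr < stall_tol * (1.0 + std::fabs(cost))) ? stall + 1 : 0;
    if (stall >= 10) { converged = true; break; }
    step = std::min(step * 1.2, step0);
  }
  total_it += it + 1;
  if (!swap_polish()) break;
  step = step0;  // fresh gradient phase from the realigned solution
  }
  Rcpp::List Wout(M);
  for (int m = 0; m < M; ++m) Wout[m] = W[m];
  return Rcpp::List::create(
    Rcpp::Named("W") = Wout,
    Rcpp::Named("cost_trace") = trace,
    Rcpp::Named("converged") = converged,
    Rcpp::Named("iterations") = total_it);
}
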