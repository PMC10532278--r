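// Multi-group SEM covariance-structure engine.
//
// A fit problem is described by an "engine" list built in R (see
// R/engine.R): fixed base matrices Lambda/Beta/Phi/Psi per group, a sparse
// entry table mapping free matrix cells to linear combinations of the
// working parameter vector theta, and the sample covariance matrices with
// their weights.  Working parameters flagged `plog` enter on the log scale
// (plain variance parameters), all others on the natural scale.
//
// Objective (ML discrepancy, summed over groups g with weights N_g):
//   F = sum_g N_g [ log|Sigma_g| + tr(S_g Sigma_g^{-1}) - log|S_g| - I ]
// with Sigma_g = Lambda G Phi G' Lambda' + Psi, G = (I - Beta)^{-1}.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Engine {
  int I, F, G, ne, npar;
  bool has_beta;
  arma::cube Lambda0, Beta0, Phi0, Psi0, S;
  arma::imat entries;      // ne x 4: grp, mat, row, col (1-based)
  arma::ivec eptr;         // ne+1, 0-based offsets
  arma::ivec pidx;         // 1-based parameter index
  arma::vec pcoef;
  arma::uvec plog;         // 0/1 per parameter
  arma::vec Ng, logdetS;
};

Engine unpack(const List& eng) {
  Engine e;
  e.I = as<int>(eng["I"]);
  e.F = as<int>(eng["nfac"]);
  e.G = as<int>(eng["G"]);
  e.has_beta = as<bool>(eng["has_beta"]);
  e.Lambda0 = as<arma::cube>(eng["Lambda0"]);
  e.Beta0 = as<arma::cube>(eng["Beta0"]);
  e.Phi0 = as<arma::cube>(eng["Phi0"]);
  e.Psi0 = as<arma::cube>(eng["Psi0"]);
  e.S = as<arma::cube>(eng["S"]);
  e.entries = as<arma::imat>(eng["entries"]);
  e.eptr = as<arma::ivec>(eng["eptr"]);
  e.pidx = as<arma::ivec>(eng["pidx"]);
  e.pcoef = as<arma::vec>(eng["pcoef"]);
  e.plog = as<arma::uvec>(eng["plog"]);
  e.Ng = as<arma::vec>(eng["Ng"]);
  e.logdetS = as<arma::vec>(eng["logdetS"]);
  e.ne = e.entries.n_rows;
  e.npar = e.plog.n_elem;
  return e;
}

// natural-scale working values and their d(value)/d(theta)
void natural(const Engine& e, const arma::vec& theta, arma::vec& x,
             arma::vec& dx) {
  x = theta;
  dx.ones(e.npar);
  for (int k = 0; k < e.npar; k++) {
    if (e.plog[k]) {
      x[k] = std::exp(theta[k]);
      dx[k] = x[k];
    }
  }
}

// materialize model matrices for all groups at theta
void build_matrices(const Engine& e, const arma::vec& x, arma::cube& Lambda,
                    arma::cube& Beta, arma::cube& Phi, arma::cube& Psi) {
  Lambda = e.Lambda0;
  Beta = e.Beta0;
  Phi = e.Phi0;
  Psi = e.Psi0;
  for (int j = 0; j < e.ne; j++) {
    double v = 0.0;
    for (int k = e.eptr[j]; k < e.eptr[j + 1]; k++)
      v += e.pcoef[k] * x[e.pidx[k] - 1];
    int g = e.entries(j, 0) - 1, m = e.entries(j, 1);
    int r = e.entries(j, 2) - 1, c = e.entries(j, 3) - 1;
    if (m == 1) Lambda(r, c, g) = v;
    else if (m == 2) Beta(r, c, g) = v;
    else if (m == 3) Phi(r, c, g) = v;
    else Psi(r, c, g) = v;
  }
  // entries of Phi/Psi are stored with row >= col; mirror lower to upper
  for (int g = 0; g < e.G; g++) {
    Phi.slice(g) = arma::symmatl(Phi.slice(g));
    Psi.slice(g) = arma::symmatl(Psi.slice(g));
  }
}

bool implied_one(const Engine& e, const arma::cube& Lambda,
                 const arma::cube& Beta, const arma::cube& Phi,
                 const arma::cube& Psi, int g, arma::mat& Sigma,
                 arma::mat& Ginv, arma::mat& C) {
  if (e.has_beta) {
    arma::mat ImB = arma::eye(e.F, e.F) - Beta.slice(g);
    if (!arma::inv(Ginv, ImB)) return false;
    C = Ginv * Phi.slice(g) * Ginv.t();
  } else {
    Ginv = arma::eye(e.F, e.F);
    C = Phi.slice(g);
  }
  Sigma = Lambda.slice(g) * C * Lambda.slice(g).t() + Psi.slice(g);
  Sigma = arma::symmatl(Sigma);
  return true;
}

const double BIG = 1e100;

}  // namespace

// [[Rcpp::export(name = ".eng_objective")]]
double eng_objective(const arma::vec& theta, const List& engine) {
  Engine e = unpack(engine);
  arma::vec x, dx;
  natural(e, theta, x, dx);
  arma::cube Lambda, Beta, Phi, Psi;
  build_matrices(e, x, Lambda, Beta, Phi, Psi);
  double F = 0.0;
  arma::mat Sigma, Ginv, C, R;
  for (int g = 0; g < e.G; g++) {
    if (!implied_one(e, Lambda, Beta, Phi, Psi, g, Sigma, Ginv, C)) return BIG;
    if (!arma::chol(R, Sigma)) return BIG;
    double logdet = 2.0 * arma::accu(arma::log(R.diag()));
    arma::mat Sinv;
    if (!arma::inv_sympd(Sinv, Sigma)) return BIG;
    double tr = arma::accu(e.S.slice(g) % Sinv);
    F += e.Ng[g] * (logdet + tr - e.logdetS[g] - e.I);
  }
  if (!std::isfinite(F)) return BIG;
  return F;
}

// [[Rcpp::export(name = ".eng_gradient")]]
arma::vec eng_gradient(const arma::vec& theta, const List& engine) {
  Engine e = unpack(engine);
  arma::vec x, dx;
  natural(e, theta, x, dx);
  arma::cube Lambda, Beta, Phi, Psi;
  build_matrices(e, x, Lambda, Beta, Phi, Psi);

  // per-group pieces of dF/d(cell value)
  arma::cube MLC(e.I, e.F, e.G), AMA(e.F, e.F, e.G), Mc(e.I, e.I, e.G),
      CBM(e.F, e.F, e.G);
  arma::mat Sigma, Ginv, C;
  for (int g = 0; g < e.G; g++) {
    if (!implied_one(e, Lambda, Beta, Phi, Psi, g, Sigma, Ginv, C)) {
      return arma::zeros(e.npar);
    }
    arma::mat Sinv;
    // ridge-repair a non-PD Sigma so a descent direction is still available
    double ridge = 1e-10 * (arma::trace(Sigma) / e.I + 1.0);
    while (!arma::inv_sympd(Sinv, Sigma)) {
      Sigma.diag() += ridge;
      ridge *= 10.0;
      if (ridge > 1e6) return arma::zeros(e.npar);
    }
    arma::mat M = e.Ng[g] * (Sinv - Sinv * e.S.slice(g) * Sinv);
    M = arma::symmatl(M);
    const arma::mat& L = Lambda.slice(g);
    arma::mat A = L * Ginv;
    MLC.slice(g) = M * L * C;          // loading cells: 2 * MLC[i,f]
    AMA.slice(g) = A.t() * M * A;      // Phi cells
    Mc.slice(g) = M;                   // Psi cells
    if (e.has_beta)
      CBM.slice(g) = C * (L.t() * M * L) * Ginv;  // Beta cell (p,q): 2*CBM(q,p)
  }

  arma::vec grad = arma::zeros(e.npar);
  for (int j = 0; j < e.ne; j++) {
    int g = e.entries(j, 0) - 1, m = e.entries(j, 1);
    int r = e.entries(j, 2) - 1, c = e.entries(j, 3) - 1;
    double d;
    if (m == 1) d = 2.0 * MLC(r, c, g);
    else if (m == 2) d = 2.0 * CBM(c, r, g);
    else if (m == 3) d = (r == c) ? AMA(r, c, g) : 2.0 * AMA(r, c, g);
    else d = (r == c) ? Mc(r, c, g) : 2.0 * Mc(r, c, g);
    for (int k = e.eptr[j]; k < e.eptr[j + 1]; k++) {
      int p = e.pidx[k] - 1;
      grad[p] += d * e.pcoef[k] * dx[p];
    }
  }
  return grad;
}

// Expected-information (Gauss-Newton) Hessian of the objective in the
// working parameterization:
//   H_ent(u,v) = N_g tr(Sigma^{-1} dSigma_u Sigma^{-1} dSigma_v)
// for entries u, v of the same group, mapped to theta through the entry
// coefficients and the exp-transform chain rule (including the first-order
// transform term so that Newton steps remain consistent off-optimum).
// [[Rcpp::export(name = ".eng_hessian")]]
arma::mat eng_hessian(const arma::vec& theta, const List& engine) {
  Engine e = unpack(engine);
  arma::vec x, dx;
  natural(e, theta, x, dx);
  arma::cube Lambda, Beta, Phi, Psi;
  build_matrices(e, x, Lambda, Beta, Phi, Psi);
  arma::mat H = arma::zeros(e.npar, e.npar);
  arma::vec gv = arma::zeros(e.npar);  // accumulates exp-chain diagonal term

  // group the entry indices
  std::vector<std::vector<int>> by_group(e.G);
  for (int j = 0; j < e.ne; j++) by_group[e.entries(j, 0) - 1].push_back(j);

  arma::mat Sigma, Ginv, C;
  for (int g = 0; g < e.G; g++) {
    if (by_group[g].empty()) continue;
    if (!implied_one(e, Lambda, Beta, Phi, Psi, g, Sigma, Ginv, C))
      return arma::eye(e.npar, e.npar);
    arma::mat Sinv;
    double ridge = 1e-10 * (arma::trace(Sigma) / e.I + 1.0);
    while (!arma::inv_sympd(Sinv, Sigma)) {
      Sigma.diag() += ridge;
      ridge *= 10.0;
      if (ridge > 1e6) return arma::eye(e.npar, e.npar);
    }
    arma::mat M = e.Ng[g] * (Sinv - Sinv * e.S.slice(g) * Sinv);
    M = arma::symmatl(M);
    const arma::mat& L = Lambda.slice(g);
    arma::mat A = L * Ginv;
    arma::mat MLC = M * L * C;
    arma::mat AMA = A.t() * M * A;
    arma::mat CBM;
    if (e.has_beta) CBM = C * (L.t() * M * L) * Ginv;

    const std::vector<int>& idx = by_group[g];
    int m = idx.size();
    std::vector<arma::mat> dS(m), Q(m);
    arma::vec dgrad(m);
    for (int u = 0; u < m; u++) {
      int j = idx[u];
      int mt = e.entries(j, 1);
      int r = e.entries(j, 2) - 1, c = e.entries(j, 3) - 1;
      arma::mat D(e.I, e.I, arma::fill::zeros);
      if (mt == 1) {
        arma::rowvec cl = C.row(c) * L.t();  // row c of C Lambda'
        D.row(r) += cl;
        D.col(r) += cl.t();
        D(r, r) += 0.0;
        dgrad[u] = 2.0 * MLC(r, c);
      } else if (mt == 2) {
        arma::mat Epq(e.F, e.F, arma::fill::zeros);
        Epq(r, c) = 1.0;
        arma::mat T = L * Ginv * Epq * C * L.t();
        D = T + T.t();
        dgrad[u] = 2.0 * CBM(c, r);
      } else if (mt == 3) {
        arma::mat Epq(e.F, e.F, arma::fill::zeros);
        Epq(r, c) = 1.0;
        if (r != c) Epq(c, r) = 1.0;
        D = A * Epq * A.t();
        dgrad[u] = (r == c) ? AMA(r, c) : 2.0 * AMA(r, c);
      } else {
        D(r, c) = 1.0;
        if (r != c) D(c, r) = 1.0;
        dgrad[u] = (r == c) ? M(r, c) : 2.0 * M(r, c);
      }
      dS[u] = D;
      Q[u] = Sinv * D * Sinv;
    }
    for (int u = 0; u < m; u++) {
      int ju = idx[u];
      for (int v = u; v < m; v++) {
        int jv = idx[v];
        double h = e.Ng[g] * arma::accu(Q[u] % dS[v]);
        for (int ku = e.eptr[ju]; ku < e.eptr[ju + 1]; ku++) {
          int pu = e.pidx[ku] - 1;
          double au = e.pcoef[ku] * dx[pu];
          for (int kv = e.eptr[jv]; kv < e.eptr[jv + 1]; kv++) {
            int pv = e.pidx[kv] - 1;
            double av = e.pcoef[kv] * dx[pv];
            H(pu, pv) += h * au * av;
            if (u != v) H(pv, pu) += h * au * av;
          }
        }
      }
      // exp-transform curvature: d2x/dtheta2 = x for log parameters
      for (int ku = e.eptr[ju]; ku < e.eptr[ju + 1]; ku++) {
        int pu = e.pidx[ku] - 1;
        if (e.plog[pu]) gv[pu] += dgrad[u] * e.pcoef[ku] * x[pu];
      }
    }
  }
  H.diag() += gv;
  H = arma::symmatu(H);
  // fix asymmetry from the one-sided accumulation above
  H = 0.5 * (H + H.t());
  return H;
}

// Complete-data local moments: conditional means by local quadratic WLS,
// residuals, and conditional covariance matrices per focal point, either
// kernel-weighted cross products or intercepts of a second local quadratic
// regression of the residual products (mode 1 = weighted, 2 = local
// regression).
// [[Rcpp::export(name = ".local_moments_cpp")]]
List local_moments_cpp(const arma::mat& x, const arma::vec& a,
                       const arma::mat& W, const arma::vec& grid,
                       bool residualize, int mode) {
  int N = x.n_rows, I = x.n_cols, T = grid.n_elem;
  arma::mat means(I, T);
  arma::cube coefs(I, 3, T, arma::fill::zeros);
  arma::cube covs(I, I, T);
  int npair = I * (I + 1) / 2;
  arma::umat pairs(npair, 2);
  {
    int k = 0;
    for (int i = 0; i < I; i++)
      for (int j = 0; j <= i; j++) { pairs(k, 0) = i; pairs(k, 1) = j; k++; }
  }
  for (int t = 0; t < T; t++) {
    arma::vec w = W.col(t);
    double Wt = arma::accu(w);
    arma::vec d = a - grid[t];
    arma::mat E;
    if (residualize) {
      arma::mat X(N, 3);
      X.col(0).ones(); X.col(1) = d; X.col(2) = d % d;
      int deg = 2;
      arma::mat B;
      while (deg >= 0) {
        arma::mat Xd = X.cols(0, deg);
        arma::mat XtW = Xd.t() * arma::diagmat(w);
        arma::mat Mm = XtW * Xd;
        bool okb = arma::solve(B, Mm, XtW * x, arma::solve_opts::no_approx);
        if (okb && B.is_finite()) break;
        deg--;
      }
      if (deg < 0) { B = (x.t() * w).t() / Wt; }  // 1 x I of weighted means
      arma::mat Bf(3, I, arma::fill::zeros);
      Bf.rows(0, B.n_rows - 1) = B;
      coefs.slice(t) = Bf.t();
      E = x - X * Bf;
      means.col(t) = Bf.row(0).t();
    } else {
      arma::rowvec mu = (x.t() * w).t() / Wt;
      E = x.each_row() - mu;
      means.col(t) = mu.t();
      coefs.slice(t).col(0) = mu.t();
    }
    if (mode == 1) {
      arma::mat Ew = E.each_col() % arma::sqrt(w);
      covs.slice(t) = (Ew.t() * Ew) / Wt;
    } else {
      arma::mat P(N, npair);
      for (int k = 0; k < npair; k++)
        P.col(k) = E.col(pairs(k, 0)) % E.col(pairs(k, 1));
      arma::mat X(N, 3);
      X.col(0).ones(); X.col(1) = d; X.col(2) = d % d;
      int deg = 2;
      arma::mat B;
      while (deg >= 0) {
        arma::mat Xd = X.cols(0, deg);
        arma::mat XtW = Xd.t() * arma::diagmat(w);
        arma::mat Mm = XtW * Xd;
        bool okb = arma::solve(B, Mm, XtW * P, arma::solve_opts::no_approx);
        if (okb && B.is_finite()) break;
        deg--;
      }
      if (deg < 0) { B = (P.t() * w).t() / Wt; }
      arma::mat S(I, I);
      for (int k = 0; k < npair; k++) {
        S(pairs(k, 0), pairs(k, 1)) = B(0, k);
        S(pairs(k, 1), pairs(k, 0)) = B(0, k);
      }
      covs.slice(t) = S;
    }
  }
  return List::create(_["means"] = means, _["coefs"] = coefs,
                      _["covs"] = covs);
}

// [[Rcpp::export(name = ".eng_implied")]]
arma::cube eng_implied(const arma::vec& theta, const List& engine) {
  Engine e = unpack(engine);
  arma::vec x, dx;
  natural(e, theta, x, dx);
  arma::cube Lambda, Beta, Phi, Psi;
  build_matrices(e, x, Lambda, Beta, Phi, Psi);
  arma::cube out(e.I, e.I, e.G);
  arma::mat Sigma, Ginv, C;
  for (int g = 0; g < e.G; g++) {
    if (!implied_one(e, Lambda, Beta, Phi, Psi, g, Sigma, Ginv, C))
      stop("singular (I - B) at supplied parameter values");
    out.slice(g) = Sigma;
  }
  return out;
}

// Kernel-weighted cross-product accumulation: for each focal point t,
// Sigma_t = W_t^{-1} sum_n w_nt e_nit e_njt with the residual matrix E
// (N x I) specific to t supplied by the caller column-block-wise.
// [[Rcpp::export(name = ".weighted_crossprod")]]
arma::mat weighted_crossprod(const arma::mat& E, const arma::vec& w) {
  arma::mat Ew = E.each_col() % arma::sqrt(w);
  return Ew.t() * Ew;
}
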