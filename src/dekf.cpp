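// Dual extended Kalman filter for time-varying MVAR coefficient tracking.
//
// Two coupled filters run in parallel over the samples: a state filter
// tracking the stacked lagged-signal state x_t = [y_t; ...; y_{t-p+1}]
// under the current coefficient estimate, and a parameter filter tracking
// a_t = vec([A1 ... Ap]) under a random-walk model, observed through the
// regression y_t = [A1 ... Ap] z_{t-1} + e_t with z taken from the state
// filter. The hot loop lives here because it runs once per sample and per
// surrogate refit. The regression matrix C_t = kron(z', I_m) and the
// companion transition F are never built densely; their structure is used
// directly.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// [[Rcpp::export]]
Rcpp::List dekf_core(const arma::mat& y, int p, const arma::vec& a0,
                     const arma::mat& R_param, double q_param,
                     const arma::mat& Q_state_top, double r_obs,
                     double p0_param, double p0_state,
                     double diverge_bound) {
  const int m = y.n_rows, T = y.n_cols;
  const int nx = m * p, na = m * m * p;

  vec a = a0;
  mat Pa = p0_param * eye(na, na);
  mat Px = p0_state * eye(nx, nx);

  // state initialized from the true first p samples: [y_p; ...; y_1]
  vec x(nx);
  for (int r = 0; r < p; ++r) x.subvec(r * m, r * m + m - 1) = y.col(p - 1 - r);

  const mat Rx = r_obs * eye(m, m);

  mat A_out(na, T - p, fill::zeros);
  vec perr(T - p, fill::zeros);
  bool diverged = false;

  mat PaCt(na, m), S(m, m), K(na, m), Kt(m, na);
  mat A1(m, nx), Pxp(nx, nx), Sx(m, m), Kx(nx, m), Kxt(m, nx);
  vec xpred(nx), e(m), a_pred(na);

  for (int t = p; t < T; ++t) {
    // ---- parameter filter: predict (random walk) ----
    Pa.diag() += q_param;

    // C_t = kron(z', I_m): column k*m+i of C' holds z(k) at row i, so
    // PaCt(:, i) = sum_k z(k) * Pa(:, k*m + i)
    const vec z = x;                       // state estimate of lagged y
    PaCt.zeros();
    for (int k = 0; k < m * p; ++k)
      PaCt += z(k) * Pa.cols(k * m, k * m + m - 1);
    // S = C Pa C' + R  (Pa symmetric => C Pa = PaCt')
    S = R_param;
    for (int k = 0; k < m * p; ++k)
      S += z(k) * PaCt.rows(k * m, k * m + m - 1).t();
    S = symmatu(S);

    const mat M(const_cast<double*>(a.memptr()), m, m * p, false, true);
    e = y.col(t) - M * z;

    if (!solve(Kt, S, PaCt.t(), solve_opts::likely_sympd)) {
      diverged = true; break;
    }
    K = Kt.t();                            // na x m gain
    a += K * e;
    Pa = symmatu(Pa - K * PaCt.t());
    perr(t - p) = norm(e);

    // ---- state filter with the updated coefficients ----
    // F = [M2; shift identity]; products use the block structure
    const mat M2(const_cast<double*>(a.memptr()), m, m * p, false, true);
    xpred.head(m) = M2 * x;
    if (p > 1) xpred.tail(nx - m) = x.head(nx - m);

    A1 = M2 * Px;                          // m x nx
    Pxp.submat(0, 0, m - 1, m - 1) = A1 * M2.t() + Q_state_top;
    if (p > 1) {
      Pxp.submat(0, m, m - 1, nx - 1) = A1.cols(0, nx - m - 1);
      Pxp.submat(m, 0, nx - 1, m - 1) = A1.cols(0, nx - m - 1).t();
      Pxp.submat(m, m, nx - 1, nx - 1) =
        Px.submat(0, 0, nx - m - 1, nx - m - 1);
      Pxp.submat(m, m, nx - 1, nx - 1).diag() += 1e-8;
    }
    Sx = symmatu(Pxp.submat(0, 0, m - 1, m - 1) + Rx);
    if (!solve(Kxt, Sx, Pxp.cols(0, m - 1).t(), solve_opts::likely_sympd)) {
      diverged = true; break;
    }
    Kx = Kxt.t();                          // nx x m gain
    x = xpred + Kx * (y.col(t) - xpred.head(m));
    Px = symmatu(Pxp - Kx * Pxp.rows(0, m - 1));

    A_out.col(t - p) = a;
    if (!a.is_finite() || norm(a) > diverge_bound) { diverged = true; break; }
  }

  return Rcpp::List::create(Rcpp::Named("a_traj") = A_out,
                            Rcpp::Named("pred_error") = perr,
                            Rcpp::Named("diverged") = diverged);
}
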