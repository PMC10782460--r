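// Core computations for the proportional-rates model on an integer-day grid.
//
// Conventions shared with the R side:
//  * days are integers 0..tau; row r is at risk on days lo[r]..hi[r] inclusive;
//  * rows are sorted by facility (fac non-decreasing, 0-based ids);
//  * eday[r] is the event day carried by row r (== hi[r]) or -1;
//  * all risk-set sums are built by sweeping interval endpoints (difference
//    arrays + prefix sums), never by splitting records per event.

#include <RcppArmadillo.h>
using namespace Rcpp;

static std::vector<int> facility_ptr(const IntegerVector& fac, int F) {
  std::vector<int> ptr(F + 1, 0);
  int R = fac.size();
  for (int r = 0; r < R; ++r) ptr[fac[r] + 1]++;
  for (int j = 0; j < F; ++j) ptr[j + 1] += ptr[j];
  return ptr;
}

// Stratified Breslow score U(beta), observed information I(beta) and log
// partial likelihood. Strata (facilities) with no events contribute nothing.
// [[Rcpp::export]]
List cpp_score(const IntegerVector& lo, const IntegerVector& hi,
               const IntegerVector& fac, const IntegerVector& eday,
               const arma::mat& Z, const arma::vec& beta, int F, int tau) {
  const int R = lo.size();
  const int p = Z.n_cols;
  const int ncell = p * (p + 1) / 2;
  arma::vec eta = Z * beta;
  arma::vec w = arma::exp(eta);

  arma::vec U(p, arma::fill::zeros);
  arma::mat I(p, p, arma::fill::zeros);
  double llik = 0.0;

  std::vector<int> ptr = facility_ptr(fac, F);

  // per-facility scratch, reset between facilities
  arma::vec d0(tau + 2);
  arma::mat d1(tau + 2, p);
  arma::mat d2(tau + 2, ncell);
  std::vector<double> dN(tau + 1, 0.0);
  std::vector<double> sEta(tau + 1, 0.0);
  arma::mat sZ(tau + 1, p, arma::fill::zeros);
  std::vector<int> days;

  arma::rowvec zbar(p);
  arma::vec cur1(p);
  arma::vec cur2(ncell);

  for (int j = 0; j < F; ++j) {
    const int r0 = ptr[j], r1 = ptr[j + 1];
    if (r0 == r1) continue;
    days.clear();
    for (int r = r0; r < r1; ++r) {
      int d = eday[r];
      if (d >= 0) {
        if (dN[d] == 0.0) days.push_back(d);
        dN[d] += 1.0;
        sEta[d] += eta[r];
        sZ.row(d) += Z.row(r);
      }
    }
    if (days.empty()) continue;   // stratum with no events: zero contribution
    std::sort(days.begin(), days.end());
    const int dmax = days.back();

    d0.zeros();
    d1.zeros();
    d2.zeros();
    for (int r = r0; r < r1; ++r) {
      const double wr = w[r];
      const int a = lo[r], b = hi[r] + 1;
      d0[a] += wr; d0[b] -= wr;
      for (int k = 0; k < p; ++k) {
        const double v = wr * Z(r, k);
        d1(a, k) += v; d1(b, k) -= v;
      }
      int c = 0;
      for (int k = 0; k < p; ++k)
        for (int l = k; l < p; ++l, ++c) {
          const double v = wr * Z(r, k) * Z(r, l);
          d2(a, c) += v; d2(b, c) -= v;
        }
    }

    // sweep days, reading off sums at this facility's event days
    double cur0 = 0.0;
    cur1.zeros();
    cur2.zeros();
    std::size_t next = 0;
    for (int d = 0; d <= dmax; ++d) {
      cur0 += d0[d];
      for (int k = 0; k < p; ++k) cur1[k] += d1(d, k);
      for (int c = 0; c < ncell; ++c) cur2[c] += d2(d, c);
      if (next < days.size() && days[next] == d) {
        ++next;
        const double S0 = cur0;
        if (S0 <= 0.0)
          stop("empty risk set at an event day (facility index %d, day %d)",
               j + 1, d);
        const double n_ev = dN[d];
        for (int k = 0; k < p; ++k) zbar[k] = cur1[k] / S0;
        for (int k = 0; k < p; ++k) U[k] += sZ(d, k) - n_ev * zbar[k];
        llik += sEta[d] - n_ev * std::log(S0);
        int c = 0;
        for (int k = 0; k < p; ++k)
          for (int l = k; l < p; ++l, ++c) {
            const double v = n_ev * (cur2[c] / S0 - zbar[k] * zbar[l]);
            I(k, l) += v;
            if (l != k) I(l, k) += v;
          }
      }
    }

    for (int d : days) { dN[d] = 0.0; sEta[d] = 0.0; sZ.row(d).zeros(); }
  }

  return List::create(_["score"] = U, _["information"] = I,
                      _["loglik"] = llik);
}

// Per-subject score contributions U_i at beta (stratified model, no alpha),
// used by the sandwich variance for beta. Returns an n x p matrix.
// [[Rcpp::export]]
arma::mat cpp_subject_scores(const IntegerVector& lo, const IntegerVector& hi,
                             const IntegerVector& fac, const IntegerVector& subj,
                             const IntegerVector& eday, const arma::mat& Z,
                             const arma::vec& beta, int F, int n, int tau) {
  const int R = lo.size();
  const int p = Z.n_cols;
  arma::vec w = arma::exp(Z * beta);
  arma::mat Uh(n, p, arma::fill::zeros);

  std::vector<int> ptr = facility_ptr(fac, F);

  arma::vec d0(tau + 2);
  arma::mat d1(tau + 2, p);
  std::vector<double> dN(tau + 1, 0.0);
  std::vector<int> days;
  // prefix sums over days of a(t) = dN_j(t)/S0_j(t) and a(t) * zbar_j(t)
  arma::vec A(tau + 2);
  arma::mat Cm(tau + 2, p);
  // zbar at event days, keyed by day (valid within one facility's pass)
  arma::mat zb_store(tau + 1, p);

  for (int j = 0; j < F; ++j) {
    const int r0 = ptr[j], r1 = ptr[j + 1];
    if (r0 == r1) continue;
    days.clear();
    for (int r = r0; r < r1; ++r) {
      int d = eday[r];
      if (d >= 0) {
        if (dN[d] == 0.0) days.push_back(d);
        dN[d] += 1.0;
      }
    }
    if (days.empty()) continue;
    std::sort(days.begin(), days.end());

    d0.zeros();
    d1.zeros();
    for (int r = r0; r < r1; ++r) {
      const double wr = w[r];
      const int a = lo[r], b = hi[r] + 1;
      d0[a] += wr; d0[b] -= wr;
      for (int k = 0; k < p; ++k) {
        const double v = wr * Z(r, k);
        d1(a, k) += v; d1(b, k) -= v;
      }
    }

    double cur0 = 0.0;
    arma::rowvec cur1(p, arma::fill::zeros);
    std::size_t next = 0;
    double accA = 0.0;
    arma::rowvec accC(p, arma::fill::zeros);
    A[0] = 0.0;
    Cm.row(0).zeros();
    for (int d = 0; d <= tau; ++d) {
      cur0 += d0[d];
      cur1 += d1.row(d);
      if (next < days.size() && days[next] == d) {
        ++next;
        const double a_t = dN[d] / cur0;
        arma::rowvec zbar = cur1 / cur0;
        accA += a_t;
        accC += a_t * zbar;
        zb_store.row(d) = zbar;
      }
      A[d + 1] = accA;
      Cm.row(d + 1) = accC;
    }

    for (int r = r0; r < r1; ++r) {
      const int s = subj[r];
      const double sA = A[hi[r] + 1] - A[lo[r]];
      Uh.row(s) -= w[r] * (Z.row(r) * sA - (Cm.row(hi[r] + 1) - Cm.row(lo[r])));
      const int d = eday[r];
      if (d >= 0) Uh.row(s) += Z.row(r) - zb_store.row(d);
    }

    for (int d : days) dN[d] = 0.0;
  }
  return Uh;
}

// Fixed-point estimation of facility effects alpha under the sum(O)=sum(E)
// constraint, alternating the Nelson-Aalen baseline (at current alpha) with
// the explicit update exp(alpha_j) = C * O_j / E_j. Facilities with O_j = 0
// are pinned at `sentinel` and excluded from the convergence check.
// [[Rcpp::export]]
List cpp_fixed_point(const IntegerVector& lo, const IntegerVector& hi,
                     const IntegerVector& fac, const IntegerVector& subj,
                     const IntegerVector& eday, const arma::mat& Z,
                     const arma::vec& beta, int F, int n, int tau,
                     double tol, int max_iter, double sentinel) {
  const int R = lo.size();
  arma::vec eta = Z * beta;
  arma::vec w = arma::exp(eta);

  arma::vec Oj(F, arma::fill::zeros);
  arma::vec Oi(n, arma::fill::zeros);
  std::vector<double> dNdot(tau + 1, 0.0);
  double sum_eta_ev = 0.0;
  for (int r = 0; r < R; ++r) {
    const int d = eday[r];
    if (d >= 0) {
      Oj[fac[r]] += 1.0;
      Oi[subj[r]] += 1.0;
      dNdot[d] += 1.0;
      sum_eta_ev += eta[r];
    }
  }
  const double Otot = arma::accu(Oj);
  if (Otot <= 0.0) stop("no events: facility effects are not estimable");

  arma::vec alpha(F, arma::fill::zeros);       // alpha^(0) = 0
  arma::vec Ej(F, arma::fill::zeros);
  arma::vec ea(F);
  std::vector<double> s0diff(tau + 2, 0.0);
  std::vector<double> Dcum(tau + 2, 0.0);
  std::vector<double> C_hist, llik_hist, delta_hist;
  bool converged = false;
  int iter = 0;

  for (int s = 0; s < max_iter; ++s) {
    iter = s + 1;
    ea = arma::exp(alpha);
    std::fill(s0diff.begin(), s0diff.end(), 0.0);
    for (int r = 0; r < R; ++r) {
      const double ww = w[r] * ea[fac[r]];
      s0diff[lo[r]] += ww;
      s0diff[hi[r] + 1] -= ww;
    }
    // baseline increments and prefix sums of dmu over days
    double acc = 0.0, cum = 0.0, llogS0 = 0.0;
    Dcum[0] = 0.0;
    for (int d = 0; d <= tau; ++d) {
      acc += s0diff[d];
      if (dNdot[d] > 0.0) {
        if (acc <= 0.0)
          stop("risk-set total is zero at event day %d", d);
        cum += dNdot[d] / acc;
        llogS0 += dNdot[d] * std::log(acc);
      }
      Dcum[d + 1] = cum;
    }
    // E_j at the current baseline (no alpha inside E, Eq. for E_j)
    Ej.zeros();
    for (int r = 0; r < R; ++r)
      Ej[fac[r]] += w[r] * (Dcum[hi[r] + 1] - Dcum[lo[r]]);

    const double C = arma::accu(Ej) / Otot;
    C_hist.push_back(C);
    // profile log-likelihood in alpha at the CURRENT alpha (baseline profiled)
    llik_hist.push_back(arma::dot(Oj, alpha) + sum_eta_ev - llogS0);

    double delta = 0.0;
    for (int j = 0; j < F; ++j) {
      double anew;
      if (Oj[j] > 0.0) {
        if (Ej[j] <= 0.0)
          stop("facility %d has events but zero expected count (no at-risk "
               "overlap with event days)", j + 1);
        anew = std::log(C * Oj[j] / Ej[j]);
        delta = std::max(delta, std::fabs(anew - alpha[j]));
      } else {
        anew = sentinel;
      }
      alpha[j] = anew;
    }
    delta_hist.push_back(delta);
    if (delta <= tol) { converged = true; break; }
  }

  // final baseline and expected counts at the converged alpha
  ea = arma::exp(alpha);
  std::fill(s0diff.begin(), s0diff.end(), 0.0);
  for (int r = 0; r < R; ++r) {
    const double ww = w[r] * ea[fac[r]];
    s0diff[lo[r]] += ww;
    s0diff[hi[r] + 1] -= ww;
  }
  arma::vec dmu(tau + 1, arma::fill::zeros);
  arma::vec S0day(tau + 1, arma::fill::zeros);
  double acc = 0.0, cum = 0.0;
  Dcum[0] = 0.0;
  for (int d = 0; d <= tau; ++d) {
    acc += s0diff[d];
    S0day[d] = acc;
    if (dNdot[d] > 0.0) dmu[d] = dNdot[d] / acc;
    cum += dmu[d];
    Dcum[d + 1] = cum;
  }
  Ej.zeros();
  arma::vec Ei(n, arma::fill::zeros);
  for (int r = 0; r < R; ++r) {
    const double e = w[r] * (Dcum[hi[r] + 1] - Dcum[lo[r]]);
    Ej[fac[r]] += e;
    Ei[subj[r]] += e;
  }

  return List::create(
      _["alpha"] = alpha, _["O_fac"] = Oj, _["E_fac"] = Ej,
      _["O_subj"] = Oi, _["E_subj"] = Ei,
      _["C_history"] = C_hist, _["loglik_history"] = llik_hist,
      _["delta_history"] = delta_hist,
      _["n_iter"] = iter, _["converged"] = converged,
      _["dmu"] = dmu, _["S0"] = S0day);
}
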