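#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// One EM sweep for the admixture model.  Input: Q (N x K) ancestry
// fractions, F (K x S) cluster minor-allele frequencies, genotype
// likelihoods L* (S x N).  Writes the updated parameters into Qn/Fn and
// returns the observed log-likelihood of the INPUT point:
//   sum_s sum_i log sum_g L_isg * P(g | h_is),  h_is = sum_k q_ik f_ks,
// with P(g|h) = ((1-h)^2, 2h(1-h), h^2).  Expected allele-copy
// attributions give the standard monotone updates.
static double em_sweep(const arma::mat& L0, const arma::mat& L1,
                       const arma::mat& L2, const arma::mat& Q,
                       const arma::mat& F, arma::mat& Qn, arma::mat& Fn,
                       double f_floor) {
  const int S = L0.n_rows, N = L0.n_cols, K = Q.n_cols;
  double ll = 0.0;
  Qn.zeros(N, K);
  arma::mat Fnum(K, S, arma::fill::zeros), Fden(K, S, arma::fill::zeros);
  std::vector<double> qf(K), qrow(K), qacc(K);
  // individual-outer loops keep the likelihood columns contiguous
  for (int i = 0; i < N; ++i) {
    const double* l0 = L0.colptr(i);
    const double* l1 = L1.colptr(i);
    const double* l2 = L2.colptr(i);
    for (int k = 0; k < K; ++k) { qrow[k] = Q(i, k); qacc[k] = 0.0; }
    for (int s = 0; s < S; ++s) {
      const double* fcol = F.colptr(s);
      double h = 0.0;
      for (int k = 0; k < K; ++k) {
        qf[k] = qrow[k] * fcol[k];
        h += qf[k];
      }
      if (h < 1e-9) h = 1e-9;
      if (h > 1.0 - 1e-9) h = 1.0 - 1e-9;
      const double w0 = l0[s] * (1.0 - h) * (1.0 - h);
      const double w1 = l1[s] * 2.0 * h * (1.0 - h);
      const double w2 = l2[s] * h * h;
      const double denom = w0 + w1 + w2;
      ll += std::log(denom);
      const double a = (w1 + 2.0 * w2) / denom;  // E[minor copies]
      const double b = 2.0 - a;                  // E[major copies]
      const double ah = a / h, bh = b / (1.0 - h);
      double* fn = Fnum.colptr(s);
      double* fd = Fden.colptr(s);
      for (int k = 0; k < K; ++k) {
        const double mshare = ah * qf[k];
        const double Mshare = bh * qrow[k] * (1.0 - fcol[k]);
        qacc[k] += mshare + Mshare;
        fn[k] += mshare;
        fd[k] += mshare + Mshare;
      }
    }
    for (int k = 0; k < K; ++k) Qn(i, k) = qacc[k];
  }
  Fn = Fnum / Fden;
  Fn.transform([f_floor](double v) {
    if (v < f_floor) return f_floor;
    if (v > 1.0 - f_floor) return 1.0 - f_floor;
    return v;
  });
  Qn /= (2.0 * S);
  for (int i = 0; i < N; ++i) Qn.row(i) /= arma::accu(Qn.row(i));
  return ll;
}

static double loglik_only(const arma::mat& L0, const arma::mat& L1,
                          const arma::mat& L2, const arma::mat& Q,
                          const arma::mat& F) {
  const int S = L0.n_rows, N = L0.n_cols, K = Q.n_cols;
  double ll = 0.0;
  std::vector<double> qrow(K);
  for (int i = 0; i < N; ++i) {
    const double* l0 = L0.colptr(i);
    const double* l1 = L1.colptr(i);
    const double* l2 = L2.colptr(i);
    for (int k = 0; k < K; ++k) qrow[k] = Q(i, k);
    for (int s = 0; s < S; ++s) {
      const double* fcol = F.colptr(s);
      double h = 0.0;
      for (int k = 0; k < K; ++k) h += qrow[k] * fcol[k];
      if (h < 1e-9) h = 1e-9;
      if (h > 1.0 - 1e-9) h = 1.0 - 1e-9;
      ll += std::log(l0[s] * (1.0 - h) * (1.0 - h) +
                     l1[s] * 2.0 * h * (1.0 - h) +
                     l2[s] * h * h);
    }
  }
  return ll;
}

static void project(arma::mat& Q, arma::mat& F, double f_floor) {
  F.transform([f_floor](double v) {
    if (v < f_floor) return f_floor;
    if (v > 1.0 - f_floor) return 1.0 - f_floor;
    return v;
  });
  Q.transform([](double v) { return v < 1e-9 ? 1e-9 : v; });
  for (arma::uword i = 0; i < Q.n_rows; ++i)
    Q.row(i) /= arma::accu(Q.row(i));
}

// SQUAREM-accelerated EM: each cycle takes two EM sweeps, extrapolates
// along the change vectors, projects back to the feasible set, and falls
// back to the plain double sweep whenever extrapolation does not improve
// the observed log-likelihood, so the reported trace stays monotone.
// [[Rcpp::export]]
List admix_em_cpp(const arma::mat& L0, const arma::mat& L1,
                  const arma::mat& L2, arma::mat Q, arma::mat F,
                  int max_iter, double tol, double f_floor,
                  bool accelerate = true) {
  std::vector<double> ll_trace;
  arma::mat Q1, F1, Q2, F2, Qt, Ft, Qd, Fd;
  double ll_prev = -std::numeric_limits<double>::infinity();
  int sweeps = 0;
  while (sweeps < max_iter) {
    double ll0 = em_sweep(L0, L1, L2, Q, F, Q1, F1, f_floor);
    ++sweeps;
    ll_trace.push_back(ll0);
    if (std::abs(ll0 - ll_prev) < tol) { Q = Q1; F = F1; break; }
    ll_prev = ll0;
    if (!accelerate) { Q = Q1; F = F1; continue; }
    double ll1 = em_sweep(L0, L1, L2, Q1, F1, Q2, F2, f_floor);
    ++sweeps;
    if (std::abs(ll1 - ll0) < tol) { Q = Q2; F = F2;
      ll_trace.push_back(ll1); break; }
    arma::mat rQ = Q1 - Q, rF = F1 - F;
    arma::mat vQ = Q2 - Q1 - rQ, vF = F2 - F1 - rF;
    double rn = std::sqrt(arma::accu(rQ % rQ) + arma::accu(rF % rF));
    double vn = std::sqrt(arma::accu(vQ % vQ) + arma::accu(vF % vF));
    if (vn < 1e-12) { Q = Q2; F = F2; continue; }
    double alpha = -std::max(1.0, rn / vn);
    Qt = Q - 2.0 * alpha * rQ + alpha * alpha * vQ;
    Ft = F - 2.0 * alpha * rF + alpha * alpha * vF;
    project(Qt, Ft, f_floor);
    double llt = loglik_only(L0, L1, L2, Qt, Ft);
    if (llt >= ll1) { Q = Qt; F = Ft; } else { Q = Q2; F = F2; }
  }
  return List::create(_["Q"] = Q, _["F"] = F,
                      _["loglik"] = ll_trace.empty() ? NA_REAL
                                                     : ll_trace.back(),
                      _["loglik_trace"] = ll_trace,
                      _["iterations"] = sweeps);
}
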