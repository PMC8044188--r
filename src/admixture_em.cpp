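#include <Rcpp.h>
using namespace Rcpp;

// Block EM for the unsupervised admixture likelihood on unphased dosages.
// G: n x m dosages in {0,1,2}, NA_INTEGER missing. Q: n x K admixture
// proportions. P: K x m group allele frequencies. Each observed allele is
// allocated to a source group proportionally to Q_ik * P_kj (alternate
// allele) or Q_ik * (1 - P_kj) (reference allele); expected counts are
// renormalized into the updated Q and P. The log-likelihood is evaluated
// at the current parameters each sweep, so the returned trace is the EM
// ascent path; convergence is declared on a relative change below tol.
// [[Rcpp::export]]
List admixture_em_cpp(IntegerMatrix G, NumericMatrix Q_, NumericMatrix P_,
                      int max_iter, double tol, double eps) {
  int n = G.nrow(), m = G.ncol(), K = Q_.ncol();
  NumericMatrix Q(clone(Q_)), P(clone(P_));
  std::vector<double> M(n, 0.0);  // non-missing loci per line
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      if (G(i, j) != NA_INTEGER) M[i] += 1.0;

  std::vector<double> trace;
  trace.reserve(max_iter);
  bool converged = false;
  int iter = 0;
  std::vector<double> t1(K), t0(K), EQ(n * K), Pnum(K * m), Pden(K * m);

  for (iter = 1; iter <= max_iter; ++iter) {
    std::fill(EQ.begin(), EQ.end(), 0.0);
    std::fill(Pnum.begin(), Pnum.end(), 0.0);
    std::fill(Pden.begin(), Pden.end(), 0.0);
    double ll = 0.0;
    for (int j = 0; j < m; ++j) {
      for (int i = 0; i < n; ++i) {
        int g = G(i, j);
        if (g == NA_INTEGER) continue;
        // alternate- and reference-allele mass; pi + qi == 1 because Q
        // rows are kept normalized, so allocations below sum exactly to g
        // and 2 - g and the row constraint cannot drift
        double pi = 0.0, qi = 0.0;
        for (int k = 0; k < K; ++k) {
          t1[k] = Q(i, k) * P(k, j);
          t0[k] = Q(i, k) * (1.0 - P(k, j));
          pi += t1[k];
          qi += t0[k];
        }
        ll += g * std::log(std::max(pi, eps)) +
          (2 - g) * std::log(std::max(qi, eps));
        for (int k = 0; k < K; ++k) {
          double a = (g > 0) ? g * t1[k] / pi : 0.0;
          double b = (g < 2) ? (2 - g) * t0[k] / qi : 0.0;
          EQ[i + (size_t)n * k] += a + b;
          Pnum[k + (size_t)K * j] += a;
          Pden[k + (size_t)K * j] += a + b;
        }
      }
    }
    trace.push_back(ll);
    if (iter > 1) {
      double prev = trace[iter - 2];
      if (std::fabs(ll - prev) < tol * (std::fabs(prev) + 1.0)) {
        converged = true;
        break;
      }
    }
    for (int i = 0; i < n; ++i) {
      if (M[i] == 0.0) continue;
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += EQ[i + (size_t)n * k];
      if (s <= 0.0) continue;
      for (int k = 0; k < K; ++k)
        Q(i, k) = EQ[i + (size_t)n * k] / s;
    }
    for (int j = 0; j < m; ++j)
      for (int k = 0; k < K; ++k) {
        double den = Pden[k + (size_t)K * j];
        if (den > 0.0) {
          double p = Pnum[k + (size_t)K * j] / den;
          if (p < eps) p = eps;
          if (p > 1.0 - eps) p = 1.0 - eps;
          P(k, j) = p;
        }
      }
  }
  if (iter > max_iter) iter = max_iter;
  return List::create(_["Q"] = Q, _["P"] = P,
                      _["trace"] = NumericVector(trace.begin(), trace.end()),
                      _["iterations"] = iter, _["converged"] = converged);
}
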