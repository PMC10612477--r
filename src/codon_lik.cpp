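// Likelihood core for GY94-family codon models: reversible rate matrix
// eigendecomposition, transition probabilities, and Felsenstein pruning over
// site-class mixtures. Column scaling keeps partials in range for long trees.

#include <RcppArmadillo.h>
#include <map>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Decomp {
  mat V1;      // D^{-1/2} U
  mat V2;      // U' D^{1/2}
  vec lam;     // eigenvalues of the UNSCALED generator
  double rate; // -sum_i pi_i q_ii of the unscaled generator
};

// Build the (unscaled) GY94 generator for one omega and eigendecompose it.
// types(i,j): 0 none, 1 syn transversion, 2 syn transition,
// 3 nonsyn transversion, 4 nonsyn transition.
Decomp decompose(const imat& types, const vec& pi, double kappa, double omega) {
  const int n = pi.n_elem;
  mat Q(n, n, fill::zeros);
  for (int i = 0; i < n; ++i) {
    double rs = 0.0;
    for (int j = 0; j < n; ++j) {
      int t = types(i, j);
      if (t == 0) continue;
      double m = (t == 1) ? 1.0 : (t == 2) ? kappa : (t == 3) ? omega : omega * kappa;
      double q = m * pi(j);
      Q(i, j) = q;
      rs += q;
    }
    Q(i, i) = -rs;
  }
  Decomp d;
  d.rate = -dot(pi, Q.diag());
  if (d.rate <= 0) d.rate = 1.0;

  vec sp = sqrt(pi);
  mat A(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      A(i, j) = Q(i, j) * sp(i) / sp(j);
  A = 0.5 * (A + A.t());

  mat U;
  eig_sym(d.lam, U, A);
  d.V1 = U;
  d.V1.each_col() /= sp;
  d.V2 = U.t();
  d.V2.each_row() %= sp.t();
  return d;
}

inline mat ptrans(const Decomp& d, double t) {
  mat P = d.V1 * diagmat(exp(d.lam * t)) * d.V2;
  P.transform([](double x) { return x < 0 ? 0.0 : x; });
  return P;
}

// Pruning over all site classes. Returns per-class, per-pattern log
// likelihoods (K x npat). Branch lengths are expected substitutions per
// codon averaged over site classes (CodeML convention): on branch b the
// generators of all classes share the scale factor
// s_b = sum_k props_k * rate(omega(k,b)).
mat class_loglik(const imat& types, const vec& pi, double kappa,
                 const imat& edges, const vec& blens,
                 const imat& tipstates, const vec& props,
                 const mat& omegas, int n_nodes) {
  const int ntip = tipstates.n_rows;
  const int npat = tipstates.n_cols;
  const int nedge = edges.n_rows;
  const int K = omegas.n_rows;
  const int nint = n_nodes - ntip;
  const int ns = pi.n_elem;

  std::map<double, Decomp> cache;
  for (int k = 0; k < K; ++k)
    for (int b = 0; b < nedge; ++b)
      if (cache.find(omegas(k, b)) == cache.end())
        cache.emplace(omegas(k, b), decompose(types, pi, kappa, omegas(k, b)));

  // per-branch mixture-average rate
  vec bscale(nedge);
  for (int b = 0; b < nedge; ++b) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += props(k) * cache.at(omegas(k, b)).rate;
    bscale(b) = (s > 0) ? s : 1.0;
  }

  const int root = edges(nedge - 1, 0);
  mat out(K, npat);

  for (int k = 0; k < K; ++k) {
    std::vector<mat> part(nint);
    for (int i = 0; i < nint; ++i) part[i] = mat(ns, npat, fill::ones);
    rowvec logscale(npat, fill::zeros);

    for (int b = 0; b < nedge; ++b) {
      const int p = edges(b, 0) - ntip;
      const int c = edges(b, 1);
      const mat P = ptrans(cache.at(omegas(k, b)), blens(b) / bscale(b));
      if (c < ntip) {
        for (int s = 0; s < npat; ++s)
          part[p].col(s) %= P.col(tipstates(c, s));
      } else {
        part[p] %= P * part[c - ntip];
      }
      // rescale parent columns to guard against underflow
      for (int s = 0; s < npat; ++s) {
        double m = part[p].col(s).max();
        if (m > 0 && m < 1e-200) {
          part[p].col(s) /= m;
          logscale(s) += std::log(m);
        }
      }
    }
    rowvec lik = pi.t() * part[root - ntip];
    for (int s = 0; s < npat; ++s)
      out(k, s) = std::log(std::max(lik(s), 1e-320)) + logscale(s);
  }
  return out;
}

}  // namespace

// [[Rcpp::export]]
double cpp_codon_lnl(const arma::imat& types, const arma::vec& pi, double kappa,
                     const arma::imat& edges, const arma::vec& blens,
                     const arma::imat& tipstates, const arma::vec& weights,
                     const arma::vec& props, const arma::mat& omegas,
                     int n_nodes) {
  mat ll = class_loglik(types, pi, kappa, edges, blens, tipstates, props, omegas, n_nodes);
  const int K = ll.n_rows, npat = ll.n_cols;
  vec lp = log(props);
  double lnl = 0.0;
  for (int s = 0; s < npat; ++s) {
    double mx = -datum::inf;
    for (int k = 0; k < K; ++k) mx = std::max(mx, lp(k) + ll(k, s));
    double acc = 0.0;
    for (int k = 0; k < K; ++k) acc += std::exp(lp(k) + ll(k, s) - mx);
    lnl += weights(s) * (mx + std::log(acc));
  }
  return lnl;
}

// [[Rcpp::export]]
Rcpp::List cpp_codon_sitelik(const arma::imat& types, const arma::vec& pi,
                             double kappa, const arma::imat& edges,
                             const arma::vec& blens, const arma::imat& tipstates,
                             const arma::vec& weights, const arma::vec& props,
                             const arma::mat& omegas, int n_nodes) {
  mat ll = class_loglik(types, pi, kappa, edges, blens, tipstates, props, omegas, n_nodes);
  const int K = ll.n_rows, npat = ll.n_cols;
  vec lp = log(props);
  double lnl = 0.0;
  for (int s = 0; s < npat; ++s) {
    double mx = -datum::inf;
    for (int k = 0; k < K; ++k) mx = std::max(mx, lp(k) + ll(k, s));
    double acc = 0.0;
    for (int k = 0; k < K; ++k) acc += std::exp(lp(k) + ll(k, s) - mx);
    lnl += weights(s) * (mx + std::log(acc));
  }
  return Rcpp::List::create(Rcpp::Named("lnl") = lnl,
                            Rcpp::Named("class_loglik") = ll);
}

// [[Rcpp::export]]
arma::mat cpp_transition_matrix(const arma::imat& types, const arma::vec& pi,
                                double kappa, double omega, double t) {
  Decomp d = decompose(types, pi, kappa, omega);
  return ptrans(d, t / d.rate);  // unit-rate scaling for the single matrix
}
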