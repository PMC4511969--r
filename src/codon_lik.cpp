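// Felsenstein pruning for the 61-state Goldman-Yang codon model.
//
// The model is time-reversible, so P(t) = exp(Qt) is computed through the
// symmetric similarity transform B = D^{1/2} Q D^{-1/2}, D = diag(pi):
// one eig_sym per branch class per likelihood evaluation. Partial
// likelihoods are propagated in postorder with per-pattern rescaling to
// avoid underflow on long alignments.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

namespace {

struct Eigensystem {
  mat U;      // D^{-1/2} V
  mat W;      // V^T D^{1/2}
  vec lambda;
};

// Build Q (rows sum 0, mean rate 1 under pi) from the neighbour pair lists.
mat build_q(double kappa, double omega, const vec& pi,
            const ivec& pr_i, const ivec& pr_j,
            const ivec& pr_ts, const ivec& pr_syn) {
  const uword n = pi.n_elem;
  mat Q(n, n, fill::zeros);
  for (uword k = 0; k < pr_i.n_elem; ++k) {
    double r = pi[pr_j[k]];
    if (pr_ts[k]) r *= kappa;
    if (!pr_syn[k]) r *= omega;
    Q(pr_i[k], pr_j[k]) = r;
  }
  Q.diag() = -sum(Q, 1);
  double scale = -dot(pi, Q.diag());
  if (scale > 0) Q /= scale;
  return Q;
}

Eigensystem decompose(const mat& Q, const vec& pi) {
  vec d = sqrt(pi);
  mat B = Q;
  B.each_col() %= d;       // rows scaled by d_i
  B.each_row() /= d.t();   // cols scaled by 1/d_j
  B = 0.5 * (B + B.t());
  Eigensystem es;
  eig_sym(es.lambda, es.U, B);
  es.W = es.U.t();
  es.W.each_row() %= d.t();   // V^T D^{1/2}
  es.U.each_col() /= d;       // D^{-1/2} V
  return es;
}

mat pmatrix(const Eigensystem& es, double t) {
  mat E = es.W;
  E.each_col() %= exp(es.lambda * t);
  mat P = es.U * E;
  P.elem(find(P < 0)).zeros();
  return P;
}

}  // namespace

// states: ntaxa x npat integer matrix, 1-based sense-codon states (no NA).
// edge: nedge x 2 (parent, child), ape 1-based node ids, postorder rows.
// edge_fg: integer 0/1 per edge. omega has one or two entries (bg, fg).
// [[Rcpp::export(name = ".cpp_codon_lnL")]]
double cpp_codon_lnL(const arma::imat& states, const arma::vec& weights,
                     const arma::imat& edge, const arma::vec& edge_len,
                     const arma::ivec& edge_fg,
                     double kappa, double omega_bg, double omega_fg,
                     const arma::vec& pi,
                     const arma::ivec& pr_i, const arma::ivec& pr_j,
                     const arma::ivec& pr_ts, const arma::ivec& pr_syn) {
  const uword ns = pi.n_elem;
  const uword ntaxa = states.n_rows;
  const uword npat = states.n_cols;
  const uword nedge = edge.n_rows;
  if (npat == 0) return 0.0;

  Eigensystem es_bg = decompose(
      build_q(kappa, omega_bg, pi, pr_i, pr_j, pr_ts, pr_syn), pi);
  bool two_class = any(edge_fg != 0) && omega_fg != omega_bg;
  Eigensystem es_fg = two_class
      ? decompose(build_q(kappa, omega_fg, pi, pr_i, pr_j, pr_ts, pr_syn), pi)
      : es_bg;

  const uword nnode = ntaxa + edge.max();  // generous upper bound on ids
  std::vector<mat> partial(nnode + 1);
  std::vector<bool> seen(nnode + 1, false);
  rowvec logscale(npat, fill::zeros);

  uword root = edge(nedge - 1, 0);
  for (uword e = 0; e < nedge; ++e) {
    uword parent = edge(e, 0), child = edge(e, 1);
    mat Lc;
    if (child <= ntaxa) {              // tip
      Lc.zeros(ns, npat);
      for (uword p = 0; p < npat; ++p)
        Lc(states(child - 1, p) - 1, p) = 1.0;
    } else {
      Lc = std::move(partial[child]);
    }
    const Eigensystem& es = (edge_fg[e] && two_class) ? es_fg : es_bg;
    mat msg = pmatrix(es, edge_len[e]) * Lc;
    if (!seen[parent]) {
      partial[parent] = std::move(msg);
      seen[parent] = true;
    } else {
      partial[parent] %= msg;
      // rescale to dodge underflow
      rowvec m = max(partial[parent], 0);
      m.elem(find(m <= 0)).ones();
      partial[parent].each_row() /= m;
      logscale += log(m);
    }
  }
  rowvec site = pi.t() * partial[root];
  double lnL = dot(weights, log(site) + logscale);
  return lnL;
}
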