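#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Felsenstein pruning over site patterns with per-node rescaling.
//
// edges:  nedge x 2 integer (parent, child), 0-based node ids, postorder
//         (every child edge appears before the edge above its parent);
//         tips are nodes 0..ntip-1, the (virtual) root is edges(nedge-1, 0).
// P:      cube A x A x (nedge * ncat); slice e * ncat + k holds the
//         transition matrix of edge e at gamma category k, P(a,b) =
//         Pr(child = b | parent = a).
// tips:   ntip x npat integer states in 0..A-1, -1 = missing.
// pi:     root frequencies. wk: category weights.
//
// Returns the per-pattern log-likelihood vector. Scaling factors are
// shared across categories (one log-scale accumulator per pattern), so the
// result is exact for >= 1e5 columns without underflow.
// [[Rcpp::export]]
arma::vec plik_patterns_cpp(const arma::imat& edges, const arma::cube& P,
                            const arma::imat& tips, const arma::vec& pi,
                            const arma::vec& wk) {
  const int nedge = edges.n_rows;
  const int ncat = wk.n_elem;
  const int A = pi.n_elem;
  const int ntip = tips.n_rows;
  const int npat = tips.n_cols;
  int nnodes = edges.max() + 1;

  // partials[node] is an (A*ncat) x npat matrix (categories stacked)
  std::vector<arma::mat> part(nnodes);
  arma::vec logscale(npat, arma::fill::zeros);

  for (int e = 0; e < nedge; ++e) {
    const int par = edges(e, 0), chd = edges(e, 1);
    arma::mat M(A * ncat, npat);
    if (chd < ntip) {
      for (int k = 0; k < ncat; ++k) {
        const arma::mat& Pk = P.slice(e * ncat + k);
        for (int j = 0; j < npat; ++j) {
          const int s = tips(chd, j);
          if (s < 0)
            M.submat(k * A, j, k * A + A - 1, j).ones();
          else
            M.submat(k * A, j, k * A + A - 1, j) = Pk.col(s);
        }
      }
    } else {
      // internal child: rescale its completed partial, then propagate
      arma::mat& L = part[chd];
      arma::rowvec mx = arma::max(L, 0);
      for (int j = 0; j < npat; ++j) {
        if (mx(j) > 0 && mx(j) != 1.0) {
          L.col(j) /= mx(j);
          logscale(j) += std::log(mx(j));
        } else if (mx(j) <= 0) {
          // impossible pattern; leave zeros, log handled at root
        }
      }
      for (int k = 0; k < ncat; ++k)
        M.rows(k * A, k * A + A - 1) =
          P.slice(e * ncat + k) * L.rows(k * A, k * A + A - 1);
      part[chd].reset();
    }
    if (part[par].n_elem == 0)
      part[par] = M;
    else
      part[par] %= M;
  }

  const int root = edges(nedge - 1, 0);
  arma::mat& L = part[root];
  arma::vec out(npat);
  for (int j = 0; j < npat; ++j) {
    double lik = 0.0;
    for (int k = 0; k < ncat; ++k)
      lik += wk(k) * arma::dot(pi, L.submat(k * A, j, k * A + A - 1, j));
    out(j) = (lik > 0) ? std::log(lik) + logscale(j) : -arma::datum::inf;
  }
  return out;
}
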