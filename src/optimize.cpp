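#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Per-branch likelihood smoothing with two-sided partials.
//
// The tree is given as a postorder edge list (parent, child), 0-based,
// tips 0..ntip-1, virtual root = edges(nedge-1, 0). The reversible model
// enters through its symmetric eigensystem: P_k(t) = L * diag(exp(lambda *
// t * r_k)) * R, stationary frequencies pi, gamma category rates r_k with
// weights wk. Site patterns are integer states (-1 missing) with weights.
//
// One sweep visits every edge in postorder. For the edge (p, c) the
// one-dimensional likelihood f(t) = sum_j w_j log sum_k wk_k
// G_k(.,j)' P_k(t) D_k(.,j) is maximized by Brent search, where D is the
// conditional likelihood of the data below c and G the flow arriving at p
// from the rest of the tree (computed fresh along the root-to-p path, so
// every per-edge optimization is exact for the current tree). After each
// accepted update the downward partials along c's root path are refreshed.
// The returned log-likelihood never falls below the starting one.

struct Workspace {
  int A, ncat, npat, nnodes, ntip, nedge;
  arma::imat edges;
  std::vector<arma::cube> D;      // down partials per node (A x npat x ncat)
  std::vector<arma::vec> dscale;  // per-node accumulated log scale (npat)
  std::vector<int> parent_edge;   // edge index above each node (-1 for root)
  std::vector<std::vector<int>> child_edges;
};

static arma::mat pmat(const arma::mat& L, const arma::mat& R,
                      const arma::vec& lambda, double t) {
  arma::mat P = L * arma::diagmat(arma::exp(lambda * t)) * R;
  P.elem(arma::find(P < 0)).zeros();
  return P;
}

// message matrix of edge e at its current length: M(a, j) = sum_b
// P_k(a,b) D_k(b, j), stacked A*ncat x npat, using child partials
static void edge_message(const Workspace& W, int e, const arma::vec& t,
                         const arma::mat& L, const arma::mat& R,
                         const arma::vec& lambda, const arma::vec& rates,
                         const arma::imat& tips, arma::mat& M,
                         arma::vec& mscale) {
  const int c = W.edges(e, 1);
  M.set_size(W.A * W.ncat, W.npat);
  if (c < W.ntip) {
    for (int k = 0; k < W.ncat; ++k) {
      arma::mat P = pmat(L, R, lambda, t(e) * rates(k));
      for (int j = 0; j < W.npat; ++j) {
        int s = tips(c, j);
        if (s < 0) M.submat(k * W.A, j, k * W.A + W.A - 1, j).ones();
        else M.submat(k * W.A, j, k * W.A + W.A - 1, j) = P.col(s);
      }
    }
    mscale.zeros(W.npat);
  } else {
    for (int k = 0; k < W.ncat; ++k) {
      arma::mat P = pmat(L, R, lambda, t(e) * rates(k));
      M.rows(k * W.A, k * W.A + W.A - 1) = P * W.D[c].slice(k);
    }
    mscale = W.dscale[c];
  }
}

// refresh the down partial of internal node p from its children
static void refresh_node(Workspace& W, int p, const arma::vec& t,
                         const arma::mat& L, const arma::mat& R,
                         const arma::vec& lambda, const arma::vec& rates,
                         const arma::imat& tips) {
  arma::mat acc(W.A * W.ncat, W.npat, arma::fill::ones);
  arma::vec sc(W.npat, arma::fill::zeros);
  arma::mat M; arma::vec ms;
  for (int e : W.child_edges[p]) {
    edge_message(W, e, t, L, R, lambda, rates, tips, M, ms);
    acc %= M;
    sc += ms;
  }
  // rescale
  arma::rowvec mx = arma::max(acc, 0);
  for (int j = 0; j < W.npat; ++j) {
    if (mx(j) > 0 && mx(j) != 1.0) { acc.col(j) /= mx(j); sc(j) += std::log(mx(j)); }
  }
  W.D[p].set_size(W.A, W.npat, W.ncat);
  for (int k = 0; k < W.ncat; ++k)
    W.D[p].slice(k) = acc.rows(k * W.A, k * W.A + W.A - 1);
  W.dscale[p] = sc;
}

static double root_loglik(const Workspace& W, const arma::vec& pi,
                          const arma::vec& wk, const arma::vec& wpat) {
  const int root = W.edges(W.nedge - 1, 0);
  double tot = 0;
  for (int j = 0; j < W.npat; ++j) {
    double lik = 0;
    for (int k = 0; k < W.ncat; ++k)
      lik += wk(k) * arma::dot(pi, W.D[root].slice(k).col(j));
    tot += wpat(j) * ((lik > 0 ? std::log(lik) : -arma::datum::inf) +
                      W.dscale[root](j));
  }
  return tot;
}

// f(t) for one edge given G (A*ncat x npat) and the child's D
static double edge_loglik(const Workspace& W, int e, double tval,
                          const arma::mat& G, const arma::vec& gscale,
                          const arma::mat& L, const arma::mat& R,
                          const arma::vec& lambda, const arma::vec& rates,
                          const arma::vec& wk, const arma::vec& wpat,
                          const arma::imat& tips) {
  const int c = W.edges(e, 1);
  double tot = 0;
  arma::mat lik(1, W.npat, arma::fill::zeros);
  arma::vec extra(W.npat, arma::fill::zeros);
  for (int k = 0; k < W.ncat; ++k) {
    arma::mat P = pmat(L, R, lambda, tval * rates(k));
    if (c < W.ntip) {
      for (int j = 0; j < W.npat; ++j) {
        int s = tips(c, j);
        arma::vec pd = (s < 0) ? arma::sum(P, 1) : arma::vec(P.col(s));
        lik(0, j) += wk(k) *
          arma::dot(G.submat(k * W.A, j, k * W.A + W.A - 1, j), pd);
      }
    } else {
      arma::mat PD = P * W.D[c].slice(k);   // A x npat
      lik.row(0) += wk(k) *
        arma::sum(G.rows(k * W.A, k * W.A + W.A - 1) % PD, 0);
      extra = W.dscale[c];
    }
  }
  for (int j = 0; j < W.npat; ++j) {
    double l = lik(0, j);
    tot += wpat(j) * ((l > 0 ? std::log(l) : -arma::datum::inf) +
                      gscale(j) + extra(j));
  }
  return tot;
}

// textbook Brent maximization on [a, b]
template <typename F>
static double brent_max(F f, double a, double b, double tol, double* fmax) {
  const double gold = 0.3819660112501051;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0, e = 0;
  for (int iter = 0; iter < 100; ++iter) {
    double m = 0.5 * (a + b);
    double tol1 = tol * std::abs(x) + 1e-10, tol2 = 2 * tol1;
    if (std::abs(x - m) <= tol2 - 0.5 * (b - a)) break;
    double p = 0, q = 0, r = 0;
    bool parab = false;
    if (std::abs(e) > tol1) {
      r = (x - w) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - w) * r;
      q = 2 * (q - r);
      if (q > 0) p = -p; else q = -q;
      if (std::abs(p) < std::abs(0.5 * q * e) && p > q * (a - x) &&
          p < q * (b - x)) {
        e = d; d = p / q; parab = true;
      }
    }
    if (!parab) {
      e = (x < m) ? b - x : a - x;
      d = gold * e;
    }
    double u = (std::abs(d) >= tol1) ? x + d : x + (d > 0 ? tol1 : -tol1);
    double fu = f(u);
    if (fu >= fx) {
      if (u < x) b = x; else a = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu >= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu >= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  *fmax = fx;
  return x;
}

// [[Rcpp::export]]
List optimize_branches_cpp(const arma::imat& edges, arma::vec t,
                           const arma::mat& L, const arma::mat& R,
                           const arma::vec& lambda, const arma::vec& pi,
                           const arma::imat& tips, const arma::vec& wpat,
                           const arma::vec& rates, const arma::vec& wk,
                           double tol, int max_sweeps, double bl_min,
                           double bl_max) {
  Workspace W;
  W.edges = edges;
  W.A = pi.n_elem; W.ncat = wk.n_elem; W.npat = tips.n_cols;
  W.ntip = tips.n_rows; W.nedge = edges.n_rows;
  W.nnodes = edges.max() + 1;
  W.D.resize(W.nnodes); W.dscale.assign(W.nnodes, arma::vec());
  W.parent_edge.assign(W.nnodes, -1);
  W.child_edges.assign(W.nnodes, {});
  for (int e = 0; e < W.nedge; ++e) {
    W.parent_edge[edges(e, 1)] = e;
    W.child_edges[edges(e, 0)].push_back(e);
  }
  const int root = edges(W.nedge - 1, 0);
  // initial down partials: refresh each internal node once all of its
  // child subtrees are complete (postorder guarantees feasibility)
  {
    std::vector<size_t> seen(W.nnodes, 0);
    for (int e = 0; e < W.nedge; ++e) {
      int p = edges(e, 0);
      if (++seen[p] == W.child_edges[p].size())
        refresh_node(W, p, t, L, R, lambda, rates, tips);
    }
  }
  double cur = root_loglik(W, pi, wk, wpat);
  const double start_lnl = cur;
  arma::vec t_best = t;

  arma::mat M; arma::vec ms;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double prev = cur;
    for (int e = 0; e < W.nedge; ++e) {
      int p = edges(e, 0), c = edges(e, 1);
      // G at p excluding edge e: product of sibling messages and the
      // flow from above, computed fresh along the root-to-p path
      arma::mat G(W.A * W.ncat, W.npat);
      arma::vec gscale(W.npat, arma::fill::zeros);
      // upward flow U at p
      std::vector<int> path;          // edges from p up to root
      for (int n = p; W.parent_edge[n] >= 0; n = edges(W.parent_edge[n], 0))
        path.push_back(W.parent_edge[n]);
      // U[root] = pi per category
      arma::mat U(W.A * W.ncat, W.npat);
      for (int k = 0; k < W.ncat; ++k)
        U.rows(k * W.A, k * W.A + W.A - 1).each_col() = pi;
      arma::vec uscale(W.npat, arma::fill::zeros);
      for (auto it = path.rbegin(); it != path.rend(); ++it) {
        int pe = *it;
        int q = edges(pe, 0), rnode = edges(pe, 1);
        // G_q->rnode = U ⊙ prod of q's other children messages
        arma::mat Gq = U;
        arma::vec gs = uscale;
        for (int se : W.child_edges[q]) {
          if (se == pe) continue;
          edge_message(W, se, t, L, R, lambda, rates, tips, M, ms);
          Gq %= M; gs += ms;
        }
        // push through edge pe: U_r(b) = sum_a Gq(a) P(a,b)
        for (int k = 0; k < W.ncat; ++k) {
          arma::mat P = pmat(L, R, lambda, t(pe) * rates(k));
          U.rows(k * W.A, k * W.A + W.A - 1) =
            P.t() * Gq.rows(k * W.A, k * W.A + W.A - 1);
        }
        uscale = gs;
        arma::rowvec mx = arma::max(U, 0);
        for (int j = 0; j < W.npat; ++j)
          if (mx(j) > 0 && mx(j) != 1.0) { U.col(j) /= mx(j); uscale(j) += std::log(mx(j)); }
        (void)rnode;
      }
      // G = U at p times sibling messages at p
      G = U; gscale = uscale;
      for (int se : W.child_edges[p]) {
        if (se == e) continue;
        edge_message(W, se, t, L, R, lambda, rates, tips, M, ms);
        G %= M; gscale += ms;
      }
      auto f = [&](double tv) {
        return edge_loglik(W, e, tv, G, gscale, L, R, lambda, rates, wk,
                           wpat, tips);
      };
      double f_old = f(t(e));
      double f_new;
      double t_new = brent_max(f, bl_min, bl_max, tol, &f_new);
      double f_floor = f(bl_min);
      if (f_floor >= f_new - 1e-9) { t_new = bl_min; f_new = f_floor; }
      if (f_new >= f_old) {
        cur += f_new - f_old;
        t(e) = t_new;
        // refresh down partials along c's root path (p up to root)
        for (int n = p; ; n = edges(W.parent_edge[n], 0)) {
          refresh_node(W, n, t, L, R, lambda, rates, tips);
          if (W.parent_edge[n] < 0) break;
        }
      }
      if ((e & 15) == 0) Rcpp::checkUserInterrupt();
    }
    cur = root_loglik(W, pi, wk, wpat);   // resync against drift
    if (cur - prev < tol) break;
  }
  if (cur < start_lnl) { t = t_best; cur = start_lnl; }
  return List::create(_["t"] = t, _["lnL"] = cur);
}
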