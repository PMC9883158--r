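// Felsenstein pruning likelihood for a 4-state CTMC and the
// Metropolis sampler / stepping-stone chains built on it. Hot paths live
// here; all user-facing surfaces are R wrappers.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Transition matrices for all edges, flattened column-major into a
// (ns*ns) x E matrix: one eigendecomposition of Q and one complex GEMM
// cover every branch; scaling-and-squaring fallback for ill-conditioned
// eigenbases (defective constrained generators).
static bool edge_pmats(const arma::mat& Q, const arma::vec& elen,
                       arma::mat& out) {
  const arma::uword ns = Q.n_rows;
  const arma::uword E = elen.n_elem;
  arma::cx_vec lam;
  arma::cx_mat U;
  bool ok = arma::eig_gen(lam, U, Q);
  arma::cx_mat Ui;
  if (ok) ok = arma::inv(Ui, U);
  if (ok) {
    arma::vec sv = arma::svd(U);
    ok = sv.min() / sv.max() > 1e-8;
  }
  if (ok) {
    // coef(a + ns*b, k) = U(a,k) * Ui(k,b); exps(k, e) = exp(lam_k t_e)
    arma::cx_mat coef(ns * ns, ns);
    for (arma::uword b = 0; b < ns; ++b)
      for (arma::uword a = 0; a < ns; ++a)
        for (arma::uword k = 0; k < ns; ++k)
          coef(a + ns * b, k) = U(a, k) * Ui(k, b);
    arma::cx_mat expx(ns, E);
    for (arma::uword k = 0; k < ns; ++k) {
      if (std::abs(lam(k).imag()) < 1e-14) {
        const double lr = lam(k).real();
        for (arma::uword e = 0; e < E; ++e)
          expx(k, e) = std::exp(lr * elen(e));   // real eigenvalue fast path
      } else {
        for (arma::uword e = 0; e < E; ++e)
          expx(k, e) = std::exp(lam(k) * elen(e));
      }
    }
    out = arma::real(coef * expx);
    out.clamp(0.0, 1.0);
  } else {
    out.set_size(ns * ns, E);
    for (arma::uword e = 0; e < E; ++e) {
      arma::mat P = arma::expmat(Q * elen(e));
      P.clamp(0.0, 1.0);
      out.col(e) = arma::vectorise(P);
    }
  }
  return true;
}

// edge: E x 2 (1-based node ids, postorder); states: 0..ns-1 or -1 = missing
static double prune_ll(const arma::imat& edge, const arma::vec& elen,
                       int ntip, const arma::ivec& states, const arma::mat& Q,
                       const arma::vec& rootf) {
  const int ns = Q.n_rows;
  const int E = (int)edge.n_rows;
  const int nnode = ntip + E + 1;           // upper bound on node count
  std::vector<double> pl((size_t)nnode * ns, 1.0);
  for (int i = 0; i < ntip; ++i) {
    if (states(i) >= 0) {
      for (int s = 0; s < ns; ++s) pl[(size_t)i * ns + s] = 0.0;
      pl[(size_t)i * ns + states(i)] = 1.0;
    }
  }
  arma::mat Pall;
  edge_pmats(Q, elen, Pall);
  const double* Pd = Pall.memptr();
  double logscale = 0.0;
  for (int e = 0; e < E; ++e) {
    const int par = edge(e, 0) - 1;
    const int chd = edge(e, 1) - 1;
    const double* P = Pd + (size_t)e * ns * ns;  // column-major: P[a + ns*b]
    const double* pc = &pl[(size_t)chd * ns];
    double* pp = &pl[(size_t)par * ns];
    double mx = 0.0;
    for (int a = 0; a < ns; ++a) {
      double v = 0.0;
      for (int b = 0; b < ns; ++b) v += P[a + ns * b] * pc[b];
      pp[a] *= v;
      if (pp[a] > mx) mx = pp[a];
    }
    if (mx <= 0.0) return -std::numeric_limits<double>::infinity();
    if (mx < 1e-100) {
      for (int a = 0; a < ns; ++a) pp[a] /= mx;
      logscale += std::log(mx);
    }
  }
  const int root = edge(E - 1, 0) - 1;
  double lik = 0.0;
  for (int s = 0; s < ns; ++s) lik += rootf(s) * pl[(size_t)root * ns + s];
  if (lik <= 0.0) return -std::numeric_limits<double>::infinity();
  return std::log(lik) + logscale;
}

// [[Rcpp::export]]
double cpp_pruning_loglik(IntegerMatrix edge, NumericVector elen, int ntip,
                          IntegerVector states, NumericMatrix Q,
                          NumericVector root_freq) {
  arma::imat E(edge.nrow(), 2);
  for (int i = 0; i < edge.nrow(); ++i) { E(i,0)=edge(i,0); E(i,1)=edge(i,1); }
  arma::vec el(elen.begin(), elen.size());
  arma::ivec st(states.size());
  for (int i = 0; i < states.size(); ++i) st(i) = states(i);
  arma::mat q(Q.begin(), Q.nrow(), Q.ncol());
  arma::vec rf(root_freq.begin(), root_freq.size());
  return prune_ll(E, el, ntip, st, q, rf);
}

struct TreeData {
  arma::imat edge;
  arma::vec elen;
  int ntip;
  arma::ivec states;
};

static void unpack_trees(List trees, std::vector<TreeData>& td) {
  td.resize(trees.size());
  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerMatrix edge = tr["edge"];
    NumericVector elen = tr["elen"];
    IntegerVector states = tr["states"];
    int ntip = as<int>(tr["ntip"]);
    TreeData& d = td[t];
    d.edge.set_size(edge.nrow(), 2);
    for (int i = 0; i < edge.nrow(); ++i) {
      d.edge(i, 0) = edge(i, 0); d.edge(i, 1) = edge(i, 1);
    }
    d.elen = arma::vec(elen.begin(), elen.size());
    d.ntip = ntip;
    d.states.set_size(states.size());
    for (int i = 0; i < states.size(); ++i) d.states(i) = states(i);
  }
}

static arma::mat build_Q(const arma::imat& free_idx, const arma::vec& rates,
                         int ns) {
  arma::mat Q(ns, ns, arma::fill::zeros);
  for (arma::uword j = 0; j < free_idx.n_rows; ++j) {
    Q(free_idx(j, 0), free_idx(j, 1)) = rates(j);
  }
  Q.diag() = -arma::sum(Q, 1);
  return Q;
}

// Metropolis-within-Gibbs chain over free transition rates with an
// exponential prior of mean m (m ~ Uniform(0, 10)), likelihood tempered by
// beta (beta = 1 for posterior sampling, beta in [0,1] for power
// posteriors). The tree index is a sampled nuisance variable with a uniform
// prior, updated by a uniform-proposal MH move. Uses R's RNG.
// [[Rcpp::export]]
List cpp_ms_chain(List trees, IntegerMatrix free_idx, NumericVector init_rates,
                  double init_m, NumericVector root_freq, double beta,
                  int n_iter, int burn, int thin, double s_joint,
                  double s_single, double m_upper, int ns) {
  RNGScope scope;
  std::vector<TreeData> td;
  unpack_trees(trees, td);
  const int ntree = (int)td.size();
  const int k = free_idx.nrow();
  arma::imat fidx(k, 2);
  for (int j = 0; j < k; ++j) { fidx(j,0)=free_idx(j,0); fidx(j,1)=free_idx(j,1); }
  arma::vec rf(root_freq.begin(), root_freq.size());
  arma::vec lrates = arma::log(arma::vec(init_rates.begin(), k));
  double m = init_m;
  int tree_i = 0;

  auto loglik = [&](const arma::vec& lr, int ti) {
    arma::mat Q = build_Q(fidx, arma::exp(lr), ns);
    return prune_ll(td[ti].edge, td[ti].elen, td[ti].ntip, td[ti].states, Q, rf);
  };
  // log prior of rates given m, on the log-rate scale (includes Jacobian)
  auto logprior = [&](const arma::vec& lr, double mm) {
    double lp = 0.0;
    for (int j = 0; j < k; ++j) {
      lp += -std::log(mm) - std::exp(lr(j)) / mm + lr(j);
    }
    return lp;
  };

  double ll = loglik(lrates, tree_i);
  double lp = logprior(lrates, m);
  int nkeep = (n_iter - burn + thin - 1) / thin;
  arma::mat draws(nkeep, k);
  arma::vec m_draws(nkeep), ll_draws(nkeep);
  arma::ivec tree_draws(nkeep);
  int kept = 0;
  long acc = 0, tries = 0;

  for (int it = 0; it < n_iter; ++it) {
    // rate update: joint or single-site on log scale
    double u = unif_rand();
    arma::vec prop = lrates;
    if (u < 0.5) {
      for (int j = 0; j < k; ++j) prop(j) += norm_rand() * s_joint;
    } else {
      int j = (int)std::floor(unif_rand() * k);
      if (j >= k) j = k - 1;
      prop(j) += norm_rand() * s_single;
    }
    double llp = loglik(prop, tree_i);
    double lpp = logprior(prop, m);
    ++tries;
    if (std::isfinite(llp) &&
        std::log(unif_rand()) < beta * (llp - ll) + (lpp - lp)) {
      lrates = prop; ll = llp; lp = lpp; ++acc;
    }
    // hyperprior mean m: RW-MH, prior-only move
    double mp = m + norm_rand() * 0.5;
    if (mp > 1e-6 && mp < m_upper) {
      double lpm = logprior(lrates, mp);
      if (std::log(unif_rand()) < lpm - lp) { m = mp; lp = lpm; }
    }
    // tree move
    if (ntree > 1) {
      int tp = (int)std::floor(unif_rand() * ntree);
      if (tp >= ntree) tp = ntree - 1;
      if (tp != tree_i) {
        double llt = loglik(lrates, tp);
        if (std::isfinite(llt) && std::log(unif_rand()) < beta * (llt - ll)) {
          tree_i = tp; ll = llt;
        }
      }
    }
    if (it >= burn && (it - burn) % thin == 0 && kept < nkeep) {
      draws.row(kept) = arma::exp(lrates).t();
      m_draws(kept) = m;
      ll_draws(kept) = ll;
      tree_draws(kept) = tree_i + 1;
      ++kept;
    }
  }
  return List::create(_["rates"] = draws.rows(0, kept - 1),
                      _["m"] = NumericVector(m_draws.begin(), m_draws.begin() + kept),
                      _["loglik"] = NumericVector(ll_draws.begin(), ll_draws.begin() + kept),
                      _["tree"] = IntegerVector(tree_draws.begin(), tree_draws.begin() + kept),
                      _["accept"] = (double)acc / (double)tries);
}
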