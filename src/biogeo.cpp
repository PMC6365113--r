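// Core numerics for the three-area range-evolution models:
// matrix-exponential transition probabilities, Felsenstein pruning with
// cladogenetic weight tables at internal nodes, and endpoint-conditioned
// CTMC path sampling by uniformization (used for stochastic mapping).
//
// State convention (1-based from R): 1..6 = H, N, E, HN, HE, NE; 7 = null
// (empty) range, absorbing under the anagenetic process and carrying zero
// likelihood at tips and nodes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int NS = 7;   // states incl. null
static const int NR = 6;   // non-null range states

// [[Rcpp::export]]
arma::mat ctmc_transition(const arma::mat& Q, double t) {
  return arma::expmat(Q * t);
}

// Pruning over a binary rooted tree in ape postorder edge order.
// edge: (nedge x 2) 1-based ape edge matrix, postorder; tip_states 1..6.
// clado: list of 6 matrices, each (m x 3) = (left, right, prob), 1-based.
// Returns loglik plus (optionally) the per-node conditional likelihoods,
// the per-edge top-of-branch vectors and transition matrices needed for
// backward-forward stochastic mapping.
// condition_survival: renormalize each transition row by the probability of
// the range not dying on the branch (1 - P(null)); the matched estimator for
// data generated with per-branch resimulation of extinct ranges.
// [[Rcpp::export]]
List biogeo_pruning(const IntegerMatrix& edge, const NumericVector& edge_length,
                    int n_tips, const IntegerVector& tip_states,
                    const arma::mat& Q, const List& clado,
                    const arma::vec& root_prior, bool keep_tables = false,
                    bool condition_survival = false) {
  const int nedge = edge.nrow();
  const int nnode = n_tips + nedge / 2 + 1;  // tips + internals (binary)

  arma::mat cl(nnode, NS, arma::fill::zeros);
  arma::vec logscale(nnode, arma::fill::zeros);
  for (int i = 0; i < n_tips; ++i) {
    int s = tip_states[i];
    if (s < 1 || s > NR) stop("tip state out of range for tip %d", i + 1);
    cl(i, s - 1) = 1.0;
  }

  // parse clado tables once
  std::vector<arma::mat> ctab(NR);
  for (int i = 0; i < NR; ++i) ctab[i] = as<arma::mat>(clado[i]);

  arma::cube P;
  arma::mat up(nedge, NS, arma::fill::zeros);
  if (keep_tables) P.set_size(NS, NS, nedge);

  // per-parent bookkeeping: indices of the (up to 2) incoming child edges
  std::vector<int> first_edge(nnode, -1);

  for (int e = 0; e < nedge; ++e) {
    int parent = edge(e, 0) - 1;
    int child  = edge(e, 1) - 1;
    arma::mat Pe = arma::expmat(Q * edge_length[e]);
    if (condition_survival)
      for (int i = 0; i < NR; ++i) {
        double surv = 1.0 - Pe(i, NS - 1);
        if (surv > 0) Pe.row(i) /= surv;
      }
    if (keep_tables) P.slice(e) = Pe;
    arma::rowvec ue = cl.row(child) * Pe.t();  // ue[i] = sum_j Pe(i,j) cl(child,j)
    up.row(e) = ue;
    if (first_edge[parent] < 0) {
      first_edge[parent] = e;
    } else {
      int e1 = first_edge[parent];
      const arma::rowvec uL = up.row(e1);
      const arma::rowvec uR = up.row(e);
      arma::rowvec v(NS, arma::fill::zeros);
      for (int i = 0; i < NR; ++i) {
        const arma::mat& tab = ctab[i];
        double acc = 0.0;
        for (arma::uword k = 0; k < tab.n_rows; ++k) {
          int l = (int)tab(k, 0) - 1, r = (int)tab(k, 1) - 1;
          acc += tab(k, 2) * uL[l] * uR[r];
        }
        v[i] = acc;
      }
      double m = v.max();
      if (m <= 0.0)
        stop("likelihood underflow to exactly zero at node %d (impossible data under model)",
             parent + 1);
      v /= m;
      cl.row(parent) = v;
      logscale[parent] = std::log(m) +
        logscale[edge(e1, 1) - 1] + logscale[child];
    }
  }

  int root = n_tips;  // ape root = n_tips + 1 (1-based)
  double lik = 0.0;
  for (int i = 0; i < NR; ++i) lik += root_prior[i] * cl(root, i);
  if (lik <= 0.0) stop("likelihood is exactly zero at the root");
  double loglik = std::log(lik) + logscale[root];

  if (!keep_tables) return List::create(_["loglik"] = loglik);
  return List::create(_["loglik"] = loglik, _["cl"] = cl, _["up"] = up,
                      _["P"] = P, _["logscale"] = logscale);
}

// Endpoint-conditioned CTMC path on [0, t] from state a to state b (1-based),
// sampled by uniformization.  Uses R's RNG so set.seed() governs.
// Returns a matrix with columns (time, state) of the *real* jumps
// (virtual self-transitions removed); zero rows if no state change.
// [[Rcpp::export]]
NumericMatrix sample_ctmc_path(const arma::mat& Q, int a, int b, double t,
                               int max_jumps = 10000) {
  a -= 1; b -= 1;
  double Omega = arma::abs(Q.diag()).max();
  if (Omega * t <= 0.0) {
    if (a != b) stop("endpoints differ on a branch with no allowed events");
    return NumericMatrix(0, 2);
  }
  arma::mat R = arma::eye(NS, NS) + Q / Omega;
  arma::mat Pt = arma::expmat(Q * t);
  double pab = Pt(a, b);
  if (pab <= 0.0) stop("endpoint pair has zero transition probability");

  // sample number of uniformized jumps N:  p(n) ~ Pois(n; Omega t) (R^n)_ab
  std::vector<arma::mat> Rpow;
  Rpow.push_back(arma::eye(NS, NS));  // R^0
  double u = unif_rand() * pab;
  double lt = Omega * t;
  double pois = std::exp(-lt);  // Pois(0)
  double cum = pois * Rpow[0](a, b);
  int N = 0;
  while (cum < u) {
    ++N;
    if (N > max_jumps) stop("uniformization truncated at %d jumps", max_jumps);
    pois *= lt / N;
    Rpow.push_back(Rpow[N - 1] * R);
    cum += pois * Rpow[N](a, b);
  }
  if (N == 0) return NumericMatrix(0, 2);

  // jump times: N sorted uniforms on (0, t)
  arma::vec times(N);
  for (int k = 0; k < N; ++k) times[k] = unif_rand() * t;
  times = arma::sort(times);

  // states: s_0 = a, s_N = b; sequential conditional sampling
  std::vector<int> s(N + 1);
  s[0] = a; s[N] = b;
  for (int k = 1; k < N; ++k) {
    arma::vec w(NS);
    for (int c = 0; c < NS; ++c) w[c] = R(s[k - 1], c) * Rpow[N - k](c, b);
    double tot = arma::accu(w);
    if (tot <= 0.0) stop("degenerate conditional path distribution");
    double v = unif_rand() * tot, acc = 0.0;
    int pick = NS - 1;
    for (int c = 0; c < NS; ++c) { acc += w[c]; if (v <= acc) { pick = c; break; } }
    s[k] = pick;
  }

  // drop virtual jumps
  std::vector<double> jt; std::vector<int> js;
  for (int k = 1; k <= N; ++k)
    if (s[k] != s[k - 1]) { jt.push_back(times[k - 1]); js.push_back(s[k] + 1); }
  NumericMatrix out(jt.size(), 2);
  for (size_t k = 0; k < jt.size(); ++k) { out(k, 0) = jt[k]; out(k, 1) = js[k]; }
  colnames(out) = CharacterVector::create("time", "state");
  return out;
}
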