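// Core dynamic programs on local genealogies:
//  - nucleotide transition matrices (JC69, K80) in closed form
//  - joint (max-product) ancestral state reconstruction in log space
//  - fixed-root small parsimony (Hartigan/Sankoff, unit costs)
//  - a batched per-site driver used by the polarisation pipeline
//
// Node convention: 0-based ids, parent[v] == -1 marks the root, leaves are
// the nodes that never appear as a parent. States are 0..3 = A,C,G,T.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double NEG_INF = -1e100;
static const int INT_INF = 10000000;

static inline double sat_add(double a, double b) {
  double s = a + b;
  return (s < NEG_INF) ? NEG_INF : s;
}

// P[4*from + to] after elapsed time dt; model 0 = JC69, 1 = K80.
// Both are parameterised so the total substitution rate per site is mu;
// transitions are the pairs A<->G and C<->T (i ^ j == 2).
static void trans_matrix(int model, double mu, double kappa, double dt,
                         double* P) {
  if (model == 0) {
    double e = std::exp(-4.0 * mu * dt / 3.0);
    double same = 0.25 + 0.75 * e;
    double diff = 0.25 - 0.25 * e;
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j)
        P[4 * i + j] = (i == j) ? same : diff;
  } else {
    double beta = mu / (kappa + 2.0);
    double A = std::exp(-4.0 * beta * dt);
    double B = std::exp(-2.0 * beta * (kappa + 1.0) * dt);
    double same = 0.25 + 0.25 * A + 0.5 * B;
    double ts = 0.25 + 0.25 * A - 0.5 * B;
    double tv = 0.25 - 0.25 * A;
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j)
        P[4 * i + j] = (i == j) ? same : (((i ^ j) == 2) ? ts : tv);
  }
}

// [[Rcpp::export]]
NumericMatrix transition_matrix_cpp(int model, double mu, double kappa,
                                    double dt) {
  double P[16];
  trans_matrix(model, mu, kappa, dt, P);
  NumericMatrix out(4, 4);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = P[4 * i + j];
  return out;
}

struct TreeIdx {
  int nn;
  int root;
  std::vector<int> parent;
  std::vector<std::vector<int> > children;
  std::vector<int> post;  // children strictly before parents
};

static TreeIdx build_tree(const IntegerVector& parent) {
  TreeIdx T;
  T.nn = parent.size();
  T.parent.assign(parent.begin(), parent.end());
  T.children.assign(T.nn, std::vector<int>());
  T.root = -1;
  for (int v = 0; v < T.nn; ++v) {
    int p = T.parent[v];
    if (p < 0) {
      if (T.root >= 0) stop("tree has more than one root");
      T.root = v;
    } else {
      if (p >= T.nn) stop("parent id out of range");
      T.children[p].push_back(v);
    }
  }
  if (T.root < 0) stop("tree has no root");
  // iterative DFS; reversed preorder gives a valid postorder
  std::vector<int> stack, pre;
  stack.push_back(T.root);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    pre.push_back(v);
    for (size_t i = 0; i < T.children[v].size(); ++i)
      stack.push_back(T.children[v][i]);
  }
  if ((int)pre.size() != T.nn) stop("tree contains a cycle or orphan nodes");
  T.post.assign(pre.rbegin(), pre.rend());
  return T;
}

// Per-edge log transition matrices, indexed by child node.
static void edge_logP(const TreeIdx& T, const NumericVector& time, int model,
                      double mu, double kappa, std::vector<double>& lp) {
  lp.assign(16 * T.nn, 0.0);
  double P[16];
  for (int v = 0; v < T.nn; ++v) {
    if (T.parent[v] < 0) continue;
    double dt = time[T.parent[v]] - time[v];
    if (dt < 0) stop("negative branch length at node %d", v + 1);
    trans_matrix(model, mu, kappa, dt, P);
    for (int k = 0; k < 16; ++k)
      lp[16 * v + k] = (P[k] > 0.0) ? std::log(P[k]) : NEG_INF;
  }
}

// Max-product DP. L[4*v+s] = best joint log probability of the subtree below
// v given v carries state s.
static void joint_dp(const TreeIdx& T, const std::vector<double>& lp,
                     const IntegerVector& leaf_state,
                     std::vector<double>& L) {
  L.assign(4 * T.nn, 0.0);
  for (size_t i = 0; i < T.post.size(); ++i) {
    int v = T.post[i];
    if (T.children[v].empty()) {
      int st = leaf_state[v];
      if (st < 0 || st > 3) stop("leaf node %d has no valid state", v + 1);
      for (int s = 0; s < 4; ++s) L[4 * v + s] = (s == st) ? 0.0 : NEG_INF;
    } else {
      for (int s = 0; s < 4; ++s) {
        double acc = 0.0;
        for (size_t k = 0; k < T.children[v].size(); ++k) {
          int c = T.children[v][k];
          double best = NEG_INF;
          for (int sc = 0; sc < 4; ++sc) {
            double val = sat_add(lp[16 * c + 4 * s + sc], L[4 * c + sc]);
            if (val > best) best = val;
          }
          acc = sat_add(acc, best);
        }
        L[4 * v + s] = acc;
      }
    }
  }
}

// choice[4*v+sp]: best state of v when its parent carries sp (ties ->
// smallest state); used only for the backtrace of the joint assignment
static void joint_choice(const TreeIdx& T, const std::vector<double>& lp,
                         const std::vector<double>& L,
                         std::vector<int>& choice) {
  choice.assign(4 * T.nn, 0);
  for (int v = 0; v < T.nn; ++v) {
    if (T.parent[v] < 0) continue;
    for (int sp = 0; sp < 4; ++sp) {
      double best = NEG_INF;
      int arg = 0;
      for (int s = 0; s < 4; ++s) {
        double val = sat_add(lp[16 * v + 4 * sp + s], L[4 * v + s]);
        if (val > best) {
          best = val;
          arg = s;
        }
      }
      choice[4 * v + sp] = arg;
    }
  }
}

static double log_sum_exp(const double* x, int k) {
  double m = NEG_INF;
  for (int i = 0; i < k; ++i)
    if (x[i] > m) m = x[i];
  if (m <= NEG_INF) return NEG_INF;
  double s = 0.0;
  for (int i = 0; i < k; ++i) s += std::exp(x[i] - m);
  return m + std::log(s);
}

// [[Rcpp::export]]
List reconstruct_cpp(IntegerVector parent, NumericVector time,
                     IntegerVector leaf_state, int model, double mu,
                     double kappa, NumericVector prior) {
  TreeIdx T = build_tree(parent);
  std::vector<double> lp;
  edge_logP(T, time, model, mu, kappa, lp);
  std::vector<double> L;
  std::vector<int> choice;
  joint_dp(T, lp, leaf_state, L);
  joint_choice(T, lp, L, choice);

  double score[4];
  for (int s = 0; s < 4; ++s) {
    double pr = prior[s];
    score[s] = sat_add((pr > 0.0) ? std::log(pr) : NEG_INF, L[4 * T.root + s]);
  }
  double lse = log_sum_exp(score, 4);
  if (lse <= NEG_INF) stop("all root states have zero probability");
  NumericVector post(4), sc(4), loglik(4);
  for (int s = 0; s < 4; ++s) {
    post[s] = std::exp(score[s] - lse);
    sc[s] = score[s];
    loglik[s] = L[4 * T.root + s];
  }
  // best joint assignment per candidate root state (preorder walk)
  IntegerMatrix assign(4, T.nn);
  std::vector<int> pre(T.post.rbegin(), T.post.rend());
  for (int r = 0; r < 4; ++r) {
    std::vector<int> st(T.nn, -1);
    st[T.root] = r;
    for (size_t i = 0; i < pre.size(); ++i) {
      int v = pre[i];
      if (v == T.root) continue;
      st[v] = T.children[v].empty() ? leaf_state[v]
                                    : choice[4 * v + st[T.parent[v]]];
    }
    for (int v = 0; v < T.nn; ++v) assign(r, v) = st[v];
  }
  return List::create(_["score"] = sc, _["loglik"] = loglik,
                      _["posterior"] = post, _["assignment"] = assign);
}

// Fixed-root Sankoff with unit costs. Down pass prefers the parent's state
// on ties (mutations sit as high as possible), then the smallest state.
static int sankoff_run(const TreeIdx& T, const IntegerVector& leaf_state,
                       int root_state, std::vector<int>& assign) {
  std::vector<int> cost(4 * T.nn, 0);
  for (size_t i = 0; i < T.post.size(); ++i) {
    int v = T.post[i];
    if (T.children[v].empty()) {
      int st = leaf_state[v];
      if (st < 0 || st > 3) stop("leaf node %d has no valid state", v + 1);
      for (int s = 0; s < 4; ++s) cost[4 * v + s] = (s == st) ? 0 : INT_INF;
    } else {
      for (int s = 0; s < 4; ++s) {
        int acc = 0;
        for (size_t k = 0; k < T.children[v].size(); ++k) {
          int c = T.children[v][k];
          int best = INT_INF;
          for (int sc = 0; sc < 4; ++sc) {
            int val = cost[4 * c + sc] + (sc == s ? 0 : 1);
            if (val < best) best = val;
          }
          acc += best;
        }
        cost[4 * v + s] = acc;
      }
    }
  }
  assign.assign(T.nn, -1);
  assign[T.root] = root_state;
  std::vector<int> pre(T.post.rbegin(), T.post.rend());
  for (size_t i = 0; i < pre.size(); ++i) {
    int v = pre[i];
    if (v == T.root) continue;
    int sp = assign[T.parent[v]];
    int best = INT_INF, arg = -1;
    for (int s = 0; s < 4; ++s) {
      int val = cost[4 * v + s] + (s == sp ? 0 : 1);
      if (val < best || (val == best && s == sp)) {
        best = val;
        arg = s;
      }
    }
    assign[v] = arg;
  }
  return cost[4 * T.root + root_state];
}

// [[Rcpp::export]]
List sankoff_cpp(IntegerVector parent, IntegerVector leaf_state,
                 int root_state) {
  if (root_state < 0 || root_state > 3) stop("invalid root state");
  TreeIdx T = build_tree(parent);
  std::vector<int> assign;
  int count = sankoff_run(T, leaf_state, root_state, assign);
  std::vector<int> mut_node, mut_from, mut_to;
  bool polytomy = false;
  for (int v = 0; v < T.nn; ++v) {
    int p = T.parent[v];
    if (p < 0) continue;
    if (assign[v] != assign[p]) {
      mut_node.push_back(v + 1);
      mut_from.push_back(assign[p]);
      mut_to.push_back(assign[v]);
      if (T.children[p].size() > 2) polytomy = true;
    }
  }
  return List::create(_["count"] = count,
                      _["node_state"] = IntegerVector(assign.begin(), assign.end()),
                      _["mut_node"] = IntegerVector(mut_node.begin(), mut_node.end()),
                      _["mut_from"] = IntegerVector(mut_from.begin(), mut_from.end()),
                      _["mut_to"] = IntegerVector(mut_to.begin(), mut_to.end()),
                      _["polytomy"] = polytomy);
}

struct SiteClass {
  int min_count;
  int n_min;        // number of candidates attaining the minimum
  bool polytomy;    // under any minimising candidate
  std::vector<int> counts;
  std::vector<int> cands;
};

static SiteClass classify_core(const TreeIdx& T,
                               const IntegerVector& leaf_state,
                               const std::vector<int>& cands) {
  SiteClass out;
  out.cands = cands;
  out.counts.resize(cands.size());
  out.min_count = INT_INF;
  bool any_polytomy = false;
  for (size_t v = 0; v < T.children.size() && !any_polytomy; ++v)
    if (T.children[v].size() > 2) any_polytomy = true;
  std::vector<int> assign;
  std::vector<char> poly(cands.size(), 0);
  for (size_t i = 0; i < cands.size(); ++i) {
    out.counts[i] = sankoff_run(T, leaf_state, cands[i], assign);
    if (out.counts[i] < out.min_count) out.min_count = out.counts[i];
    if (any_polytomy) {
      for (int v = 0; v < T.nn; ++v) {
        int p = T.parent[v];
        if (p >= 0 && assign[v] != assign[p] && T.children[p].size() > 2)
          poly[i] = 1;
      }
    }
  }
  out.n_min = 0;
  out.polytomy = false;
  for (size_t i = 0; i < cands.size(); ++i) {
    if (out.counts[i] != out.min_count) continue;
    ++out.n_min;
    if (poly[i]) out.polytomy = true;
  }
  return out;
}

// [[Rcpp::export]]
List classify_cpp(IntegerVector parent, IntegerVector leaf_state,
                  IntegerVector candidates) {
  TreeIdx T = build_tree(parent);
  std::vector<int> cands(candidates.begin(), candidates.end());
  SiteClass sc = classify_core(T, leaf_state, cands);
  return List::create(
      _["counts"] = IntegerVector(sc.counts.begin(), sc.counts.end()),
      _["min_count"] = sc.min_count, _["n_min"] = sc.n_min,
      _["polytomy"] = sc.polytomy);
}

// Batched pipeline core: sites grouped by local tree so per-edge transition
// matrices are computed once per tree. leaf_states is sites x n_leaves with
// leaves assumed to be nodes 0..n_leaves-1 of every tree.
//
// Output columns (one row per site):
//  1-4   unrestricted posterior A,C,G,T
//  5-8   posterior restricted to observed alleles
//  9     called ancestral state (0..3) by max restricted posterior
//  10    tie flag for the call
//  11    parsimony minimum over candidates
//  12    non-informative flag
//  13    multiple-mutations flag
//  14    homoplasy flag
//  15    polytomy-with-mutation flag
//  16    number of observed alleles
// [[Rcpp::export]]
NumericMatrix polarise_batch_cpp(List tree_parent, List tree_time,
                                 IntegerVector site_tree,
                                 IntegerMatrix leaf_states, int model,
                                 double mu, double kappa, NumericVector prior,
                                 bool candidates_all4) {
  int nsites = leaf_states.nrow();
  int nleaf = leaf_states.ncol();
  if (site_tree.size() != nsites) stop("site_tree length mismatch");
  int ntrees = tree_parent.size();
  NumericMatrix out(nsites, 16);
  std::fill(out.begin(), out.end(), NA_REAL);

  // order sites by tree index
  std::vector<std::vector<int> > by_tree(ntrees);
  for (int i = 0; i < nsites; ++i) {
    int t = site_tree[i];
    if (t < 0 || t >= ntrees) stop("site_tree index out of range");
    by_tree[t].push_back(i);
  }

  IntegerVector ls(0);
  for (int ti = 0; ti < ntrees; ++ti) {
    if (by_tree[ti].empty()) continue;
    IntegerVector parent = tree_parent[ti];
    NumericVector time = tree_time[ti];
    TreeIdx T = build_tree(parent);
    std::vector<double> lp;
    edge_logP(T, time, model, mu, kappa, lp);
    IntegerVector leaf_state(T.nn, -1);
    std::vector<double> L;

    for (size_t si = 0; si < by_tree[ti].size(); ++si) {
      int i = by_tree[ti][si];
      bool seen[4] = {false, false, false, false};
      for (int j = 0; j < nleaf; ++j) {
        int st = leaf_states(i, j);
        if (st < 0 || st > 3) stop("invalid leaf state at site row %d", i + 1);
        leaf_state[j] = st;
        seen[st] = true;
      }
      int nall = seen[0] + seen[1] + seen[2] + seen[3];
      out(i, 15) = nall;
      if (nall < 2) continue;  // monomorphic: left NA

      joint_dp(T, lp, leaf_state, L);
      double score[4];
      for (int s = 0; s < 4; ++s) {
        double pr = prior[s];
        score[s] =
            sat_add((pr > 0.0) ? std::log(pr) : NEG_INF, L[4 * T.root + s]);
      }
      double lse = log_sum_exp(score, 4);
      double post[4];
      for (int s = 0; s < 4; ++s) {
        post[s] = std::exp(score[s] - lse);
        out(i, s) = post[s];
      }
      // restricted posterior
      double obs_scores[4];
      int obs_idx[4], nobs = 0;
      for (int s = 0; s < 4; ++s)
        if (seen[s]) {
          obs_scores[nobs] = score[s];
          obs_idx[nobs] = s;
          ++nobs;
        }
      double lse_r = log_sum_exp(obs_scores, nobs);
      double postr[4] = {0, 0, 0, 0};
      for (int k = 0; k < nobs; ++k)
        postr[obs_idx[k]] = std::exp(obs_scores[k] - lse_r);
      for (int s = 0; s < 4; ++s) out(i, 4 + s) = postr[s];
      // call: max restricted posterior, lexicographic on ties
      int call = -1;
      double best = -1.0;
      for (int s = 0; s < 4; ++s)
        if (seen[s] && postr[s] > best) {
          best = postr[s];
          call = s;
        }
      bool tie = false;
      for (int s = 0; s < 4; ++s)
        if (seen[s] && s != call &&
            std::fabs(postr[s] - best) <= 1e-12 * std::max(1.0, best))
          tie = true;
      out(i, 8) = call;
      out(i, 9) = tie ? 1.0 : 0.0;
      // parsimony classification
      std::vector<int> cands;
      for (int s = 0; s < 4; ++s)
        if (candidates_all4 || seen[s]) cands.push_back(s);
      SiteClass scls = classify_core(T, leaf_state, cands);
      out(i, 10) = scls.min_count;
      out(i, 11) = (scls.n_min >= 2) ? 1.0 : 0.0;
      out(i, 12) = (scls.min_count > 1) ? 1.0 : 0.0;
      out(i, 13) = (scls.min_count > 1 && nall == 2) ? 1.0 : 0.0;
      out(i, 14) = scls.polytomy ? 1.0 : 0.0;
    }
  }
  return out;
}
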