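// Coalescent simulator with recombination along a chromosome (SMC'
// approximation), piecewise-constant diploid population size, and discrete
// finite-site mutations under JC69 or K80 with an arbitrary root nucleotide
// distribution.
//
// The first marginal tree is drawn from the standard (piecewise) coalescent.
// Moving along the sequence, breakpoints arrive at rate r * (total branch
// length) per bp; at each breakpoint a point is chosen uniformly on the
// tree, the lineage above it is detached and re-coalesces with the full
// tree (back-coalescence onto its own branch leaves the tree unchanged and
// the interval is simply extended). Mutations are laid down per interval at
// integer positions, several hits at one position giving multi-allelic or
// homoplasic sites. Uses R's RNG throughout.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Demography {
  std::vector<double> start;  // epoch start times, start[0] == 0
  std::vector<double> size;   // diploid N per epoch
  int epoch_at(double t) const {
    int j = (int)(std::upper_bound(start.begin(), start.end(), t) -
                  start.begin()) - 1;
    return j < 0 ? 0 : j;
  }
  double end_of(int j) const {
    return (j + 1 < (int)start.size()) ? start[j + 1] : R_PosInf;
  }
};

// waiting time from t0 for an inhomogeneous exponential with hazard
// mult / (2 N(t))
static double sample_coal_time(double t0, double mult, const Demography& D) {
  double E = R::exp_rand();
  int j = D.epoch_at(t0);
  double t = t0;
  while (true) {
    double rate = mult / (2.0 * D.size[j]);
    double tend = D.end_of(j);
    if (!R_FINITE(tend)) return t + E / rate;
    double cap = (tend - t) * rate;
    if (E <= cap) return t + E / rate;
    E -= cap;
    t = tend;
    ++j;
  }
}

struct SimTree {
  int n;                       // leaves 0..n-1
  std::vector<int> parent;     // -1 at root
  std::vector<int> child1, child2;
  std::vector<double> time;
  int root;

  void other_child_swap(int p, int oldc, int newc) {
    if (child1[p] == oldc) child1[p] = newc;
    else child2[p] = newc;
  }
  int sibling(int c) const {
    int p = parent[c];
    return (child1[p] == c) ? child2[p] : child1[p];
  }
  double total_length() const {
    double T = 0.0;
    for (size_t v = 0; v < parent.size(); ++v)
      if (parent[v] >= 0) T += time[parent[v]] - time[v];
    return T;
  }
};

static SimTree initial_tree(int n, const Demography& D) {
  SimTree tr;
  tr.n = n;
  int nn = 2 * n - 1;
  tr.parent.assign(nn, -1);
  tr.child1.assign(nn, -1);
  tr.child2.assign(nn, -1);
  tr.time.assign(nn, 0.0);
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  double t = 0.0;
  int next_id = n;
  int k = n;
  while (k > 1) {
    double mult = 0.5 * k * (k - 1);
    t = sample_coal_time(t, mult, D);
    int i = (int)std::floor(R::unif_rand() * k);
    int j = (int)std::floor(R::unif_rand() * (k - 1));
    if (j >= i) ++j;
    int a = active[i], b = active[j];
    int p = next_id++;
    tr.parent[a] = p;
    tr.parent[b] = p;
    tr.child1[p] = a;
    tr.child2[p] = b;
    tr.time[p] = t;
    // keep 'active' compact
    if (i > j) std::swap(i, j);
    active[i] = p;
    active[j] = active[k - 1];
    active.pop_back();
    --k;
  }
  tr.root = active[0];
  return tr;
}

// number of tree lineages spanning time t (>=1 once past the root)
static double sample_recoal_time(const SimTree& tr, double t_r,
                                 const Demography& D) {
  int nn = 2 * tr.n - 1;
  std::vector<double> itimes;
  itimes.reserve(tr.n - 1);
  for (int v = tr.n; v < nn; ++v) itimes.push_back(tr.time[v]);
  std::sort(itimes.begin(), itimes.end());
  double E = R::exp_rand();
  double t = t_r;
  // internal times <= t already consumed
  size_t idx = std::upper_bound(itimes.begin(), itimes.end(), t) -
               itimes.begin();
  int j = D.epoch_at(t);
  while (true) {
    int k = tr.n - (int)idx;
    if (k < 1) k = 1;
    double rate = (double)k / (2.0 * D.size[j]);
    double t_node = (idx < itimes.size()) ? itimes[idx] : R_PosInf;
    double t_epoch = D.end_of(j);
    double tend = std::min(t_node, t_epoch);
    if (!R_FINITE(tend)) return t + E / rate;
    double cap = (tend - t) * rate;
    if (E <= cap) return t + E / rate;
    E -= cap;
    t = tend;
    if (t_node <= t_epoch) ++idx;
    if (t_epoch <= t_node) ++j;
  }
}

// uniform choice among lineages spanning t_c; returns the child-end node id,
// or the root id if the ancestral (root) lineage is chosen
static int pick_lineage(const SimTree& tr, double t_c) {
  int nn = 2 * tr.n - 1;
  std::vector<int> cand;
  for (int v = 0; v < nn; ++v) {
    if (v == tr.root) {
      if (tr.time[v] <= t_c) cand.push_back(v);
    } else if (tr.time[v] <= t_c && t_c < tr.time[tr.parent[v]]) {
      cand.push_back(v);
    }
  }
  int i = (int)std::floor(R::unif_rand() * cand.size());
  if (i >= (int)cand.size()) i = cand.size() - 1;
  return cand[i];
}

struct Mut {
  int node;      // child end of the mutated edge
  double time;
};

static int draw_root_state(const NumericVector& prior) {
  double u = R::unif_rand(), acc = 0.0;
  for (int s = 0; s < 4; ++s) {
    acc += prior[s];
    if (u <= acc) return s;
  }
  return 3;
}

// mutation kernel: given the current state, draw the new (different) state
static int draw_mutation(int from, int model, double kappa) {
  if (model == 0) {
    int k = (int)std::floor(R::unif_rand() * 3.0);
    if (k > 2) k = 2;
    int s = (k >= from) ? k + 1 : k;
    return s;
  }
  // K80: transition partner with prob kappa/(kappa+2), else a transversion
  double u = R::unif_rand() * (kappa + 2.0);
  if (u < kappa) return from ^ 2;
  // the two transversion targets are the states with odd xor
  int tv1 = from ^ 1, tv2 = from ^ 3;
  return (u < kappa + 1.0) ? std::min(tv1, tv2) : std::max(tv1, tv2);
}

// [[Rcpp::export]]
List sim_replicate_cpp(int n, double seqlen, double recomb, double mu,
                       int model, double kappa, NumericVector prior,
                       NumericVector epoch_start, NumericVector epoch_size,
                       bool store_all) {
  if (n < 2) stop("need at least 2 haplotypes");
  Demography D;
  D.start.assign(epoch_start.begin(), epoch_start.end());
  D.size.assign(epoch_size.begin(), epoch_size.end());
  SimTree tr = initial_tree(n, D);
  int nn = 2 * n - 1;

  // outputs
  std::vector<int> t_parent, t_child_dummy;  // flattened nn x ntrees
  std::vector<double> t_time, t_left, t_right;
  std::vector<int> s_pos, s_tree, s_anc, s_nmut, s_nall;
  std::vector<int> s_states;  // flattened nsites x n
  long n_intervals = 0, n_recomb = 0, n_invisible = 0;

  std::vector<double> cum(nn);
  std::vector<int> preorder;
  preorder.reserve(nn);

  double left = 0.0, x = 0.0;
  while (true) {
    double T = tr.total_length();
    double dist = R::exp_rand() / (recomb * T);
    double right = std::min(x + dist, seqlen);
    bool at_end = (x + dist >= seqlen);

    bool visible = false;
    int rec_c = -1;
    double rec_tr = 0.0, t_c = 0.0;
    int target = -1;
    if (!at_end) {
      // choose recombination point uniformly on the tree
      double u = R::unif_rand() * T, acc = 0.0;
      for (int v = 0; v < nn; ++v) {
        if (v == tr.root) continue;
        acc += tr.time[tr.parent[v]] - tr.time[v];
        rec_c = v;
        if (u <= acc) break;
      }
      rec_tr = tr.time[tr.parent[rec_c]] - (acc - u);
      t_c = sample_recoal_time(tr, rec_tr, D);
      target = pick_lineage(tr, t_c);
      ++n_recomb;
      visible = (target != rec_c);
      if (!visible) ++n_invisible;
    }

    if (visible || at_end) {
      // emit interval [left, right) on the current tree
      ++n_intervals;
      int first = (int)std::ceil(left);
      int nint = (int)std::ceil(right) - first;
      std::map<int, std::vector<Mut> > by_pos;
      if (nint > 0) {
        int m = (int)R::rpois(mu * T * (double)nint);
        for (int k = 0; k < m; ++k) {
          int pos = first + (int)std::floor(R::unif_rand() * nint);
          if (pos >= first + nint) pos = first + nint - 1;
          // edge proportional to branch length
          double u = R::unif_rand() * T, acc = 0.0;
          int v = -1;
          for (int w = 0; w < nn; ++w) {
            if (w == tr.root) continue;
            acc += tr.time[tr.parent[w]] - tr.time[w];
            v = w;
            if (u <= acc) break;
          }
          Mut mt;
          mt.node = v;
          mt.time = tr.time[tr.parent[v]] - (acc - u) +
                    0.0;  // uniform height within the edge
          by_pos[pos].push_back(mt);
        }
      }
      bool stored = false;
      int tree_id = -1;
      if (store_all || !by_pos.empty()) {
        for (int v = 0; v < nn; ++v) {
          t_parent.push_back(tr.parent[v]);
          t_time.push_back(tr.time[v]);
        }
        t_left.push_back(left);
        t_right.push_back(right);
        tree_id = (int)t_left.size() - 1;
        stored = true;
      }
      if (!by_pos.empty()) {
        // preorder of the current tree
        preorder.clear();
        std::vector<int> stack;
        stack.push_back(tr.root);
        while (!stack.empty()) {
          int v = stack.back();
          stack.pop_back();
          preorder.push_back(v);
          if (tr.child1[v] >= 0) stack.push_back(tr.child1[v]);
          if (tr.child2[v] >= 0) stack.push_back(tr.child2[v]);
        }
        std::vector<int> st(nn);
        for (std::map<int, std::vector<Mut> >::iterator it = by_pos.begin();
             it != by_pos.end(); ++it) {
          std::vector<Mut>& ms = it->second;
          // oldest first along each edge
          std::sort(ms.begin(), ms.end(),
                    [](const Mut& a, const Mut& b) { return a.time > b.time; });
          int rs = draw_root_state(prior);
          st[tr.root] = rs;
          for (size_t i = 0; i < preorder.size(); ++i) {
            int v = preorder[i];
            if (v == tr.root) continue;
            int s = st[tr.parent[v]];
            for (size_t k = 0; k < ms.size(); ++k)
              if (ms[k].node == v) s = draw_mutation(s, model, kappa);
            st[v] = s;
          }
          bool seen[4] = {false, false, false, false};
          for (int l = 0; l < n; ++l) seen[st[l]] = true;
          int nall = seen[0] + seen[1] + seen[2] + seen[3];
          s_pos.push_back(it->first);
          s_tree.push_back(tree_id);
          s_anc.push_back(rs);
          s_nmut.push_back((int)ms.size());
          s_nall.push_back(nall);
          for (int l = 0; l < n; ++l) s_states.push_back(st[l]);
        }
      }
      (void)stored;
      left = right;
    }

    if (at_end) break;
    x = x + dist;
    if (visible) {
      // apply the SPR move: splice out the old parent of rec_c, reattach at
      // t_c above 'target'
      int c = rec_c;
      int p = tr.parent[c];
      int sib = tr.sibling(c);
      int gp = tr.parent[p];
      if (target == p) target = sib;
      // splice p out
      tr.parent[sib] = gp;
      if (gp >= 0) tr.other_child_swap(gp, p, sib);
      else tr.root = sib;
      if (target == tr.root && t_c >= tr.time[tr.root]) {
        // re-coalesce onto the ancestral root lineage: p becomes the new root
        tr.parent[p] = -1;
        tr.child1[p] = c;
        tr.child2[p] = tr.root == p ? sib : tr.root;
        int old_root = (tr.root == p) ? sib : tr.root;
        tr.child2[p] = old_root;
        tr.parent[old_root] = p;
        tr.parent[c] = p;
        tr.time[p] = t_c;
        tr.root = p;
      } else {
        int tp = tr.parent[target];
        tr.parent[p] = tp;
        if (tp >= 0) tr.other_child_swap(tp, target, p);
        else tr.root = p;
        tr.child1[p] = c;
        tr.child2[p] = target;
        tr.parent[c] = p;
        tr.parent[target] = p;
        tr.time[p] = t_c;
      }
    }
  }

  int ntrees = (int)t_left.size();
  int nsites = (int)s_pos.size();
  IntegerMatrix TP(nn, ntrees);
  NumericMatrix TT(nn, ntrees);
  for (int j = 0; j < ntrees; ++j)
    for (int v = 0; v < nn; ++v) {
      TP(v, j) = t_parent[(size_t)j * nn + v];
      TT(v, j) = t_time[(size_t)j * nn + v];
    }
  IntegerMatrix LS(nsites, n);
  for (int i = 0; i < nsites; ++i)
    for (int l = 0; l < n; ++l) LS(i, l) = s_states[(size_t)i * n + l];
  return List::create(
      _["tree_parent"] = TP, _["tree_time"] = TT,
      _["tree_left"] = NumericVector(t_left.begin(), t_left.end()),
      _["tree_right"] = NumericVector(t_right.begin(), t_right.end()),
      _["site_pos"] = IntegerVector(s_pos.begin(), s_pos.end()),
      _["site_tree"] = IntegerVector(s_tree.begin(), s_tree.end()),
      _["site_anc"] = IntegerVector(s_anc.begin(), s_anc.end()),
      _["site_nmut"] = IntegerVector(s_nmut.begin(), s_nmut.end()),
      _["site_nalleles"] = IntegerVector(s_nall.begin(), s_nall.end()),
      _["leaf_states"] = LS, _["n_recomb"] = (double)n_recomb,
      _["n_invisible"] = (double)n_invisible,
      _["n_intervals"] = (double)n_intervals);
}
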