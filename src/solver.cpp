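// Exact branch-and-bound core for the parametric (non-fractional) subproblem
//   max  sum_{v in S} w_v
//   s.t. S induces a subgraph in which every node is reachable from a
//        single root by a directed path inside S (root-connectivity),
//        kmin <= |S| <= kmax, root drawn from an admissible root set,
//        optional terminal condition (every selected non-terminal node has a
//        selected out-neighbor), include/exclude sets, and no-good cuts
//        (S must not equal any given cut set exactly; supersets remain
//        admissible, the weakest exclusion guaranteeing a new node set).
//
// Connectivity is enforced constructively: the search grows S from the root
// through out-neighbors only, so every explored S is root-connected by
// construction. The bound adds the largest positive weights among nodes
// still reachable from S through undecided nodes within the remaining size
// budget (breadth-first distance <= budget).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <chrono>
using namespace Rcpp;

namespace {

struct Solver {
  int n, kmin, kmax;
  bool enforce_terminal;
  bool prefer_larger = false;  // among equal-value optima keep the largest set
  std::vector<std::vector<int>> out_adj, in_adj;
  std::vector<double> w;
  std::vector<char> is_terminal, is_include, base_excluded;

  std::vector<std::vector<int>> cuts;
  std::vector<std::vector<int>> cuts_of;  // node -> indices into cuts
  std::vector<int> cut_sel;

  std::vector<int> state;  // 0 undecided, 1 selected, 2 banned/excluded
  std::vector<int> sel;
  std::vector<int> out_sel_count;
  int deficit = 0, inc_sel = 0, n_inc = 0;
  double cur_w = 0.0;
  std::vector<int> frontier;
  std::vector<char> in_frontier;

  bool has_best = false;
  double best_val = 0.0;
  std::vector<int> best_set;
  int best_root = -1;

  long long nodes_explored = 0, node_limit = 0;
  bool hit_limit = false;
  std::chrono::steady_clock::time_point t_end;

  // BFS scratch
  std::vector<int> visit_token, dist_arr, bfs_q;
  std::vector<double> cand_w;
  int token = 0;

  static const double EPS;

  bool limits_ok() {
    if (hit_limit) return false;
    if ((++nodes_explored & 1023) == 0) {
      if (nodes_explored > node_limit ||
          std::chrono::steady_clock::now() > t_end) {
        hit_limit = true;
        return false;
      }
    }
    return true;
  }

  void maybe_update_incumbent(int root) {
    if ((int)sel.size() < kmin || (int)sel.size() > kmax) return;
    if (deficit > 0 || inc_sel < n_inc) return;
    for (size_t ci = 0; ci < cuts.size(); ++ci) {
      if (cut_sel[ci] == (int)cuts[ci].size() &&
          (int)cuts[ci].size() == (int)sel.size()) {
        return;  // exactly a forbidden previous solution
      }
    }
    bool better = !has_best || cur_w > best_val + EPS ||
                  (prefer_larger && cur_w > best_val - EPS &&
                   (int)sel.size() > (int)best_set.size());
    if (better) {
      has_best = true;
      best_val = cur_w;
      best_set = sel;
      best_root = root;
    }
  }

  // Upper bound via budget-limited BFS over undecided nodes.
  // Returns true when the branch can be pruned.
  bool bound_prune() {
    int b_max = kmax - (int)sel.size();
    int b_min = std::max(0, kmin - (int)sel.size());
    if (b_max <= 0) return true;  // caller handles |S|==kmax before this
    ++token;
    bfs_q.clear();
    cand_w.clear();
    for (int v : frontier) {
      if (state[v] == 0 && visit_token[v] != token) {
        visit_token[v] = token;
        dist_arr[v] = 1;
        bfs_q.push_back(v);
      }
    }
    int found_inc = 0;
    for (size_t head = 0; head < bfs_q.size(); ++head) {
      int v = bfs_q[head];
      if (w[v] > 0) cand_w.push_back(w[v]);
      if (is_include[v]) ++found_inc;
      if (dist_arr[v] < b_max) {
        for (int u : out_adj[v]) {
          if (state[u] == 0 && visit_token[u] != token) {
            visit_token[u] = token;
            dist_arr[u] = dist_arr[v] + 1;
            bfs_q.push_back(u);
          }
        }
      }
    }
    if ((int)bfs_q.size() < b_min) return true;        // cannot reach kmin
    if (n_inc - inc_sel > found_inc) return true;      // include out of reach
    if (n_inc - inc_sel > b_max) return true;
    std::sort(cand_w.begin(), cand_w.end(), std::greater<double>());
    int take = std::min((int)cand_w.size(), b_max);
    double ub = cur_w;
    for (int i = 0; i < take; ++i) ub += cand_w[i];
    if (!has_best) return false;
    if (!prefer_larger) return ub <= best_val + EPS;
    if (ub < best_val - EPS) return true;
    // value tie still admissible: prune only when this branch cannot beat
    // the incumbent's cardinality either
    int max_size = (int)sel.size() + std::min((int)bfs_q.size(), b_max);
    return ub <= best_val + EPS && max_size <= (int)best_set.size();
  }

  int pick_branch_node() {
    int best = -1;
    for (int v : frontier) {
      if (state[v] != 0) continue;
      if (best == -1 || w[v] > w[best] + EPS ||
          (w[v] > w[best] - EPS && v < best)) {
        best = v;
      }
    }
    return best;
  }

  // Adds v to S and returns the number of frontier entries appended.
  int add_node(int v) {
    state[v] = 1;
    sel.push_back(v);
    cur_w += w[v];
    if (is_include[v]) ++inc_sel;
    for (int ci : cuts_of[v]) ++cut_sel[ci];
    if (enforce_terminal) {
      if (!is_terminal[v]) {
        int c = 0;
        for (int u : out_adj[v]) if (state[u] == 1) ++c;
        out_sel_count[v] = c;
        if (c == 0) ++deficit;
      }
      for (int p : in_adj[v]) {
        if (state[p] == 1 && !is_terminal[p]) {
          if (out_sel_count[p]++ == 0) --deficit;
        }
      }
    }
    int appended = 0;
    for (int u : out_adj[v]) {
      if (!in_frontier[u] && state[u] != 1) {
        in_frontier[u] = 1;
        frontier.push_back(u);
        ++appended;
      }
    }
    return appended;
  }

  void undo_add(int v, int appended) {
    for (int i = 0; i < appended; ++i) {
      in_frontier[frontier.back()] = 0;
      frontier.pop_back();
    }
    if (enforce_terminal) {
      for (int p : in_adj[v]) {
        if (state[p] == 1 && !is_terminal[p]) {
          if (--out_sel_count[p] == 0) ++deficit;
        }
      }
      if (!is_terminal[v] && out_sel_count[v] == 0) --deficit;
      out_sel_count[v] = 0;
    }
    for (int ci : cuts_of[v]) --cut_sel[ci];
    if (is_include[v]) --inc_sel;
    cur_w -= w[v];
    sel.pop_back();
    state[v] = 0;
  }

  // A selected non-terminal node whose last potential out-neighbor was just
  // banned can never be repaired: the whole subtree is dead.
  bool ban_kills_branch(int v) {
    if (!enforce_terminal) return false;
    for (int p : in_adj[v]) {
      if (state[p] == 1 && !is_terminal[p] && out_sel_count[p] == 0) {
        bool any = false;
        for (int u : out_adj[p]) {
          if (state[u] == 0) { any = true; break; }
        }
        if (!any) return true;
      }
    }
    return false;
  }

  void dfs(int root) {
    if (!limits_ok()) return;
    maybe_update_incumbent(root);
    if ((int)sel.size() >= kmax) return;
    if (bound_prune()) return;
    int v = pick_branch_node();
    if (v < 0) return;
    int appended = add_node(v);
    dfs(root);
    undo_add(v, appended);
    if (hit_limit) return;
    if (!is_include[v]) {
      state[v] = 2;
      if (!ban_kills_branch(v)) dfs(root);
      state[v] = 0;
    }
  }

  void reset_state() {
    for (int v = 0; v < n; ++v) state[v] = base_excluded[v] ? 2 : 0;
    std::fill(out_sel_count.begin(), out_sel_count.end(), 0);
    std::fill(cut_sel.begin(), cut_sel.end(), 0);
    std::fill(in_frontier.begin(), in_frontier.end(), 0);
    frontier.clear();
    sel.clear();
    cur_w = 0.0;
    deficit = 0;
    inc_sel = 0;
  }

  void run(const std::vector<int> &roots) {
    // roots in descending weight (ties: ascending index) for fast incumbents
    std::vector<int> order(roots);
    std::sort(order.begin(), order.end(), [&](int a, int b) {
      if (w[a] != w[b]) return w[a] > w[b];
      return a < b;
    });
    for (int r : order) {
      if (base_excluded[r] || hit_limit) continue;
      reset_state();
      add_node(r);
      dfs(r);
    }
  }
};

const double Solver::EPS = 1e-12;

}  // namespace

// [[Rcpp::export]]
List drn_solve_core(int n, IntegerVector edge_from, IntegerVector edge_to,
                    NumericVector weights, IntegerVector roots,
                    LogicalVector excluded, IntegerVector include_idx,
                    LogicalVector terminal, bool enforce_terminal, int kmin,
                    int kmax, List cuts, double time_limit,
                    double node_limit, bool prefer_larger) {
  Solver s;
  s.n = n;
  s.kmin = kmin;
  s.kmax = kmax;
  s.enforce_terminal = enforce_terminal;
  s.prefer_larger = prefer_larger;
  s.out_adj.assign(n, {});
  s.in_adj.assign(n, {});
  for (int i = 0; i < edge_from.size(); ++i) {
    s.out_adj[edge_from[i]].push_back(edge_to[i]);
    s.in_adj[edge_to[i]].push_back(edge_from[i]);
  }
  for (int v = 0; v < n; ++v) {  // deterministic neighbor order
    std::sort(s.out_adj[v].begin(), s.out_adj[v].end());
    std::sort(s.in_adj[v].begin(), s.in_adj[v].end());
  }
  s.w.assign(weights.begin(), weights.end());
  s.is_terminal.assign(n, 0);
  for (int i = 0; i < terminal.size(); ++i) s.is_terminal[i] = terminal[i];
  s.is_include.assign(n, 0);
  s.n_inc = include_idx.size();
  for (int i = 0; i < include_idx.size(); ++i) s.is_include[include_idx[i]] = 1;
  s.base_excluded.assign(n, 0);
  for (int i = 0; i < excluded.size(); ++i) s.base_excluded[i] = excluded[i];
  s.cuts_of.assign(n, {});
  for (int ci = 0; ci < cuts.size(); ++ci) {
    IntegerVector cut = cuts[ci];
    std::vector<int> cs(cut.begin(), cut.end());
    for (int v : cs) s.cuts_of[v].push_back(ci);
    s.cuts.push_back(cs);
  }
  s.cut_sel.assign(s.cuts.size(), 0);
  s.state.assign(n, 0);
  s.out_sel_count.assign(n, 0);
  s.in_frontier.assign(n, 0);
  s.visit_token.assign(n, 0);
  s.dist_arr.assign(n, 0);
  s.node_limit = (long long)node_limit;
  s.t_end = std::chrono::steady_clock::now() +
            std::chrono::milliseconds((long long)(time_limit * 1000.0));

  std::vector<int> rts(roots.begin(), roots.end());
  s.run(rts);

  IntegerVector out_set(s.best_set.begin(), s.best_set.end());
  return List::create(
      Named("feasible") = s.has_best, Named("value") = s.best_val,
      Named("set") = out_set, Named("root") = s.best_root,
      Named("hit_limit") = s.hit_limit,
      Named("nodes_explored") = (double)s.nodes_explored);
}
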