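// (6,6) body-bar pebble game.
//
// Bodies carry 6 pebbles (6 rigid-body DOF).  A bar between bodies u,v is
// independent iff 7 pebbles can be gathered on {u,v}; covering consumes one
// pebble from u and records a directed edge u->v.  Pebble searches are DFS
// with path reversal.  Invariant: pebbles[v] + outdeg[v] == 6 for every body,
// so free pebbles count the uncovered DOF of the framework.
//
// Beyond independence labels, this file computes the cluster decomposition
// used by the flexibility index: locked rotatable bonds grouped into rigid
// clusters (isostatic or over-constrained, with redundant-bar counts B), and
// free rotatable bonds grouped into flexible clusters as connected components
// of the quotient matroid of their test bars over the engaged network
// (components derived from fundamental circuits w.r.t. the pebble-game basis).

#include <Rcpp.h>
#include <functional>
#include <vector>
using namespace Rcpp;

namespace {

const int KP = 6; // pebbles per body

struct Game {
  int n;
  std::vector<int> pebbles;
  std::vector< std::vector<int> > out;
  std::vector<int> visited, parent, parent_ei, stack_;
  int stamp;

  explicit Game(int n_)
      : n(n_), pebbles(n_, KP), out(n_), visited(n_, 0), parent(n_, -1),
        parent_ei(n_, -1), stamp(0) {}

  // Move one free pebble to `start` if reachable (excl is off-limits).
  bool find_pebble(int start, int excl) {
    ++stamp;
    visited[start] = stamp;
    if (excl >= 0) visited[excl] = stamp;
    stack_.clear();
    stack_.push_back(start);
    parent[start] = -1;
    while (!stack_.empty()) {
      int u = stack_.back();
      stack_.pop_back();
      for (size_t ei = 0; ei < out[u].size(); ++ei) {
        int w = out[u][ei];
        if (visited[w] == stamp) continue;
        visited[w] = stamp;
        parent[w] = u;
        parent_ei[w] = static_cast<int>(ei);
        if (pebbles[w] > 0) {
          int x = w; // reverse the tree path start -> ... -> w
          while (parent[x] != -1) {
            int p = parent[x];
            int idx = parent_ei[x];
            out[p][idx] = out[p].back();
            out[p].pop_back();
            out[x].push_back(p);
            x = p;
          }
          --pebbles[w];
          ++pebbles[start];
          return true;
        }
        stack_.push_back(w);
      }
    }
    return false;
  }

  bool collect(int u, int v, int target) {
    while (pebbles[u] + pebbles[v] < target) {
      if (!find_pebble(u, v) && !find_pebble(v, u)) return false;
    }
    return true;
  }

  // Returns true if the bar was independent (and inserts it).
  bool insert_bar(int u, int v) {
    if (!collect(u, v, KP + 1)) return false;
    --pebbles[u];
    out[u].push_back(v);
    return true;
  }

  // Mutual rigidity: a further bar between u,v would be redundant.
  bool pair_rigid(int u, int v) {
    if (u == v) return true;
    return !collect(u, v, KP + 1);
  }

  int free_pebbles() const {
    int s = 0;
    for (int i = 0; i < n; ++i) s += pebbles[i];
    return s;
  }
};

} // namespace

// Run the game on engaged bars only; independence labels + free pebbles.
// [[Rcpp::export(name = ".pg_rank")]]
List pg_rank(int n_bodies, IntegerVector bar_u, IntegerVector bar_v) {
  int m = bar_u.size();
  Game g(n_bodies);
  LogicalVector indep(m);
  for (int i = 0; i < m; ++i)
    indep[i] = g.insert_bar(bar_u[i] - 1, bar_v[i] - 1);
  return List::create(_["independent"] = indep,
                      _["free_pebbles"] = g.free_pebbles());
}

// Full decomposition.  Engaged bars are inserted in the given (entropy) order;
// one test bar per entry of test_bond (indices into the rotatable-bond list)
// probes the disordered torsions afterwards.
// [[Rcpp::export(name = ".pg_analyze")]]
List pg_analyze(int n_bodies, IntegerVector bar_u, IntegerVector bar_v,
                IntegerVector rot_u, IntegerVector rot_v,
                IntegerVector test_bond) {
  const int m = bar_u.size(), nrot = rot_u.size(), ntest = test_bond.size();

  Game g(n_bodies);
  LogicalVector indep(m);
  for (int i = 0; i < m; ++i)
    indep[i] = g.insert_bar(bar_u[i] - 1, bar_v[i] - 1);
  const int free_peb = g.free_pebbles();
  const Game base = g; // snapshot after the engaged phase

  // --- locked rotatable bonds and rigid clusters (engaged network) ---------
  LogicalVector locked(nrot);
  {
    Game w = base;
    for (int b = 0; b < nrot; ++b)
      locked[b] = w.pair_rigid(rot_u[b] - 1, rot_v[b] - 1);
  }

  std::vector<int> cluster_of_bond(nrot, -1);
  std::vector<int> rigid_rep;      // representative body per rigid cluster
  std::vector<int> rigid_nbond;    // locked rotatable bonds per cluster
  std::vector<int> rigid_B;        // redundant engaged bars per cluster
  {
    Game w = base;
    for (int b = 0; b < nrot; ++b) {
      if (!locked[b]) continue;
      int u = rot_u[b] - 1;
      int hit = -1;
      for (size_t c = 0; c < rigid_rep.size(); ++c) {
        if (w.pair_rigid(u, rigid_rep[c])) { hit = static_cast<int>(c); break; }
      }
      if (hit < 0) {
        rigid_rep.push_back(u);
        rigid_nbond.push_back(0);
        rigid_B.push_back(0);
        hit = static_cast<int>(rigid_rep.size()) - 1;
      }
      cluster_of_bond[b] = hit;
      ++rigid_nbond[hit];
    }
    // map redundant engaged bars onto rigid clusters (endpoints of a
    // redundant bar are always mutually rigid)
    for (int i = 0; i < m; ++i) {
      if (indep[i]) continue;
      int u = bar_u[i] - 1;
      int hit = -1;
      for (size_t c = 0; c < rigid_rep.size(); ++c) {
        if (w.pair_rigid(u, rigid_rep[c])) { hit = static_cast<int>(c); break; }
      }
      if (hit < 0) { // over-constrained region holding no rotatable bond
        rigid_rep.push_back(u);
        rigid_nbond.push_back(0);
        rigid_B.push_back(0);
        hit = static_cast<int>(rigid_rep.size()) - 1;
      }
      ++rigid_B[hit];
    }
  }

  // --- flexible clusters: quotient matroid of test bars over engaged set ---
  LogicalVector test_indep(ntest);
  std::vector<int> ins_order;       // test entries actually inserted (free)
  std::vector<int> basis;           // independent test entries, in order
  std::vector<int> uf(ntest);
  for (int i = 0; i < ntest; ++i) uf[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (uf[x] != x) { uf[x] = uf[uf[x]]; x = uf[x]; }
    return x;
  };
  auto unite = [&](int a, int b) { uf[find(a)] = find(b); };

  {
    Game w = base;
    for (int t = 0; t < ntest; ++t) {
      int b = test_bond[t] - 1;
      if (locked[b]) { test_indep[t] = false; continue; }
      bool ok = w.insert_bar(rot_u[b] - 1, rot_v[b] - 1);
      test_indep[t] = ok;
      if (ok) basis.push_back(t);
      else {
        // fundamental circuit of this test bar w.r.t. the basis prefix:
        // re-run with each basis element deleted in turn
        for (size_t k = 0; k < basis.size(); ++k) {
          Game w2 = base;
          for (size_t j = 0; j < basis.size(); ++j) {
            if (j == k) continue;
            int bb = test_bond[basis[j]] - 1;
            w2.insert_bar(rot_u[bb] - 1, rot_v[bb] - 1);
          }
          if (w2.insert_bar(rot_u[b] - 1, rot_v[b] - 1))
            unite(t, basis[k]); // basis[k] is in the circuit
        }
      }
      ins_order.push_back(t);
    }
  }

  // component labels for free bonds
  const int n_rigid = static_cast<int>(rigid_rep.size());
  std::vector<int> comp_label(ntest, -1);
  std::vector<int> flex_nbond, flex_A;
  {
    std::vector<int> root2comp(ntest, -1);
    for (size_t z = 0; z < ins_order.size(); ++z) {
      int t = ins_order[z];
      int r = find(t);
      if (root2comp[r] < 0) {
        root2comp[r] = static_cast<int>(flex_nbond.size());
        flex_nbond.push_back(0);
        flex_A.push_back(0);
      }
      comp_label[t] = root2comp[r];
      ++flex_nbond[root2comp[r]];
      if (test_indep[t]) ++flex_A[root2comp[r]];
      cluster_of_bond[test_bond[t] - 1] = n_rigid + root2comp[r];
    }
  }

  // assemble cluster table: rigid clusters first, then flexible
  const int n_flex = static_cast<int>(flex_nbond.size());
  const int n_cl = n_rigid + n_flex;
  IntegerVector cl_nbond(n_cl), cl_A(n_cl), cl_B(n_cl);
  CharacterVector cl_label(n_cl);
  for (int c = 0; c < n_rigid; ++c) {
    cl_nbond[c] = rigid_nbond[c];
    cl_A[c] = NA_INTEGER;
    cl_B[c] = rigid_B[c];
    cl_label[c] = rigid_B[c] > 0 ? "overconstrained" : "isostatic";
  }
  for (int c = 0; c < n_flex; ++c) {
    cl_nbond[n_rigid + c] = flex_nbond[c];
    cl_A[n_rigid + c] = flex_A[c];
    cl_B[n_rigid + c] = NA_INTEGER;
    cl_label[n_rigid + c] = "flexible";
  }

  IntegerVector bond_cluster(nrot);
  for (int b = 0; b < nrot; ++b) bond_cluster[b] = cluster_of_bond[b] + 1;

  return List::create(
      _["independent"] = indep, _["free_pebbles"] = free_peb,
      _["locked"] = locked, _["bond_cluster"] = bond_cluster,
      _["test_independent"] = test_indep,
      _["cluster_label"] = cl_label, _["cluster_n_bonds"] = cl_nbond,
      _["cluster_A"] = cl_A, _["cluster_B"] = cl_B);
}
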