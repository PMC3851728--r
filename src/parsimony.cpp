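#include <Rcpp.h>
#include <algorithm>
#include <deque>
#include <set>
#include <string>
#include <vector>
using namespace Rcpp;

// Unit-cost small parsimony on binary characters with the root state fixed
// at 0 (ancestral).  criterion 0 = wagner (free 0<->1 reversals, Fitch
// lengths), criterion 1 = camin_sokal (only 0->1 changes permitted on any
// root-to-leaf path).  Missing states (NA) behave as the free state set
// {0,1} and contribute the cheapest consistent assignment.

static const int BIG = 1 << 24; // effectively infinite per-character cost

// ---------------------------------------------------------------------------
// Scoring over an ape-style postorder edge matrix (general rooted trees,
// multifurcations allowed).  states: ntip x nchar, rows in tip-number order.

// [[Rcpp::export]]
IntegerVector cpp_score_postorder(IntegerMatrix edge, int ntip,
                                  IntegerMatrix states, int criterion) {
  int nchar = states.ncol();
  int nedge = edge.nrow();
  int nnode = ntip;
  for (int i = 0; i < nedge; i++) {
    nnode = std::max(nnode, std::max(edge(i, 0), edge(i, 1)));
  }
  std::vector<int> c0(nnode + 1), c1(nnode + 1);
  IntegerVector out(nchar);
  int root = ntip + 1;
  for (int ch = 0; ch < nchar; ch++) {
    for (int v = 1; v <= nnode; v++) {
      if (v <= ntip) {
        int s = states(v - 1, ch);
        if (s == NA_INTEGER) { c0[v] = 0; c1[v] = 0; }
        else if (s == 0)     { c0[v] = 0; c1[v] = BIG; }
        else                 { c0[v] = BIG; c1[v] = 0; }
      } else {
        c0[v] = 0; c1[v] = 0;
      }
    }
    for (int i = 0; i < nedge; i++) {
      int p = edge(i, 0), v = edge(i, 1);
      int d0 = std::min(c0[v], c1[v] + 1); // parent 0 -> child 0 or 1
      int d1 = (criterion == 1) ? c1[v]    // parent 1 -> child must stay 1
                                : std::min(c1[v], c0[v] + 1);
      c0[p] = std::min(c0[p] + d0, BIG);
      c1[p] = std::min(c1[p] + d1, BIG);
    }
    out[ch] = c0[root]; // root fixed ancestral
  }
  return out;
}

// ---------------------------------------------------------------------------
// Internal tree structure for search: ntax leaves 0..ntax-1, rooted at the
// all-ancestral leaf `root` (degree 1, its single child in ch1).  Internal
// nodes are ntax..2*ntax-3.

struct PTree {
  int ntax;
  int root;
  std::vector<int> par, ch1, ch2;
  PTree() : ntax(0), root(-1) {}
  PTree(int n, int r) : ntax(n), root(r),
    par(2 * n - 2, -1), ch1(2 * n - 2, -1), ch2(2 * n - 2, -1) {}
};

static inline void replace_child(PTree &t, int p, int oldc, int newc) {
  if (p == t.root) { t.ch1[p] = newc; return; }
  if (t.ch1[p] == oldc) t.ch1[p] = newc; else t.ch2[p] = newc;
}

// insert leaf x above node c0 using fresh internal node w
static inline void insert_leaf(PTree &t, int x, int c0, int w) {
  int p = t.par[c0];
  replace_child(t, p, c0, w);
  t.par[w] = p; t.ch1[w] = c0; t.ch2[w] = x;
  t.par[c0] = w; t.par[x] = w;
}

// undo insert_leaf(x, c0, w)
static inline void remove_leaf(PTree &t, int x, int c0, int w) {
  int p = t.par[w];
  replace_child(t, p, w, c0);
  t.par[c0] = p;
  t.par[x] = -1; t.par[w] = -1; t.ch1[w] = -1; t.ch2[w] = -1;
}

// deterministic preorder edge enumeration; edges identified by child node
static void edge_list(const PTree &t, std::vector<int> &edges) {
  edges.clear();
  std::vector<int> stack;
  stack.push_back(t.ch1[t.root]);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    edges.push_back(v);
    if (t.ch1[v] >= 0 && v != t.root) {
      stack.push_back(t.ch2[v]);
      stack.push_back(t.ch1[v]);
    }
  }
}

static void postorder_nodes(const PTree &t, std::vector<int> &po) {
  po.clear();
  std::vector<int> stack;
  stack.push_back(t.ch1[t.root]);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    po.push_back(v);
    if (t.ch1[v] >= 0) {
      stack.push_back(t.ch1[v]);
      stack.push_back(t.ch2[v]);
    }
  }
  std::reverse(po.begin(), po.end());
}

// score the tree; stop early once the accumulated length exceeds cutoff
static long score_tree(const PTree &t, const IntegerMatrix &states,
                       const IntegerVector &weights, int criterion,
                       long cutoff,
                       std::vector<int> &po, std::vector<int> &c0,
                       std::vector<int> &c1) {
  postorder_nodes(t, po);
  int nchar = states.ncol();
  long total = 0;
  for (int ch = 0; ch < nchar; ch++) {
    for (size_t i = 0; i < po.size(); i++) {
      int v = po[i];
      if (t.ch1[v] < 0) { // leaf
        int s = states(v, ch);
        if (s == NA_INTEGER) { c0[v] = 0; c1[v] = 0; }
        else if (s == 0)     { c0[v] = 0; c1[v] = BIG; }
        else                 { c0[v] = BIG; c1[v] = 0; }
      } else {
        int a = t.ch1[v], b = t.ch2[v];
        int a0 = std::min(c0[a], c1[a] + 1);
        int b0 = std::min(c0[b], c1[b] + 1);
        int a1 = (criterion == 1) ? c1[a] : std::min(c1[a], c0[a] + 1);
        int b1 = (criterion == 1) ? c1[b] : std::min(c1[b], c0[b] + 1);
        c0[v] = std::min(a0 + b0, BIG);
        c1[v] = std::min(a1 + b1, BIG);
      }
    }
    // root is the ancestral leaf: state 0, transition to its single child
    int u = t.ch1[t.root];
    int len = std::min(c0[u], c1[u] + 1);
    total += (long)len * weights[ch];
    if (total > cutoff) return total;
  }
  return total;
}

static std::string leaf_label(int v) {
  char buf[16];
  std::snprintf(buf, sizeof(buf), "t%06d", v + 1);
  return std::string(buf);
}

static std::string canon_subtree(const PTree &t, int v) {
  if (t.ch1[v] < 0) return leaf_label(v);
  std::string a = canon_subtree(t, t.ch1[v]);
  std::string b = canon_subtree(t, t.ch2[v]);
  if (b < a) std::swap(a, b);
  return "(" + a + "," + b + ")";
}

// rooted on the ancestral leaf's pendant edge
static std::string tree_newick(const PTree &t) {
  return "(" + leaf_label(t.root) + "," + canon_subtree(t, t.ch1[t.root]) +
         ");";
}

// ---------------------------------------------------------------------------
// Exhaustive enumeration with branch-and-bound.

struct BabState {
  const IntegerMatrix *states;
  const IntegerVector *weights;
  int criterion;
  int max_trees;
  bool prune;
  long best;
  long n_complete;
  bool overflow; // more ties than max_trees
  std::vector<std::string> trees;
  std::vector<int> order;
  std::vector<int> po, c0, c1;
};

static void bab_recurse(PTree &t, size_t k, BabState &st) {
  long cutoff = st.prune ? st.best : (long)BIG;
  long len = score_tree(t, *st.states, *st.weights, st.criterion, cutoff,
                        st.po, st.c0, st.c1);
  if (st.prune && len > st.best) return;
  if (k == st.order.size()) {
    st.n_complete++;
    if (len < st.best) {
      st.best = len;
      st.trees.clear();
      st.overflow = false;
    }
    if (len == st.best) {
      if ((int)st.trees.size() < st.max_trees) st.trees.push_back(tree_newick(t));
      else st.overflow = true;
    }
    return;
  }
  int x = st.order[k];
  int w = t.ntax + (int)k + 1; // fresh internal node (ntax used by the seed)
  std::vector<int> edges;
  edge_list(t, edges);
  for (size_t i = 0; i < edges.size(); i++) {
    insert_leaf(t, x, edges[i], w);
    bab_recurse(t, k + 1, st);
    remove_leaf(t, x, edges[i], w);
  }
}

// [[Rcpp::export]]
List cpp_bab(IntegerMatrix states, IntegerVector weights, int root0,
             IntegerVector order0, int criterion, int max_trees,
             int init_bound, bool prune) {
  int ntax = states.nrow();
  PTree t(ntax, root0);
  BabState st;
  st.states = &states; st.weights = &weights;
  st.criterion = criterion; st.max_trees = max_trees;
  st.prune = prune; st.best = init_bound; st.n_complete = 0;
  st.overflow = false;
  for (int i = 3; i < order0.size(); i++) st.order.push_back(order0[i]);
  st.po.reserve(2 * ntax); st.c0.resize(2 * ntax); st.c1.resize(2 * ntax);
  // initial 3-taxon tree: root leaf + cherry of the next two
  int w = ntax;
  t.ch1[root0] = w; t.par[w] = root0;
  t.ch1[w] = order0[1]; t.ch2[w] = order0[2];
  t.par[order0[1]] = w; t.par[order0[2]] = w;
  bab_recurse(t, 0, st); // st.order holds the taxa still to add
  return List::create(_["trees"] = wrap(st.trees),
                      _["best"] = (int)st.best,
                      _["n_complete"] = (double)st.n_complete,
                      _["tie_overflow"] = st.overflow);
}

// ---------------------------------------------------------------------------
// Heuristic: stepwise addition, then branch swapping (NNI or SPR) with
// plateau collection of equally parsimonious topologies.

static PTree copy_tree(const PTree &t) { return t; }

typedef std::vector<PTree> TreeVec;

static void nni_neighbors(const PTree &t, TreeVec &out) {
  out.clear();
  int nnode = 2 * t.ntax - 2;
  for (int c = t.ntax; c < nnode; c++) {
    int p = t.par[c];
    if (p < 0 || p == t.root) continue; // pendant/root edge: no NNI
    if (p < t.ntax) continue;           // parent is a leaf only for root
    if (t.ch1[c] < 0) continue;         // c must be internal
    int b = (t.ch1[p] == c) ? t.ch2[p] : t.ch1[p];
    for (int which = 0; which < 2; which++) {
      PTree nt = copy_tree(t);
      int x = (which == 0) ? nt.ch1[c] : nt.ch2[c];
      // swap subtrees b (sibling of c) and x (child of c)
      if (nt.ch1[p] == b) nt.ch1[p] = x; else nt.ch2[p] = x;
      if (which == 0) nt.ch1[c] = b; else nt.ch2[c] = b;
      nt.par[x] = p; nt.par[b] = c;
      out.push_back(nt);
    }
  }
}

static void subtree_nodes(const PTree &t, int v, std::vector<bool> &inside) {
  std::fill(inside.begin(), inside.end(), false);
  std::vector<int> stack(1, v);
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    inside[u] = true;
    if (t.ch1[u] >= 0 && u != t.root) {
      stack.push_back(t.ch1[u]);
      stack.push_back(t.ch2[u]);
    }
  }
}

static void spr_neighbors(const PTree &t, TreeVec &out) {
  out.clear();
  int nnode = 2 * t.ntax - 2;
  std::vector<bool> inside(nnode);
  for (int v = 0; v < nnode; v++) {
    if (v == t.root || t.par[v] < 0) continue;
    if (v == t.ch1[t.root]) continue; // pruning it would empty the ingroup
    int w = t.par[v];
    subtree_nodes(t, v, inside);
    std::vector<int> edges;
    edge_list(t, edges);
    for (size_t i = 0; i < edges.size(); i++) {
      int u = edges[i];
      if (inside[u] || u == w) continue;
      PTree nt = copy_tree(t);
      int s = (nt.ch1[w] == v) ? nt.ch2[w] : nt.ch1[w];
      int p = nt.par[w];
      replace_child(nt, p, w, s);
      nt.par[s] = p;
      if (u == s && nt.par[s] == p) {
        // regrafting onto the spliced sibling edge recreates t; still valid
      }
      int q = nt.par[u];
      replace_child(nt, q, u, w);
      nt.par[w] = q; nt.ch1[w] = u; nt.ch2[w] = v;
      nt.par[u] = w; nt.par[v] = w;
      out.push_back(nt);
    }
  }
}

// moving the ancestral root leaf to another ingroup edge: equivalent to the
// unrooted SPR of the root leaf, which the subtree moves above cannot reach
// (and which changes the Camin-Sokal length, since that criterion is
// root-dependent)
static void reroot_moves(const PTree &t, TreeVec &out) {
  int c0 = t.ch1[t.root];
  if (c0 < t.ntax || t.ch1[c0] < 0) return; // ingroup root is a leaf
  int a = t.ch1[c0], b = t.ch2[c0];
  // undirected ingroup edges, with the degree-2 vertex c0 suppressed
  std::vector<std::pair<int, int> > ed;
  std::vector<int> stack;
  ed.push_back(std::make_pair(a, b));
  stack.push_back(a);
  stack.push_back(b);
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    if (t.ch1[v] >= 0 && v != t.root) {
      ed.push_back(std::make_pair(v, t.ch1[v]));
      ed.push_back(std::make_pair(v, t.ch2[v]));
      stack.push_back(t.ch1[v]);
      stack.push_back(t.ch2[v]);
    }
  }
  int nnode = 2 * t.ntax - 2;
  for (size_t f = 1; f < ed.size(); f++) { // f = 0 recreates t
    // adjacency with c0 re-used to subdivide edge f
    std::vector<std::vector<int> > adj(nnode);
    for (size_t i = 0; i < ed.size(); i++) {
      if (i == f) continue;
      adj[ed[i].first].push_back(ed[i].second);
      adj[ed[i].second].push_back(ed[i].first);
    }
    adj[c0].push_back(ed[f].first);
    adj[c0].push_back(ed[f].second);
    adj[ed[f].first].push_back(c0);
    adj[ed[f].second].push_back(c0);
    PTree nt(t.ntax, t.root);
    nt.ch1[t.root] = c0;
    nt.par[c0] = t.root;
    std::vector<int> st2;
    st2.push_back(c0);
    while (!st2.empty()) {
      int v = st2.back(); st2.pop_back();
      int slot = 0;
      for (size_t i = 0; i < adj[v].size(); i++) {
        int u = adj[v][i];
        if (u == nt.par[v]) continue;
        if (slot == 0) nt.ch1[v] = u; else nt.ch2[v] = u;
        slot++;
        nt.par[u] = v;
        if (t.ch1[u] >= 0 || u == c0) st2.push_back(u);
      }
      if (v != c0 && t.ch1[v] >= 0 && slot == 0) { /* leaf-like: done */ }
    }
    out.push_back(nt);
  }
}

// neighbor newicks of an ape-coded tree; for cross-validation of the
// rearrangement neighborhoods in tests. anc0: 0-based tip index of the
// ancestor leaf (the rooting point). swap: 1 = NNI, 2 = SPR (+ reroot).
// [[Rcpp::export]]
CharacterVector cpp_phylo_neighbors(IntegerMatrix edge, int ntip, int anc0,
                                    int swap) {
  int nnode_ape = ntip;
  for (int i = 0; i < edge.nrow(); i++)
    nnode_ape = std::max(nnode_ape, std::max(edge(i, 0), edge(i, 1)));
  PTree t(ntip, anc0);
  int ape_root = ntip + 1;
  // ape internal j (> ntip+1) -> ntip + (j - ntip - 2); the ape root node is
  // dropped (the tree is re-rooted at the ancestor leaf)
  std::vector<int> map(nnode_ape + 1, -1);
  for (int v = 1; v <= ntip; v++) map[v] = v - 1;
  int nxt = ntip;
  for (int v = ntip + 2; v <= nnode_ape; v++) map[v] = nxt++;
  int other = -1; // the ape root's non-ancestor child
  for (int i = 0; i < edge.nrow(); i++) {
    int p = edge(i, 0), v = edge(i, 1);
    if (p == ape_root) {
      if (map[v] == anc0) continue;
      if (other >= 0) stop("ape root must have exactly 2 children");
      other = map[v];
    } else {
      int pm = map[p], vm = map[v];
      t.par[vm] = pm;
      if (t.ch1[pm] < 0) t.ch1[pm] = vm; else t.ch2[pm] = vm;
    }
  }
  t.ch1[anc0] = other;
  t.par[other] = anc0;
  TreeVec nbs;
  if (swap == 1) nni_neighbors(t, nbs);
  else {
    spr_neighbors(t, nbs);
    TreeVec rr;
    reroot_moves(t, rr);
    for (size_t i = 0; i < rr.size(); i++) nbs.push_back(rr[i]);
  }
  CharacterVector out(nbs.size());
  for (size_t i = 0; i < nbs.size(); i++) out[i] = tree_newick(nbs[i]);
  return out;
}

static void gen_neighbors(const PTree &t, int swap, TreeVec &nbs) {
  if (swap == 1) nni_neighbors(t, nbs);
  else {
    spr_neighbors(t, nbs);
    TreeVec rr;
    reroot_moves(t, rr);
    for (size_t q = 0; q < rr.size(); q++) nbs.push_back(rr[q]);
  }
}

// first-improvement hill climb to a local optimum; returns the final length
static long hill_climb(PTree &t, const IntegerMatrix &states,
                       const IntegerVector &w, int crit, int swap,
                       std::vector<int> &po, std::vector<int> &c0,
                       std::vector<int> &c1) {
  long cur = score_tree(t, states, w, crit, (long)BIG * 1000, po, c0, c1);
  bool improved = true;
  TreeVec nbs;
  while (improved) {
    improved = false;
    gen_neighbors(t, swap, nbs);
    for (size_t j = 0; j < nbs.size(); j++) {
      long len = score_tree(nbs[j], states, w, crit, cur, po, c0, c1);
      if (len < cur) {
        t = nbs[j];
        cur = len;
        improved = true;
        break;
      }
    }
  }
  return cur;
}

// [[Rcpp::export]]
List cpp_search(IntegerMatrix states, IntegerVector weights, int root0,
                IntegerVector order0, int criterion, int max_trees,
                int swap, IntegerMatrix ratchet_w) {
  int ntax = states.nrow();
  std::vector<int> po; po.reserve(2 * ntax);
  std::vector<int> c0(2 * ntax), c1(2 * ntax);
  PTree t(ntax, root0);
  int w = ntax;
  t.ch1[root0] = w; t.par[w] = root0;
  t.ch1[w] = order0[1]; t.ch2[w] = order0[2];
  t.par[order0[1]] = w; t.par[order0[2]] = w;
  // stepwise addition: each taxon at the first placement of minimal length
  for (int k = 3; k < ntax; k++) {
    int x = order0[k];
    int nw = ntax + k - 2;
    std::vector<int> edges;
    edge_list(t, edges);
    long bestlen = BIG;
    int bestedge = -1;
    for (size_t i = 0; i < edges.size(); i++) {
      insert_leaf(t, x, edges[i], nw);
      long len = score_tree(t, states, weights, criterion, bestlen, po, c0, c1);
      remove_leaf(t, x, edges[i], nw);
      if (len < bestlen) { bestlen = len; bestedge = (int)i; }
    }
    insert_leaf(t, x, edges[bestedge], nw);
  }
  long best = score_tree(t, states, weights, criterion, (long)BIG * 1000,
                         po, c0, c1);
  if (swap > 0) {
    best = hill_climb(t, states, weights, criterion, swap, po, c0, c1);
    // parsimony ratchet: re-optimize under perturbed character weights,
    // then under the true weights; accept ties to drift between optima
    PTree tbest = t;
    long cur = best;
    for (int it = 0; it < ratchet_w.ncol(); it++) {
      IntegerVector wp = ratchet_w(_, it);
      PTree t2 = t;
      hill_climb(t2, states, wp, criterion, swap, po, c0, c1);
      long len = hill_climb(t2, states, weights, criterion, swap, po, c0, c1);
      if (len <= cur) { t = t2; cur = len; }
      if (len < best) { tbest = t2; best = len; }
    }
    t = tbest;
  }
  std::vector<PTree> kept;
  std::vector<std::string> keptnwk;
  std::set<std::string> seen;
  kept.push_back(t);
  keptnwk.push_back(tree_newick(t));
  seen.insert(keptnwk[0]);
  if (swap > 0) {
    bool restart = true;
    while (restart) {
      restart = false;
      std::deque<size_t> queue;
      for (size_t i = 0; i < kept.size(); i++) queue.push_back(i);
      TreeVec nbs;
      while (!queue.empty() && (int)kept.size() < max_trees + 1) {
        size_t idx = queue.front(); queue.pop_front();
        PTree cur = kept[idx];
        if (swap == 1) nni_neighbors(cur, nbs);
        else {
          spr_neighbors(cur, nbs);
          TreeVec rr;
          reroot_moves(cur, rr);
          for (size_t q = 0; q < rr.size(); q++) nbs.push_back(rr[q]);
        }
        for (size_t j = 0; j < nbs.size(); j++) {
          long len = score_tree(nbs[j], states, weights, criterion, best,
                                po, c0, c1);
          if (len < best) {
            best = len;
            kept.clear(); keptnwk.clear(); seen.clear();
            kept.push_back(nbs[j]);
            keptnwk.push_back(tree_newick(nbs[j]));
            seen.insert(keptnwk[0]);
            restart = true;
            break;
          } else if (len == best && (int)kept.size() < max_trees) {
            std::string nwk = tree_newick(nbs[j]);
            if (seen.insert(nwk).second) {
              kept.push_back(nbs[j]);
              keptnwk.push_back(nwk);
              queue.push_back(kept.size() - 1);
            }
          }
        }
        if (restart) break;
      }
    }
  }
  if ((int)kept.size() > max_trees) {
    kept.resize(max_trees);
    keptnwk.resize(max_trees);
  }
  return List::create(_["trees"] = wrap(keptnwk), _["best"] = (int)best);
}
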