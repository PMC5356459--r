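// Decremental dynamic connectivity, Holm-de Lichtenberg-Thorup (HDT)
// scheme: a hierarchy of spanning forests F_0 >= F_1 >= ... where F_i
// spans the subgraph of edges with level >= i, each forest stored as
// Euler-tour sequences in randomized treaps.  Supports edge insertion,
// edge deletion with split detection in O(log^2 N) amortized, plus
// component size and member enumeration.
//
// Treap-node augmentation:
//   cnt     -- number of vertex-occurrence nodes below (component size)
//   subTree -- some arc below belongs to a tree edge of level == forest level
//   subNT   -- some vertex below has nontree edges at this level
//
// Each vertex occurs once per Euler tour; each tree edge contributes two
// arc nodes per forest it belongs to.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>

namespace {

struct Node {
  Node *l = nullptr, *r = nullptr, *p = nullptr;
  uint32_t pri = 0;
  int sz = 1;              // total nodes in subtree
  int cnt = 0;             // vertex nodes in subtree
  bool isVertex = false;
  int vid = -1;            // vertex id (vertex nodes)
  long long ekey = -1;     // edge key (arc nodes)
  bool treeFlag = false, subTree = false;
  bool ntFlag = false, subNT = false;
};

inline int sz(Node* x) { return x ? x->sz : 0; }
inline int cnt(Node* x) { return x ? x->cnt : 0; }
inline bool sTree(Node* x) { return x && x->subTree; }
inline bool sNT(Node* x) { return x && x->subNT; }

inline void pull(Node* x) {
  x->sz = 1 + sz(x->l) + sz(x->r);
  x->cnt = (x->isVertex ? 1 : 0) + cnt(x->l) + cnt(x->r);
  x->subTree = x->treeFlag || sTree(x->l) || sTree(x->r);
  x->subNT = x->ntFlag || sNT(x->l) || sNT(x->r);
}

inline Node* troot(Node* x) { while (x->p) x = x->p; return x; }

inline void pull_up(Node* x) { for (; x; x = x->p) pull(x); }

Node* join(Node* a, Node* b) {
  if (!a) return b;
  if (!b) return a;
  if (a->pri > b->pri) {
    Node* m = join(a->r, b);
    a->r = m; if (m) m->p = a; pull(a);
    return a;
  } else {
    Node* m = join(a, b->l);
    b->l = m; if (m) m->p = b; pull(b);
    return b;
  }
}

// Split the sequence containing x into (A, B): A strictly before x,
// B starting at x.
std::pair<Node*, Node*> split_before(Node* x) {
  Node* A = x->l;
  if (A) A->p = nullptr;
  x->l = nullptr; pull(x);
  Node* B = x;
  Node* cur = x;
  Node* par = cur->p;
  cur->p = nullptr;
  while (par) {
    Node* gp = par->p;
    par->p = nullptr;
    if (par->r == cur) {      // par-part precedes x
      par->r = nullptr; pull(par);
      A = join(par, A);
    } else {                  // par-part follows x's block
      par->l = nullptr; pull(par);
      B = join(B, par);
    }
    cur = par; par = gp;
  }
  return {A, B};
}

// Split into (A, B): A ending at x, B strictly after x.
std::pair<Node*, Node*> split_after(Node* x) {
  Node* B = x->r;
  if (B) B->p = nullptr;
  x->r = nullptr; pull(x);
  Node* A = x;
  Node* cur = x;
  Node* par = cur->p;
  cur->p = nullptr;
  while (par) {
    Node* gp = par->p;
    par->p = nullptr;
    if (par->r == cur) {
      par->r = nullptr; pull(par);
      A = join(par, A);
    } else {
      par->l = nullptr; pull(par);
      B = join(B, par);
    }
    cur = par; par = gp;
  }
  return {A, B};
}

int order_of(Node* x) {
  int idx = sz(x->l);
  Node* cur = x;
  while (cur->p) {
    if (cur->p->r == cur) idx += sz(cur->p->l) + 1;
    cur = cur->p;
  }
  return idx;
}

struct Edge {
  int u, v;
  int level = 0;
  bool tree = false;
  std::vector<std::pair<Node*, Node*>> arcs;  // per forest 0..level (tree edges)
};

struct HDT {
  int n, L;
  uint64_t rng_state;
  std::vector<std::vector<Node*>> vnode;                       // [level][vertex]
  std::unordered_map<long long, Edge> edges;
  std::vector<std::unordered_map<int, std::unordered_set<int>>> nt;  // nontree adj per level
  long long n_insert = 0, n_delete = 0, n_splits = 0;

  explicit HDT(int n_) : n(n_) {
    rng_state = 0x9e3779b97f4a7c15ULL;
    L = 1; while ((1 << L) < std::max(n, 2)) ++L;
    vnode.assign(L + 1, std::vector<Node*>(n, nullptr));
    nt.assign(L + 1, {});
    for (int v = 0; v < n; ++v) getv(0, v);
  }
  ~HDT() {
    for (auto& lev : vnode)
      for (Node* nd : lev) delete nd;
    for (auto& kv : edges)
      for (auto& pr : kv.second.arcs) { delete pr.first; delete pr.second; }
  }

  uint32_t rnd() {
    rng_state ^= rng_state << 13; rng_state ^= rng_state >> 7;
    rng_state ^= rng_state << 17;
    return (uint32_t)(rng_state >> 32);
  }

  long long key(int u, int v) const {
    int a = std::min(u, v), b = std::max(u, v);
    return (long long)a * n + b;
  }

  Node* getv(int lev, int v) {
    Node*& nd = vnode[lev][v];
    if (!nd) {
      nd = new Node();
      nd->pri = rnd(); nd->isVertex = true; nd->vid = v;
      pull(nd);
    }
    return nd;
  }

  void reroot(int lev, int v) {
    Node* x = vnode[lev][v];
    auto ab = split_before(x);
    join(ab.second, ab.first);
  }

  Node* new_arc(long long k, bool flagged) {
    Node* a = new Node();
    a->pri = rnd(); a->ekey = k; a->treeFlag = flagged;
    pull(a);
    return a;
  }

  // Link u and v in forest `lev` with arcs for edge e.
  void link_at(int lev, Edge& e, bool flagged) {
    Node* nu = getv(lev, e.u);
    Node* nv = getv(lev, e.v);
    reroot(lev, e.u); reroot(lev, e.v);
    long long k = key(e.u, e.v);
    Node* a = new_arc(k, flagged);
    Node* b = new_arc(k, flagged);
    e.arcs[lev] = {a, b};
    join(join(join(troot(nu), a), troot(nv)), b);
  }

  void cut_at(int lev, Edge& e) {
    Node* a = e.arcs[lev].first;
    Node* b = e.arcs[lev].second;
    if (order_of(a) > order_of(b)) std::swap(a, b);
    // a precedes b in the tour
    auto pq = split_before(a);   // pq.first = P, pq.second = [a .. end]
    auto qr = split_after(b);    // applied to the part containing b
    // qr.first = [a .. b], qr.second = R (rest after b)
    auto inner1 = split_after(a);    // on [a..b]: ([a], [.. b])
    auto inner2 = split_before(b);   // on [.. b]: (inner, [b])
    delete a; delete b;
    e.arcs[lev] = {nullptr, nullptr};
    join(pq.first, qr.second);
    (void)inner1; (void)inner2;   // inner2.first is the detached subtree
  }

  void set_ntflag(int lev, int v) {
    bool want = !nt[lev][v].empty();
    Node* nd = getv(lev, v);
    if (nd->ntFlag != want) { nd->ntFlag = want; pull_up(nd); }
  }

  void nt_add(int lev, int u, int v) {
    nt[lev][u].insert(v); nt[lev][v].insert(u);
    set_ntflag(lev, u); set_ntflag(lev, v);
  }
  void nt_remove(int lev, int u, int v) {
    nt[lev][u].erase(v); nt[lev][v].erase(u);
    set_ntflag(lev, u); set_ntflag(lev, v);
  }

  bool connected_at(int lev, int u, int v) {
    Node* a = vnode[lev][u]; Node* b = vnode[lev][v];
    if (!a || !b) return false;
    return troot(a) == troot(b);
  }

  void insert(int u, int v) {
    long long k = key(u, v);
    if (edges.count(k)) return;       // duplicate insert is a no-op
    Edge e; e.u = u; e.v = v; e.level = 0;
    if (!connected_at(0, u, v)) {
      e.tree = true;
      e.arcs.assign(1, {nullptr, nullptr});
      edges.emplace(k, std::move(e));
      link_at(0, edges[k], true);
    } else {
      e.tree = false;
      edges.emplace(k, std::move(e));
      nt_add(0, u, v);
    }
    ++n_insert;
  }

  Node* find_tree_arc(Node* t) {
    while (true) {
      if (t->l && t->l->subTree) { t = t->l; continue; }
      if (t->treeFlag) return t;
      t = t->r;
    }
  }
  Node* find_nt_vertex(Node* t) {
    while (true) {
      if (t->l && t->l->subNT) { t = t->l; continue; }
      if (t->ntFlag) return t;
      t = t->r;
    }
  }

  // Returns true if the deletion split a component.
  bool remove(int u, int v) {
    long long k = key(u, v);
    auto it = edges.find(k);
    if (it == edges.end()) Rcpp::stop("cannot delete: edge not present");
    Edge e = std::move(it->second);
    edges.erase(it);
    ++n_delete;
    if (!e.tree) {
      nt_remove(e.level, e.u, e.v);
      return false;
    }
    int lev = e.level;
    for (int i = 0; i <= lev; ++i) cut_at(i, e);
    for (int i = lev; i >= 0; --i) {
      Node* ru = troot(vnode[i][u]);
      Node* rv = troot(vnode[i][v]);
      if (ru->cnt > rv->cnt) std::swap(ru, rv);
      // raise level-i tree edges of the smaller side to i+1
      while (ru->subTree) {
        Node* arc = find_tree_arc(ru);
        Edge& f = edges[arc->ekey];
        Node* a1 = f.arcs[i].first;
        Node* a2 = f.arcs[i].second;
        a1->treeFlag = false; pull_up(a1);
        a2->treeFlag = false; pull_up(a2);
        f.level = i + 1;
        f.arcs.resize(i + 2, {nullptr, nullptr});
        link_at(i + 1, f, true);
        ru = troot(ru);
      }
      // scan level-i nontree edges of the smaller side
      bool replaced = false;
      while (ru->subNT) {
        Node* xn = find_nt_vertex(ru);
        int x = xn->vid;
        auto& sx = nt[i][x];
        while (!sx.empty()) {
          int y = *sx.begin();
          Node* ry = troot(vnode[i][y]);
          if (ry == rv) {
            // replacement found: promote (x, y) to a tree edge in F_0..F_i
            nt_remove(i, x, y);
            Edge& g = edges[key(x, y)];
            g.tree = true;
            g.arcs.assign(i + 1, {nullptr, nullptr});
            for (int j = 0; j <= i; ++j) link_at(j, g, j == i);
            replaced = true;
            break;
          } else {
            // both endpoints on the smaller side: raise to level i+1
            nt_remove(i, x, y);
            nt_add(i + 1, x, y);
            edges[key(x, y)].level = i + 1;
          }
        }
        if (replaced) break;
        ru = troot(ru);
      }
      if (replaced) return false;
    }
    ++n_splits;
    return true;
  }

  int comp_size(int v) { return troot(vnode[0][v])->cnt; }

  void collect(Node* t, std::vector<int>& out) {
    std::vector<Node*> stack{t};
    while (!stack.empty()) {
      Node* x = stack.back(); stack.pop_back();
      if (x->isVertex) out.push_back(x->vid);
      if (x->l) stack.push_back(x->l);
      if (x->r) stack.push_back(x->r);
    }
  }

  std::vector<int> members(int v) {
    std::vector<int> out;
    collect(troot(vnode[0][v]), out);
    return out;
  }
};

void check_vertex(HDT* h, int v) {
  if (v < 1 || v > h->n) Rcpp::stop("vertex id out of range: %d", v);
}

HDT* get(SEXP p) {
  Rcpp::XPtr<HDT> ptr(p);
  return ptr.get();
}

}  // namespace

// [[Rcpp::export]]
SEXP hdt_new(int n) {
  if (n < 1) Rcpp::stop("need at least one vertex");
  Rcpp::XPtr<HDT> ptr(new HDT(n), true);
  return ptr;
}

// [[Rcpp::export]]
void hdt_insert(SEXP p, int u, int v) {
  HDT* h = get(p);
  check_vertex(h, u); check_vertex(h, v);
  if (u == v) Rcpp::stop("self-loops are not allowed");
  h->insert(u - 1, v - 1);
}

// [[Rcpp::export]]
Rcpp::List hdt_delete(SEXP p, int u, int v) {
  HDT* h = get(p);
  check_vertex(h, u); check_vertex(h, v);
  bool split = h->remove(u - 1, v - 1);
  if (!split) return Rcpp::List::create(Rcpp::Named("split") = false);
  return Rcpp::List::create(
    Rcpp::Named("split") = true,
    Rcpp::Named("size_u") = h->comp_size(u - 1),
    Rcpp::Named("size_v") = h->comp_size(v - 1));
}

// [[Rcpp::export]]
bool hdt_connected(SEXP p, int u, int v) {
  HDT* h = get(p);
  check_vertex(h, u); check_vertex(h, v);
  if (u == v) return true;
  return h->connected_at(0, u - 1, v - 1);
}

// [[Rcpp::export]]
int hdt_size(SEXP p, int v) {
  HDT* h = get(p);
  check_vertex(h, v);
  return h->comp_size(v - 1);
}

// [[Rcpp::export]]
Rcpp::IntegerVector hdt_members(SEXP p, int v) {
  HDT* h = get(p);
  check_vertex(h, v);
  std::vector<int> m = h->members(v - 1);
  Rcpp::IntegerVector out(m.size());
  for (size_t i = 0; i < m.size(); ++i) out[i] = m[i] + 1;
  return out;
}

// [[Rcpp::export]]
bool hdt_has_edge(SEXP p, int u, int v) {
  HDT* h = get(p);
  check_vertex(h, u); check_vertex(h, v);
  return h->edges.count(h->key(u - 1, v - 1)) > 0;
}

// [[Rcpp::export]]
Rcpp::List hdt_stats(SEXP p) {
  HDT* h = get(p);
  return Rcpp::List::create(
    Rcpp::Named("n_insert") = (double)h->n_insert,
    Rcpp::Named("n_delete") = (double)h->n_delete,
    Rcpp::Named("n_splits") = (double)h->n_splits,
    Rcpp::Named("n_edges") = (double)h->edges.size());
}
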