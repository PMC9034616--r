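// Core graph engine: equitable refinement, canonical labelling by
// individualization-refinement, explicit automorphism enumeration, and
// isomorph-free generation of connected simple graphs by canonical
// augmentation (vertices are added one at a time; a graph is accepted only if
// it is reached along its canonical construction path).
//
// Graphs are limited to 32 vertices; adjacency is kept as one 32-bit mask per
// vertex.  Heavy-atom skeletons of small molecules are far below this bound.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <set>
#include <algorithm>
using namespace Rcpp;

typedef uint32_t bits;

static inline int popcnt(bits x) { return __builtin_popcount(x); }
static inline int ctz(bits x) { return __builtin_ctz(x); }

static const int MAXN = 32;

// order-preserving remap of arbitrary integer colours to dense ranks 0..k-1
static void densify(std::vector<int> &col) {
  std::vector<int> sorted = col;
  std::sort(sorted.begin(), sorted.end());
  sorted.erase(std::unique(sorted.begin(), sorted.end()), sorted.end());
  for (size_t v = 0; v < col.size(); v++)
    col[v] = (int)(std::lower_bound(sorted.begin(), sorted.end(), col[v]) -
                   sorted.begin());
}

// ---------------------------------------------------------------------------
// Equitable refinement (1-dimensional Weisfeiler-Leman).
//
// col[] is refined in place to dense cell ids 0..k-1; cells are ordered by id
// and the ordering is isomorphism-invariant because new ids are assigned from
// sorted (old id, neighbour-count vector) keys.
// ---------------------------------------------------------------------------
static void refine(int n, const bits *adj, std::vector<int> &col) {
  densify(col);
  int ncell = 0;
  for (int v = 0; v < n; v++) ncell = std::max(ncell, col[v] + 1);
  for (;;) {
    if (ncell == n) return;
    std::vector<std::vector<int>> key(n);
    for (int v = 0; v < n; v++) {
      std::vector<int> k(ncell + 1, 0);
      k[0] = col[v];
      bits nb = adj[v];
      while (nb) { int u = ctz(nb); nb &= nb - 1; k[1 + col[u]]++; }
      key[v] = std::move(k);
    }
    std::vector<int> idx(n);
    for (int v = 0; v < n; v++) idx[v] = v;
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) { return key[a] < key[b]; });
    int c = 0;
    std::vector<int> newcol(n);
    for (int i = 0; i < n; i++) {
      if (i > 0 && key[idx[i]] != key[idx[i - 1]]) c++;
      newcol[idx[i]] = c;
    }
    int newncell = c + 1;
    col.swap(newcol);
    if (newncell == ncell) return;  // no cell split: partition is equitable
    ncell = newncell;
  }
}

// ---------------------------------------------------------------------------
// Canonical labelling search.
//
// Branches on the first non-singleton cell; prunes a branch only when an
// already-discovered automorphism fixing the individualized prefix pointwise
// maps its vertex onto one already tried at the same node.  Every leaf whose
// encoding ties the current best (or the first leaf) yields an automorphism;
// the union-find over the discovered generators gives the vertex orbits.
// ---------------------------------------------------------------------------
struct CanonSearch {
  int n;
  const bits *adj;
  std::vector<std::vector<int>> gens;   // automorphism generators (0-based)
  std::vector<int> uf;
  std::vector<bits> bestEnc, firstEnc;
  std::vector<int> bestLab, firstLab;   // lab[v] = canonical position of v
  bool haveFirst = false;
  std::vector<int> prefix;

  int find(int x) {
    while (uf[x] != x) { uf[x] = uf[uf[x]]; x = uf[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) uf[std::max(a, b)] = std::min(a, b);
  }

  void encode(const std::vector<int> &lab, std::vector<bits> &enc) {
    enc.assign(n, 0);
    for (int v = 0; v < n; v++) {
      bits nb = adj[v];
      while (nb) { int u = ctz(nb); nb &= nb - 1; enc[lab[v]] |= (bits(1) << lab[u]); }
    }
  }

  void add_automorphism(const std::vector<int> &labA, const std::vector<int> &labB) {
    // labA, labB: two labellings with equal encodings; v -> labB^{-1}(labA(v))
    std::vector<int> invB(n), g(n);
    for (int v = 0; v < n; v++) invB[labB[v]] = v;
    bool ident = true;
    for (int v = 0; v < n; v++) {
      g[v] = invB[labA[v]];
      if (g[v] != v) ident = false;
    }
    if (ident) return;
    for (int v = 0; v < n; v++) unite(v, g[v]);
    gens.push_back(g);
  }

  void leaf(const std::vector<int> &col) {
    std::vector<int> lab = col;  // discrete partition: colour = position
    std::vector<bits> enc;
    encode(lab, enc);
    if (!haveFirst) {
      firstEnc = enc; firstLab = lab; haveFirst = true;
      bestEnc = enc; bestLab = lab;
      return;
    }
    if (enc == bestEnc) { add_automorphism(lab, bestLab); return; }
    if (enc == firstEnc) { add_automorphism(lab, firstLab); return; }
    if (enc > bestEnc) { bestEnc = enc; bestLab = lab; }
  }

  // true iff v is mapped onto an already-tried vertex by the subgroup
  // generated by the discovered automorphisms fixing `prefix` pointwise
  bool pruned(int v, const std::vector<int> &tried) {
    if (gens.empty() || tried.empty()) return false;
    std::vector<const std::vector<int> *> fix;
    for (auto &g : gens) {
      bool ok = true;
      for (int p : prefix) if (g[p] != p) { ok = false; break; }
      if (ok) fix.push_back(&g);
    }
    if (fix.empty()) return false;
    bits orb = bits(1) << v, tr = 0;
    for (int t : tried) tr |= bits(1) << t;
    for (;;) {
      bits nxt = orb;
      for (auto *g : fix) {
        bits o = orb;
        while (o) {
          int u = ctz(o); o &= o - 1;
          nxt |= bits(1) << (*g)[u];
          for (int w = 0; w < n; w++)       // pre-images, for group closure
            if ((*g)[w] == u) nxt |= bits(1) << w;
        }
      }
      if (nxt == orb) break;
      orb = nxt;
    }
    return (orb & tr) != 0;
  }

  void search(std::vector<int> col) {
    refine(n, adj, col);
    std::vector<int> cnt(n, 0);
    for (int v = 0; v < n; v++) cnt[col[v]]++;
    int target = -1;
    for (int c = 0; c < n; c++) if (cnt[c] >= 2) { target = c; break; }
    if (target < 0) { leaf(col); return; }
    std::vector<int> members, tried;
    for (int v = 0; v < n; v++) if (col[v] == target) members.push_back(v);
    for (int v : members) {
      if (pruned(v, tried)) continue;
      tried.push_back(v);
      prefix.push_back(v);
      std::vector<int> col2(n);
      for (int u = 0; u < n; u++) col2[u] = 2 * col[u] + 1;
      col2[v] = 2 * target;   // v becomes a singleton cell before its old cell
      search(col2);
      prefix.pop_back();
    }
  }

  void run(const std::vector<int> &col0) {
    uf.resize(n);
    for (int v = 0; v < n; v++) uf[v] = v;
    search(col0);
  }
};

// ---------------------------------------------------------------------------
// Explicit enumeration of colour-preserving automorphisms.
// ---------------------------------------------------------------------------
struct AutEnum {
  int n;
  const bits *adj;
  std::vector<int> rcol;             // refined colours (invariant, so safe)
  std::vector<int> img;
  bits used = 0;
  long long count = 0, cap;
  bool overflow = false;
  std::vector<std::vector<int>> *out;  // may be null (count only)

  void rec(int v) {
    if (overflow) return;
    if (v == n) {
      count++;
      if (count > cap) { overflow = true; return; }
      if (out) out->push_back(img);
      return;
    }
    for (int u = 0; u < n; u++) {
      if ((used >> u) & 1) continue;
      if (rcol[u] != rcol[v]) continue;
      bool ok = true;
      for (int w = 0; w < v; w++) {
        bool a1 = (adj[v] >> w) & 1, a2 = (adj[u] >> img[w]) & 1;
        if (a1 != a2) { ok = false; break; }
      }
      if (!ok) continue;
      used |= bits(1) << u; img[v] = u;
      rec(v + 1);
      used &= ~(bits(1) << u);
      if (overflow) return;
    }
  }
};

static long long aut_enumerate(int n, const bits *adj, std::vector<int> col0,
                               long long cap, std::vector<std::vector<int>> *out,
                               bool *overflow) {
  AutEnum ae;
  ae.n = n; ae.adj = adj; ae.cap = cap; ae.out = out;
  ae.rcol = std::move(col0);
  refine(n, adj, ae.rcol);
  ae.img.assign(n, 0);
  ae.rec(0);
  if (overflow) *overflow = ae.overflow;
  return ae.count;
}

// ---------------------------------------------------------------------------
// Articulation points (cut vertices) of a connected graph.
// ---------------------------------------------------------------------------
struct Artic {
  const bits *adj;
  std::vector<int> disc, low;
  bits cuts = 0;
  int timer = 0;

  void dfs(int v, int parent) {
    disc[v] = low[v] = ++timer;
    int children = 0;
    bits nb = adj[v];
    while (nb) {
      int u = ctz(nb); nb &= nb - 1;
      if (!disc[u]) {
        children++;
        dfs(u, v);
        low[v] = std::min(low[v], low[u]);
        if (parent >= 0 && low[u] >= disc[v]) cuts |= bits(1) << v;
      } else if (u != parent) {
        low[v] = std::min(low[v], disc[u]);
      }
    }
    if (parent < 0 && children > 1) cuts |= bits(1) << v;
  }
};

static bits articulation_points(int n, const bits *adj) {
  Artic a;
  a.adj = adj;
  a.disc.assign(n, 0);
  a.low.assign(n, 0);
  a.dfs(0, -1);
  return a.cuts;
}

// ---------------------------------------------------------------------------
// Canonical augmentation generator.
// ---------------------------------------------------------------------------

// Colouring used for the flower-respecting subgroup N of the emitted graph:
// colour 0 for vertices not in flowers, colour i for the i-th lowest-numbered
// vertex of each flower (a flower = all degree-1 vertices sharing a
// neighbour; singleton flowers are allowed).
static void flower_colors(int n, const bits *adj, const int *deg,
                          std::vector<int> &col) {
  col.assign(n, 0);
  for (int c = 0; c < n; c++) {
    int pos = 0;
    for (int v = 0; v < n; v++)
      if (deg[v] == 1 && adj[v] == (bits(1) << c)) col[v] = ++pos;
  }
}

struct GenCtx {
  int n, minE, maxE, maxDeg;
  bool stats, collect;
  long long collectCap;
  Function *cb = nullptr;   // optional R callback, receives an m x 2 edge matrix
  long long autCap;
  double count = 0;
  double nTrivialN = 0;
  double maxN = 0;
  std::vector<IntegerMatrix> graphs;
  bool aborted = false;     // collection cap exceeded
  long tick = 0;
};

static IntegerMatrix edge_matrix(int n, const bits *adj) {
  std::vector<std::pair<int, int>> es;
  for (int v = 0; v < n; v++) {
    bits nb = adj[v] >> (v + 1);
    while (nb) {
      int u = ctz(nb); nb &= nb - 1;
      es.push_back(std::make_pair(v + 1, v + u + 2));  // 1-based, i<j, lex order
    }
  }
  IntegerMatrix m((int)es.size(), 2);
  for (size_t i = 0; i < es.size(); i++) { m(i, 0) = es[i].first; m(i, 1) = es[i].second; }
  return m;
}

static void emit(GenCtx &ctx, int n, const bits *adj, const int *deg) {
  ctx.count += 1;
  if (ctx.stats) {
    std::vector<int> col;
    flower_colors(n, adj, deg, col);
    bool ov = false;
    long long N = aut_enumerate(n, adj, col, ctx.autCap, nullptr, &ov);
    if (ov) N = ctx.autCap;
    if (N == 1) ctx.nTrivialN += 1;
    if ((double)N > ctx.maxN) ctx.maxN = (double)N;
  }
  if (ctx.collect) {
    if ((long long)ctx.graphs.size() >= ctx.collectCap) { ctx.aborted = true; return; }
    ctx.graphs.push_back(edge_matrix(n, adj));
  }
  if (ctx.cb) (*ctx.cb)(edge_matrix(n, adj));
}

// Accept iff the newest vertex (index k-1 of the k-vertex graph) lies in the
// same automorphism orbit as the canonical deletion vertex: the non-cut
// vertex holding the highest canonical position.
static bool parent_rule(int k, const bits *adj, std::vector<bits> *encOut) {
  CanonSearch cs;
  cs.n = k; cs.adj = adj;
  cs.run(std::vector<int>(k, 0));
  if (encOut) *encOut = cs.bestEnc;
  bits cuts = articulation_points(k, adj);
  int w = -1, wpos = -1;
  for (int v = 0; v < k; v++) {
    if ((cuts >> v) & 1) continue;
    if (cs.bestLab[v] > wpos) { wpos = cs.bestLab[v]; w = v; }
  }
  return cs.find(w) == cs.find(k - 1);
}

static void gen_extend(GenCtx &ctx, int k, bits *adj, int *deg, int m);

// DFS over attachment sets S for the new vertex k, in lexicographic order of
// the increasing candidate sequence; accepted siblings are deduplicated by
// the canonical form of the child (equal forms imply the attachment sets are
// equivalent under the parent's automorphism group).
static void subsets_rec(GenCtx &ctx, int k, bits *adj, int *deg, int m,
                        int smin, int smax, size_t start, bits S, int sz,
                        const std::vector<int> &cand,
                        std::set<std::vector<bits>> &seen) {
  if (ctx.aborted) return;
  if (sz >= smin) {
    adj[k] = S; deg[k] = sz;
    bits Sw = S;
    while (Sw) { int u = ctz(Sw); Sw &= Sw - 1; adj[u] |= bits(1) << k; deg[u]++; }
    std::vector<bits> enc;
    if (parent_rule(k + 1, adj, &enc) && seen.insert(enc).second) {
      if (k + 1 == ctx.n) {
        if (m + sz >= ctx.minE && m + sz <= ctx.maxE) emit(ctx, k + 1, adj, deg);
      } else {
        gen_extend(ctx, k + 1, adj, deg, m + sz);
      }
    }
    Sw = S;
    while (Sw) { int u = ctz(Sw); Sw &= Sw - 1; adj[u] &= ~(bits(1) << k); deg[u]--; }
    adj[k] = 0; deg[k] = 0;
  }
  if (sz == smax) return;
  for (size_t i = start; i < cand.size(); i++) {
    subsets_rec(ctx, k, adj, deg, m, smin, smax, i + 1,
                S | (bits(1) << cand[i]), sz + 1, cand, seen);
    if (ctx.aborted) return;
  }
}

static void gen_extend(GenCtx &ctx, int k, bits *adj, int *deg, int m) {
  if (ctx.aborted) return;
  if (++ctx.tick % 4096 == 0) Rcpp::checkUserInterrupt();
  int r = ctx.n - k;               // vertices still to add (>= 1 here)
  int mu = m - k + 1;              // cycle rank; can only grow from here
  int smax = ctx.maxDeg;
  smax = std::min(smax, (ctx.maxE - ctx.n + 1) - mu + 1);
  smax = std::min(smax, ctx.maxE - m - (r - 1));  // later vertices add >= 1 edge each
  int smin = std::max(1, ctx.minE - m - (r - 1) * ctx.maxDeg);
  if (smax < smin) return;
  std::vector<int> cand;
  for (int v = 0; v < k; v++) if (deg[v] < ctx.maxDeg) cand.push_back(v);
  if ((int)cand.size() < smin) return;
  std::set<std::vector<bits>> seen;
  subsets_rec(ctx, k, adj, deg, m, smin, std::min(smax, (int)cand.size()),
              0, 0, 0, cand, seen);
}

// ---------------------------------------------------------------------------
// R interface
// ---------------------------------------------------------------------------

static void fill_adj(int n, const IntegerMatrix &edges, bits *adj) {
  for (int v = 0; v < n; v++) adj[v] = 0;
  for (int i = 0; i < edges.nrow(); i++) {
    int a = edges(i, 0) - 1, b = edges(i, 1) - 1;
    if (a < 0 || b < 0 || a >= n || b >= n || a == b)
      stop("invalid edge (%d,%d) for n=%d", a + 1, b + 1, n);
    adj[a] |= bits(1) << b;
    adj[b] |= bits(1) << a;
  }
}

static std::vector<int> colors_or_uniform(int n, Nullable<IntegerVector> colors) {
  std::vector<int> col(n, 0);
  if (colors.isNotNull()) {
    IntegerVector cv(colors);
    if (cv.size() != n) stop("colors must have length n");
    for (int v = 0; v < n; v++) col[v] = cv[v];
    densify(col);
  }
  return col;
}

// [[Rcpp::export]]
List cpp_generate(int n, int min_edges, int max_edges, int max_degree,
                  bool stats = false, bool collect = true,
                  double collect_cap = 2e6,
                  Nullable<Function> callback = R_NilValue,
                  double aut_cap = 1e6) {
  if (n < 1 || n > MAXN) stop("vertex count must be in 1..32");
  GenCtx ctx;
  ctx.n = n; ctx.minE = min_edges; ctx.maxE = max_edges; ctx.maxDeg = max_degree;
  ctx.stats = stats; ctx.collect = collect;
  ctx.collectCap = (long long)collect_cap;
  ctx.autCap = (long long)aut_cap;
  Function cbf = Environment::base_env()["identity"];
  if (callback.isNotNull()) { cbf = Function(callback); ctx.cb = &cbf; }

  bits adj[MAXN] = {0};
  int deg[MAXN] = {0};
  if (n == 1) {
    if (min_edges <= 0 && max_edges >= 0) emit(ctx, 1, adj, deg);
  } else if (max_edges >= n - 1 && max_degree >= 1) {
    gen_extend(ctx, 1, adj, deg, 0);
  }
  if (ctx.aborted)
    stop("stage-1 collection cap exceeded; use counting or callback mode");
  List out = List::create(
      _["count"] = ctx.count,
      _["n_trivial_N"] = ctx.stats ? ctx.nTrivialN : NA_REAL,
      _["max_N"] = ctx.stats ? ctx.maxN : NA_REAL);
  if (ctx.collect) {
    List gl(ctx.graphs.size());
    for (size_t i = 0; i < ctx.graphs.size(); i++) gl[i] = ctx.graphs[i];
    out["graphs"] = gl;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_canon(int n, IntegerMatrix edges,
               Nullable<IntegerVector> colors = R_NilValue) {
  if (n < 1 || n > MAXN) stop("vertex count must be in 1..32");
  bits adj[MAXN];
  fill_adj(n, edges, adj);
  CanonSearch cs;
  cs.n = n; cs.adj = adj;
  cs.run(colors_or_uniform(n, colors));
  IntegerVector lab(n), orb(n);
  for (int v = 0; v < n; v++) { lab[v] = cs.bestLab[v] + 1; orb[v] = cs.find(v) + 1; }
  NumericVector enc(n);
  for (int v = 0; v < n; v++) enc[v] = (double)cs.bestEnc[v];
  List gens(cs.gens.size());
  for (size_t i = 0; i < cs.gens.size(); i++) {
    IntegerVector g(n);
    for (int v = 0; v < n; v++) g[v] = cs.gens[i][v] + 1;
    gens[i] = g;
  }
  return List::create(_["labelling"] = lab, _["orbits"] = orb,
                      _["encoding"] = enc, _["generators"] = gens);
}

// [[Rcpp::export]]
List cpp_aut_group(int n, IntegerMatrix edges,
                   Nullable<IntegerVector> colors = R_NilValue,
                   double cap = 1e6, bool members = true) {
  if (n < 1 || n > MAXN) stop("vertex count must be in 1..32");
  bits adj[MAXN];
  fill_adj(n, edges, adj);
  std::vector<std::vector<int>> mem;
  bool ov = false;
  long long cnt = aut_enumerate(n, adj, colors_or_uniform(n, colors),
                                (long long)cap, members ? &mem : nullptr, &ov);
  if (ov) stop("automorphism group larger than cap (%.0f)", cap);
  List out(mem.size());
  for (size_t i = 0; i < mem.size(); i++) {
    IntegerVector g(n);
    for (int v = 0; v < n; v++) g[v] = mem[i][v] + 1;
    out[i] = g;
  }
  return List::create(_["order"] = (double)cnt, _["members"] = out);
}

// [[Rcpp::export]]
IntegerVector cpp_flower_colors(int n, IntegerMatrix edges) {
  if (n < 1 || n > MAXN) stop("vertex count must be in 1..32");
  bits adj[MAXN];
  fill_adj(n, edges, adj);
  int deg[MAXN];
  for (int v = 0; v < n; v++) deg[v] = popcnt(adj[v]);
  std::vector<int> col;
  flower_colors(n, adj, deg, col);
  return IntegerVector(col.begin(), col.end());
}

// True iff this labelled connected graph is exactly the representative the
// generator emits for its isomorphism class: every prefix must pass the
// parent rule, and at every level the attachment set must be the first (in
// enumeration order) accepted set producing this child up to isomorphism.
// [[Rcpp::export]]
bool cpp_is_canonical_member(int n, IntegerMatrix edges) {
  if (n < 1 || n > MAXN) stop("vertex count must be in 1..32");
  bits adj[MAXN];
  fill_adj(n, edges, adj);
  for (int k = n; k >= 2; k--) {
    bits maskk = (k == 32) ? ~bits(0) : ((bits(1) << k) - 1);
    bits sub[MAXN];
    for (int v = 0; v < k; v++) sub[v] = adj[v] & maskk;
    bits S = sub[k - 1];
    if (S == 0) return false;              // vertex k not attached to 1..k-1
    bits seen = 1, frontier = 1;           // connectivity of the prefix
    while (frontier) {
      bits nxt = 0, f = frontier;
      while (f) { int v = ctz(f); f &= f - 1; nxt |= sub[v]; }
      frontier = nxt & ~seen;
      seen |= frontier;
    }
    if (seen != maskk) return false;
    std::vector<bits> enc;
    if (!parent_rule(k, sub, &enc)) return false;
    // earlier same-size attachment sets (lexicographic order on the increasing
    // vertex sequence, as the generator enumerates them) that are accepted and
    // give an isomorphic child would have shadowed this one
    int sz = popcnt(S);
    std::vector<int> pick(sz);
    for (int i = 0; i < sz; i++) pick[i] = i;
    bits alt_adj[MAXN];
    for (;;) {
      bits Sa = 0;
      for (int i = 0; i < sz; i++) Sa |= bits(1) << pick[i];
      if (Sa == S) break;                  // reached our own set: it is first
      // try alternative child with attachment Sa
      for (int v = 0; v < k; v++) alt_adj[v] = sub[v];
      for (int v = 0; v < k - 1; v++) alt_adj[v] &= ~(bits(1) << (k - 1));
      alt_adj[k - 1] = Sa;
      bits Sw = Sa;
      while (Sw) { int u = ctz(Sw); Sw &= Sw - 1; alt_adj[u] |= bits(1) << (k - 1); }
      std::vector<bits> enc2;
      if (parent_rule(k, alt_adj, &enc2) && enc2 == enc) return false;
      // next combination of size sz from {0..k-2} in lexicographic order
      int i = sz - 1;
      while (i >= 0 && pick[i] == (k - 2) - (sz - 1 - i)) i--;
      if (i < 0) break;
      pick[i]++;
      for (int j = i + 1; j < sz; j++) pick[j] = pick[j - 1] + 1;
    }
  }
  return true;
}

// [[Rcpp::export]]
NumericVector cpp_canon_key(int n, IntegerMatrix edges,
                            Nullable<IntegerVector> colors = R_NilValue) {
  List r = cpp_canon(n, edges, colors);
  return r["encoding"];
}
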