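// Exact maximum-weight matching on a general (non-bipartite) graph.
//
// Primal-dual blossom method (Galil 1986 formulation), dense O(V^3)
// implementation. Vertices are 1..n; blossoms occupy ids n+1..2n. Input
// weights must be positive integers; they are doubled internally so that
// every dual adjustment stays integral. The matching maximizes total weight
// and is not required to be perfect: the search stops once the dual
// variables of free vertices reach zero, at which point no augmentation can
// increase the weight.
//
// Used for the assembly of ancestral contigs from candidate adjacencies of
// protogene ends; exactness is required (greedy matching is not optimal).

#include <Rcpp.h>
#include <algorithm>
#include <deque>
#include <vector>

namespace {

typedef long long ll;
const ll INF = (ll)1e18;

struct Edge {
  int u, v;
  ll w;
};

class Blossom {
 public:
  explicit Blossom(int n_) : n(n_), n_x(n_) {
    int m = 2 * n + 1;
    g.assign((size_t)m * m, Edge{0, 0, 0});
    for (int u = 1; u <= 2 * n; ++u)
      for (int v = 1; v <= 2 * n; ++v) {
        at(u, v).u = u;
        at(u, v).v = v;
      }
    lab.assign(m, 0);
    match.assign(m, 0);
    slack.assign(m, 0);
    st.assign(m, 0);
    pa.assign(m, 0);
    S.assign(m, -1);
    vis.assign(m, 0);
    flower.assign(m, std::vector<int>());
    flower_from.assign((size_t)m * (n + 1), 0);
  }

  void add_edge(int u, int v, ll w) {
    // doubled weight keeps all dual updates integral; parallel edges keep max
    ll w2 = std::max(at(u, v).w, 2 * w);
    at(u, v).w = at(v, u).w = w2;
  }

  // returns mate vector (0 = unmatched) over vertices 1..n
  std::vector<int> solve() {
    for (int u = 0; u <= n; ++u) st[u] = u;
    n_x = n;
    ll w_max = 0;
    for (int u = 1; u <= n; ++u)
      for (int v = 1; v <= n; ++v) {
        ff(u, v) = (u == v ? u : 0);
        w_max = std::max(w_max, at(u, v).w);
      }
    for (int u = 1; u <= n; ++u) lab[u] = w_max;
    while (matching()) {
    }
    std::vector<int> mate(n + 1, 0);
    for (int u = 1; u <= n; ++u)
      if (match[u] && at(u, match[u]).w > 0) mate[u] = match[u];
    return mate;
  }

 private:
  int n, n_x;
  std::vector<Edge> g;
  std::vector<ll> lab;
  std::vector<int> match, slack, st, pa, S, vis;
  std::vector<std::vector<int>> flower;
  std::vector<int> flower_from;
  std::deque<int> q;
  int lca_tick = 0;

  Edge& at(int u, int v) { return g[(size_t)u * (2 * n + 1) + v]; }
  int& ff(int b, int x) { return flower_from[(size_t)b * (n + 1) + x]; }

  ll e_delta(const Edge& e) { return lab[e.u] + lab[e.v] - at(e.u, e.v).w * 2; }

  void update_slack(int u, int x) {
    if (!slack[x] || e_delta(at(u, x)) < e_delta(at(slack[x], x))) slack[x] = u;
  }

  void set_slack(int x) {
    slack[x] = 0;
    for (int u = 1; u <= n; ++u)
      if (at(u, x).w > 0 && st[u] != x && S[st[u]] == 0) update_slack(u, x);
  }

  void q_push(int x) {
    if (x <= n) {
      q.push_back(x);
    } else {
      for (size_t i = 0; i < flower[x].size(); ++i) q_push(flower[x][i]);
    }
  }

  void set_st(int x, int b) {
    st[x] = b;
    if (x > n)
      for (size_t i = 0; i < flower[x].size(); ++i) set_st(flower[x][i], b);
  }

  int get_pr(int b, int xr) {
    int pr = (int)(std::find(flower[b].begin(), flower[b].end(), xr) -
                   flower[b].begin());
    if (pr % 2 == 1) {  // walk the cycle the other way so xr sits at an even slot
      std::reverse(flower[b].begin() + 1, flower[b].end());
      return (int)flower[b].size() - pr;
    }
    return pr;
  }

  void set_match(int u, int v) {
    match[u] = at(u, v).v;
    if (u > n) {
      Edge e = at(u, v);
      int xr = ff(u, e.u);
      int pr = get_pr(u, xr);
      for (int i = 0; i < pr; ++i) set_match(flower[u][i], flower[u][i ^ 1]);
      set_match(xr, v);
      std::rotate(flower[u].begin(), flower[u].begin() + pr, flower[u].end());
    }
  }

  void augment(int u, int v) {
    for (;;) {
      int xnv = st[match[u]];
      set_match(u, v);
      if (!xnv) return;
      set_match(xnv, st[pa[xnv]]);
      u = st[pa[xnv]];
      v = xnv;
    }
  }

  int get_lca(int u, int v) {
    for (++lca_tick; u || v; std::swap(u, v)) {
      if (u == 0) continue;
      if (vis[u] == lca_tick) return u;
      vis[u] = lca_tick;
      u = st[match[u]];
      if (u) u = st[pa[u]];
    }
    return 0;
  }

  void add_blossom(int u, int lca, int v) {
    int b = n + 1;
    while (b <= n_x && st[b]) ++b;
    if (b > n_x) ++n_x;
    lab[b] = 0;
    S[b] = 0;
    match[b] = match[lca];
    flower[b].clear();
    flower[b].push_back(lca);
    for (int x = u, y; x != lca; x = st[pa[y]]) {
      flower[b].push_back(x);
      flower[b].push_back(y = st[match[x]]);
      q_push(y);
    }
    std::reverse(flower[b].begin() + 1, flower[b].end());
    for (int x = v, y; x != lca; x = st[pa[y]]) {
      flower[b].push_back(x);
      flower[b].push_back(y = st[match[x]]);
      q_push(y);
    }
    set_st(b, b);
    for (int x = 1; x <= n_x; ++x) at(b, x).w = at(x, b).w = 0;
    for (int x = 1; x <= n; ++x) ff(b, x) = 0;
    for (size_t i = 0; i < flower[b].size(); ++i) {
      int xs = flower[b][i];
      for (int x = 1; x <= n_x; ++x)
        if (at(b, x).w == 0 || e_delta(at(xs, x)) < e_delta(at(b, x))) {
          at(b, x) = at(xs, x);
          at(x, b) = at(x, xs);
        }
      for (int x = 1; x <= n; ++x)
        if (ff(xs, x)) ff(b, x) = xs;
    }
    set_slack(b);
  }

  void expand_blossom(int b) {
    for (size_t i = 0; i < flower[b].size(); ++i) set_st(flower[b][i], flower[b][i]);
    int xr = ff(b, at(b, pa[b]).u);
    int pr = get_pr(b, xr);
    for (int i = 0; i < pr; i += 2) {
      int xs = flower[b][i], xns = flower[b][i + 1];
      pa[xs] = at(xns, xs).u;
      S[xs] = 1;
      S[xns] = 0;
      slack[xs] = 0;
      set_slack(xns);
      q_push(xns);
    }
    S[xr] = 1;
    pa[xr] = pa[b];
    for (size_t i = pr + 1; i < flower[b].size(); ++i) {
      int xs = flower[b][i];
      S[xs] = -1;
      set_slack(xs);
    }
    st[b] = 0;
  }

  bool on_found_edge(const Edge& e) {
    int u = st[e.u], v = st[e.v];
    if (S[v] == -1) {
      pa[v] = e.u;
      S[v] = 1;
      int nu = st[match[v]];
      slack[v] = slack[nu] = 0;
      S[nu] = 0;
      q_push(nu);
    } else if (S[v] == 0) {
      int lca = get_lca(u, v);
      if (!lca) {
        augment(u, v);
        augment(v, u);
        return true;
      }
      add_blossom(u, lca, v);
    }
    return false;
  }

  bool matching() {
    std::fill(S.begin() + 1, S.begin() + n_x + 1, -1);
    std::fill(slack.begin() + 1, slack.begin() + n_x + 1, 0);
    q.clear();
    for (int x = 1; x <= n_x; ++x)
      if (st[x] == x && !match[x]) {
        pa[x] = 0;
        S[x] = 0;
        q_push(x);
      }
    if (q.empty()) return false;
    for (;;) {
      while (!q.empty()) {
        int u = q.front();
        q.pop_front();
        if (S[st[u]] == 1) continue;
        for (int v = 1; v <= n; ++v)
          if (at(u, v).w > 0 && st[u] != st[v]) {
            if (e_delta(at(u, v)) == 0) {
              if (on_found_edge(at(u, v))) return true;
            } else {
              update_slack(u, st[v]);
            }
          }
      }
      ll d = INF;
      for (int b = n + 1; b <= n_x; ++b)
        if (st[b] == b && S[b] == 1) d = std::min(d, lab[b] / 2);
      for (int x = 1; x <= n_x; ++x)
        if (st[x] == x && slack[x]) {
          if (S[x] == -1)
            d = std::min(d, e_delta(at(slack[x], x)));
          else if (S[x] == 0)
            d = std::min(d, e_delta(at(slack[x], x)) / 2);
        }
      for (int u = 1; u <= n; ++u) {
        if (S[st[u]] == 0) {
          if (lab[u] <= d) return false;  // free duals hit zero: optimum reached
          lab[u] -= d;
        } else if (S[st[u]] == 1) {
          lab[u] += d;
        }
      }
      for (int b = n + 1; b <= n_x; ++b)
        if (st[b] == b) {
          if (S[b] == 0)
            lab[b] += d * 2;
          else if (S[b] == 1)
            lab[b] -= d * 2;
        }
      q.clear();
      for (int x = 1; x <= n_x; ++x)
        if (st[x] == x && slack[x] && st[slack[x]] != x &&
            e_delta(at(slack[x], x)) == 0)
          if (on_found_edge(at(slack[x], x))) return true;
      for (int b = n + 1; b <= n_x; ++b)
        if (st[b] == b && S[b] == 1 && lab[b] == 0) expand_blossom(b);
    }
    return false;
  }
};

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".mwm_dense")]]
Rcpp::IntegerVector mwm_dense(int n, Rcpp::IntegerVector u, Rcpp::IntegerVector v,
                              Rcpp::IntegerVector w) {
  if (n < 1) return Rcpp::IntegerVector(0);
  Blossom bl(n);
  for (int i = 0; i < u.size(); ++i) {
    if (u[i] < 1 || u[i] > n || v[i] < 1 || v[i] > n || u[i] == v[i])
      Rcpp::stop("invalid edge endpoints");
    if (w[i] <= 0) Rcpp::stop("edge weights must be positive integers");
    bl.add_edge(u[i], v[i], w[i]);
  }
  std::vector<int> mate = bl.solve();
  Rcpp::IntegerVector out(n);
  for (int i = 1; i <= n; ++i) out[i - 1] = mate[i];
  return out;
}
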