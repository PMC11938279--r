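// Face-spiral kernels for dual fullerene triangulations.
//
// A dual fullerene T_n is a sphere triangulation on m = n/2 + 2 vertices
// with degrees in {5, 6} and exactly twelve vertices of degree 5.  A face
// spiral lists the faces of the fullerene (= vertices of T_n) so that each
// new face touches the previous face and the earliest face that is still
// open.  Winding a degree sequence up into a triangulation, unwinding a
// triangulation into its lexicographically smallest degree sequence, the
// backtracking enumeration of all canonical sequences, the gSW zigzag path
// search and the acceptance-rejection sampler all live here: they are the
// hot loops of the package.

#include <Rcpp.h>
#include <vector>
#include <deque>
#include <cstring>
#include <algorithm>

using namespace Rcpp;

namespace {

struct WindState {
    int m;                       // total number of faces
    int placed;                  // faces placed so far
    std::vector<uint8_t> adj;    // m*m adjacency matrix
    std::vector<int8_t> deg;     // target degree of each placed face
    std::vector<int8_t> cnt;     // current degree
    std::deque<int> boundary;    // open boundary, front = earliest open face

    void init(int m_) {
        m = m_;
        placed = 0;
        adj.assign((size_t)m * m, 0);
        deg.assign(m, 0);
        cnt.assign(m, 0);
        boundary.clear();
    }
    inline bool has_edge(int a, int b) const { return adj[(size_t)a * m + b] != 0; }
    inline bool add_edge(int a, int b) {
        if (a == b) return false;
        if (has_edge(a, b)) return false;
        if (cnt[a] >= deg[a] || cnt[b] >= deg[b]) return false;
        adj[(size_t)a * m + b] = 1;
        adj[(size_t)b * m + a] = 1;
        ++cnt[a];
        ++cnt[b];
        return true;
    }
};

// Place face j with the given size (5 or 6).  For j == m-1 the face must
// close the remaining boundary.  Returns false on any violation; the state
// is then unusable (callers work on copies).
bool add_face(WindState &st, int j, int size) {
    st.deg[j] = (int8_t)size;
    st.placed = j + 1;
    if (j == 0) {
        st.boundary.push_back(0);
        return true;
    }
    if (j == 1) {
        if (!st.add_edge(0, 1)) return false;
        st.boundary.push_back(1);
        return true;
    }
    if (j == st.m - 1) {
        // last face: adjacent to every remaining boundary vertex
        for (int v : st.boundary)
            if (!st.add_edge(j, v)) return false;
        st.boundary.clear();
        st.boundary.push_back(j);
        // closure: every vertex saturated, 3m-6 edges
        for (int v = 0; v < st.m; ++v)
            if (st.cnt[v] != st.deg[v]) return false;
        return true;
    }
    // attach to the spiral end
    if (st.boundary.size() < 2) return false;
    if (!st.add_edge(j, st.boundary.back())) return false;
    // the end of the boundary rolls up while saturated
    while (st.cnt[st.boundary.back()] == st.deg[st.boundary.back()]) {
        st.boundary.pop_back();
        if (st.boundary.empty()) return false;
        if (!st.has_edge(j, st.boundary.back()))
            if (!st.add_edge(j, st.boundary.back())) return false;
    }
    // attach to the earliest open face, advancing over saturated faces
    if (!st.has_edge(j, st.boundary.front()))
        if (!st.add_edge(j, st.boundary.front())) return false;
    while (st.cnt[st.boundary.front()] == st.deg[st.boundary.front()]) {
        st.boundary.pop_front();
        if (st.boundary.empty()) return false;
        if (!st.has_edge(j, st.boundary.front()))
            if (!st.add_edge(j, st.boundary.front())) return false;
    }
    st.boundary.push_back(j);
    return true;
}

bool windup_full(const std::vector<int> &sizes, WindState &st) {
    int m = (int)sizes.size();
    st.init(m);
    for (int j = 0; j < m; ++j)
        if (!add_face(st, j, sizes[j])) return false;
    return true;
}

// ---------------------------------------------------------------------------
// Unwinding: generate face spirals of a finished triangulation.
//
// Graph: adjacency matrix + neighbour lists + degrees.  A spiral is grown
// from a single start vertex; the next face is a common neighbour of the
// current end and the earliest open face.  Ambiguities (always present at
// step 2, where they encode the two winding directions) are explored by
// branching, so all spirals from all starts are covered by looping over the
// start vertex only.

struct Graph {
    int m;
    std::vector<uint8_t> adj;
    std::vector<std::vector<int> > nb;
    std::vector<int> deg;
    inline bool has_edge(int a, int b) const { return adj[(size_t)a * m + b] != 0; }
};

Graph graph_from_state(const WindState &st) {
    Graph g;
    g.m = st.m;
    g.adj = st.adj;
    g.deg.resize(g.m);
    g.nb.assign(g.m, std::vector<int>());
    for (int v = 0; v < g.m; ++v) {
        g.deg[v] = st.deg[v];
        for (int u = 0; u < g.m; ++u)
            if (st.adj[(size_t)v * g.m + u]) g.nb[v].push_back(u);
    }
    return g;
}

struct SpiralSearch {
    const Graph *g;
    const int *ref;          // reference sequence (or NULL)
    bool find_smaller_only;  // true: return as soon as a spiral < ref completes
    std::vector<int> best;   // smallest complete sequence found (if tracking)
    bool have_best;

    std::vector<int> order;      // spiral order so far
    std::vector<uint8_t> in_s;
    std::vector<int> seq;        // degree sequence along the spiral
    int open_ptr;                // index into order of earliest open face
    bool found_smaller;

    // cmp: -1 seq is (strictly) smaller than ref so far, 0 tie
    bool step(int k, int cmp) {
        int m = g->m;
        if (k == m) {
            if (find_smaller_only) {
                if (cmp < 0) { found_smaller = true; return true; }
                return false;
            }
            // compare explicitly: cmp can be stale when best improved mid-search
            if (!have_best || std::lexicographical_compare(seq.begin(), seq.end(),
                                                           best.begin(), best.end())) {
                best = seq;
                have_best = true;
            }
            return false;
        }
        // advance the open pointer over saturated faces
        int saved_open = open_ptr;
        while (open_ptr < (int)order.size()) {
            int f = order[open_ptr];
            bool open = false;
            for (int u : g->nb[f]) if (!in_s[u]) { open = true; break; }
            if (open) break;
            ++open_ptr;
        }
        if (open_ptr >= (int)order.size()) { open_ptr = saved_open; return false; }
        int open_face = order[open_ptr];
        int end_face = order.back();
        // candidates: unused common neighbours of end and earliest open face
        int cand[8]; int nc = 0;
        for (int u : g->nb[end_face]) {
            if (in_s[u]) continue;
            if (end_face != open_face && !g->has_edge(u, open_face)) continue;
            if (nc < 8) cand[nc++] = u;
        }
        // try degree-5 candidates first so smaller sequences are found early
        std::sort(cand, cand + nc, [this](int a, int b) {
            if (g->deg[a] != g->deg[b]) return g->deg[a] < g->deg[b];
            return a < b;
        });
        bool stop = false;
        for (int ci = 0; ci < nc && !stop; ++ci) {
            int u = cand[ci];
            int d = g->deg[u];
            int c2 = cmp;
            if (c2 == 0) {
                int r = ref ? ref[k] : (have_best ? best[k] : 99);
                if (d > r) continue;          // lexicographically worse: prune
                if (d < r) c2 = -1;
            }
            in_s[u] = 1;
            order.push_back(u);
            seq.push_back(d);
            int op = open_ptr;
            stop = step(k + 1, c2);
            open_ptr = op;
            seq.pop_back();
            order.pop_back();
            in_s[u] = 0;
        }
        open_ptr = saved_open;
        return stop;
    }

    bool run_start(int v1, int cmp0) {
        order.assign(1, v1);
        in_s.assign(g->m, 0);
        in_s[v1] = 1;
        seq.assign(1, g->deg[v1]);
        open_ptr = 0;
        return step(1, cmp0);
    }
};

// Is there a successful spiral strictly smaller than ref?
bool smaller_spiral_exists(const Graph &g, const std::vector<int> &ref) {
    SpiralSearch s;
    s.g = &g;
    s.ref = ref.data();
    s.find_smaller_only = true;
    s.have_best = false;
    s.found_smaller = false;
    for (int v = 0; v < g.m; ++v) {
        int d = g.deg[v];
        int cmp0;
        if (d > ref[0]) continue;
        cmp0 = (d < ref[0]) ? -1 : 0;
        if (s.run_start(v, cmp0)) return true;
    }
    return false;
}

// Lexicographically smallest successful spiral; empty if none exists.
std::vector<int> canonical_spiral(const Graph &g) {
    SpiralSearch s;
    s.g = &g;
    s.ref = NULL;
    s.find_smaller_only = false;
    s.have_best = false;
    for (int v = 0; v < g.m; ++v) {
        if (s.have_best && g.deg[v] > s.best[0]) continue;
        s.run_start(v, (s.have_best && g.deg[v] < s.best[0]) ? -1 : 0);
    }
    if (!s.have_best) return std::vector<int>();
    return s.best;
}

Graph graph_from_r(const IntegerMatrix &am, const IntegerVector &degrees) {
    Graph g;
    g.m = am.nrow();
    g.adj.assign((size_t)g.m * g.m, 0);
    g.nb.assign(g.m, std::vector<int>());
    g.deg.assign(degrees.begin(), degrees.end());
    for (int i = 0; i < g.m; ++i)
        for (int j = 0; j < g.m; ++j)
            if (am(i, j) != 0) {
                g.adj[(size_t)i * g.m + j] = 1;
                if (i != j) ; // no loops expected
            }
    for (int i = 0; i < g.m; ++i)
        for (int j = 0; j < g.m; ++j)
            if (g.adj[(size_t)i * g.m + j]) g.nb[i].push_back(j);
    return g;
}

std::vector<int> positions_from_sizes(const std::vector<int> &sizes) {
    std::vector<int> pos;
    for (int i = 0; i < (int)sizes.size(); ++i)
        if (sizes[i] == 5) pos.push_back(i + 1);
    return pos;
}

} // namespace

// [[Rcpp::export(name = ".windup_cpp")]]
List windup_cpp(IntegerVector sizes) {
    std::vector<int> s(sizes.begin(), sizes.end());
    WindState st;
    bool ok = windup_full(s, st);
    if (!ok) return List::create(Named("ok") = false);
    int m = st.m;
    List nb(m);
    for (int v = 0; v < m; ++v) {
        std::vector<int> nv;
        for (int u = 0; u < m; ++u)
            if (st.adj[(size_t)v * m + u]) nv.push_back(u + 1);
        nb[v] = wrap(nv);
    }
    return List::create(Named("ok") = true, Named("neighbors") = nb);
}

// [[Rcpp::export(name = ".canonical_spiral_cpp")]]
IntegerVector canonical_spiral_cpp(IntegerMatrix am, IntegerVector degrees) {
    Graph g = graph_from_r(am, degrees);
    std::vector<int> best = canonical_spiral(g);
    return wrap(best);   // empty vector: no spiral exists
}

// ---------------------------------------------------------------------------
// Enumeration: depth-first search over partial spirals with undo-based
// backtracking (no state copies) and an endgame bound on the boundary size
// (the boundary shrinks by at most 3 per face and the last face closes it).

namespace {

const int MAXM = 128;

struct EnumState {
    int m;
    uint64_t adj[MAXM][2];
    int8_t deg[MAXM], cnt[MAXM];
    int buf[MAXM + 2];          // boundary = buf[head..tail)
    int head, tail;

    void init(int m_) {
        m = m_;
        std::memset(adj, 0, sizeof(adj));
        std::memset(deg, 0, sizeof(deg));
        std::memset(cnt, 0, sizeof(cnt));
        head = tail = 0;
    }
    inline bool has_edge(int a, int b) const {
        return (adj[a][b >> 6] >> (b & 63)) & 1ull;
    }
    inline int bsize() const { return tail - head; }
};

struct UndoRec {
    int head, tail;
    int pushed_pos, pushed_saved;
    bool pushed;
    int n_edges;
    int edges[10][2];
};

inline bool add_edge_u(EnumState &st, int a, int b, UndoRec &u) {
    if (a == b || st.has_edge(a, b)) return false;
    if (st.cnt[a] >= st.deg[a] || st.cnt[b] >= st.deg[b]) return false;
    st.adj[a][b >> 6] |= 1ull << (b & 63);
    st.adj[b][a >> 6] |= 1ull << (a & 63);
    ++st.cnt[a];
    ++st.cnt[b];
    if (u.n_edges < 10) { u.edges[u.n_edges][0] = a; u.edges[u.n_edges][1] = b; }
    ++u.n_edges;
    return true;
}

inline void undo_face(EnumState &st, int j, UndoRec &u) {
    for (int i = u.n_edges - 1; i >= 0; --i) {
        int a = u.edges[i][0], b = u.edges[i][1];
        st.adj[a][b >> 6] &= ~(1ull << (b & 63));
        st.adj[b][a >> 6] &= ~(1ull << (a & 63));
        --st.cnt[a];
        --st.cnt[b];
    }
    if (u.pushed) st.buf[u.pushed_pos] = u.pushed_saved;
    st.head = u.head;
    st.tail = u.tail;
    st.deg[j] = 0;
}

// place face j; every mutation is logged in u so the caller can undo
inline bool add_face_u(EnumState &st, int j, int size, UndoRec &u) {
    u.head = st.head; u.tail = st.tail;
    u.pushed = false; u.n_edges = 0;
    st.deg[j] = (int8_t)size;
    if (j == 0) {
        u.pushed = true; u.pushed_pos = st.tail; u.pushed_saved = st.buf[st.tail];
        st.buf[st.tail++] = 0;
        return true;
    }
    if (j == 1) {
        if (!add_edge_u(st, 0, 1, u)) return false;
        u.pushed = true; u.pushed_pos = st.tail; u.pushed_saved = st.buf[st.tail];
        st.buf[st.tail++] = 1;
        return true;
    }
    if (j == st.m - 1) {
        for (int i = st.head; i < st.tail; ++i)
            if (!add_edge_u(st, j, st.buf[i], u)) return false;
        for (int v = 0; v <= j; ++v)
            if (st.cnt[v] != st.deg[v]) return false;
        return true;
    }
    if (st.bsize() < 2) return false;
    if (!add_edge_u(st, j, st.buf[st.tail - 1], u)) return false;
    while (st.cnt[st.buf[st.tail - 1]] == st.deg[st.buf[st.tail - 1]]) {
        --st.tail;
        if (st.bsize() == 0) return false;
        if (!st.has_edge(j, st.buf[st.tail - 1]))
            if (!add_edge_u(st, j, st.buf[st.tail - 1], u)) return false;
    }
    if (!st.has_edge(j, st.buf[st.head]))
        if (!add_edge_u(st, j, st.buf[st.head], u)) return false;
    while (st.cnt[st.buf[st.head]] == st.deg[st.buf[st.head]]) {
        ++st.head;
        if (st.bsize() == 0) return false;
        if (!st.has_edge(j, st.buf[st.head]))
            if (!add_edge_u(st, j, st.buf[st.head], u)) return false;
    }
    u.pushed = true; u.pushed_pos = st.tail; u.pushed_saved = st.buf[st.tail];
    st.buf[st.tail++] = j;
    return true;
}

Graph graph_from_enum(const EnumState &st) {
    Graph g;
    g.m = st.m;
    g.adj.assign((size_t)st.m * st.m, 0);
    g.nb.assign(st.m, std::vector<int>());
    g.deg.resize(st.m);
    for (int v = 0; v < st.m; ++v) {
        g.deg[v] = st.deg[v];
        for (int u = 0; u < st.m; ++u)
            if (st.has_edge(v, u)) {
                g.adj[(size_t)v * st.m + u] = 1;
                g.nb[v].push_back(u);
            }
    }
    return g;
}

struct Enumerator {
    EnumState st;
    int m;
    int limit;
    bool reverse;
    std::vector<int> sizes;
    std::vector<std::vector<int> > results;
    unsigned long nodes;
    bool done;

    void rec(int j, int pent_used) {
        if (done) return;
        if ((++nodes & 0x3ffff) == 0) Rcpp::checkUserInterrupt();
        int sz[2] = {5, 6};
        if (reverse) { sz[0] = 6; sz[1] = 5; }
        for (int c = 0; c < 2 && !done; ++c) {
            int size = sz[c];
            int pu = pent_used + (size == 5 ? 1 : 0);
            if (pu > 12) continue;
            if (12 - pu > m - 1 - j) continue;
            UndoRec u;
            sizes[j] = size;
            bool ok = add_face_u(st, j, size, u);
            if (ok && j < m - 1 && st.bsize() - 6 > 3 * (m - j - 2)) ok = false;
            if (ok) {
                if (j == m - 1) {
                    Graph g = graph_from_enum(st);
                    if (!smaller_spiral_exists(g, sizes)) {
                        results.push_back(positions_from_sizes(sizes));
                        if (limit > 0 && (int)results.size() >= limit) done = true;
                    }
                } else {
                    rec(j + 1, pu);
                }
            }
            undo_face(st, j, u);
        }
    }
};

} // namespace

// Enumerate canonical pentagon-position vectors for C_n in lexicographic
// order (descending if reverse).  limit == 0 enumerates everything.
// [[Rcpp::export(name = ".enumerate_spirals_cpp")]]
IntegerMatrix enumerate_spirals_cpp(int n, int limit, bool reverse) {
    int m = n / 2 + 2;
    if (m > MAXM) stop("vertex count too large for the enumeration kernel");
    Enumerator e;
    e.st.init(m);
    e.m = m;
    e.limit = limit;
    e.reverse = reverse;
    e.sizes.assign(m, 6);
    e.nodes = 0;
    e.done = false;
    e.rec(0, 0);
    IntegerMatrix out((int)e.results.size(), 12);
    for (int i = 0; i < (int)e.results.size(); ++i)
        for (int k = 0; k < 12; ++k) out(i, k) = e.results[i][k];
    return out;
}

// ---------------------------------------------------------------------------
// gSW path search: zigzag sequences (v_1, ..., v_2w) with deg(v_1) =
// deg(v_2w) = 5, deg(v_2) = deg(v_2w-1) = 6, all vertices distinct,
// consecutive vertices adjacent and (v_i, v_i+2) always an edge.

namespace {

struct GswSearch {
    const Graph *g;
    int max_len;                 // 2 * max_w
    bool stop_at_first;
    std::vector<int> path;
    std::vector<uint8_t> used;
    std::vector<std::vector<int> > found;
    bool hit;

    void extend() {
        int k = (int)path.size();
        int last = path[k - 1];
        if (k >= 4 && k % 2 == 0 && g->deg[last] == 5 && g->deg[path[k - 2]] == 6) {
            found.push_back(path);
            if (stop_at_first) { hit = true; return; }
        }
        if (k >= max_len) return;
        for (int u : g->nb[last]) {
            if (used[u]) continue;
            if (k >= 2 && !g->has_edge(u, path[k - 2])) continue;
            if (k == 1 && g->deg[u] != 6) continue;
            used[u] = 1;
            path.push_back(u);
            extend();
            path.pop_back();
            used[u] = 0;
            if (hit) return;
        }
    }

    void run(int max_w, bool first_only) {
        max_len = 2 * max_w;
        stop_at_first = first_only;
        hit = false;
        found.clear();
        used.assign(g->m, 0);
        for (int v = 0; v < g->m && !hit; ++v) {
            if (g->deg[v] != 5) continue;
            path.assign(1, v);
            used[v] = 1;
            extend();
            used[v] = 0;
        }
    }
};

} // namespace

// [[Rcpp::export(name = ".gsw_paths_cpp")]]
List gsw_paths_cpp(IntegerMatrix am, IntegerVector degrees, int max_w,
                   bool first_only) {
    Graph g = graph_from_r(am, degrees);
    GswSearch s;
    s.g = &g;
    s.run(max_w, first_only);
    List out(s.found.size());
    for (int i = 0; i < (int)s.found.size(); ++i) {
        IntegerVector p(s.found[i].size());
        for (int k = 0; k < (int)s.found[i].size(); ++k) p[k] = s.found[i][k] + 1;
        out[i] = p;
    }
    return out;
}

// ---------------------------------------------------------------------------
// Acceptance-rejection sampler.  Pentagon-position vectors are drawn
// uniformly from the 12-subsets of {1..L} (L = m by default, L = n under
// the length-n dialect), wound up, and accepted only when the vector equals
// the canonical code of the decoded triangulation, which makes accepted
// isomers uniform.

// [[Rcpp::export(name = ".sample_rejection_cpp")]]
List sample_rejection_cpp(int n, int n_accept, double max_trials, int seq_length) {
    int m = n / 2 + 2;
    int L = seq_length;
    // binomial table C(0..L, 0..12) in doubles (exact far beyond these sizes)
    std::vector<std::vector<double> > C(L + 1, std::vector<double>(13, 0.0));
    for (int i = 0; i <= L; ++i) {
        C[i][0] = 1.0;
        for (int k = 1; k <= 12 && k <= i; ++k)
            C[i][k] = C[i - 1][k - 1] + (i - 1 >= k ? C[i - 1][k] : 0.0);
    }
    double total = C[L][12];
    RNGScope scope;
    std::vector<std::vector<int> > accepted;
    double trials = 0.0;
    std::vector<double> trial_counts;
    double since_last = 0.0;
    WindState st;
    while ((int)accepted.size() < n_accept && trials < max_trials) {
        ++trials;
        ++since_last;
        // draw N uniform on 1..C(L,12), unrank to an ascending 12-subset
        double N = std::floor(unif_rand() * total) + 1.0;
        if (N > total) N = total;
        int pos[12];
        int x = 1;
        double r = N;
        for (int k = 0; k < 12; ++k) {
            // smallest value for coordinate k such that enough subsets remain
            while (true) {
                double cnt = C[L - x][11 - k];  // subsets with coordinate k == x
                if (r <= cnt) { pos[k] = x; ++x; break; }
                r -= cnt;
                ++x;
            }
        }
        if (pos[11] > m) continue;           // beyond the face count: reject
        std::vector<int> sizes(m, 6);
        for (int k = 0; k < 12; ++k) sizes[pos[k] - 1] = 5;
        if (!windup_full(sizes, st)) continue;
        Graph g = graph_from_state(st);
        if (smaller_spiral_exists(g, sizes)) continue;   // not canonical
        accepted.push_back(std::vector<int>(pos, pos + 12));
        trial_counts.push_back(since_last);
        since_last = 0.0;
        if (((long long)trials & 0xfff) == 0) Rcpp::checkUserInterrupt();
    }
    IntegerMatrix codes((int)accepted.size(), 12);
    for (int i = 0; i < (int)accepted.size(); ++i)
        for (int k = 0; k < 12; ++k) codes(i, k) = accepted[i][k];
    return List::create(Named("codes") = codes,
                        Named("trials") = trials,
                        Named("trials_per_accept") = wrap(trial_counts));
}
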