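// Exact minimum-weight perfect matching on a complete graph via Edmonds'
// primal-dual blossom algorithm. Written for the moderate problem sizes of
// two-sample cross-match testing (N up to a few hundred); the per-phase
// work is O(n^3) because dual updates rescan all edges, which keeps the
// bookkeeping simple and auditable.
//
// Internally a maximum-weight perfect matching is computed on transformed
// weights w = (2*max(D) + 1) - D; on a complete graph with positive weights
// the maximum-weight matching is perfect, and maximizing sum(w) minimizes
// sum(D).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Blossom {
  // State for one matching problem instance.
  int n;                 // number of vertices
  int nslot;             // 2n id slots: 0..n-1 vertices, n..2n-1 blossoms
  std::vector<double> w; // n x n transformed weights (maximized)
  double eps;

  std::vector<int> mate;                  // vertex -> matched vertex or -1
  std::vector<int> label;                 // per slot: 0 free, 1 S, 2 T
  std::vector<int> lab_u, lab_v;          // labelling edge (u outside, v inside)
  std::vector<int> inblossom;             // vertex -> top-level slot
  std::vector<int> bparent;               // slot -> parent slot or -1
  std::vector<int> base;                  // slot -> base vertex
  std::vector<double> dual;               // y for vertices, z for blossoms
  std::vector<std::vector<int> > childs;  // blossom slot -> cycle children
  std::vector<std::vector<std::pair<int,int> > > bedges; // cycle edges
  std::vector<bool> used_slot;
  std::vector<int> queue;                 // S-vertices pending scan

  double wt(int u, int v) const { return w[u + (size_t)n * v]; }
  double slack(int u, int v) const { return dual[u] + dual[v] - wt(u, v); }

  void leaves(int b, std::vector<int> &out) const {
    if (b < n) { out.push_back(b); return; }
    for (size_t i = 0; i < childs[b].size(); ++i) leaves(childs[b][i], out);
  }

  // Top-level blossom slots currently alive.
  std::vector<int> top_blossoms() const {
    std::vector<int> out;
    for (int b = n; b < nslot; ++b)
      if (used_slot[b] && bparent[b] == -1) out.push_back(b);
    return out;
  }

  void assign_label(int v, int t, int eu, int ev) {
    int b = inblossom[v];
    if (label[b] != 0) stop("internal error: relabelling a labelled blossom");
    label[b] = t;
    lab_u[b] = eu;
    lab_v[b] = ev;
    if (t == 1) {
      std::vector<int> lv;
      leaves(b, lv);
      for (size_t i = 0; i < lv.size(); ++i) queue.push_back(lv[i]);
    } else {
      int bb = base[b];
      int mw = mate[bb];
      if (mw < 0) stop("internal error: T-labelled blossom with exposed base");
      assign_label(mw, 1, bb, mw);
    }
  }

  // Path of top-level slots from the top blossom of vertex v to its root.
  std::vector<int> root_path(int bstart) const {
    std::vector<int> path;
    int b = bstart;
    while (true) {
      path.push_back(b);
      if (lab_u[b] < 0) break;
      b = inblossom[lab_u[b]];
    }
    return path;
  }

  // Deepest common ancestor blossom of the trees of u and v, or -1.
  int find_lca(int bu, int bv) const {
    std::vector<int> pu = root_path(bu), pv = root_path(bv);
    for (size_t i = 0; i < pu.size(); ++i)
      for (size_t j = 0; j < pv.size(); ++j)
        if (pu[i] == pv[j]) return pu[i];
    return -1;
  }

  int new_slot() {
    for (int b = n; b < nslot; ++b)
      if (!used_slot[b]) { used_slot[b] = true; return b; }
    stop("internal error: out of blossom slots");
    return -1; // unreached
  }

  void add_blossom(int lca, int u, int v) {
    int b = new_slot();
    std::vector<int> ch;
    std::vector<std::pair<int,int> > ed;
    // u-side path from inblossom[u] up to (excluding) lca.
    std::vector<int> pu, pv;
    std::vector<std::pair<int,int> > eu_list, ev_list;
    for (int x = inblossom[u]; x != lca; x = inblossom[lab_u[x]]) {
      pu.push_back(x);
      eu_list.push_back(std::make_pair(lab_u[x], lab_v[x]));
    }
    for (int x = inblossom[v]; x != lca; x = inblossom[lab_u[x]]) {
      pv.push_back(x);
      ev_list.push_back(std::make_pair(lab_u[x], lab_v[x]));
    }
    // Cycle: lca, pu[k-1], ..., pu[0], pv[0], ..., pv[m-1], back to lca.
    ch.push_back(lca);
    for (int i = (int)pu.size() - 1; i >= 0; --i) {
      ch.push_back(pu[i]);
      ed.push_back(eu_list[i]); // (in previous child, in pu[i])
    }
    ed.push_back(std::make_pair(u, v));
    for (size_t i = 0; i < pv.size(); ++i) {
      ch.push_back(pv[i]);
      // labelend of pv[i] points out of pv[i]; reverse the orientation.
      ed.push_back(std::make_pair(ev_list[i].second, ev_list[i].first));
    }
    // Fix ordering of edge list: ed[i] must connect ch[i] -> ch[i+1].
    // Built above: ed[0] connects lca -> pu[k-1] ... but the pv edges were
    // appended as (in pv[i], in pv[i+1]) which already fits; the final pv
    // edge connects pv[m-1] -> lca, closing the cycle.
    childs[b] = ch;
    bedges[b] = ed;
    base[b] = base[lca];
    bparent[b] = -1;
    dual[b] = 0.0;
    label[b] = 1;
    lab_u[b] = lab_u[lca];
    lab_v[b] = lab_v[lca];
    for (size_t i = 0; i < ch.size(); ++i) bparent[ch[i]] = b;
    std::vector<int> lv;
    for (size_t i = 0; i < ch.size(); ++i) {
      // Vertices of formerly-T children are newly S and must be scanned.
      if (label[ch[i]] == 2) {
        lv.clear();
        leaves(ch[i], lv);
        for (size_t k = 0; k < lv.size(); ++k) queue.push_back(lv[k]);
      }
    }
    lv.clear();
    leaves(b, lv);
    for (size_t i = 0; i < lv.size(); ++i) inblossom[lv[i]] = b;
  }

  // Rearrange the matching inside blossom b so that vertex v becomes the
  // base (v will be matched externally).
  void augment_blossom(int b, int v) {
    int t = v;
    while (bparent[t] != b) t = bparent[t];
    if (t >= n) augment_blossom(t, v);
    int m = (int)childs[b].size();
    int i = 0;
    while (childs[b][i] != t) ++i;
    for (int s = 1; s < m; s += 2) {
      int j = (i + s) % m;
      std::pair<int,int> e = bedges[b][j];
      int cj = childs[b][j], cj1 = childs[b][(j + 1) % m];
      if (cj >= n) augment_blossom(cj, e.first);
      if (cj1 >= n) augment_blossom(cj1, e.second);
      mate[e.first] = e.second;
      mate[e.second] = e.first;
    }
    std::rotate(childs[b].begin(), childs[b].begin() + i, childs[b].end());
    std::rotate(bedges[b].begin(), bedges[b].begin() + i, bedges[b].end());
    base[b] = v;
  }

  // Augment the matching along the two tree paths meeting at edge (u, v).
  void augment_matching(int u, int v) {
    int ends[2][2] = {{u, v}, {v, u}};
    for (int side = 0; side < 2; ++side) {
      int s = ends[side][0], j = ends[side][1];
      while (true) {
        int bs = inblossom[s];
        if (label[bs] != 1) stop("internal error: augmenting through non-S");
        if (bs >= n) augment_blossom(bs, s);
        mate[s] = j;
        if (lab_u[bs] < 0) break; // reached a root
        int t = lab_u[bs];        // base vertex of the T parent
        int bt = inblossom[t];
        int x = lab_u[bt], y = lab_v[bt]; // unlabelled tight edge into bt
        if (bt >= n) augment_blossom(bt, y);
        mate[y] = x;
        s = x;
        j = y;
      }
    }
  }

  void set_label_direct(int b, int t, int eu, int ev) {
    label[b] = t;
    lab_u[b] = eu;
    lab_v[b] = ev;
  }

  void expand_blossom(int b, bool endstage) {
    std::vector<int> ch = childs[b];
    int m = (int)ch.size();
    std::vector<int> lv;
    for (int i = 0; i < m; ++i) {
      bparent[ch[i]] = -1;
      lv.clear();
      leaves(ch[i], lv);
      for (size_t k = 0; k < lv.size(); ++k) inblossom[lv[k]] = ch[i];
      if (!endstage) set_label_direct(ch[i], 0, -1, -1);
    }
    if (!endstage && label[b] == 2) {
      // Re-thread the alternating tree through the dissolved cycle, from
      // the entry child down to the base child (an even number of edges).
      int entry_v = lab_v[b];
      int j = 0;
      {
        int t = entry_v;
        while (bparent[t] != -1) t = bparent[t];
        while (ch[j] != t) ++j;
      }
      if (j == 0) {
        assign_t_no_mate_check(ch[0], lab_u[b], lab_v[b]);
      } else {
        int step = (j % 2 == 0) ? -1 : 1;
        int pos = j;
        int eu = lab_u[b], ev = lab_v[b];
        while (true) {
          if (pos == 0) {
            assign_t_no_mate_check(ch[0], eu, ev);
            break;
          }
          assign_label(ev, 2, eu, ev); // T here, auto-S on the next child
          int nxt = (pos + 2 * step + m) % m;
          // Unmatched cycle edge leading into child `nxt`.
          std::pair<int,int> e;
          if (step == 1) {
            e = bedges[b][(pos + 1) % m];      // (in pos+1, in pos+2)
            eu = e.first; ev = e.second;
          } else {
            e = bedges[b][(pos - 2 + m) % m];  // (in pos-2, in pos-1)
            eu = e.second; ev = e.first;
          }
          pos = nxt;
        }
      }
    }
    used_slot[b] = false;
    childs[b].clear();
    bedges[b].clear();
    label[b] = 0;
    lab_u[b] = lab_v[b] = -1;
  }

  // T-label the base child of an expanded T-blossom. Its base is matched
  // to the already-S child below it in the tree, so the usual automatic
  // S-labelling of the mate must be skipped.
  void assign_t_no_mate_check(int b, int eu, int ev) {
    set_label_direct(b, 2, eu, ev);
  }

  bool scan_queue() {
    // Returns true if the matching was augmented.
    while (!queue.empty()) {
      int u = queue.back();
      queue.pop_back();
      for (int v = 0; v < n; ++v) {
        int bu = inblossom[u];
        if (label[bu] != 1) break; // u swallowed into a T-side? cannot occur
        int bv = inblossom[v];
        if (bv == bu) continue;
        if (slack(u, v) > eps) continue;
        if (label[bv] == 0) {
          assign_label(v, 2, u, v);
        } else if (label[bv] == 1) {
          int lca = find_lca(bu, bv);
          if (lca < 0) {
            augment_matching(u, v);
            return true;
          }
          add_blossom(lca, u, v);
        } // label 2: nothing to do
      }
    }
    return false;
  }

  void push_all_s() {
    queue.clear();
    for (int v = 0; v < n; ++v)
      if (label[inblossom[v]] == 1) queue.push_back(v);
  }

  void solve() {
    int phases = 0;
    while (true) {
      bool any_free = false;
      for (int v = 0; v < n; ++v) if (mate[v] < 0) { any_free = true; break; }
      if (!any_free) break;
      if (++phases > n) stop("matching failed to converge");
      // Phase initialisation.
      for (int b = 0; b < nslot; ++b) set_label_direct(b, 0, -1, -1);
      queue.clear();
      for (int v = 0; v < n; ++v)
        if (mate[v] < 0 && label[inblossom[v]] == 0)
          assign_label(v, 1, -1, -1);
      bool augmented = false;
      int guard = 0;
      while (!augmented) {
        if (++guard > 16 * n + 64) stop("matching stalled (numerical issue)");
        augmented = scan_queue();
        if (augmented) break;
        // Dual update.
        double delta = R_PosInf;
        int dtype = -1, darg = -1;
        for (int uu = 0; uu < n; ++uu) {
          if (label[inblossom[uu]] != 1) continue;
          for (int vv = 0; vv < n; ++vv) {
            int bv = inblossom[vv];
            if (bv == inblossom[uu]) continue;
            double s = slack(uu, vv);
            if (label[bv] == 1) {
              if (s / 2 < delta) { delta = s / 2; dtype = 3; }
            } else if (label[bv] == 0) {
              if (s < delta) { delta = s; dtype = 2; }
            }
          }
        }
        std::vector<int> tops = top_blossoms();
        for (size_t i = 0; i < tops.size(); ++i)
          if (label[tops[i]] == 2 && dual[tops[i]] / 2 < delta) {
            delta = dual[tops[i]] / 2;
            dtype = 4;
            darg = tops[i];
          }
        if (!R_finite(delta))
          stop("matching infeasible: no dual update possible");
        if (delta < 0) delta = 0;
        for (int v = 0; v < n; ++v) {
          int lb = label[inblossom[v]];
          if (lb == 1) dual[v] -= delta;
          else if (lb == 2) dual[v] += delta;
        }
        tops = top_blossoms();
        for (size_t i = 0; i < tops.size(); ++i) {
          if (label[tops[i]] == 1) dual[tops[i]] += 2 * delta;
          else if (label[tops[i]] == 2) dual[tops[i]] -= 2 * delta;
        }
        if (dtype == 4) expand_blossom(darg, false);
        push_all_s();
      }
      // End of phase: dissolve blossoms whose dual fell to zero.
      bool changed = true;
      while (changed) {
        changed = false;
        std::vector<int> tops = top_blossoms();
        for (size_t i = 0; i < tops.size(); ++i)
          if (dual[tops[i]] <= eps) {
            expand_blossom(tops[i], true);
            changed = true;
          }
      }
    }
  }
};

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_min_weight_perfect_matching(NumericMatrix D) {
  int n = D.nrow();
  if (D.ncol() != n) stop("distance matrix must be square");
  if (n % 2 != 0) stop("perfect matching requires an even number of points");
  if (n == 0) return IntegerVector(0);
  double maxd = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      if (!R_finite(D(i, j))) stop("distances must be finite");
      if (D(i, j) > maxd) maxd = D(i, j);
    }
  Blossom B;
  B.n = n;
  B.nslot = 2 * n;
  B.w.assign((size_t)n * n, 0.0);
  double C = 2 * maxd + 1;
  double maxw = 0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double wij = (i == j) ? 0.0 : C - 0.5 * (D(i, j) + D(j, i));
      B.w[i + (size_t)n * j] = wij;
      if (wij > maxw) maxw = wij;
    }
  B.eps = 1e-9 * (1 + maxw);
  B.mate.assign(n, -1);
  B.label.assign(B.nslot, 0);
  B.lab_u.assign(B.nslot, -1);
  B.lab_v.assign(B.nslot, -1);
  B.inblossom.resize(n);
  for (int v = 0; v < n; ++v) B.inblossom[v] = v;
  B.bparent.assign(B.nslot, -1);
  B.base.resize(B.nslot);
  for (int v = 0; v < B.nslot; ++v) B.base[v] = v < n ? v : -1;
  B.dual.assign(B.nslot, 0.0);
  for (int v = 0; v < n; ++v) B.dual[v] = maxw / 2;
  B.childs.resize(B.nslot);
  B.bedges.resize(B.nslot);
  B.used_slot.assign(B.nslot, false);
  for (int v = 0; v < n; ++v) B.used_slot[v] = true;
  B.solve();
  IntegerVector out(n);
  for (int v = 0; v < n; ++v) out[v] = B.mate[v] + 1; // 1-based for R
  return out;
}
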