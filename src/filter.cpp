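// Compiled whole-game belief filter.
//
// Mirrors the R reference implementation (R/model.R, R/filter.R) exactly:
// hypotheses are (state, confidence, mode, visited-bitmask) tuples; one game
// step conditions on the observed action through the confidence-appropriate
// strategy and propagates through the observed outcome scene, with backtrack
// re-estimation over the states consistent with the recent observable window.
// Used by negative_log_evidence / fitting, where the filter is evaluated many
// thousands of times; equivalence with the R path is asserted in the tests.
// Scene/transition/forward-policy tables are precomputed per call, and
// hypothesis merging works on 64-bit packed keys.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Maze {
  int R, C;
  std::vector<int> ew; // R x (C-1), row-major
  std::vector<int> ns; // (R-1) x C, row-major
  bool door(int r, int c, int dir) const {
    // dir: 0=N,1=E,2=S,3=W
    switch (dir) {
      case 0: return r >= 1 && ns[(r - 1) * C + c];
      case 2: return r <= R - 2 && ns[r * C + c];
      case 1: return c <= C - 2 && ew[r * (C - 1) + c];
      default: return c >= 1 && ew[r * (C - 1) + (c - 1)];
    }
  }
};

// state index: (r * C + c) * 4 + o, o in 0..3 (N,E,S,W)
inline int srow(const Maze& m, int s) { return (s >> 2) / m.C; }
inline int scol(const Maze& m, int s) { return (s >> 2) % m.C; }
inline int sori(int s) { return s & 3; }
inline int sidx(const Maze& m, int r, int c, int o) { return (r * m.C + c) * 4 + o; }

inline void step_cell(int r, int c, int dir, int& r2, int& c2) {
  r2 = r; c2 = c;
  if (dir == 0) r2 = r - 1;
  else if (dir == 2) r2 = r + 1;
  else if (dir == 1) c2 = c + 1;
  else c2 = c - 1;
}

// precomputed per-state tables
struct Tables {
  int n_states;
  std::vector<int> scene;          // 3-bit label per state
  std::vector<int> trans;          // n_states x 3 (left, forward, right)
  std::vector<uint32_t> cellmask;  // grid-cell bit per state
  std::vector<double> fwd;         // forward-dominant policy, n_states x 3
};

void build_tables(const Maze& m, double alpha, Tables& T) {
  T.n_states = m.R * m.C * 4;
  T.scene.resize(T.n_states);
  T.trans.resize(T.n_states * 3);
  T.cellmask.resize(T.n_states);
  T.fwd.resize(T.n_states * 3);
  for (int s = 0; s < T.n_states; ++s) {
    int r = srow(m, s), c = scol(m, s), o = sori(s);
    bool pa[3];
    pa[0] = m.door(r, c, (o + 3) & 3);
    pa[1] = m.door(r, c, o);
    pa[2] = m.door(r, c, (o + 1) & 3);
    T.scene[s] = 4 * pa[0] + 2 * pa[1] + pa[2];
    T.cellmask[s] = uint32_t(1) << (r * m.C + c);
    for (int a = 0; a < 3; ++a) {
      int no = (o + (a - 1) + 4) & 3;
      if (!m.door(r, c, no)) { T.trans[s * 3 + a] = s; continue; }
      int r2, c2; step_cell(r, c, no, r2, c2);
      T.trans[s * 3 + a] = sidx(m, r2, c2, no);
    }
    // forward-dominant strategy: forward if open, else right when both side
    // doors are open, else the first passable in (left, forward, right) order
    int opt;
    if (pa[1]) opt = 1;
    else if (pa[0] && pa[2]) opt = 2;
    else opt = pa[0] ? 0 : 2;
    int n_nopt = (pa[0] + pa[1] + pa[2]) - 1;
    for (int a = 0; a < 3; ++a) {
      if (a == opt) T.fwd[s * 3 + a] = n_nopt == 0 ? 1.0 : alpha;
      else T.fwd[s * 3 + a] = pa[a] ? (1.0 - alpha) / n_nopt : 0.0;
    }
  }
}

struct Hyp {
  int s, conf, mode; // mode: 0 update, 1 backtrack, 2 action_backtrack, 3 forced_update
  uint32_t vis;
  double w;
};

// grid-graph BFS distance from every cell to the nearest unvisited cell
void unvisited_dist(const Maze& m, uint32_t vis, std::vector<int>& d) {
  int n = m.R * m.C;
  d.assign(n, INT32_MAX);
  std::queue<int> q;
  for (int g = 0; g < n; ++g)
    if (!(vis & (uint32_t(1) << g))) { d[g] = 0; q.push(g); }
  while (!q.empty()) {
    int g = q.front(); q.pop();
    int r = g / m.C, c = g % m.C;
    for (int dir = 0; dir < 4; ++dir) {
      if (!m.door(r, c, dir)) continue;
      int r2, c2; step_cell(r, c, dir, r2, c2);
      int g2 = r2 * m.C + c2;
      if (d[g2] > d[g] + 1) { d[g2] = d[g] + 1; q.push(g2); }
    }
  }
}

void dist_from_optimal(const bool pa[3], const bool opt[3], double p_opt,
                       double out[3]) {
  int n_opt = 0, n_nopt = 0;
  for (int a = 0; a < 3; ++a) {
    out[a] = 0.0;
    if (opt[a]) ++n_opt;
    else if (pa[a]) ++n_nopt;
  }
  if (n_nopt == 0) {
    for (int a = 0; a < 3; ++a) if (opt[a]) out[a] = 1.0 / n_opt;
  } else {
    for (int a = 0; a < 3; ++a) {
      if (opt[a]) out[a] = p_opt / n_opt;
      else if (pa[a]) out[a] = (1.0 - p_opt) / n_nopt;
    }
  }
}

void efficient_exploration(const Maze& m, const Tables& T, int s,
                           uint32_t vis, double beta, double out[3]) {
  int lab = T.scene[s];
  bool pa[3] = {(lab & 4) != 0, (lab & 2) != 0, (lab & 1) != 0};
  int n_pa = pa[0] + pa[1] + pa[2];
  bool opt[3] = {false, false, false};
  if (n_pa == 1) {
    for (int a = 0; a < 3; ++a) opt[a] = pa[a];
    dist_from_optimal(pa, opt, 1.0, out);
    return;
  }
  bool any_unvis = false;
  for (int a = 0; a < 3; ++a) {
    if (!pa[a]) continue;
    int d = T.trans[s * 3 + a];
    if (!(vis & T.cellmask[d])) { opt[a] = true; any_unvis = true; }
  }
  if (!any_unvis) {
    uint32_t full = (uint32_t(1) << (m.R * m.C)) - 1;
    if ((vis & full) == full) {
      for (int a = 0; a < 3; ++a) opt[a] = pa[a];
    } else {
      std::vector<int> d;
      unvisited_dist(m, vis, d);
      int best = INT32_MAX;
      for (int a = 0; a < 3; ++a)
        if (pa[a]) {
          int t = T.trans[s * 3 + a];
          int g = srow(m, t) * m.C + scol(m, t);
          if (d[g] < best) best = d[g];
        }
      for (int a = 0; a < 3; ++a)
        if (pa[a]) {
          int t = T.trans[s * 3 + a];
          int g = srow(m, t) * m.C + scol(m, t);
          if (d[g] == best) opt[a] = true;
        }
    }
  }
  dist_from_optimal(pa, opt, beta, out);
}

// variant: 0 switching, 1 forward_only, 2 efficient_only
inline void policy(const Maze& m, const Tables& T, const Hyp& h,
                   double beta, int variant, double out[3]) {
  bool eff = (variant == 2) || (variant == 0 && h.conf == 1);
  if (eff) efficient_exploration(m, T, h.s, h.vis, beta, out);
  else {
    out[0] = T.fwd[h.s * 3];
    out[1] = T.fwd[h.s * 3 + 1];
    out[2] = T.fwd[h.s * 3 + 2];
  }
}

int classify(const Maze& m, const Tables& T, const Hyp& h, int a,
             int next_label) {
  int h2 = T.trans[h.s * 3 + a];
  if (T.scene[h2] != next_label) return 1; // backtrack
  bool same_cell = T.cellmask[h2] == T.cellmask[h.s];
  bool revisit = (h.vis & T.cellmask[h2]) != 0;
  if (revisit && !same_cell) {
    int lab = T.scene[h.s];
    bool pa[3] = {(lab & 4) != 0, (lab & 2) != 0, (lab & 1) != 0};
    bool all_visited = true;
    for (int aa = 0; aa < 3; ++aa) {
      if (!pa[aa]) continue;
      if (!(h.vis & T.cellmask[T.trans[h.s * 3 + aa]])) {
        all_visited = false; break;
      }
    }
    return all_visited ? 3 : 2; // forced_update : action_backtrack
  }
  return 0; // update
}

// states (with traversed-cell unions) consistent with the observable window
void history_consistent(const Maze& m, const Tables& T,
                        const std::vector<int>& win_scenes,
                        const std::vector<int>& win_actions,
                        std::vector<int>& states, std::vector<uint32_t>& vis) {
  std::vector<uint32_t> acc(T.n_states, 0);
  std::vector<char> hit(T.n_states, 0);
  for (int s0 = 0; s0 < T.n_states; ++s0) {
    if (T.scene[s0] != win_scenes[0]) continue;
    int s = s0;
    uint32_t cells = T.cellmask[s];
    bool ok = true;
    for (size_t i = 0; i < win_actions.size(); ++i) {
      s = T.trans[s * 3 + win_actions[i]];
      cells |= T.cellmask[s];
      if (T.scene[s] != win_scenes[i + 1]) { ok = false; break; }
    }
    if (!ok) continue;
    hit[s] = 1;
    acc[s] |= cells;
  }
  states.clear(); vis.clear();
  for (int s = 0; s < T.n_states; ++s)
    if (hit[s]) { states.push_back(s); vis.push_back(acc[s]); }
}

// hypothesis key packed into 64 bits: visited mask | state | conf | mode;
// sorting these keys groups identical hypotheses for merging
inline uint64_t pack_key(int s, int conf, int mode, uint32_t vis) {
  return (uint64_t(vis) << 32) | (uint64_t(s) << 4) |
         (uint64_t(conf) << 3) | uint64_t(mode);
}

struct Branch { uint64_t key; double w; };

} // namespace

// [[Rcpp::export]]
List cpp_filter_game(int n_rows, int n_cols,
                     LogicalMatrix doors_ew, LogicalMatrix doors_ns,
                     IntegerVector actions, IntegerVector scene_labels,
                     int final_label, IntegerVector pred_after,
                     double alpha, double beta, double p_lh, double p_hl,
                     int n_history, int variant, int visited_reset,
                     bool ab_resamples, double prune, double eps) {
  Maze m; m.R = n_rows; m.C = n_cols;
  m.ew.resize(n_rows * (n_cols - 1));
  m.ns.resize((n_rows - 1) * n_cols);
  for (int r = 0; r < n_rows; ++r)
    for (int c = 0; c < n_cols - 1; ++c)
      m.ew[r * (n_cols - 1) + c] = doors_ew(r, c);
  for (int r = 0; r < n_rows - 1; ++r)
    for (int c = 0; c < n_cols; ++c)
      m.ns[r * n_cols + c] = doors_ns(r, c);
  if (n_rows * n_cols > 30) stop("belief filtering supports mazes of at most 30 cells");

  Tables T;
  build_tables(m, alpha, T);

  int K = actions.size();
  NumericVector pred_probs(K);
  int zero_guard_count = 0;
  int n_pred = pred_after.size();
  NumericMatrix readouts(n_pred, 14);
  int pred_i = 0;

  // initial belief from the first scene
  std::vector<Hyp> belief;
  for (int s = 0; s < T.n_states; ++s)
    if (T.scene[s] == scene_labels[0])
      belief.push_back({s, 0, 0, T.cellmask[s], 0.0});
  if (belief.empty()) stop("inconsistent observation: first scene not realized");
  for (auto& h : belief) h.w = 1.0 / belief.size();

  std::vector<int> hist_scenes(1, scene_labels[0]);
  std::vector<int> hist_actions;
  std::vector<Branch> acc;
  std::vector<double> marg(T.n_states);

  for (int k = 0; k < K; ++k) {
    int a = actions[k];

    // prediction-trial read-outs (belief before conditioning on the action)
    if (pred_i < n_pred && pred_after[pred_i] == k + 1) {
      std::fill(marg.begin(), marg.end(), 0.0);
      double p1 = 0.0;
      for (auto& h : belief) { marg[h.s] += h.w; if (h.conf == 1) p1 += h.w; }
      double mx = 0.0;
      for (int s = 0; s < T.n_states; ++s) if (marg[s] > mx) mx = marg[s];
      int map_s = -1;
      for (int s = 0; s < T.n_states; ++s)
        if (marg[s] >= mx - 1e-12) { map_s = s; break; }
      // state confidence: max joint P(c=1, h) over the maximal-marginal
      // states, against the total mass at c=0
      double p0_total = 0.0;
      std::vector<double> p1s(T.n_states, 0.0);
      for (auto& h : belief) {
        if (h.conf == 1) p1s[h.s] += h.w;
        else p0_total += h.w;
      }
      double max_p1 = 0.0;
      for (int s = 0; s < T.n_states; ++s)
        if (marg[s] >= mx - 1e-12 && p1s[s] > max_p1) max_p1 = p1s[s];
      int c_hat = (max_p1 <= p0_total) ? 0 : 1;
      double dist[8] = {0, 0, 0, 0, 0, 0, 0, 0};
      for (auto& h : belief) dist[T.scene[T.trans[h.s * 3 + a]]] += h.w;
      int best_lab = 0; double best_p = -1.0;
      for (int l = 0; l < 8; ++l)
        if (dist[l] > best_p + 1e-12) { best_p = dist[l]; best_lab = l; }
      readouts(pred_i, 0) = c_hat;
      readouts(pred_i, 1) = p1;
      readouts(pred_i, 2) = srow(m, map_s);
      readouts(pred_i, 3) = scol(m, map_s);
      readouts(pred_i, 4) = sori(map_s);
      readouts(pred_i, 5) = best_lab;
      for (int l = 0; l < 8; ++l) readouts(pred_i, 6 + l) = dist[l];
      ++pred_i;
    }

    // phase 1: condition on the observed action
    std::vector<double> L(belief.size());
    double pred = 0.0;
    for (size_t i = 0; i < belief.size(); ++i) {
      double p[3];
      policy(m, T, belief[i], beta, variant, p);
      L[i] = p[a];
      pred += belief[i].w * L[i];
    }
    if (pred <= 0.0) {
      ++zero_guard_count;
      std::fill(L.begin(), L.end(), 1.0);
      pred_probs[k] = eps;
    } else {
      pred_probs[k] = pred;
    }
    double tot = 0.0;
    for (size_t i = 0; i < belief.size(); ++i) tot += belief[i].w * L[i];
    for (size_t i = 0; i < belief.size(); ++i) belief[i].w *= L[i] / tot;

    // outcome scene for this step
    int out_label = (k < K - 1) ? scene_labels[k + 1] : final_label;
    if (out_label < 0) { // truncated log: no observation after the last action
      hist_actions.push_back(a);
      continue;
    }

    // observable window for backtrack re-estimation:
    // up to n_history actions (including the current one) plus their scenes
    int nw = std::min(n_history - 1, (int)hist_actions.size());
    std::vector<int> win_scenes, win_actions;
    for (int i = (int)hist_actions.size() - nw; i < (int)hist_actions.size(); ++i) {
      win_scenes.push_back(hist_scenes[i]);
      win_actions.push_back(hist_actions[i]);
    }
    win_scenes.push_back(hist_scenes.back());
    win_actions.push_back(a);
    win_scenes.push_back(out_label);

    // phase 2: propagate through the outcome
    bool have_H = false;
    std::vector<int> H_states; std::vector<uint32_t> H_vis;
    acc.clear();
    for (auto& h : belief) {
      int mode = classify(m, T, h, a, out_label);
      double ct0, ct1;
      if (mode == 1 || mode == 2) { // backtrack confidence matrix
        if (h.conf == 0) { ct0 = 1.0; ct1 = 0.0; }
        else { ct0 = p_hl; ct1 = 1.0 - p_hl; }
      } else {                      // update confidence matrix
        if (h.conf == 0) { ct0 = 1.0 - p_lh; ct1 = p_lh; }
        else { ct0 = 0.0; ct1 = 1.0; }
      }
      bool resample = (mode == 1) || (mode == 2 && ab_resamples);
      if (!resample) {
        int h2 = T.trans[h.s * 3 + a];
        uint32_t vis = h.vis | T.cellmask[h2];
        if (ct0 > 0) acc.push_back({pack_key(h2, 0, mode, vis), h.w * ct0});
        if (ct1 > 0) acc.push_back({pack_key(h2, 1, mode, vis), h.w * ct1});
      } else {
        if (!have_H) {
          history_consistent(m, T, win_scenes, win_actions, H_states, H_vis);
          have_H = true;
          if (H_states.empty()) stop("re-estimation set empty; log inconsistent with maze");
        }
        double inv_k = 1.0 / H_states.size();
        for (size_t i = 0; i < H_states.size(); ++i) {
          int s2 = H_states[i];
          uint32_t vis;
          if (visited_reset == 0) vis = H_vis[i];
          else if (visited_reset == 1) vis = h.vis | T.cellmask[s2];
          else vis = T.cellmask[s2];
          if (ct0 > 0) acc.push_back({pack_key(s2, 0, mode, vis), h.w * ct0 * inv_k});
          if (ct1 > 0) acc.push_back({pack_key(s2, 1, mode, vis), h.w * ct1 * inv_k});
        }
      }
    }
    // merge identical keys, prune, renormalize
    std::sort(acc.begin(), acc.end(),
              [](const Branch& x, const Branch& y) { return x.key < y.key; });
    double tw = 0.0;
    for (auto& b : acc) tw += b.w;
    belief.clear();
    double kept = 0.0;
    size_t i = 0;
    while (i < acc.size()) {
      uint64_t key = acc[i].key;
      double w = 0.0;
      while (i < acc.size() && acc[i].key == key) { w += acc[i].w; ++i; }
      if (w / tw < prune) continue;
      Hyp h;
      h.vis = uint32_t(key >> 32);
      h.s = int((key >> 4) & 0x7FFFFFF);
      h.conf = int((key >> 3) & 1);
      h.mode = int(key & 7);
      h.w = w;
      belief.push_back(h);
      kept += w;
    }
    for (auto& h : belief) h.w /= kept;

    hist_actions.push_back(a);
    hist_scenes.push_back(out_label);
  }

  return List::create(_["pred_probs"] = pred_probs,
                      _["zero_guard_count"] = zero_guard_count,
                      _["readouts"] = readouts);
}
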