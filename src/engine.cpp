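// Core engines for the guarded-command pathway models:
//  - mc_simulate: Monte-Carlo trajectory simulation under the uniform
//    scheduler (uses R's RNG, so results are reproducible via set.seed)
//  - build_chain_cpp: breadth-first explicit-state enumeration of the
//    induced DTMC (states encoded base-6 in a 64-bit key)
//
// Command encoding (shared with R/.encodeCommands):
//   kind: 1 init, 2 source, 3 activation, 4 inhibition1, 5 inhibition2
//   src, tgt: 0-based gene indices (src = -1 where not applicable)
//   p1: probability of the first branch (second branch has 1 - p1)

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline bool cmd_enabled(int kind, int sv, int tv) {
  switch (kind) {
  case 1: return tv == -1;
  case 2: return tv == 1 || tv == 2;
  case 3: return sv > 2 && (tv == 1 || tv == 2);
  case 4: return sv < 3 && (tv == 1 || tv == 2);
  case 5: return sv > 2 && tv > 2;
  }
  return false;
}

static inline int apply_branch(int kind, int sv, int tv, bool first) {
  switch (kind) {
  case 1: return first ? 1 : 2;
  case 2: return first ? tv + 2 : 0;
  case 3: return first ? ((sv == 3 && tv == 1) ? 3 : 4) : 0;
  case 4: return first ? tv + 2 : 0;
  case 5: return first ? tv - 2 : 0;
  }
  return tv;
}

// [[Rcpp::export]]
List mc_simulate(IntegerVector kind, IntegerVector src, IntegerVector tgt,
                 NumericVector p1, int n_genes, IntegerVector targets,
                 int n_traj, int step_cap) {
  const int n_cmd = kind.size();
  const int n_tar = targets.size();
  // raw copies: the inner loop must not touch SEXP accessors
  std::vector<int> K(kind.begin(), kind.end());
  std::vector<int> S(src.begin(), src.end());
  std::vector<int> Tg(tgt.begin(), tgt.end());
  std::vector<double> P(p1.begin(), p1.end());
  std::vector<int> state(n_genes);
  std::vector<int> enabled(n_cmd);
  std::vector<int> tar_of(n_genes, -1);
  for (int t = 0; t < n_tar; ++t) tar_of[targets[t]] = t;
  std::vector<int> successes(n_tar, 0);
  std::vector<char> hit(n_tar);
  int censored = 0;

  for (int tr = 0; tr < n_traj; ++tr) {
    std::fill(state.begin(), state.end(), -1);
    std::fill(hit.begin(), hit.end(), 0);
    int n_hit = 0;
    bool stopped = false;  // deadlock or all targets reached
    int step = 0;
    for (; step < step_cap; ++step) {
      int m = 0;
      for (int c = 0; c < n_cmd; ++c) {
        int sv = S[c] >= 0 ? state[S[c]] : 0;
        if (cmd_enabled(K[c], sv, state[Tg[c]])) enabled[m++] = c;
      }
      if (m == 0) { stopped = true; break; }
      int c = enabled[(int)(unif_rand() * m)];
      if (c >= n_cmd) c = n_cmd - 1;  // guard against unif_rand() == 1
      int sv = S[c] >= 0 ? state[S[c]] : 0;
      bool first = unif_rand() < P[c];
      int nv = apply_branch(K[c], sv, state[Tg[c]], first);
      state[Tg[c]] = nv;
      if (nv == 4) {
        int t = tar_of[Tg[c]];
        if (t >= 0 && !hit[t]) { hit[t] = 1; ++n_hit; }
      }
      if (n_hit == n_tar) { stopped = true; break; }
    }
    if (!stopped) ++censored;
    for (int t = 0; t < n_tar; ++t) if (hit[t]) ++successes[t];
  }
  return List::create(_["successes"] = IntegerVector(successes.begin(),
                                                     successes.end()),
                      _["censored"] = censored);
}

// [[Rcpp::export]]
List build_chain_cpp(IntegerVector kind, IntegerVector src, IntegerVector tgt,
                     NumericVector p1, int n_genes, int state_cap) {
  if (n_genes > 24) stop("explicit-state engine supports at most 24 genes; "
                         "use the Monte-Carlo engine");
  const int n_cmd = kind.size();
  std::vector<int> K(kind.begin(), kind.end());
  std::vector<int> S(src.begin(), src.end());
  std::vector<int> Tg(tgt.begin(), tgt.end());
  std::vector<double> P(p1.begin(), p1.end());
  std::vector<uint64_t> pow6(n_genes);
  pow6[0] = 1;
  for (int g = 1; g < n_genes; ++g) pow6[g] = pow6[g - 1] * 6;

  std::vector<uint64_t> keys;
  std::unordered_map<uint64_t, int> index;
  std::vector<int> i_out, j_out;
  std::vector<double> x_out;
  bool capped = false;

  uint64_t init_key = 0;  // all variables -1 -> digit 0
  keys.push_back(init_key);
  index[init_key] = 0;

  std::vector<int> state(n_genes);
  std::unordered_map<uint64_t, double> succ;

  for (size_t idx = 0; idx < keys.size() && !capped; ++idx) {
    uint64_t key = keys[idx];
    for (int g = 0; g < n_genes; ++g)
      state[g] = (int)((key / pow6[g]) % 6) - 1;
    // enabled commands
    int m = 0;
    succ.clear();
    for (int c = 0; c < n_cmd; ++c) {
      int sv = S[c] >= 0 ? state[S[c]] : 0;
      if (cmd_enabled(K[c], sv, state[Tg[c]])) ++m;
    }
    if (m == 0) {  // deadlock: absorbing self-loop
      i_out.push_back((int)idx + 1);
      j_out.push_back((int)idx + 1);
      x_out.push_back(1.0);
      continue;
    }
    double w = 1.0 / m;
    for (int c = 0; c < n_cmd; ++c) {
      int sv = S[c] >= 0 ? state[S[c]] : 0;
      int tv = state[Tg[c]];
      if (!cmd_enabled(K[c], sv, tv)) continue;
      for (int br = 0; br < 2; ++br) {
        double pr = (br == 0 ? P[c] : 1.0 - P[c]) * w;
        if (pr <= 0) continue;
        int nv = apply_branch(K[c], sv, tv, br == 0);
        uint64_t nk = key + (uint64_t)(nv - tv) * pow6[Tg[c]];
        succ[nk] += pr;
      }
    }
    for (auto &kv : succ) {
      auto it = index.find(kv.first);
      int j;
      if (it == index.end()) {
        if ((int)keys.size() >= state_cap) { capped = true; break; }
        j = (int)keys.size();
        index[kv.first] = j;
        keys.push_back(kv.first);
      } else {
        j = it->second;
      }
      i_out.push_back((int)idx + 1);
      j_out.push_back(j + 1);
      x_out.push_back(kv.second);
    }
  }

  int n = (int)keys.size();
  IntegerMatrix states(n, n_genes);
  for (int s = 0; s < n; ++s)
    for (int g = 0; g < n_genes; ++g)
      states(s, g) = (int)((keys[s] / pow6[g]) % 6) - 1;

  return List::create(
    _["states"] = states,
    _["i"] = IntegerVector(i_out.begin(), i_out.end()),
    _["j"] = IntegerVector(j_out.begin(), j_out.end()),
    _["x"] = NumericVector(x_out.begin(), x_out.end()),
    _["capped"] = capped);
}
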