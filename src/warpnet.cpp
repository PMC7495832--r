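// Compiled inner loops: batch dynamic time warping over all cross-network
// node pairs, and the simulated-annealing search over one-to-one match
// sets. Both are called from thin R wrappers; all containers and scoring
// conventions are defined on the R side.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// DTW cumulative distance between two feature matrices (rows = time points)
// plus the length of the tie-broken optimal warping path (diagonal first,
// then the row-decreasing step, then the column step).
static void dtw_pair(const NumericMatrix& p, const NumericMatrix& q,
                     double& dist, int& path_len) {
  const int m = p.nrow(), n = q.nrow(), f = p.ncol();
  std::vector<double> lam((m + 1) * (n + 1),
                          std::numeric_limits<double>::infinity());
  std::vector<int> klen((m + 1) * (n + 1), 0);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };
  lam[at(0, 0)] = 0.0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double d = 0.0;
      for (int k = 0; k < f; ++k) {
        const double diff = p(i - 1, k) - q(j - 1, k);
        d += diff * diff;
      }
      const double diag = lam[at(i - 1, j - 1)];
      const double up   = lam[at(i - 1, j)];
      const double left = lam[at(i, j - 1)];
      double best = diag;
      int best_k = klen[at(i - 1, j - 1)];
      if (up < best) { best = up; best_k = klen[at(i - 1, j)]; }
      if (left < best) { best = left; best_k = klen[at(i, j - 1)]; }
      // tie-break for the recorded path length: diagonal, then up, then left
      if (diag == best) best_k = klen[at(i - 1, j - 1)];
      else if (up == best) best_k = klen[at(i - 1, j)];
      lam[at(i, j)] = d + best;
      klen[at(i, j)] = best_k + 1;
    }
  }
  dist = lam[at(m, n)];
  path_len = klen[at(m, n)];
}

// [[Rcpp::export]]
List dtw_cross_cpp(List seqs1, List seqs2) {
  const int n1 = seqs1.size(), n2 = seqs2.size();
  NumericMatrix D(n1, n2);
  IntegerMatrix K(n1, n2);
  std::vector<NumericMatrix> right(n2);
  for (int j = 0; j < n2; ++j) right[j] = as<NumericMatrix>(seqs2[j]);
  for (int i = 0; i < n1; ++i) {
    NumericMatrix p = as<NumericMatrix>(seqs1[i]);
    for (int j = 0; j < n2; ++j) {
      double d; int k;
      dtw_pair(p, right[j], d, k);
      D(i, j) = d;
      K(i, j) = k;
    }
  }
  return List::create(_["distance"] = D, _["path_len"] = K);
}

// Simulated annealing over one-to-one match sets. S holds the pair scores
// with NA marking inadmissible pairs; init is the 0-based starting match
// (init[i] = column matched to row i, or -1). Moves: with probability 1/2
// swap the partners of two random matched pairs (when both swapped pairs
// are admissible); otherwise pick a random row node and either reassign it
// to a random admissible free partner or unmatch it. Accept improvements
// always, deteriorations with probability exp(delta / T). Returns the best
// match encountered; its score is recomputed from S at the end.
// [[Rcpp::export]]
List sa_align_cpp(NumericMatrix S, IntegerVector init, double t0,
                  double cooling, int iters_per_temp, double min_temp,
                  int seed) {
  const int n1 = S.nrow(), n2 = S.ncol();
  std::vector<std::vector<int>> cand(n1);   // admissible columns per row
  for (int i = 0; i < n1; ++i)
    for (int j = 0; j < n2; ++j)
      if (!NumericMatrix::is_na(S(i, j))) cand[i].push_back(j);

  std::vector<int> match1(n1, -1), match2(n2, -1);
  double cur = 0.0;
  for (int i = 0; i < n1; ++i) {
    int j = init[i];
    if (j >= 0) {
      match1[i] = j;
      match2[j] = i;
      cur += S(i, j);
    }
  }
  // matched-row bookkeeping for O(1) uniform sampling of matched pairs
  std::vector<int> matched, pos(n1, -1);
  for (int i = 0; i < n1; ++i)
    if (match1[i] >= 0) { pos[i] = matched.size(); matched.push_back(i); }
  auto add_matched = [&](int i) { pos[i] = matched.size(); matched.push_back(i); };
  auto rm_matched = [&](int i) {
    int p = pos[i], last = matched.back();
    matched[p] = last; pos[last] = p;
    matched.pop_back(); pos[i] = -1;
  };

  std::vector<int> best_match = match1;
  double best = cur;

  std::mt19937 rng(static_cast<uint32_t>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  for (double T = t0; T >= min_temp; T *= cooling) {
    for (int it = 0; it < iters_per_temp; ++it) {
      if (unif(rng) < 0.5 && matched.size() >= 2) {
        // swap partners of two matched pairs
        int a = matched[(int)(unif(rng) * matched.size()) % matched.size()];
        int b = matched[(int)(unif(rng) * matched.size()) % matched.size()];
        if (a == b) continue;
        int ja = match1[a], jb = match1[b];
        if (NumericMatrix::is_na(S(a, jb)) || NumericMatrix::is_na(S(b, ja)))
          continue;
        double delta = S(a, jb) + S(b, ja) - S(a, ja) - S(b, jb);
        if (delta >= 0 || unif(rng) < std::exp(delta / T)) {
          match1[a] = jb; match1[b] = ja;
          match2[ja] = b; match2[jb] = a;
          cur += delta;
        }
      } else {
        // reassign one row node to a free admissible partner, or unmatch it
        int i = (int)(unif(rng) * n1) % n1;
        const std::vector<int>& ci = cand[i];
        // options: each free admissible partner, plus "unmatch" if matched
        int n_free = 0;
        for (int j : ci) if (match2[j] < 0) ++n_free;
        bool is_matched = match1[i] >= 0;
        int n_opt = n_free + (is_matched ? 1 : 0);
        if (n_opt == 0) continue;
        int pick = (int)(unif(rng) * n_opt) % n_opt;
        if (is_matched && pick == n_free) {
          double delta = -S(i, match1[i]);
          if (delta >= 0 || unif(rng) < std::exp(delta / T)) {
            match2[match1[i]] = -1;
            match1[i] = -1;
            rm_matched(i);
            cur += delta;
          }
        } else {
          int j_new = -1, seen = 0;
          for (int j : ci) {
            if (match2[j] < 0) {
              if (seen == pick) { j_new = j; break; }
              ++seen;
            }
          }
          double delta = S(i, j_new) - (is_matched ? S(i, match1[i]) : 0.0);
          if (delta >= 0 || unif(rng) < std::exp(delta / T)) {
            if (is_matched) match2[match1[i]] = -1;
            else add_matched(i);
            match1[i] = j_new;
            match2[j_new] = i;
            cur += delta;
          }
        }
      }
      if (cur > best) {
        best = cur;
        best_match = match1;
      }
    }
  }
  double best_exact = 0.0;
  for (int i = 0; i < n1; ++i)
    if (best_match[i] >= 0) best_exact += S(i, best_match[i]);
  return List::create(_["match"] = IntegerVector(best_match.begin(), best_match.end()),
                      _["score"] = best_exact);
}
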