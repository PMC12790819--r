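#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Count-preserving swap simulated annealing on a (possibly weighted) contact
// graph. The energy is the Frobenius norm ||P - rownorm(X'AX)||_F where the
// K x K contact count matrix TT is maintained incrementally: relabelling node
// i from a to b moves the weighted neighbour-type tally of i between the rows
// and columns a and b of TT (all-zero rows normalise to zero rows).
//
// The graph is passed in CSR form (0-based, both directions of every edge
// present, so TT counts ordered endpoint pairs). `selfw` carries the
// within-node contact weight used when a node represents a zone of cells
// (number of ordered intra-zone adjacent pairs); it contributes to TT[a,a].
//
// All randomness flows through R's RNG (RNGScope), so results are
// reproducible under set.seed().

namespace {

struct SAState {
  int N, K;
  std::vector<int> lab;                 // 0-based labels
  std::vector<double> TT;               // K x K, row-major
  const IntegerVector &ptr, &idx;
  const NumericVector &w, &selfw;
  const NumericMatrix &P;
  std::vector<double> tab;

  SAState(const IntegerVector &labels0, int K_,
          const IntegerVector &ptr_, const IntegerVector &idx_,
          const NumericVector &w_, const NumericVector &selfw_,
          const NumericMatrix &P_)
      : N(labels0.size()), K(K_), lab(N), TT(K_ * K_, 0.0),
        ptr(ptr_), idx(idx_), w(w_), selfw(selfw_), P(P_), tab(K_, 0.0) {
    for (int i = 0; i < N; ++i) lab[i] = labels0[i] - 1;
    for (int i = 0; i < N; ++i) {
      int a = lab[i];
      for (int p = ptr[i]; p < ptr[i + 1]; ++p)
        TT[a * K + lab[idx[p]]] += w[p];
      TT[a * K + a] += selfw[i];
    }
  }

  double energy() const {
    double e = 0.0;
    for (int a = 0; a < K; ++a) {
      double rs = 0.0;
      for (int b = 0; b < K; ++b) rs += TT[a * K + b];
      for (int b = 0; b < K; ++b) {
        double r = rs > 0.0 ? TT[a * K + b] / rs : 0.0;
        double d = P(a, b) - r;
        e += d * d;
      }
    }
    return std::sqrt(e);
  }

  void relabel(int i, int b) {
    int a = lab[i];
    std::fill(tab.begin(), tab.end(), 0.0);
    for (int p = ptr[i]; p < ptr[i + 1]; ++p) tab[lab[idx[p]]] += w[p];
    for (int c = 0; c < K; ++c) {
      double t = tab[c];
      if (t != 0.0) {
        TT[a * K + c] -= t; TT[c * K + a] -= t;
        TT[b * K + c] += t; TT[c * K + b] += t;
      }
    }
    TT[a * K + a] -= selfw[i];
    TT[b * K + b] += selfw[i];
    lab[i] = b;
  }

  int runif_int(int n) {
    int v = (int)(unif_rand() * n);
    return v >= n ? n - 1 : v;
  }

  // propose `swaps` label exchanges between nodes of different types,
  // applying them; records the pairs so the move can be reverted
  void propose(int swaps, std::vector<std::pair<int, int> > &moves) {
    moves.clear();
    for (int s = 0; s < swaps; ++s) {
      int i = runif_int(N), j = -1;
      for (int tries = 0; tries < 64; ++tries) {
        int cand = runif_int(N);
        if (lab[cand] != lab[i]) { j = cand; break; }
      }
      if (j < 0) continue;
      int a = lab[i], b = lab[j];
      relabel(i, b);
      relabel(j, a);
      moves.push_back(std::make_pair(i, j));
    }
  }

  void revert(const std::vector<std::pair<int, int> > &moves) {
    for (std::vector<std::pair<int, int> >::const_reverse_iterator it =
             moves.rbegin(); it != moves.rend(); ++it) {
      int i = it->first, j = it->second;
      int a = lab[i], b = lab[j];
      relabel(i, b);
      relabel(j, a);
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".sa_kernel")]]
List sa_kernel(IntegerVector labels0, int K,
               IntegerVector ptr, IntegerVector idx,
               NumericVector w, NumericVector selfw,
               NumericMatrix P,
               int swaps_per_iter, double t0, double alpha,
               double tmin_frac, int iters_per_temp, int stall_limit) {
  SAState st(labels0, K, ptr, idx, w, selfw, P);
  double curE = st.energy();
  double bestE = curE;
  std::vector<int> best(st.lab);
  std::vector<std::pair<int, int> > moves;

  // default initial temperature: mean |dE| over 100 random candidate moves
  if (t0 <= 0.0) {
    double acc = 0.0;
    int m = 0;
    for (int s = 0; s < 100; ++s) {
      st.propose(swaps_per_iter, moves);
      if (moves.empty()) continue;
      double e1 = st.energy();
      st.revert(moves);
      acc += std::fabs(e1 - curE);
      ++m;
    }
    t0 = m > 0 ? acc / m : 0.0;
    if (t0 <= 0.0) t0 = 1e-8;  // effectively greedy descent
  }

  std::vector<double> tr_temp, tr_cur, tr_best, tr_acc;
  double t = t0, tmin = t0 * tmin_frac;
  int stall = 0;
  bool done = false;

  while (!done && t >= tmin) {
    int accepted = 0;
    for (int it = 0; it < iters_per_temp; ++it) {
      st.propose(swaps_per_iter, moves);
      if (moves.empty()) {  // no valid move exists (e.g. single label left)
        if (++stall >= stall_limit) { done = true; break; }
        continue;
      }
      double newE = st.energy();
      double dE = newE - curE;
      if (dE <= 0.0 || unif_rand() < std::exp(-dE / t)) {
        curE = newE;
        ++accepted;
        stall = 0;
        if (curE < bestE - 1e-12) {
          bestE = curE;
          best = st.lab;
        }
      } else {
        st.revert(moves);
        if (++stall >= stall_limit) { done = true; break; }
      }
    }
    tr_temp.push_back(t);
    tr_cur.push_back(curE);
    tr_best.push_back(bestE);
    tr_acc.push_back((double)accepted / iters_per_temp);
    t *= alpha;
  }

  IntegerVector out(st.N);
  for (int i = 0; i < st.N; ++i) out[i] = best[i] + 1;
  return List::create(_["labels"] = out,
                      _["best_energy"] = bestE,
                      _["final_energy"] = curE,
                      _["t0"] = t0,
                      _["trace"] = DataFrame::create(
                          _["temperature"] = tr_temp,
                          _["objective"] = tr_cur,
                          _["best_objective"] = tr_best,
                          _["acceptance"] = tr_acc));
}
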