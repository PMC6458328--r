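#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Frequency-driven ("equal-input", F81-like over k states) simulation on a
// fixed tree.  Along a branch of length t (expected replacements per site)
// the transition probability is
//   P(i -> j | t) = pi_j * (1 - exp(-beta t)) + [i == j] * exp(-beta t),
// with beta = 1 / (1 - sum pi^2) so that t is measured in expected
// replacements per site at stationarity.  Callers pass, per edge, the
// pre-computed "event" probability q = 1 - exp(-beta t): a site either
// keeps the parental state or redraws from pi.  Sites are independent, so
// the event sites of an edge form a Bernoulli(q) process over columns; we
// sample them by geometric skipping (one RNG draw per event, not per
// site), which is exact and much faster on long alignments.  All
// randomness goes through R's RNG so set.seed() gives reproducible
// output.

static inline int draw_state(const double *cum, int k) {
  double u = unif_rand();
  for (int j = 0; j < k - 1; ++j)
    if (u <= cum[j]) return j;
  return k - 1;
}

static void cumulate(const NumericVector &freqs, std::vector<double> &cum) {
  double acc = 0.0;
  for (int j = 0; j < freqs.size(); ++j) {
    acc += freqs[j];
    cum[j] = acc;
  }
  cum[freqs.size() - 1] = 1.0;
}

// Simulate one replicate into st (row-major: st[node * L + site]).
static void sim_replicate(std::vector<int> &st, const IntegerVector &parent,
                          const IntegerVector &child,
                          const NumericVector &event_prob, int root,
                          const double *cum, int k, int L) {
  int *root_row = st.data() + (size_t)root * L;
  for (int s = 0; s < L; ++s) root_row[s] = draw_state(cum, k);
  int ne = parent.size();
  for (int e = 0; e < ne; ++e) {
    const int *pr = st.data() + (size_t)parent[e] * L;
    int *cr = st.data() + (size_t)child[e] * L;
    std::copy(pr, pr + L, cr);
    double q = event_prob[e];
    if (q <= 0.0) continue;
    if (q >= 1.0) {
      for (int s = 0; s < L; ++s) cr[s] = draw_state(cum, k);
      continue;
    }
    double log1mq = std::log1p(-q);
    long pos = -1;
    for (;;) {
      double u = unif_rand();
      pos += 1 + (long)std::floor(std::log(u) / log1mq);
      if (pos >= L) break;
      cr[pos] = draw_state(cum, k);
    }
  }
}

// Simulate states (0-based, in 0..k-1) at every node of a tree.  Edges
// must be in preorder (every parent appears as a child earlier, root
// excepted); node indices are 0-based with the root at index `root`.
// Returns an n_nodes x length integer matrix.
// [[Rcpp::export]]
IntegerMatrix sim_node_states_cpp(IntegerVector parent, IntegerVector child,
                                  NumericVector event_prob, int n_nodes,
                                  int root, NumericVector freqs, int length) {
  int k = freqs.size();
  std::vector<double> cum(k);
  cumulate(freqs, cum);
  std::vector<int> st((size_t)n_nodes * length);
  RNGScope scope;
  sim_replicate(st, parent, child, event_prob, root, cum.data(), k, length);
  IntegerMatrix out(n_nodes, length);
  for (int v = 0; v < n_nodes; ++v)
    for (int s = 0; s < length; ++s)
      out(v, s) = st[(size_t)v * length + s];
  return out;
}

// Null distribution of the composition chi-square statistic: simulate
// `n_sims` replicate alignments of `length` columns on the guide tree,
// apply the observed presence mask (n_tip x length; 1 = residue observed
// at that taxon/column), and return the X^2 of the masked tip-by-state
// count table of each replicate.  Conditioning the null on the observed
// gap pattern matters: taxa that sample different column windows convert
// shared column-level variance into between-taxon variance, which
// full-length replicates would miss.  Tips are node indices 0..n_tip-1
// (ape numbering shifted to 0-based).
// [[Rcpp::export]]
NumericVector x2_null_cpp(IntegerVector parent, IntegerVector child,
                          NumericVector event_prob, int n_nodes, int root,
                          int n_tip, NumericVector freqs, int length,
                          int n_sims, IntegerMatrix mask) {
  int k = freqs.size();
  if (mask.nrow() != n_tip || mask.ncol() != length)
    stop("mask must be n_tip x length");
  std::vector<double> cum(k);
  cumulate(freqs, cum);
  std::vector<int> st((size_t)n_nodes * length);
  std::vector<double> counts((size_t)n_tip * k);
  std::vector<double> rowtot(n_tip, 0.0);
  double grand = 0.0;
  for (int t = 0; t < n_tip; ++t) {
    for (int s = 0; s < length; ++s) rowtot[t] += mask(t, s);
    grand += rowtot[t];
  }
  NumericVector x2(n_sims);
  RNGScope scope;
  for (int r = 0; r < n_sims; ++r) {
    sim_replicate(st, parent, child, event_prob, root, cum.data(), k, length);
    std::fill(counts.begin(), counts.end(), 0.0);
    for (int t = 0; t < n_tip; ++t) {
      const int *row = st.data() + (size_t)t * length;
      double *crow = counts.data() + (size_t)t * k;
      for (int s = 0; s < length; ++s)
        if (mask(t, s)) crow[row[s]] += 1.0;
    }
    double stat = 0.0;
    for (int j = 0; j < k; ++j) {
      double colsum = 0.0;
      for (int t = 0; t < n_tip; ++t) colsum += counts[(size_t)t * k + j];
      if (colsum <= 0.0) continue;
      for (int t = 0; t < n_tip; ++t) {
        double e = rowtot[t] * colsum / grand;
        if (e <= 0.0) continue;
        double d = counts[(size_t)t * k + j] - e;
        stat += d * d / e;
      }
    }
    x2[r] = stat;
    if ((r & 31) == 0) Rcpp::checkUserInterrupt();
  }
  return x2;
}
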