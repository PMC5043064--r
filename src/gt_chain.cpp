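#include <Rcpp.h>
using namespace Rcpp;

// Guo-Thompson style Markov chain for exact Hardy-Weinberg tests.
//
// The chain swaps one randomly chosen allele copy between two randomly
// chosen individuals. Viewed on the space of ordered arrangements of the
// 2n gene copies this is a random-transposition walk, which is doubly
// stochastic and hence uniform at stationarity; projecting onto unordered
// genotype tables recovers exactly the Levene distribution (a labelled
// genotype list has 2^h ordered preimages, h = heterozygote count, and
// the proposal asymmetry cancels this weight, so every proposal is
// accepted). Both test criteria below are evaluated against that
// stationary law.

namespace {

struct LocusChain {
  int n;                 // individuals
  int k;                 // alleles
  std::vector<int> A1, A2;      // per-individual allele indices (0-based)
  std::vector<int> cell;        // cell counts, index i*(i+1)/2+j for i>=j
  int h;                        // heterozygote count
  double logpi;                 // h*log2 - sum lgamma(cell+1) (+const)

  int cidx(int a, int b) const {
    int i = std::max(a, b), j = std::min(a, b);
    return i * (i + 1) / 2 + j;
  }

  void init(const IntegerMatrix& counts) {
    k = counts.nrow();
    cell.assign(k * (k + 1) / 2, 0);
    A1.clear(); A2.clear();
    h = 0;
    for (int i = 0; i < k; ++i)
      for (int j = 0; j <= i; ++j) {
        int c = counts(i, j);
        if (i != j) c += counts(j, i);  // accept full symmetric input
        cell[cidx(i, j)] = c;
        for (int t = 0; t < c; ++t) { A1.push_back(i); A2.push_back(j); }
        if (i != j) h += c;
      }
    n = (int)A1.size();
    logpi = h * std::log(2.0);
    for (size_t c = 0; c < cell.size(); ++c)
      logpi -= std::lgamma((double)cell[c] + 1.0);
  }

  // one proposed switch; updates state in place when accepted
  void step() {
    if (n < 2) return;
    int i1 = (int)(unif_rand() * n);
    int i2 = (int)(unif_rand() * (n - 1));
    if (i2 >= i1) ++i2;
    bool s1 = unif_rand() < 0.5, s2 = unif_rand() < 0.5;
    int x = s1 ? A1[i1] : A2[i1];
    int y = s2 ? A1[i2] : A2[i2];
    // genotypes after the swap
    int g1a = s1 ? y : A1[i1], g1b = s1 ? A2[i1] : y;
    int g2a = s2 ? x : A1[i2], g2b = s2 ? A2[i2] : x;
    int dh = 0;
    dh += (g1a != g1b) - (A1[i1] != A2[i1]);
    dh += (g2a != g2b) - (A1[i2] != A2[i2]);
    // always accepted (see header comment); update cells/logpi
    int c_old1 = cidx(A1[i1], A2[i1]), c_old2 = cidx(A1[i2], A2[i2]);
    int c_new1 = cidx(g1a, g1b), c_new2 = cidx(g2a, g2b);
    logpi += dh * std::log(2.0);
    int touch[4] = {c_old1, c_old2, c_new1, c_new2};
    int delta[4] = {-1, -1, +1, +1};
    // sequential per-cell updates: exact even when cells coincide
    for (int t = 0; t < 4; ++t) {
      logpi += std::lgamma((double)cell[touch[t]] + 1.0);
      cell[touch[t]] += delta[t];
      logpi -= std::lgamma((double)cell[touch[t]] + 1.0);
    }
    A1[i1] = std::min(g1a, g1b); A2[i1] = std::max(g1a, g1b);
    A1[i2] = std::min(g2a, g2b); A2[i2] = std::max(g2a, g2b);
    h += dh;
  }

  // recompute logpi from the cell counts (kills float drift; called once
  // per batch so tie comparisons stay exact over long runs)
  void refresh_logpi() {
    logpi = h * std::log(2.0);
    for (size_t c = 0; c < cell.size(); ++c)
      logpi -= std::lgamma((double)cell[c] + 1.0);
  }
};

}  // namespace

// [[Rcpp::export(name = ".gt_chain")]]
List gt_chain(IntegerMatrix counts, int dememorization, int batches,
              int iter_per_batch) {
  LocusChain ch;
  ch.init(counts);
  const double obs_logpi = ch.logpi + 1e-9;
  const int obs_h = ch.h;
  for (int t = 0; t < dememorization; ++t) ch.step();
  NumericVector bp_prob(batches), bp_def(batches), bp_exc(batches);
  for (int b = 0; b < batches; ++b) {
    ch.refresh_logpi();
    int hit_prob = 0, hit_def = 0, hit_exc = 0;
    for (int t = 0; t < iter_per_batch; ++t) {
      ch.step();
      if (ch.logpi <= obs_logpi) ++hit_prob;
      if (ch.h <= obs_h) ++hit_def;
      if (ch.h >= obs_h) ++hit_exc;
    }
    bp_prob[b] = (double)hit_prob / iter_per_batch;
    bp_def[b] = (double)hit_def / iter_per_batch;
    bp_exc[b] = (double)hit_exc / iter_per_batch;
  }
  return List::create(_["batch_prob"] = bp_prob, _["batch_def"] = bp_def,
                      _["batch_exc"] = bp_exc);
}

// Multilocus heterozygote-deficiency chain: independent per-locus chains
// advanced in lock step; the global statistic is the summed heterozygote
// count across loci.
// [[Rcpp::export(name = ".gt_chain_global")]]
List gt_chain_global(List counts_list, int dememorization, int batches,
                     int iter_per_batch) {
  int L = counts_list.size();
  std::vector<LocusChain> chains(L);
  int obs_tot = 0;
  for (int l = 0; l < L; ++l) {
    chains[l].init(as<IntegerMatrix>(counts_list[l]));
    obs_tot += chains[l].h;
  }
  for (int t = 0; t < dememorization; ++t)
    for (int l = 0; l < L; ++l) chains[l].step();
  NumericVector bp_def(batches);
  for (int b = 0; b < batches; ++b) {
    int hit = 0;
    for (int t = 0; t < iter_per_batch; ++t) {
      int tot = 0;
      for (int l = 0; l < L; ++l) { chains[l].step(); tot += chains[l].h; }
      if (tot <= obs_tot) ++hit;
    }
    bp_def[b] = (double)hit / iter_per_batch;
  }
  return List::create(_["batch_def"] = bp_def, _["obs_total_het"] = obs_tot);
}
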