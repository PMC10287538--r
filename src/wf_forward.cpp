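// Forward Wright-Fisher sweep simulator (fixture scale).
//
// Haploid population of N chromosomes, infinite-sites mutation, single
// crossover recombination, one selected site. The beneficial allele starts
// from the supplied focal column (standing variation) or is injected de novo
// in a single copy; the trajectory is conditioned on reaching the target
// ending frequency by rejection (restart on loss), selection is lifted at
// the target and the population drifts tau further generations before
// sampling. Uses R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Pop {
  std::vector<std::vector<uint8_t>> cols;  // one vector<N> per site
  std::vector<double> pos;                 // sorted positions, bp
  int focal;                               // index into cols, -1 if none yet
};

int weighted_parent(const std::vector<uint8_t> &sel, double s, int N) {
  // rejection sampling against max fitness 1+s
  for (;;) {
    int i = (int)(unif_rand() * N);
    if (i >= N) i = N - 1;
    double w = sel.empty() ? 1.0 : (sel[i] ? 1.0 + s : 1.0);
    if (s <= 0.0 || unif_rand() * (1.0 + s) <= w) return i;
  }
}

int focal_count(const Pop &p, int N) {
  if (p.focal < 0) return 0;
  int c = 0;
  for (int i = 0; i < N; ++i) c += p.cols[p.focal][i];
  return c;
}

void step(Pop &p, int N, double s, double mut_total, double rec_prob,
          double L) {
  const bool selected = s > 0.0 && p.focal >= 0;
  std::vector<uint8_t> sel;
  if (selected) sel = p.cols[p.focal];

  std::vector<int> parent(N);
  for (int i = 0; i < N; ++i)
    parent[i] = weighted_parent(sel, selected ? s : 0.0, N);

  const int S = (int)p.cols.size();
  std::vector<std::vector<uint8_t>> next(S, std::vector<uint8_t>(N));
  for (int j = 0; j < S; ++j) {
    const std::vector<uint8_t> &cur = p.cols[j];
    std::vector<uint8_t> &nx = next[j];
    for (int i = 0; i < N; ++i) nx[i] = cur[parent[i]];
  }

  // recombination: replace the right-hand segment with a second parent
  for (int i = 0; i < N; ++i) {
    if (unif_rand() < rec_prob) {
      int p2 = weighted_parent(sel, selected ? s : 0.0, N);
      double bp = unif_rand() * L;
      int j0 = (int)(std::lower_bound(p.pos.begin(), p.pos.end(), bp) -
                     p.pos.begin());
      for (int j = j0; j < S; ++j) next[j][i] = p.cols[j][p2];
    }
  }
  p.cols.swap(next);

  // new mutations (infinite sites, continuous positions)
  int nmut = (int)R::rpois(mut_total);
  for (int m = 0; m < nmut; ++m) {
    double bp = unif_rand() * L;
    int at = (int)(std::lower_bound(p.pos.begin(), p.pos.end(), bp) -
                   p.pos.begin());
    if (at < (int)p.pos.size() && p.pos[at] == bp) continue;
    std::vector<uint8_t> col(N, 0);
    int carrier = (int)(unif_rand() * N);
    if (carrier >= N) carrier = N - 1;
    col[carrier] = 1;
    p.cols.insert(p.cols.begin() + at, std::move(col));
    p.pos.insert(p.pos.begin() + at, bp);
    if (p.focal >= at) ++p.focal;
  }

  // prune lost and fixed columns (keep the focal column whatever its state)
  const int f_orig = p.focal;
  int new_focal = -1;
  int keep = 0;
  for (int j = 0; j < (int)p.cols.size(); ++j) {
    int c = 0;
    for (int i = 0; i < N; ++i) c += p.cols[j][i];
    const bool is_focal = (j == f_orig);
    if (is_focal || (c > 0 && c < N)) {
      if (keep != j) {
        p.cols[keep] = std::move(p.cols[j]);
        p.pos[keep] = p.pos[j];
      }
      if (is_focal) new_focal = keep;
      ++keep;
    }
  }
  p.focal = new_focal;
  p.cols.resize(keep);
  p.pos.resize(keep);
}

}  // namespace

// [[Rcpp::export]]
List wf_forward_cpp(IntegerMatrix init, NumericVector init_pos,
                    double locus_length, int focal0, double s, double eaf,
                    int tau, double mut_total, double rec_prob,
                    int max_restarts, int n_sample, int max_generations) {
  const int N = init.nrow();
  const int S0 = init.ncol();

  Pop start;
  start.cols.resize(S0, std::vector<uint8_t>(N));
  for (int j = 0; j < S0; ++j)
    for (int i = 0; i < N; ++i) start.cols[j][i] = (uint8_t)init(i, j);
  start.pos.assign(init_pos.begin(), init_pos.end());
  start.focal = focal0;

  if (start.focal < 0) {
    // de novo: inject a single copy at the locus centre
    double bp = locus_length / 2.0;
    int at = (int)(std::lower_bound(start.pos.begin(), start.pos.end(), bp) -
                   start.pos.begin());
    std::vector<uint8_t> col(N, 0);
    col[0] = 1;  // placeholder copy; the carrier is re-randomized per attempt
    start.cols.insert(start.cols.begin() + at, col);
    start.pos.insert(start.pos.begin() + at, bp);
    start.focal = at;
  }

  const int target = std::max(1, (int)std::ceil(eaf * N));
  int restarts = 0;
  int gens_used = 0;
  Pop p;

  for (;;) {
    if (restarts > max_restarts)
      stop("sweep trajectory failed to reach the target frequency after %d "
           "restarts", restarts - 1);
    p = start;
    bool ok = false;
    int carrier = (int)(unif_rand() * N);  // fresh de-novo carrier per try
    if (carrier >= N) carrier = N - 1;
    if (std::count(p.cols[p.focal].begin(), p.cols[p.focal].end(),
                   (uint8_t)1) == 1) {
      std::fill(p.cols[p.focal].begin(), p.cols[p.focal].end(), (uint8_t)0);
      p.cols[p.focal][carrier] = 1;
    }
    gens_used = 0;
    while (gens_used < max_generations) {
      step(p, N, s, mut_total, rec_prob, locus_length);
      ++gens_used;
      int c = focal_count(p, N);
      if (c == 0) break;            // lost: restart
      if (c >= target) { ok = true; break; }
    }
    if (ok) break;
    ++restarts;
  }

  // selection lifted: drift for tau generations
  for (int g = 0; g < tau; ++g)
    step(p, N, 0.0, mut_total, rec_prob, locus_length);

  // sample without replacement
  std::vector<int> perm(N);
  for (int i = 0; i < N; ++i) perm[i] = i;
  for (int i = 0; i < n_sample; ++i) {
    int j = i + (int)(unif_rand() * (N - i));
    if (j >= N) j = N - 1;
    std::swap(perm[i], perm[j]);
  }

  const int S = (int)p.cols.size();
  std::vector<int> segcols;
  segcols.reserve(S);
  for (int j = 0; j < S; ++j) {
    int c = 0;
    for (int i = 0; i < n_sample; ++i) c += p.cols[j][perm[i]];
    if (c > 0 && c < n_sample) segcols.push_back(j);
  }

  IntegerMatrix out(n_sample, (int)segcols.size());
  NumericVector opos((int)segcols.size());
  int focal_out = -1;
  for (int k = 0; k < (int)segcols.size(); ++k) {
    int j = segcols[k];
    if (j == p.focal) focal_out = k;
    opos[k] = p.pos[j];
    for (int i = 0; i < n_sample; ++i) out(i, k) = p.cols[j][perm[i]];
  }

  double pop_freq = (double)focal_count(p, N) / N;
  double sample_freq = 0.0;
  if (p.focal >= 0) {
    int c = 0;
    for (int i = 0; i < n_sample; ++i) c += p.cols[p.focal][perm[i]];
    sample_freq = (double)c / n_sample;
  }

  return List::create(
      _["alleles"] = out, _["positions"] = opos,
      _["focal_index"] = focal_out + 1,  // 1-based, 0 if non-segregating
      _["focal_pop_freq"] = pop_freq, _["focal_sample_freq"] = sample_freq,
      _["generations"] = gens_used, _["restarts"] = restarts);
}
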