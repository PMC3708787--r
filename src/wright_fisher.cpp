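#include <Rcpp.h>
#include <vector>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

// Forward-time haploid Wright-Fisher simulator with recombination, island
// migration and an optional selective sweep.
//
// The founding generation is a mosaic-copying process over `n_founders`
// random founder haplotypes: each chromosome copies founder segments whose
// genetic lengths are Exponential(mean seg_cM), which creates block-like
// background LD. The sweep allele is seeded in deme 0 by overwriting
// round(f0 * N) chromosomes with copies of one carrier haplotype (a single
// mutational origin that has drifted to f0). Each generation, every deme
// produces N offspring by sampling two parents with probability proportional
// to fitness (1 + s for sweep-allele carriers in deme 0; neutral elsewhere)
// and recombining them with a Poisson number of crossovers at the map's cM
// rate; chromosomes then swap demes with probability m. No mutation occurs
// during the forward phase.
//
// Returns the final population (rows = chromosomes, grouped by deme), the
// final sweep-allele frequency per deme, the seeded carrier haplotype, and a
// flag when the sweep allele was lost everywhere.

static inline int sample_parent(const std::vector<double>& cumw, double W) {
  double u = unif_rand() * W;
  int lo = 0, hi = (int) cumw.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cumw[mid] > u) hi = mid; else lo = mid + 1;
  }
  return lo;
}

// [[Rcpp::export]]
List sim_sweep_cpp(int n_demes, int N, double m, NumericVector pos_cM,
                   double s, int sweep_site, double f0, int n_gen,
                   int n_founders, double seg_cM) {
  const int L = pos_cM.size();
  const int total = n_demes * N;
  const double cM0 = pos_cM[0], cMspan = pos_cM[L - 1] - pos_cM[0];

  std::vector<unsigned char> cur((size_t) total * L), nxt((size_t) total * L);

  // founder haplotypes
  std::vector<unsigned char> founders((size_t) n_founders * L);
  for (size_t i = 0; i < founders.size(); ++i)
    founders[i] = unif_rand() < 0.5 ? 1 : 0;
  for (int f = 0; f < n_founders; ++f)
    founders[(size_t) f * L + sweep_site] = 0;  // sweep allele absent

  // mosaic founding generation
  for (int c = 0; c < total; ++c) {
    unsigned char* row = &cur[(size_t) c * L];
    int f = (int) (unif_rand() * n_founders); if (f >= n_founders) f = n_founders - 1;
    double brk = cM0 + exp_rand() * seg_cM;
    for (int j = 0; j < L; ++j) {
      while (pos_cM[j] >= brk) {
        f = (int) (unif_rand() * n_founders); if (f >= n_founders) f = n_founders - 1;
        brk += exp_rand() * seg_cM;
      }
      row[j] = founders[(size_t) f * L + j];
    }
  }

  // seed the sweep in deme 0 from a single carrier haplotype
  int n_seed = (int) std::lround(f0 * N);
  if (n_seed < 1) n_seed = 1;
  int origin = (int) (unif_rand() * N); if (origin >= N) origin = N - 1;
  cur[(size_t) origin * L + sweep_site] = 1;
  IntegerVector seed_hap(L);
  for (int j = 0; j < L; ++j) seed_hap[j] = cur[(size_t) origin * L + j];
  {
    // copy onto n_seed - 1 other distinct chromosomes of deme 0
    std::vector<int> perm(N);
    for (int i = 0; i < N; ++i) perm[i] = i;
    std::swap(perm[0], perm[origin]);
    for (int k = 1; k < n_seed; ++k) {
      int pick = k + (int) (unif_rand() * (N - k));
      if (pick >= N) pick = N - 1;
      std::swap(perm[k], perm[pick]);
      std::memcpy(&cur[(size_t) perm[k] * L], &cur[(size_t) origin * L], L);
    }
  }

  std::vector<double> cumw(N);
  std::vector<double> cross; cross.reserve(16);

  for (int g = 0; g < n_gen; ++g) {
    for (int dm = 0; dm < n_demes; ++dm) {
      const unsigned char* deme = &cur[(size_t) dm * N * L];
      unsigned char* out = &nxt[(size_t) dm * N * L];
      double W = 0.0;
      const double sd = (dm == 0) ? s : 0.0;
      for (int i = 0; i < N; ++i) {
        W += 1.0 + sd * deme[(size_t) i * L + sweep_site];
        cumw[i] = W;
      }
      for (int off = 0; off < N; ++off) {
        int p1 = sample_parent(cumw, W);
        int ncx = (int) R::rpois(cMspan / 100.0);
        unsigned char* dst = &out[(size_t) off * L];
        if (ncx == 0) {
          std::memcpy(dst, &deme[(size_t) p1 * L], L);
          continue;
        }
        int p2 = sample_parent(cumw, W);
        cross.clear();
        for (int x = 0; x < ncx; ++x) cross.push_back(cM0 + unif_rand() * cMspan);
        std::sort(cross.begin(), cross.end());
        const unsigned char* par[2] = { &deme[(size_t) p1 * L],
                                        &deme[(size_t) p2 * L] };
        int which = 0, cx = 0, j0 = 0;
        for (int j = 0; j < L; ++j) {
          while (cx < ncx && pos_cM[j] >= cross[cx]) {
            if (j > j0) std::memcpy(dst + j0, par[which] + j0, j - j0);
            j0 = j; which ^= 1; ++cx;
          }
          if (cx >= ncx) break;
        }
        std::memcpy(dst + j0, par[which] + j0, L - j0);
      }
    }
    std::swap(cur, nxt);
    // conservative migration: every chromosome emigrates with probability m
    // to a uniformly chosen other deme; emigrants are exchanged pairwise
    // between demes (unmatched intents are dropped) so deme sizes stay fixed
    // and the realised per-chromosome migration rate is ~m
    if (n_demes > 1 && m > 0) {
      std::vector< std::vector<int> > intent(n_demes * n_demes);
      for (int c = 0; c < total; ++c) {
        if (unif_rand() < m) {
          int dm = c / N;
          int od = (int) (unif_rand() * (n_demes - 1));
          if (od >= n_demes - 1) od = n_demes - 2;
          if (od >= dm) ++od;
          intent[dm * n_demes + od].push_back(c);
        }
      }
      for (int a = 0; a < n_demes; ++a) {
        for (int b = a + 1; b < n_demes; ++b) {
          std::vector<int>& ab = intent[a * n_demes + b];
          std::vector<int>& ba = intent[b * n_demes + a];
          // shuffle the longer list so the dropped surplus is random
          std::vector<int>& lng = ab.size() > ba.size() ? ab : ba;
          for (int i = (int) lng.size() - 1; i > 0; --i) {
            int j = (int) (unif_rand() * (i + 1)); if (j > i) j = i;
            std::swap(lng[i], lng[j]);
          }
          size_t k = std::min(ab.size(), ba.size());
          for (size_t i = 0; i < k; ++i)
            for (int x = 0; x < L; ++x)
              std::swap(cur[(size_t) ab[i] * L + x],
                        cur[(size_t) ba[i] * L + x]);
        }
      }
    }
  }

  NumericVector freq(n_demes);
  for (int dm = 0; dm < n_demes; ++dm) {
    int cnt = 0;
    for (int i = 0; i < N; ++i)
      cnt += cur[((size_t) dm * N + i) * L + sweep_site];
    freq[dm] = (double) cnt / N;
  }
  bool lost = true;
  for (int dm = 0; dm < n_demes; ++dm) if (freq[dm] > 0) lost = false;

  IntegerMatrix H(total, L);
  for (int c = 0; c < total; ++c)
    for (int j = 0; j < L; ++j)
      H(c, j) = cur[(size_t) c * L + j];

  return List::create(_["haplotypes"] = H, _["sweep_freq"] = freq,
                      _["seed_hap"] = seed_hap, _["lost"] = lost);
}
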