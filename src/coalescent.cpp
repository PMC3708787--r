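#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Structured coalescent under the finite island model, one locus at a time.
//
// Sampled lineages start in the first r of d demes (n_by_deme chromosomes
// each). Within a deme, k_j lineages coalesce at rate choose(k_j, 2) (time in
// 2N-deme units); every lineage migrates at rate M/2 to a uniformly chosen
// other deme. Infinite-alleles mutations fall on the genealogy at rate
// theta/2 per branch-length unit; allelic classes are collapsed to biallelic
// (most frequent allele vs all others pooled). Loci monomorphic after
// collapse are rejected and redrawn.
//
// Returns the per-deme count of the major allele for every locus, plus the
// total number of rejected (monomorphic) draws. Uses R's RNG stream.

// [[Rcpp::export]]
List sim_island_loci_cpp(IntegerVector n_by_deme, int d_total, double M,
                         NumericVector theta_by_locus, double max_redraws) {
  const int r = n_by_deme.size();
  int k0 = 0;
  for (int i = 0; i < r; ++i) k0 += n_by_deme[i];
  const int n_loci = theta_by_locus.size();
  const int nnodes = 2 * k0 - 1;

  IntegerMatrix counts(n_loci, r);
  double redraws = 0.0;

  std::vector<int> parent(nnodes), mutc(nnodes), allele(nnodes);
  std::vector<double> ntime(nnodes);
  std::vector<int> lin(k0), linDeme(k0), leafDeme(k0), kj(d_total);
  std::vector<int> inDeme;  // scratch: active-list positions in chosen deme
  inDeme.reserve(k0);

  for (int locus = 0; locus < n_loci; ++locus) {
    const double theta = theta_by_locus[locus];
    bool poly = false;
    while (!poly) {
      // --- initialise lineages ---
      std::fill(kj.begin(), kj.end(), 0);
      int idx = 0;
      for (int dm = 0; dm < r; ++dm)
        for (int c = 0; c < n_by_deme[dm]; ++c) {
          lin[idx] = idx; linDeme[idx] = dm; leafDeme[idx] = dm; ++idx;
        }
      for (int dm = 0; dm < r; ++dm) kj[dm] = n_by_deme[dm];
      double sumpairs = 0.0;
      for (int dm = 0; dm < r; ++dm)
        sumpairs += 0.5 * kj[dm] * (kj[dm] - 1.0);
      int active = k0, nextNode = k0;
      double t = 0.0;
      for (int i = 0; i < k0; ++i) ntime[i] = 0.0;

      // --- genealogy ---
      while (active > 1) {
        // Strong-migration regime: when the expected number of migration
        // events per coalescence, M*d/(k-1), is very large, the island model
        // is in its separation-of-timescales limit and lineages coalesce as
        // a panmictic population with pairwise rate 1/d. Drawing coalescences
        // directly there (error O(1/M)) avoids simulating millions of
        // individual migration events; once entered, the condition only
        // strengthens as k falls, so deme bookkeeping can stop.
        if (M * d_total > 1000.0 * (active - 1)) {
          double rate = 0.5 * active * (active - 1.0) / d_total;
          t += exp_rand() / rate;
          int a = (int) (unif_rand() * active); if (a >= active) a = active - 1;
          int b = (int) (unif_rand() * (active - 1)); if (b >= active - 1) b = active - 2;
          if (b >= a) ++b;
          int lo = std::min(a, b), hi = std::max(a, b);
          int node = nextNode++;
          ntime[node] = t;
          parent[lin[lo]] = node;
          parent[lin[hi]] = node;
          lin[lo] = node;
          lin[hi] = lin[active - 1];
          --active;
          continue;
        }
        double coalRate = sumpairs;
        double migRate = active * M * 0.5;
        double R = coalRate + migRate;
        t += exp_rand() / R;
        if (unif_rand() * R < coalRate) {
          // coalescence: deme weighted by choose(k_j, 2)
          double u = unif_rand() * sumpairs, acc = 0.0;
          int deme = -1;
          for (int dm = 0; dm < d_total; ++dm) {
            acc += 0.5 * kj[dm] * (kj[dm] - 1.0);
            if (u < acc) { deme = dm; break; }
          }
          if (deme < 0) deme = d_total - 1;  // numeric edge
          inDeme.clear();
          for (int i = 0; i < active; ++i)
            if (linDeme[i] == deme) inDeme.push_back(i);
          int sz = (int) inDeme.size();
          int a = (int) (unif_rand() * sz); if (a >= sz) a = sz - 1;
          int b = (int) (unif_rand() * (sz - 1)); if (b >= sz - 1) b = sz - 2;
          if (b >= a) ++b;
          int lo = std::min(inDeme[a], inDeme[b]);
          int hi = std::max(inDeme[a], inDeme[b]);
          int node = nextNode++;
          ntime[node] = t;
          parent[lin[lo]] = node;
          parent[lin[hi]] = node;
          lin[lo] = node;  // replaces one child; deme unchanged
          lin[hi] = lin[active - 1];  // remove the other (swap-pop)
          linDeme[hi] = linDeme[active - 1];
          --active;
          sumpairs -= (kj[deme] - 1.0);
          kj[deme] -= 1;
        } else {
          // migration: uniform lineage, uniform other deme
          int i = (int) (unif_rand() * active); if (i >= active) i = active - 1;
          int od = linDeme[i];
          int nd = (int) (unif_rand() * (d_total - 1));
          if (nd >= d_total - 1) nd = d_total - 2;
          if (nd >= od) ++nd;
          sumpairs += -(kj[od] - 1.0) + kj[nd];
          kj[od] -= 1; kj[nd] += 1;
          linDeme[i] = nd;
        }
      }
      int root = nextNode - 1;
      parent[root] = -1;

      // --- infinite-alleles mutations ---
      for (int v = 0; v < nnodes; ++v) {
        if (v == root) { mutc[v] = 0; continue; }
        double len = ntime[parent[v]] - ntime[v];
        mutc[v] = (int) R::rpois(0.5 * theta * len);
      }
      // assign alleles root-down; internal nodes were created in increasing
      // time order, so reverse creation order visits parents first
      int ac = 0;
      allele[root] = 0;
      for (int v = nnodes - 2; v >= k0; --v)
        allele[v] = mutc[v] > 0 ? ++ac : allele[parent[v]];
      for (int v = 0; v < k0; ++v)
        allele[v] = mutc[v] > 0 ? ++ac : allele[parent[v]];

      // --- biallelic collapse: major allele vs rest ---
      std::vector<int> tot(ac + 1, 0);
      for (int v = 0; v < k0; ++v) tot[allele[v]] += 1;
      int major = 0;
      for (int al = 1; al <= ac; ++al) if (tot[al] > tot[major]) major = al;
      if (tot[major] < k0) {
        poly = true;
        for (int dm = 0; dm < r; ++dm) counts(locus, dm) = 0;
        for (int v = 0; v < k0; ++v)
          if (allele[v] == major) counts(locus, leafDeme[v]) += 1;
      } else {
        redraws += 1.0;
        if (redraws > max_redraws)
          stop("island-model simulation rejected > %0.f monomorphic draws; "
               "increase theta_mut", max_redraws);
      }
    }
  }
  return List::create(_["counts"] = counts, _["n_redraws"] = redraws);
}
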