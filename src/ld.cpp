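#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Two-locus LD statistics on phased chromosomes, with the likelihood-grid
// confidence interval on |D'| used by the Gabriel block rule.
//
// For a pair with allele-1 frequencies (p, q) and haplotype frequency f11,
// D = f11 - p*q, D' = |D| / Dmax, r2 = D^2 / (p(1-p)q(1-q)), and LOD is the
// log10 likelihood ratio of the observed haplotype counts against linkage
// equilibrium. The CI evaluates the multinomial likelihood of the observed
// 2x2 haplotype counts on a |D'| grid (step `grid_step`) with the allele
// frequencies fixed at their observed values and the sign of D fixed at its
// observed sign, normalises it to unit mass, and reports the smallest grid
// values with cumulative mass >= 0.05 and >= 0.95.
//
// Pair classes: 1 = strong LD (ci_low >= 0.70 and ci_high >= 0.98),
// 2 = strong recombination (ci_high < 0.90), 0 = inconclusive.

static void pair_from_counts(double n00, double n01, double n10, double n11,
                             double grid_step, double* out) {
  double n = n00 + n01 + n10 + n11;
  double p = (n10 + n11) / n;   // allele 1 at first site
  double q = (n01 + n11) / n;   // allele 1 at second site
  double f11 = n11 / n;
  double D = f11 - p * q;
  double dmax_pos = std::min(p * (1 - q), (1 - p) * q);
  double dmax_neg = std::min(p * q, (1 - p) * (1 - q));
  double dmax = (D >= 0) ? dmax_pos : dmax_neg;
  double dprime = (dmax > 0) ? std::fabs(D) / dmax : 0.0;
  double denom = p * (1 - p) * q * (1 - q);
  double r2 = (denom > 0) ? D * D / denom : 0.0;
  // LOD: sum n_h log10(fhat_h) - sum n_h log10(marginal product)
  double lod = 0.0;
  const double nh[4] = { n00, n01, n10, n11 };
  const double fh[4] = { n00 / n, n01 / n, n10 / n, n11 / n };
  const double eh[4] = { (1 - p) * (1 - q), (1 - p) * q, p * (1 - q), p * q };
  for (int h = 0; h < 4; ++h)
    if (nh[h] > 0) lod += nh[h] * (std::log10(fh[h]) - std::log10(eh[h]));
  if (lod < 0) lod = 0.0;  // numeric guard; the MLE ratio is >= 1

  // likelihood grid on |D'|
  double ci_low = NA_REAL, ci_high = NA_REAL;
  if (p > 0 && p < 1 && q > 0 && q < 1) {
    int ng = (int) std::floor(1.0 / grid_step + 0.5) + 1;
    std::vector<double> ll(ng);
    double sgn = (D >= 0) ? 1.0 : -1.0;
    double llmax = R_NegInf;
    for (int gidx = 0; gidx < ng; ++gidx) {
      double dp = gidx * grid_step;
      double Dg = sgn * dp * dmax;
      double g[4] = { (1 - p) * (1 - q) + Dg, (1 - p) * q - Dg,
                      p * (1 - q) - Dg, p * q + Dg };
      double v = 0.0;
      bool ok = true;
      for (int h = 0; h < 4; ++h) {
        if (g[h] < 1e-12) {
          if (nh[h] > 0) { ok = false; break; }
        } else if (nh[h] > 0) v += nh[h] * std::log(g[h]);
      }
      ll[gidx] = ok ? v : R_NegInf;
      if (ll[gidx] > llmax) llmax = ll[gidx];
    }
    double tot = 0.0;
    for (int gidx = 0; gidx < ng; ++gidx) {
      ll[gidx] = (ll[gidx] == R_NegInf) ? 0.0 : std::exp(ll[gidx] - llmax);
      tot += ll[gidx];
    }
    double cum = 0.0;
    for (int gidx = 0; gidx < ng; ++gidx) {
      cum += ll[gidx];
      if (ISNA(ci_low) && cum >= 0.05 * tot) ci_low = gidx * grid_step;
      if (cum >= 0.95 * tot) { ci_high = gidx * grid_step; break; }
    }
    if (ISNA(ci_high)) ci_high = 1.0;
  }

  out[0] = D; out[1] = dprime; out[2] = r2; out[3] = lod;
  out[4] = ci_low; out[5] = ci_high;
}

// [[Rcpp::export]]
NumericVector ld_pair_cpp(double n00, double n01, double n10, double n11,
                          double grid_step) {
  NumericVector out(6);
  pair_from_counts(n00, n01, n10, n11, grid_step, REAL(out));
  return out;
}

// All pairwise LD statistics within a site window.
// H: chromosomes x sites matrix of 0/1 for one population.
// Pairs (i, j) with j - i <= max_span; monomorphic members yield class -1.
// [[Rcpp::export]]
DataFrame ld_pair_table_cpp(IntegerMatrix H, int max_span, double grid_step) {
  const int nc = H.nrow(), L = H.ncol();
  std::vector<int> vi, vj, cls;
  std::vector<double> vD, vdp, vr2, vlod, vcl, vch;
  double st[6];
  std::vector<int> colsum(L, 0);
  for (int j = 0; j < L; ++j) {
    int s = 0;
    for (int c = 0; c < nc; ++c) s += H(c, j);
    colsum[j] = s;
  }
  for (int i = 0; i < L - 1; ++i) {
    int jmax = std::min(L - 1, i + max_span);
    for (int j = i + 1; j <= jmax; ++j) {
      vi.push_back(i + 1); vj.push_back(j + 1);
      bool mono = (colsum[i] == 0 || colsum[i] == nc ||
                   colsum[j] == 0 || colsum[j] == nc);
      if (mono) {
        vD.push_back(NA_REAL); vdp.push_back(NA_REAL); vr2.push_back(NA_REAL);
        vlod.push_back(NA_REAL); vcl.push_back(NA_REAL); vch.push_back(NA_REAL);
        cls.push_back(-1);
        continue;
      }
      int n11 = 0;
      for (int c = 0; c < nc; ++c) n11 += H(c, i) & H(c, j);
      double d11 = n11;
      double d10 = colsum[i] - n11;
      double d01 = colsum[j] - n11;
      double d00 = nc - colsum[i] - colsum[j] + n11;
      pair_from_counts(d00, d01, d10, d11, grid_step, st);
      vD.push_back(st[0]); vdp.push_back(st[1]); vr2.push_back(st[2]);
      vlod.push_back(st[3]); vcl.push_back(st[4]); vch.push_back(st[5]);
      int cl = 0;
      if (st[4] >= 0.70 && st[5] >= 0.98) cl = 1;
      else if (st[5] < 0.90) cl = 2;
      cls.push_back(cl);
    }
  }
  return DataFrame::create(_["i"] = vi, _["j"] = vj, _["D"] = vD,
                           _["Dprime"] = vdp, _["r2"] = vr2, _["LOD"] = vlod,
                           _["ci_low"] = vcl, _["ci_high"] = vch,
                           _["class"] = cls);
}

// Gabriel candidate spans from a pair-class table.
// cls is indexed flat: pair (i, j), 0-based, j - i <= max_span, at
// i * max_span + (j - i - 1); value 1 strong LD, 2 strong recombination,
// 0 inconclusive, -1 undefined. A candidate span [i, j] needs a strong-LD
// outermost pair and >= min_frac of its informative pairs strong.
// [[Rcpp::export]]
DataFrame gabriel_candidates_cpp(IntegerVector cls, int L, int max_span,
                                 double min_frac) {
  std::vector<int> ci, cj, cninf;
  std::vector<double> cfrac;
  for (int i = 0; i < L - 1; ++i) {
    int jmax = std::min(L - 1, i + max_span);
    long strong = 0, inf = 0;
    for (int j = i + 1; j <= jmax; ++j) {
      for (int a = i; a < j; ++a) {
        if (j - a > max_span) continue;
        int c = cls[(size_t) a * max_span + (j - a - 1)];
        if (c == 1) { ++strong; ++inf; }
        else if (c == 2) ++inf;
      }
      int outer = cls[(size_t) i * max_span + (j - i - 1)];
      if (outer == 1 && inf > 0) {
        double fr = (double) strong / inf;
        if (fr >= min_frac) {
          ci.push_back(i + 1); cj.push_back(j + 1);
          cninf.push_back((int) inf); cfrac.push_back(fr);
        }
      }
    }
  }
  return DataFrame::create(_["i"] = ci, _["j"] = cj,
                           _["n_informative"] = cninf, _["frac_strong"] = cfrac);
}
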