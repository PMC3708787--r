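---
title: "Methods: a four-stage selection scan on phased haplotype panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a four-stage selection scan on phased haplotype panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

sweepscan looks for natural selection in multi-population phased haplotype
panels with two complementary signals: allele-frequency differentiation
between populations (F_ST and its neutral envelope) and unusually long,
unusually frequent haplotypes (EHH/REHH). This vignette explains the models
behind each stage, the parameters that matter, what the synthetic generators
do and do not emulate, and the numerical choices made where the design was
genuinely open.

## 1. Weir–Cockerham F_ST on chromosome counts

All data enter as phased chromosomes (two rows per individual), so allele
frequencies are chromosome counts and the fixation index is estimated with
the haploid (chromosome-level) Weir–Cockerham variance components. For `r`
populations with allele frequencies `p_i` on `n_i` chromosomes:

- n̄ = Σn_i / r, n_c = (Σn_i − Σn_i²/Σn_i)/(r−1), p̄ = Σn_i p_i / Σn_i
- s² = Σn_i (p_i − p̄)² / ((r−1) n̄)
- a = (n̄/n_c)[s² − (p̄(1−p̄) − s²(r−1)/r)/(n̄−1)] (among-population)
- b = (n̄/(n̄−1))[p̄(1−p̄) − s²(r−1)/r] (residual)
- θ = a/(a+b)

The sample-size correction lives in the weighted p̄ and the (n̄−1)
unbiasedness terms. θ is reported as computed — slightly negative values
are legitimate for undifferentiated loci and preserve the estimator's
ranking properties (`clamp_negative` exists but defaults to off). A site
monomorphic and identical in every population has a+b = 0 and is flagged
undefined; such sites are excluded from empirical reference distributions.
Multi-site estimates combine per-site components as a ratio of sums
(Σa / Σ(a+b)), the standard multi-locus form.

A diploid variant using observed heterozygosity is deliberately out of
scope: on phased data the chromosome-level estimator is the natural one,
and published genotype-level values can differ from it by roughly ±0.02 at
these sample sizes.

Empirical significance is a midrank percentile: a candidate's θ is ranked
against the same statistic computed at every (defined) site of the
chromosome, ties counting half. Values at or above the 95th percentile are
flagged.

## 2. FDIST-style neutrality test

The outlier test asks whether a site's F_ST is extreme *given its
heterozygosity* under a neutral island model. The null is simulated with a
structured coalescent: `d` demes (default 100, the classic FDIST setting),
lineages coalescing within a deme at rate C(k,2) with time in units of 2N
per deme, and migration at rate M/2 per lineage toward a uniform other
deme. Infinite-alleles mutations are dropped on the genealogy at rate θ/2
per unit branch length, and allelic classes are collapsed to biallelic
(most frequent allele versus the rest pooled) so simulated loci are
comparable to SNPs; loci monomorphic after collapse are rejected and
redrawn. In the strong-migration regime (expected migrations per
coalescence above ~10³) the simulator switches to the exact
separation-of-timescales limit — panmictic coalescence at pairwise rate
1/d — which keeps the panmixia end of the calibration bracket affordable;
the approximation error there is O(1/M).

Two numerical choices deserve note:

- **Mutation rate spread.** A single θ concentrates simulated
  heterozygosity in a narrow band, starving the conditional test at other
  He values. Per-locus rates are therefore drawn log-uniformly over
  [θ/10, 10θ] around the configured θ (default 0.05), which fills the He
  axis; `theta_spread = 1` restores a fixed rate.
- **Calibration.** The envelope must be centred on the data. `M` is found
  by bisection on log M over [10⁻³, 10⁴] so that the median simulated F_ST
  matches the trimmed mean (central 90%) of the observed per-locus values
  to within ±0.005, with one fixed evaluation seed (common random numbers)
  so the objective is monotone and the bisection stable. A target outside
  the bracket's achievable range is an error, never an extrapolation.

The outlier probability of an observed (He, F_ST) pair is the midrank
fraction of simulated F_ST below the observed value among simulated loci
with |He_sim − He_obs| ≤ 0.025 (the bandwidth doubles until at least 200
matches; if the whole envelope cannot supply them, the nearest 200 loci
are used with a warning). Classification: `positive-candidate` at
p ≥ 0.975, `balancing-candidate` at p ≤ 0.025, else `neutral`. These
thresholds give a nominal 5% two-sided error rate, which the acceptance
suite verifies on a neutral Balding–Nichols panel. Because the exact
internals of the original FDIST software are not published to
reimplementation precision, printed P values from that lineage of tools
reproduce here qualitatively (same classifications), not bit-for-bit.

## 3. Gabriel haplotype blocks

Two-locus statistics are tabulated directly from phased haplotype counts
(no EM step). For each pair: D = f11 − p q, D′ = |D|/Dmax with the usual
sign-dependent Dmax, r², and a LOD score of observed haplotype frequencies
against independence (0·log 0 := 0). The confidence interval on |D′|
follows the likelihood-grid construction: the multinomial likelihood of
the observed 2×2 counts is evaluated on a |D′| grid of step 0.001 with
allele frequencies fixed at their observed values and the sign of D fixed;
after normalising to unit mass, the 5th and 95th cumulative points give
(ci_low, ci_high). Pairs are `strong-LD` when ci_low ≥ 0.70 and
ci_high ≥ 0.98, `strong-recombination` when ci_high < 0.90, else
`inconclusive`.

Blocks are contiguous spans whose outermost pair is strong-LD and in which
at least 95% of informative pairs (strong-LD or strong-recombination) are
strong-LD; candidates are sorted by bp length, longest first, and accepted
greedily without overlap. Sites below the MAF filter (default 0.05) do not
participate; a block's core is therefore contiguous over the filtered
marker set. The marker-count-dependent fraction adjustments and distance
caps of the Haploview implementation are not reproduced; instead a plain
`max_span_sites` cap (default 250 markers) bounds the quadratic pair
computation. On empirical human data blocks rarely exceed a few tens of
markers, so the cap is not binding there; on smooth synthetic LD
landscapes it acts as the block-length prior that recombination-rate
variation provides in real genomes.

## 4. EHH and REHH

A core region's distinct allele strings are its core haplotypes. The EHH
of a core haplotype at boundary x is the probability that two random
carrier chromosomes are identical at every marker from the core edge out
to x; it is computed by partitioning carriers by their allele vector over
the intervening markers: EHH = Σ C(e_g, 2)/C(c, 2). Evaluation happens at
marker boundaries only — the first marker at or beyond the target genetic
distance (default 0.25 cM) from the core edge, via linear interpolation of
the genetic map; when no marker reaches the distance the outermost marker
is used and the record flagged truncated.

REHH divides the target's EHH by the EHH of **all other core haplotypes
combined**, the grouped comparison set: the numerator counts identical
pairs within each non-target core (two chromosomes with different cores
are never identical once the core is included in the extended haplotype)
and the denominator counts *all* pairs of non-target chromosomes,
including carriers of rare cores below the enumeration threshold. This is
the long-range-haplotype test's definition and is the package default
(`others = "combined"`). A conditional variant that averages only within
the enumerated cores (Σ_j Σ_g C(e_gj,2) / Σ_j C(c_j,2)) is available as
`others = "within-core"`; it ignores between-core heterogeneity and
yields systematically smaller REHH at loci whose comparison set is
fragmented — exactly the situation at a swept locus — so it is not used
for scanning.

The chromosome-wide scan computes REHH in both directions for every core
haplotype (frequency ≥ 0.05) of every block, pools directions, assigns
each record to a frequency bin of width 0.05 (top bin closed), and ranks
log REHH within its bin by midrank percentile; records at or above the
95th percentile are flagged and at or above the 99th highlighted.
Percentiles are ranked on the log scale because REHH is a ratio; raw-value
ranking gives the same order but the log is kept for symmetry of the
stored statistic.

## 5. Synthetic data: what it emulates, what it does not

Two generators provide the test bed.

**Balding–Nichols island panels** (`gen_island_snp_panel`) draw, per site,
an ancestral frequency p₀ ~ U(0.05, 0.95) and deme frequencies from
Beta(p₀(1−F)/F, (1−p₀)(1−F)/F) with F the target F_ST; chromosomes are
independent Bernoulli draws. Sites are unlinked, so these panels exercise
the F_ST and FDIST stages (the multi-population ratio-of-sums θ recovers F
to within Monte-Carlo error) but carry no LD and say nothing about the
haplotype stages.

**Forward Wright–Fisher sweep panels** (`gen_sweep_panel`) build a founding
generation by mosaic-copying over 20 founder haplotypes with
exponentially distributed segment lengths (mean 0.5 cM), which creates
block-like background LD; then evolve `n_generations` of fitness-weighted
parent sampling (fitness 1 + s for sweep-allele carriers in deme 1),
recombination as a Poisson process at the genetic-map rate, and
conservative pairwise-exchange migration at per-chromosome rate m. The
sweep allele starts as round(f₀N) identical copies of a single carrier
haplotype — a hard sweep from one mutational origin that has drifted to
f₀. Defaults are desk-scale (N = 1,000 chromosomes per deme, 2,000 sites
over 5 Mb at 1 cM/Mb, 200 generations, 200 chromosomes sampled per deme —
the last matching the ~100 individuals of a typical phased reference
panel) and run in a few seconds.

Two limitations matter for interpreting green tests. First, background
diversity is only as old as the founding mosaic plus the simulated
generations, whereas real neutral haplotype diversity is orders of
magnitude older; neutral EHH is therefore higher here than in real data,
and the sweep/background contrast correspondingly smaller — passing the
recovery test at this adverse contrast is encouraging but not a power
estimate for real panels. Second, with s = 0.1 over 200 generations the
sweep is complete in the selected deme long before sampling, and its
hitchhiking shoulder spans most of a 5 Mb region. The recovery analysis
therefore scans the *unselected* deme, where the sweep arrives by
migration and is still segregating at sampling, and ranks the planted
core's REHH against the frequency-matched background pooled from matched
neutral panels (frequency window ±0.05, the scan's bin width): a
desk-scale stand-in for the field's usual ranking against an entire
chromosome that is overwhelmingly neutral. Ranking within the sweep
panel's own 5 Mb would compare the sweep against its own shoulder.

No mutation occurs during the forward phase, demography is constant, and
selection is genic and haploid; bottlenecks, growth, dominance and soft
sweeps are out of scope.

## 6. Degenerate inputs and tie-breaking

- Sites with missing genotypes are dropped at load (the site, not the
  chromosome); unphased genotypes are a format error because haplotype
  identity is undefined on them; multiallelic sites are excluded with a
  warning.
- Monomorphic-in-all-populations sites: θ undefined, excluded from
  reference distributions. Monomorphic in one population only: kept.
- Percentiles use midrank ties everywhere (half weight), making a value
  equal to its whole reference land at 50.
- Genetic maps collapse duplicate positions to the last entry, must be
  non-decreasing in cM, and extrapolate beyond their ends at the terminal
  interval's rate.
- Block candidates tie-break on bp length, then leftmost start — the
  partition is deterministic.
- REHH with a zero denominator (others fully homozygous and the numerator
  positive) is reported as infinite and excluded from percentile ranking.

## 7. Problem sizes used by the validation suite

The acceptance checks run at sizes a laptop handles comfortably: 1,000
random EHH cases against brute-force pair enumeration; 1,000 random
frequency configurations against an independent ANOVA derivation of the
Weir–Cockerham estimator; a 2,000-locus Balding–Nichols panel at
F_ST = 0.10 with a 10,000-replicate calibrated envelope for the 5%
type-I check; constructed perfect-LD and free-recombination fixtures for
the block rule; and 20 sweep panels against 20 matched neutral panels
(the simulator's defaults above) for sweep recovery. Recovered sweep REHH
values typically land around 3–12, the magnitude the long-range-haplotype
literature reports for genuine recent sweeps at comparable frequencies.
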