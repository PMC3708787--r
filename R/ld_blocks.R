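#' Two-locus LD statistics for one pair of sites
#'
#' Tabulates the 2x2 phased haplotype counts for sites `i` and `j` in one
#' population (no EM is needed on phased data) and computes D, D' (Lewontin),
#' r^2, the LOD score against linkage equilibrium, and the 90% likelihood
#' interval on |D'| used by the Gabriel rule (multinomial likelihood on a
#' |D'| grid with allele frequencies fixed at observed values and the sign of
#' D fixed; the 5th and 95th points of the normalised cumulative mass).
#'
#' @param panel a [haplotype_panel()]
#' @param i,j site indices or ids
#' @param pop population code (NULL = all chromosomes)
#' @param grid_step |D'| grid resolution for the confidence interval
#' @return list with `site_i`, `site_j`, `hap_counts` (n00, n01, n10, n11),
#'   `D`, `Dprime`, `r2`, `LOD`, `ci_low`, `ci_high`, `class`, `defined`
#' @export
ld_pair <- function(panel, i, j, pop = NULL, grid_step = 0.001) {
  i <- resolve_sites(panel, i); j <- resolve_sites(panel, j)
  rows <- pop_rows(panel, pop)
  hi <- panel$haplotypes[rows, i]; hj <- panel$haplotypes[rows, j]
  n11 <- sum(hi & hj); n10 <- sum(hi) - n11; n01 <- sum(hj) - n11
  n00 <- length(rows) - n11 - n10 - n01
  res <- ld_pair_from_counts(n00, n01, n10, n11, grid_step)
  res$site_i <- panel$sites$site_id[i]
  res$site_j <- panel$sites$site_id[j]
  res
}

#' LD statistics from 2x2 haplotype counts
#'
#' @param n00,n01,n10,n11 phased two-locus haplotype counts; the first index
#'   is the allele at the first site
#' @param grid_step |D'| grid resolution
#' @return as [ld_pair()] (without site ids)
#' @export
ld_pair_from_counts <- function(n00, n01, n10, n11, grid_step = 0.001) {
  n <- n00 + n01 + n10 + n11
  p <- (n10 + n11) / n; q <- (n01 + n11) / n
  if (p %in% c(0, 1) || q %in% c(0, 1))
    return(list(hap_counts = c(n00 = n00, n01 = n01, n10 = n10, n11 = n11),
                D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                LOD = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                class = "undefined", defined = FALSE))
  st <- ld_pair_cpp(n00, n01, n10, n11, grid_step)
  list(hap_counts = c(n00 = n00, n01 = n01, n10 = n10, n11 = n11),
       D = st[1], Dprime = st[2], r2 = st[3], LOD = st[4],
       ci_low = st[5], ci_high = st[6],
       class = classify_pair(st[5], st[6]), defined = TRUE)
}

#' 90% likelihood interval on |D'|
#'
#' @param n00,n01,n10,n11 haplotype counts
#' @param grid_step grid resolution
#' @return numeric `c(ci_low, ci_high)`
#' @export
dprime_ci <- function(n00, n01, n10, n11, grid_step = 0.001) {
  res <- ld_pair_from_counts(n00, n01, n10, n11, grid_step)
  if (!res$defined) stop("degenerate allele frequencies: CI undefined")
  c(ci_low = res$ci_low, ci_high = res$ci_high)
}

#' Gabriel pair classification from the |D'| confidence interval
#'
#' `strong-LD` iff `ci_low >= 0.70` and `ci_high >= 0.98`;
#' `strong-recombination` iff `ci_high < 0.90`; otherwise `inconclusive`.
#'
#' @param ci_low,ci_high interval bounds (vectors)
#' @return character vector
#' @export
classify_pair <- function(ci_low, ci_high) {
  ifelse(is.na(ci_low) | is.na(ci_high), "undefined",
         ifelse(ci_low >= 0.70 & ci_high >= 0.98, "strong-LD",
                ifelse(ci_high < 0.90, "strong-recombination",
                       "inconclusive")))
}

#' LD colour class of a pair (triangle-plot convention)
#'
#' white: D' < 1, LOD < 2; blue: D' = 1, LOD < 2; pink: D' < 1, LOD >= 2;
#' bright-red: D' = 1, LOD >= 2. Equality to 1 is tested with tolerance 1e-9.
#'
#' @param Dprime,LOD numeric vectors
#' @return character vector
#' @export
ld_colour_class <- function(Dprime, LOD) {
  is1 <- abs(Dprime - 1) <= 1e-9
  ifelse(is1 & LOD >= 2, "bright-red",
         ifelse(is1, "blue", ifelse(LOD >= 2, "pink", "white")))
}

#' Pairwise LD table for one population
#'
#' All pairs within `max_span_sites` of each other among sites passing the
#' MAF filter, with Gabriel pair classes.
#'
#' @param panel a [haplotype_panel()]
#' @param pop population code (NULL = all chromosomes)
#' @param maf_min minor-allele-frequency filter applied before pairing
#' @param max_span_sites maximum pair distance in (filtered) site index space
#' @param grid_step |D'| grid resolution
#' @return data.frame with columns `i`, `j` (indices into the original
#'   panel), `site_i`, `site_j`, `D`, `Dprime`, `r2`, `LOD`, `ci_low`,
#'   `ci_high`, `class`; attribute `"kept_sites"` maps filtered to panel
#'   indices
#' @export
ld_pair_table <- function(panel, pop = NULL, maf_min = 0.05,
                          max_span_sites = 250, grid_step = 0.001) {
  rows <- pop_rows(panel, pop)
  H <- panel$haplotypes[rows, , drop = FALSE]
  p <- colMeans(H)
  keep <- which(pmin(p, 1 - p) >= maf_min)
  tab <- ld_pair_table_cpp(H[, keep, drop = FALSE], as.integer(max_span_sites),
                           grid_step)
  tab$i <- keep[tab$i]; tab$j <- keep[tab$j]
  tab$site_i <- panel$sites$site_id[tab$i]
  tab$site_j <- panel$sites$site_id[tab$j]
  cls_chr <- rep("undefined", nrow(tab))
  cls_chr[tab$class == 0L] <- "inconclusive"
  cls_chr[tab$class == 1L] <- "strong-LD"
  cls_chr[tab$class == 2L] <- "strong-recombination"
  tab$class <- cls_chr
  attr(tab, "kept_sites") <- keep
  tab
}

#' Gabriel-rule haplotype blocks
#'
#' Candidate blocks are contiguous spans of MAF-filtered sites whose
#' outermost pair is strong-LD and in which at least `min_frac` of the
#' informative pairs (strong-LD or strong-recombination; inconclusive and
#' undefined pairs are excluded) are strong-LD. Candidates are sorted by bp
#' length (descending, ties broken by leftmost start) and accepted greedily
#' without overlap.
#'
#' @param panel a [haplotype_panel()]
#' @param pop population code
#' @param maf_min MAF filter (default 0.05)
#' @param max_span_sites maximum block span in filtered-site index distance
#' @param min_frac required fraction of informative pairs that are strong-LD
#' @param grid_step |D'| grid resolution
#' @return data.frame of blocks: `start_site`, `end_site` (panel indices of
#'   the outermost block members), `start_bp`, `end_bp`, `n_sites`,
#'   `n_informative_pairs`, `frac_strong_ld`; attribute `"site_indices"` is a
#'   list of the panel site indices inside each block
#' @export
gabriel_blocks <- function(panel, pop = NULL, maf_min = 0.05,
                           max_span_sites = 250, min_frac = 0.95,
                           grid_step = 0.001) {
  rows <- pop_rows(panel, pop)
  H <- panel$haplotypes[rows, , drop = FALSE]
  p <- colMeans(H)
  keep <- which(pmin(p, 1 - p) >= maf_min)
  empty <- data.frame(start_site = integer(), end_site = integer(),
                      start_bp = integer(), end_bp = integer(),
                      n_sites = integer(), n_informative_pairs = integer(),
                      frac_strong_ld = numeric())
  if (length(keep) < 2) {
    attr(empty, "site_indices") <- list()
    return(empty)
  }
  Hk <- H[, keep, drop = FALSE]
  L <- ncol(Hk)
  max_span_sites <- as.integer(min(max_span_sites, L - 1L))
  tab <- ld_pair_table_cpp(Hk, max_span_sites, grid_step)
  cls <- integer(L * max_span_sites)
  cls[(tab$i - 1L) * max_span_sites + (tab$j - tab$i)] <- tab$class
  cand <- gabriel_candidates_cpp(cls, L, max_span_sites, min_frac)
  if (!nrow(cand)) {
    attr(empty, "site_indices") <- list()
    return(empty)
  }
  pos <- panel$sites$pos_bp
  start_bp <- pos[keep[cand$i]]; end_bp <- pos[keep[cand$j]]
  ord <- order(-(end_bp - start_bp), start_bp, cand$i)
  taken <- rep(FALSE, L)
  acc <- integer(0)
  for (k in ord) {
    span <- cand$i[k]:cand$j[k]
    if (!any(taken[span])) {
      taken[span] <- TRUE
      acc <- c(acc, k)
    }
  }
  acc <- acc[order(cand$i[acc])]
  blocks <- data.frame(start_site = keep[cand$i[acc]],
                       end_site = keep[cand$j[acc]],
                       start_bp = pos[keep[cand$i[acc]]],
                       end_bp = pos[keep[cand$j[acc]]],
                       n_sites = cand$j[acc] - cand$i[acc] + 1L,
                       n_informative_pairs = cand$n_informative[acc],
                       frac_strong_ld = cand$frac_strong[acc])
  attr(blocks, "site_indices") <- lapply(acc, function(k)
    keep[cand$i[k]:cand$j[k]])
  blocks
}
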