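#' Per-population allele frequencies and expected heterozygosity
#'
#' Counts allele 1 on chromosomes (not genotypes): `p = count / n_chrom`,
#' `He = 2 p (1 - p)`.
#'
#' @param panel a [haplotype_panel()]
#' @param sites integer site indices or character site ids; NULL = all sites
#' @param pops population codes; NULL = all populations in the panel
#' @return data.frame with columns `site_id`, `pop`, `n_chrom`, `p`, `He`
#' @export
allele_freqs <- function(panel, sites = NULL, pops = NULL) {
  idx <- resolve_sites(panel, sites)
  if (is.null(pops)) pops <- panel_pops(panel)
  out <- lapply(pops, function(pp) {
    rows <- pop_rows(panel, pp)
    if (!length(rows)) stop("empty population: ", pp)
    cnt <- colSums(panel$haplotypes[rows, idx, drop = FALSE])
    p <- cnt / length(rows)
    data.frame(site_id = panel$sites$site_id[idx], pop = pp,
               n_chrom = length(rows), p = p, He = 2 * p * (1 - p),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

resolve_sites <- function(panel, sites) {
  if (is.null(sites)) return(seq_len(nrow(panel$sites)))
  if (is.character(sites)) {
    idx <- match(sites, panel$sites$site_id)
    if (anyNA(idx)) stop("unknown site id(s): ",
                         paste(sites[is.na(idx)], collapse = ", "))
    return(idx)
  }
  if (any(sites < 1 | sites > nrow(panel$sites))) stop("site index out of range")
  as.integer(sites)
}

#' Weir-Cockerham variance components for one site
#'
#' Haploid (chromosome-level) Weir-Cockerham estimator of the fixation index:
#' given allele frequencies `p_i` on `n_i` sampled chromosomes in each of
#' `r >= 2` populations, computes the among-population component `a`, the
#' residual component `b`, and `theta = a / (a + b)`. `theta` may be negative
#' and is returned as computed (optionally clamped to zero); a site
#' monomorphic and identical in every population has `a + b = 0` and is
#' flagged undefined.
#'
#' @param p numeric vector of allele-1 frequencies, one per population
#' @param n integer vector of sampled chromosome counts (each >= 2)
#' @param clamp_negative if TRUE, negative theta is reported as 0
#' @return list with `a_comp`, `b_comp`, `theta`, `defined`
#' @export
wc_theta_site <- function(p, n, clamp_negative = FALSE) {
  if (length(p) < 2L || length(p) != length(n))
    stop("need frequencies and counts for r >= 2 populations")
  if (any(n < 2)) stop("each population needs >= 2 chromosomes")
  cmp <- wc_components_matrix(matrix(p, nrow = 1), matrix(n, nrow = 1))
  theta <- cmp$theta
  if (clamp_negative && cmp$defined && !is.na(theta) && theta < 0) theta <- 0
  list(a_comp = cmp$a, b_comp = cmp$b, theta = theta, defined = cmp$defined)
}

# vectorised haploid WC components: P, N are loci x r matrices
wc_components_matrix <- function(P, N) {
  r <- ncol(P)
  ntot <- rowSums(N)
  nbar <- ntot / r
  nc <- (ntot - rowSums(N^2) / ntot) / (r - 1)
  pbar <- rowSums(N * P) / ntot
  s2 <- rowSums(N * (P - pbar)^2) / ((r - 1) * nbar)
  inner <- pbar * (1 - pbar) - s2 * (r - 1) / r
  a <- (nbar / nc) * (s2 - inner / (nbar - 1))
  b <- (nbar / (nbar - 1)) * inner
  tot <- a + b
  defined <- tot != 0
  theta <- ifelse(defined, a / tot, NA_real_)
  list(a = a, b = b, theta = theta, defined = defined)
}

#' Multi-site Weir-Cockerham estimate (ratio of sums)
#'
#' Combines per-site variance components over a site set:
#' `theta = sum(a) / sum(a + b)`. With one site this reduces to the per-site
#' estimate.
#'
#' @param a_comp,b_comp numeric vectors of per-site components
#' @return list with `a_comp`, `b_comp` (sums), `theta`, `defined`
#' @export
wc_theta_multi <- function(a_comp, b_comp) {
  ok <- !is.na(a_comp) & !is.na(b_comp)
  if (!any(ok)) return(list(a_comp = NA_real_, b_comp = NA_real_,
                            theta = NA_real_, defined = FALSE))
  A <- sum(a_comp[ok]); TOT <- sum(a_comp[ok] + b_comp[ok])
  if (TOT == 0) return(list(a_comp = A, b_comp = TOT - A, theta = NA_real_,
                            defined = FALSE))
  list(a_comp = A, b_comp = TOT - A, theta = A / TOT, defined = TRUE)
}

#' Per-site Weir-Cockerham theta across panel populations
#'
#' @param panel a [haplotype_panel()]
#' @param pops populations to include (default: all, i.e. the r-population
#'   estimator); give two codes for a pairwise scan
#' @param sites site indices/ids, NULL = all
#' @return data.frame with `site_id`, `a_comp`, `b_comp`, `theta`, `defined`
#' @export
site_fst <- function(panel, pops = NULL, sites = NULL) {
  if (is.null(pops)) pops <- panel_pops(panel)
  if (length(pops) < 2L) stop("need >= 2 populations")
  idx <- resolve_sites(panel, sites)
  counts <- vapply(pops, function(pp) {
    rows <- pop_rows(panel, pp)
    colSums(panel$haplotypes[rows, idx, drop = FALSE])
  }, numeric(length(idx)))
  if (length(idx) == 1L) counts <- matrix(counts, nrow = 1)
  nvec <- vapply(pops, function(pp) length(pop_rows(panel, pp)), 1L)
  N <- matrix(nvec, nrow = length(idx), ncol = length(pops), byrow = TRUE)
  cmp <- wc_components_matrix(counts / N, N)
  data.frame(site_id = panel$sites$site_id[idx], a_comp = cmp$a,
             b_comp = cmp$b, theta = cmp$theta, defined = cmp$defined,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Midrank empirical percentile of a value in a reference distribution
#'
#' `100 * (#\{ref < value\} + 0.5 * #\{ref == value\}) / length(ref)`. Ties get
#' half weight; a value above every reference point scores 100, below every
#' point 0.
#'
#' @param value numeric vector of statistics to rank
#' @param reference non-empty numeric vector (NAs removed) of the same
#'   statistic computed genome- or chromosome-wide
#' @return numeric vector of percentiles in `[0, 100]`
#' @export
empirical_percentile <- function(value, reference) {
  reference <- reference[!is.na(reference)]
  if (!length(reference)) stop("empty reference distribution")
  sr <- sort(reference)
  below <- findInterval(value, sr)              # ref <= value
  beloweq <- below
  below <- findInterval(value, sr, left.open = TRUE)  # ref < value
  ties <- beloweq - below
  100 * (below + 0.5 * ties) / length(sr)
}

#' Pairwise F_ST between populations at candidate sites, with empirical ranks
#'
#' For every pair of the requested populations, computes the per-site
#' Weir-Cockerham theta at the candidate sites plus the combined ratio-of-sums
#' estimate, and ranks each against the chromosome-wide per-site theta
#' distribution of the same pair (sites monomorphic in both populations are
#' excluded from the reference). Percentiles at or above `sig_percentile` are
#' flagged significant.
#'
#' @param panel a [haplotype_panel()]
#' @param sites candidate site ids/indices
#' @param pops populations; NULL = all in panel
#' @param combine also report the multi-site ratio-of-sums theta per pair
#' @param sig_percentile significance threshold on the empirical percentile
#' @return data.frame with one row per (pair, site) and, when `combine`, one
#'   row per pair with `site_id = "combined"`
#' @export
pairwise_fst <- function(panel, sites, pops = NULL, combine = TRUE,
                         sig_percentile = 95) {
  if (is.null(pops)) pops <- panel_pops(panel)
  prs <- utils::combn(pops, 2L, simplify = FALSE)
  idx <- resolve_sites(panel, sites)
  out <- lapply(prs, function(pr) {
    all_fst <- site_fst(panel, pops = pr)
    ref <- all_fst$theta[all_fst$defined]
    cand <- all_fst[idx, , drop = FALSE]
    res <- data.frame(pop_a = pr[1], pop_b = pr[2], site_id = cand$site_id,
                      theta = cand$theta,
                      percentile = ifelse(cand$defined,
                                          empirical_percentile(cand$theta, ref),
                                          NA_real_),
                      stringsAsFactors = FALSE, row.names = NULL)
    if (combine) {
      cmb <- wc_theta_multi(cand$a_comp[cand$defined],
                            cand$b_comp[cand$defined])
      res <- rbind(res, data.frame(pop_a = pr[1], pop_b = pr[2],
                                   site_id = "combined", theta = cmb$theta,
                                   percentile = if (cmb$defined)
                                     empirical_percentile(cmb$theta, ref)
                                   else NA_real_,
                                   stringsAsFactors = FALSE))
    }
    res
  })
  out <- do.call(rbind, out)
  out$significant <- !is.na(out$percentile) & out$percentile >= sig_percentile
  out
}
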