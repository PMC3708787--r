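#' Enumerate core haplotypes over a core region
#'
#' A core haplotype is a distinct allele string over a contiguous set of core
#' SNPs among the chromosomes of one population. Haplotypes below `min_freq`
#' are reported separately (element `rare`), so the main frequencies may sum
#' to less than 1.
#'
#' @param panel a [haplotype_panel()]
#' @param core_sites contiguous site indices (or ids) defining the core
#' @param pop population code (NULL = all chromosomes)
#' @param min_freq minimum frequency for the main list
#' @return object of class `core_haplotypes`: list with `core_sites`, `pop`,
#'   `n_chrom`, `haps` (list of `allele_string`, `carrier_rows`,
#'   `frequency`, sorted by descending frequency), `rare` (same shape)
#' @export
enumerate_core_haplotypes <- function(panel, core_sites, pop = NULL,
                                      min_freq = 0.05) {
  # core sites must form a contiguous span over the marker set in use (the
  # panel, or the MAF-filtered markers a block was built on); positions in
  # between that are absent from `core_sites` are treated as non-core
  idx <- sort(unique(resolve_sites(panel, core_sites)))
  rows <- pop_rows(panel, pop)
  M <- panel$haplotypes[rows, idx, drop = FALSE]
  key <- apply(M, 1L, paste, collapse = "")
  a0 <- panel$sites$allele0[idx]; a1 <- panel$sites$allele1[idx]
  tab <- sort(table(key), decreasing = TRUE)
  haps <- lapply(names(tab), function(k) {
    bits <- as.integer(strsplit(k, "")[[1]])
    list(allele_string = paste(ifelse(bits == 1L, a1, a0), collapse = ""),
         carrier_rows = rows[key == k],
         frequency = unname(tab[k]) / length(rows))
  })
  freqs <- vapply(haps, `[[`, numeric(1), "frequency")
  structure(list(core_sites = idx, pop = pop, n_chrom = length(rows),
                 haps = haps[freqs >= min_freq],
                 rare = haps[freqs < min_freq]),
            class = "core_haplotypes")
}

#' @export
print.core_haplotypes <- function(x, ...) {
  cat("core_haplotypes:", length(x$core_sites), "core SNPs,",
      length(x$haps), "haplotype(s) (", length(x$rare), "rare ) on",
      x$n_chrom, "chromosomes\n")
  for (h in x$haps)
    cat(sprintf("  %s  %.4f (%d carriers)\n", h$allele_string, h$frequency,
                length(h$carrier_rows)))
  invisible(x)
}

# sites strictly between the core edge and x_bp (inclusive) in a direction
flank_sites <- function(panel, core_idx, direction, x_bp) {
  pos <- panel$sites$pos_bp
  if (direction == "downstream") {
    edge <- pos[max(core_idx)]
    which(pos > edge & pos <= x_bp)
  } else {
    edge <- pos[min(core_idx)]
    which(pos < edge & pos >= x_bp)
  }
}

#' Extended haplotype homozygosity of a core haplotype at a boundary
#'
#' The probability that two randomly chosen carrier chromosomes of the core
#' haplotype are identical at every site from the core edge out to `x_bp`
#' (inclusive): carriers are partitioned by their allele vector over the
#' intervening sites and `EHH = sum(choose(e_g, 2)) / choose(c, 2)` over the
#' group sizes `e_g` of the `c` carriers. An empty interval gives 1.
#'
#' @param panel a [haplotype_panel()]
#' @param carrier_rows chromosome row indices carrying the core haplotype
#'   (>= 2)
#' @param core_sites the core site indices
#' @param direction `"downstream"` (increasing bp) or `"upstream"`
#' @param x_bp outer boundary position
#' @return EHH value in `[0, 1]`
#' @export
ehh <- function(panel, carrier_rows, core_sites,
                direction = c("downstream", "upstream"), x_bp) {
  direction <- match.arg(direction)
  if (length(carrier_rows) < 2) return(NA_real_)
  fl <- flank_sites(panel, resolve_sites(panel, core_sites), direction, x_bp)
  group_homozygosity(panel$haplotypes, carrier_rows, fl) /
    choose(length(carrier_rows), 2)
}

# number of identical pairs among rows over the given site columns
group_homozygosity <- function(H, rows, site_cols) {
  if (!length(site_cols)) return(choose(length(rows), 2))
  key <- apply(H[rows, site_cols, drop = FALSE], 1L, paste, collapse = "")
  sum(choose(table(key), 2))
}

#' EHH decay curve of a core haplotype
#'
#' Evaluates EHH at every marker boundary moving outward from the core in one
#' direction, with the genetic distance of each boundary from the core edge.
#'
#' @inheritParams ehh
#' @param map a [genetic_map()]
#' @param max_distance_cM stop once this genetic distance is reached (NULL =
#'   chromosome end)
#' @return data.frame `pos_bp`, `distance_cM`, `ehh` (non-increasing)
#' @export
ehh_curve <- function(panel, carrier_rows, core_sites,
                      direction = c("downstream", "upstream"), map,
                      max_distance_cM = NULL) {
  direction <- match.arg(direction)
  core_idx <- sort(resolve_sites(panel, core_sites))
  pos <- panel$sites$pos_bp
  edge_pos <- if (direction == "downstream") pos[max(core_idx)] else
    pos[min(core_idx)]
  edge_cM <- interpolate_cM(map, edge_pos)
  out_idx <- if (direction == "downstream")
    which(pos > edge_pos) else rev(which(pos < edge_pos))
  c <- length(carrier_rows)
  denom <- choose(c, 2)
  grp <- rep(1L, c)
  res <- data.frame(pos_bp = numeric(0), distance_cM = numeric(0),
                    ehh = numeric(0))
  for (sidx in out_idx) {
    d_cM <- abs(interpolate_cM(map, pos[sidx]) - edge_cM)
    grp <- match(paste(grp, panel$haplotypes[carrier_rows, sidx]),
                 unique(paste(grp, panel$haplotypes[carrier_rows, sidx])))
    e <- sum(choose(tabulate(grp), 2)) / denom
    res <- rbind(res, data.frame(pos_bp = pos[sidx], distance_cM = d_cM,
                                 ehh = e))
    if (!is.null(max_distance_cM) && d_cM >= max_distance_cM) break
  }
  res
}

# homozygosity of all cores except `target` over the flank interval.
# "combined" treats the non-target carriers as one grouped set (two
# chromosomes with different cores are never identical, so the numerator is
# the within-core identical-pair sum but the denominator is all pairs of the
# set, including rare below-threshold cores); "within-core" divides by the
# within-core pair count of the enumerated cores only
pooled_other_ehh <- function(panel, cores, target, flank,
                             pooling = c("combined", "within-core")) {
  pooling <- match.arg(pooling)
  num <- 0; den <- 0; total <- 0
  hap_sets <- c(cores$haps[-target], if (pooling == "combined") cores$rare)
  for (h in hap_sets) {
    cr <- h$carrier_rows
    total <- total + length(cr)
    if (length(cr) < 2) next
    num <- num + group_homozygosity(panel$haplotypes, cr, flank)
    den <- den + choose(length(cr), 2)
  }
  if (pooling == "combined") den <- choose(total, 2)
  c(num = num, den = den)
}

#' Relative EHH of a core haplotype at a genetic distance
#'
#' REHH is the EHH of the target core haplotype divided by the pooled EHH of
#' all the other enumerated core haplotypes combined (sum of identical
#' carrier pairs over sum of carrier pairs), which corrects for local
#' variation in recombination rate. The evaluation boundary is the first
#' marker at genetic distance >= `distance_cM` from the core edge in the
#' requested direction (the last available marker, flagged `truncated`, if
#' none reaches that distance).
#'
#' @param panel a [haplotype_panel()]
#' @param cores a [enumerate_core_haplotypes()] result
#' @param target index of the target haplotype within `cores$haps`
#' @param direction `"downstream"` or `"upstream"`
#' @param distance_cM evaluation distance (default 0.25)
#' @param map a [genetic_map()]
#' @param others how the comparison set is pooled. `"combined"` (default)
#'   follows the long-range-haplotype test's definition: the EHH of all other
#'   core haplotypes *combined*, i.e. the grouped set of every non-target
#'   chromosome (rare, below-threshold cores included); since the extended
#'   haplotype includes the core, chromosomes with different cores are never
#'   identical, so splitting the comparison set across many cores lowers its
#'   EHH. `"within-core"` instead averages within the enumerated cores only
#'   (`sum_j sum_g C(e_gj,2) / sum_j C(c_j,2)`), a conditional variant that
#'   ignores between-core heterogeneity.
#' @return list with `rehh`, `ehh_target`, `ehh_others`, `x_bp`,
#'   `distance_cM` (realised), `frequency`, `truncated`, `infinite`
#' @export
rehh <- function(panel, cores, target, direction = c("downstream", "upstream"),
                 distance_cM = 0.25, map,
                 others = c("combined", "within-core")) {
  others <- match.arg(others)
  direction <- match.arg(direction)
  stopifnot(target >= 1, target <= length(cores$haps))
  core_idx <- cores$core_sites
  pos <- panel$sites$pos_bp
  edge_pos <- if (direction == "downstream") pos[max(core_idx)] else
    pos[min(core_idx)]
  edge_cM <- interpolate_cM(map, edge_pos)
  if (direction == "downstream") {
    cand <- which(pos > edge_pos &
                    interpolate_cM(map, pos) - edge_cM >= distance_cM)
    trunc <- !length(cand)
    x_idx <- if (trunc) length(pos) else min(cand)
  } else {
    cand <- which(pos < edge_pos &
                    edge_cM - interpolate_cM(map, pos) >= distance_cM)
    trunc <- !length(cand)
    x_idx <- if (trunc) 1L else max(cand)
  }
  x_bp <- pos[x_idx]
  flank <- flank_sites(panel, core_idx, direction, x_bp)
  tgt <- cores$haps[[target]]
  if (length(tgt$carrier_rows) < 2)
    stop("target core haplotype has < 2 carriers")
  e_t <- group_homozygosity(panel$haplotypes, tgt$carrier_rows, flank) /
    choose(length(tgt$carrier_rows), 2)
  oth <- pooled_other_ehh(panel, cores, target, flank, pooling = others)
  if (oth["den"] == 0)
    stop("no other core haplotype with >= 2 carriers")
  e_o <- unname(oth["num"] / oth["den"])
  inf_flag <- e_o == 0 & e_t > 0
  list(rehh = if (inf_flag) Inf else if (e_t == 0 && e_o == 0) NA_real_
       else e_t / e_o,
       ehh_target = e_t, ehh_others = e_o, x_bp = x_bp,
       distance_cM = abs(interpolate_cM(map, x_bp) - edge_cM),
       frequency = tgt$frequency, truncated = trunc, infinite = inf_flag)
}

#' Chromosome-wide REHH scan with frequency-binned empirical significance
#'
#' For every haplotype block, enumerates core haplotypes (minimum frequency
#' `min_freq`) and computes REHH in both directions at `distance_cM`. Records
#' are assigned to 20 frequency bins of width 0.05 (`floor(freq / 0.05)`,
#' frequency 1 in the top bin); within each bin the percentile of `log(REHH)`
#' is computed against all records of that bin (both directions pooled,
#' midrank ties, the record itself included). Records at or above the 95th
#' percentile are flagged `significant`; at or above the 99th, `highlighted`.
#' Infinite or undefined REHH values are reported but excluded from ranking.
#'
#' @param panel a [haplotype_panel()]
#' @param pop population code
#' @param map a [genetic_map()]
#' @param blocks a [gabriel_blocks()] result (its `"site_indices"` attribute
#'   supplies the cores); alternatively a list of site-index vectors
#' @param distance_cM evaluation distance (default 0.25)
#' @param min_freq minimum core haplotype frequency (default 0.05)
#' @param others comparison-set pooling, see [rehh()]
#' @return data.frame with one row per (block, core haplotype, direction):
#'   `block`, `core_string`, `frequency`, `n_carriers`, `direction`, `ehh`,
#'   `ehh_others`, `rehh`, `freq_bin`, `percentile`, `significant`,
#'   `highlighted`, `truncated`. Attribute `"low_confidence"` is TRUE when
#'   fewer than 20 core haplotypes were scanned.
#' @export
rehh_scan <- function(panel, pop = NULL, map, blocks, distance_cM = 0.25,
                      min_freq = 0.05,
                      others = c("combined", "within-core")) {
  others <- match.arg(others)
  core_list <- if (is.data.frame(blocks)) attr(blocks, "site_indices")
  else blocks
  rec <- list()
  n_cores_total <- 0L
  for (b in seq_along(core_list)) {
    cores <- enumerate_core_haplotypes(panel, core_list[[b]], pop = pop,
                                       min_freq = min_freq)
    usable <- vapply(cores$haps, function(h) length(h$carrier_rows) >= 2,
                     TRUE)
    n_cores_total <- n_cores_total + length(cores$haps)
    if (sum(usable) < 1) next
    for (k in which(usable)) {
      pool <- c(cores$haps[-k], if (others == "combined") cores$rare)
      n_other <- sum(vapply(pool, function(h) length(h$carrier_rows), 1L))
      others_ok <- if (others == "combined") n_other >= 2 else
        any(vapply(cores$haps[-k], function(h)
          length(h$carrier_rows) >= 2, TRUE))
      if (!others_ok) next
      for (dir in c("downstream", "upstream")) {
        r <- rehh(panel, cores, k, dir, distance_cM, map, others = others)
        rec[[length(rec) + 1L]] <- data.frame(
          block = b, core_string = cores$haps[[k]]$allele_string,
          frequency = cores$haps[[k]]$frequency,
          n_carriers = length(cores$haps[[k]]$carrier_rows),
          direction = dir, ehh = r$ehh_target, ehh_others = r$ehh_others,
          rehh = r$rehh, truncated = r$truncated,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rec)) {
    out <- data.frame(block = integer(), core_string = character(),
                      frequency = numeric(), n_carriers = integer(),
                      direction = character(), ehh = numeric(),
                      ehh_others = numeric(), rehh = numeric(),
                      truncated = logical(), freq_bin = integer(),
                      percentile = numeric(), significant = logical(),
                      highlighted = logical())
    attr(out, "low_confidence") <- TRUE
    return(out)
  }
  out <- do.call(rbind, rec)
  out$freq_bin <- pmin(floor(out$frequency / 0.05), 19)
  out$percentile <- NA_real_
  rankable <- is.finite(out$rehh) & out$rehh > 0
  lr <- log(out$rehh)
  for (b in unique(out$freq_bin[rankable])) {
    in_bin <- rankable & out$freq_bin == b
    out$percentile[in_bin] <- empirical_percentile(lr[in_bin], lr[in_bin])
  }
  out$significant <- !is.na(out$percentile) & out$percentile >= 95
  out$highlighted <- !is.na(out$percentile) & out$percentile >= 99
  attr(out, "low_confidence") <- n_cores_total < 20
  out
}
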