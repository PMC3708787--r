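# small programmatic fixtures shared across test files

# write a minimal phased VCF for the given genotype-string matrix
# gt: sites x individuals matrix of "a|b" strings (or unphased for contract
# tests); alt may contain commas for multiallelic sites
write_test_vcf <- function(path, pos, ref, alt, gt, ids = NULL,
                           chrom = "11") {
  n_ind <- ncol(gt)
  samples <- paste0("IND", seq_len(n_ind))
  if (is.null(ids)) ids <- paste0("rs", seq_along(pos))
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (i in seq_along(pos))
    lines <- c(lines, paste(c(chrom, pos[i], ids[i], ref[i], alt[i], ".",
                              "PASS", ".", "GT", gt[i, ]), collapse = "\t"))
  writeLines(lines, path)
  samples
}

# pop_map for IND1..INDn, all one population unless given
test_pop_map <- function(n, pops = "POP1") {
  stats::setNames(rep(pops, length.out = n), paste0("IND", seq_len(n)))
}

# tiny deterministic panel built directly from a 0/1 matrix
# H: chromosomes x sites
make_panel <- function(H, pops = NULL, pos = NULL, chrom = "1") {
  H <- as.matrix(H)
  n_ind <- nrow(H) / 2
  if (is.null(pops)) pops <- rep("P1", nrow(H))
  if (is.null(pos)) pos <- seq_len(ncol(H)) * 1000L
  sites <- data.frame(site_id = paste0("s", seq_len(ncol(H))), chrom = chrom,
                      pos_bp = pos, allele0 = "A", allele1 = "G",
                      stringsAsFactors = FALSE)
  haplotype_panel(sites, H, sample_ids = paste0("i", seq_len(n_ind)),
                  pop_labels = pops)
}

# independent brute-force EHH: compare full allele vectors of all carrier
# pairs over the interval
brute_ehh <- function(panel, carriers, core_idx, direction, x_bp) {
  pos <- panel$sites$pos_bp
  if (direction == "downstream") {
    edge <- pos[max(core_idx)]
    cols <- which(pos > edge & pos <= x_bp)
  } else {
    edge <- pos[min(core_idx)]
    cols <- which(pos < edge & pos >= x_bp)
  }
  c <- length(carriers)
  if (c < 2) return(NA_real_)
  same <- 0
  for (i in seq_len(c - 1)) for (j in (i + 1):c) {
    if (identical(panel$haplotypes[carriers[i], cols],
                  panel$haplotypes[carriers[j], cols])) same <- same + 1
  }
  same / choose(c, 2)
}

# independent Weir-Cockerham theta through the classical one-way ANOVA
# mean squares (stats::lm/anova), haploid observations
anova_theta <- function(counts, n) {
  y <- unlist(mapply(function(ci, ni) c(rep(1L, ci), rep(0L, ni - ci)),
                     counts, n, SIMPLIFY = FALSE))
  g <- factor(rep(seq_along(n), n))
  fit <- stats::anova(stats::lm(y ~ g))
  MSA <- fit$`Mean Sq`[1]; MSW <- fit$`Mean Sq`[2]
  r <- length(n); ntot <- sum(n)
  nc <- (ntot - sum(n^2) / ntot) / (r - 1)
  sa <- (MSA - MSW) / nc
  sa / (sa + MSW)
}

# independent likelihood-grid |D'| interval, plain R
brute_dprime_ci <- function(n00, n01, n10, n11, step = 0.001) {
  n <- n00 + n01 + n10 + n11
  p <- (n10 + n11) / n; q <- (n01 + n11) / n
  D <- n11 / n - p * q
  dmax <- if (D >= 0) min(p * (1 - q), (1 - p) * q) else
    min(p * q, (1 - p) * (1 - q))
  dp <- seq(0, 1, by = step)
  Dg <- sign(D + (D == 0)) * dp * dmax
  ll <- vapply(Dg, function(d) {
    f <- c((1 - p) * (1 - q) + d, (1 - p) * q - d, p * (1 - q) - d,
           p * q + d)
    nh <- c(n00, n01, n10, n11)
    if (any(f < 1e-12 & nh > 0)) return(-Inf)
    sum(nh[nh > 0] * log(f[nh > 0]))
  }, numeric(1))
  w <- exp(ll - max(ll)); w[!is.finite(w)] <- 0
  cum <- cumsum(w) / sum(w)
  c(dp[which(cum >= 0.05)[1]], dp[which(cum >= 0.95)[1]])
}
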