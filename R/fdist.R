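#' @useDynLib sweepscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# evaluate expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Island-model configuration for the FDIST neutrality test
#'
#' Describes the neutral null model: `n_demes_total` islands exchanging
#' migrants symmetrically at scaled rate `scaled_migration` (M, per lineage),
#' with chromosomes sampled from `length(sample_sizes)` demes.
#' Infinite-alleles mutations fall on the simulated genealogies at scaled rate
#' `theta_mut`; to cover the whole heterozygosity axis the per-locus rate is
#' drawn log-uniformly over `[theta_mut / theta_spread, theta_mut *
#' theta_spread]` (set `theta_spread = 1` for a fixed rate). Simulated allelic
#' classes are collapsed to biallelic (major allele vs rest) so simulated loci
#' are comparable to SNPs.
#'
#' @param sample_sizes integer vector: sampled chromosomes per sampled deme
#'   (r = its length; each >= 2)
#' @param n_demes_total island count d (>= r); 100 is the classic FDIST
#'   setting
#' @param scaled_migration M > 0, usually set by [calibrate_migration()]
#' @param theta_mut scaled infinite-alleles mutation rate (> 0), per
#'   branch-length unit of the 2N-deme-scaled coalescent
#' @param theta_spread log-uniform spread factor for per-locus mutation rates
#' @param n_replicates default number of simulated loci for an envelope
#' @param seed master RNG seed (integer) or NULL to use the current RNG state
#' @return object of class `island_model_config`
#' @export
island_model_config <- function(sample_sizes, n_demes_total = 100,
                                scaled_migration = NULL, theta_mut = 0.05,
                                theta_spread = 10, n_replicates = 10000,
                                seed = NULL) {
  r <- length(sample_sizes)
  if (r < 2) stop("need samples from >= 2 demes")
  if (n_demes_total < r) stop("n_demes_total must be >= number sampled")
  if (any(sample_sizes < 2)) stop("each sampled deme needs >= 2 chromosomes")
  if (!is.null(scaled_migration) && scaled_migration <= 0)
    stop("scaled_migration must be > 0")
  if (theta_mut <= 0) stop("theta_mut must be > 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(list(sample_sizes = as.integer(sample_sizes),
                 n_demes_total = as.integer(n_demes_total),
                 scaled_migration = scaled_migration, theta_mut = theta_mut,
                 theta_spread = theta_spread,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "island_model_config")
}

#' Simulate neutral (He, Fst) pairs under the island model
#'
#' Runs the structured coalescent with infinite-alleles mutation for `n`
#' independent loci, collapses each to biallelic, and computes the pooled
#' expected heterozygosity and the haploid Weir-Cockerham theta on the sampled
#' chromosome counts. Loci monomorphic after collapse are rejected and
#' redrawn (the count is returned as attribute `n_redraws`).
#'
#' @param config an [island_model_config()] with `scaled_migration` set
#' @param n number of loci (default `config$n_replicates`)
#' @param seed overrides `config$seed` when given
#' @return data.frame with columns `He`, `Fst`
#' @export
simulate_island_loci <- function(config, n = config$n_replicates,
                                 seed = config$seed) {
  if (is.null(config$scaled_migration))
    stop("scaled_migration is not set; run calibrate_migration() first")
  with_seed(seed, {
    spread <- max(config$theta_spread, 1)
    theta <- exp(stats::runif(n, log(config$theta_mut / spread),
                              log(config$theta_mut * spread)))
    sim <- sim_island_loci_cpp(config$sample_sizes, config$n_demes_total,
                               config$scaled_migration, theta, 1e6)
    counts <- sim$counts
    N <- matrix(config$sample_sizes, nrow = n,
                ncol = length(config$sample_sizes), byrow = TRUE)
    pbar <- rowSums(counts) / rowSums(N)
    cmp <- wc_components_matrix(counts / N, N)
    out <- data.frame(He = 2 * pbar * (1 - pbar), Fst = cmp$theta)
    attr(out, "n_redraws") <- sim$n_redraws
    out
  })
}

#' Calibrate the island-model migration rate to observed F_ST
#'
#' FDIST-style centring of the neutral envelope: finds the scaled migration
#' rate M at which the median simulated F_ST matches the trimmed mean
#' (central 90%) of the observed per-locus values, by bisection on log(M)
#' over `bracket`. Every evaluation simulates a fresh batch of `batch` loci
#' under one fixed evaluation seed (common random numbers), so the objective
#' is monotone decreasing in M and the bisection is stable.
#'
#' @param observed_fst numeric vector of >= 10 observed per-locus theta values
#'   (NAs dropped)
#' @param config an [island_model_config()]; its `scaled_migration` is ignored
#' @param batch loci per evaluation (>= 2000 recommended)
#' @param tol stopping tolerance on the matched F_ST
#' @param bracket search interval for M
#' @param max_iter bisection iteration cap
#' @return list with `M`, `achieved` (median simulated F_ST at `M`),
#'   `target`, `n_iter`
#' @export
calibrate_migration <- function(observed_fst, config, batch = 2000,
                                tol = 0.005, bracket = c(1e-3, 1e4),
                                max_iter = 40) {
  observed_fst <- observed_fst[!is.na(observed_fst)]
  if (length(observed_fst) < 10) stop("need >= 10 observed loci")
  target <- mean(observed_fst, trim = 0.05)
  eval_seed <- if (is.null(config$seed)) {
    sample.int(.Machine$integer.max, 1)
  } else (config$seed + 104729L) %% .Machine$integer.max
  f <- function(M) {
    cfg <- config
    cfg$scaled_migration <- M
    stats::median(simulate_island_loci(cfg, n = batch, seed = eval_seed)$Fst,
                  na.rm = TRUE)
  }
  lo <- log(bracket[1]); hi <- log(bracket[2])
  flo <- f(exp(lo)); fhi <- f(exp(hi))
  if (target > flo || target < fhi)
    stop(sprintf(paste0("calibration target %.4f outside achievable range ",
                        "[%.4f at M=%.3g, %.4f at M=%.3g]"),
                 target, fhi, bracket[2], flo, bracket[1]))
  achieved <- NA_real_; mid <- (lo + hi) / 2
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    achieved <- f(exp(mid))
    if (abs(achieved - target) <= tol) break
    if (achieved > target) lo <- mid else hi <- mid
  }
  list(M = exp(mid), achieved = achieved, target = target, n_iter = it)
}

#' Build a neutral (He, Fst) envelope
#'
#' Simulates `n_replicates` neutral loci at the configured migration rate and
#' summarises the conditional F_ST distribution as 2.5% / 50% / 97.5%
#' quantile curves over a grid of He values (for inspection and plotting; the
#' outlier test itself uses the raw simulated points).
#'
#' @param config an [island_model_config()] with `scaled_migration` set
#'   (e.g. from [calibrate_migration()])
#' @param n_replicates number of simulated loci
#' @param seed overrides `config$seed`
#' @return object of class `neutral_envelope` with elements `sim_points`,
#'   `quantile_curves`, `target_mean_fst`, `config`
#' @export
build_neutral_envelope <- function(config, n_replicates = config$n_replicates,
                                   seed = config$seed) {
  pts <- simulate_island_loci(config, n = n_replicates, seed = seed)
  grid <- seq(0.025, 0.5, by = 0.025)
  qc <- do.call(rbind, lapply(grid, function(h) {
    sel <- cond_select(pts$He, h, 0.025, 200)
    qs <- stats::quantile(pts$Fst[sel], c(0.025, 0.5, 0.975), na.rm = TRUE,
                          names = FALSE)
    data.frame(He = h, q025 = qs[1], q50 = qs[2], q975 = qs[3])
  }))
  structure(list(sim_points = pts, quantile_curves = qc,
                 target_mean_fst = stats::median(pts$Fst, na.rm = TRUE),
                 config = config),
            class = "neutral_envelope")
}

#' @export
print.neutral_envelope <- function(x, ...) {
  cat("neutral_envelope:", nrow(x$sim_points), "simulated loci, d =",
      x$config$n_demes_total, ", M =",
      signif(x$config$scaled_migration, 4), "\n")
  cat("  median simulated F_ST:", signif(x$target_mean_fst, 4), "\n")
  invisible(x)
}

# indices of simulated loci matched on He: bandwidth widened (doubled) until
# >= min_pts matches; falls back to the nearest min_pts with a warning
cond_select <- function(he_sim, he_obs, bandwidth, min_pts) {
  bw <- bandwidth
  span <- max(he_sim) - min(he_sim)
  repeat {
    sel <- which(abs(he_sim - he_obs) <= bw)
    if (length(sel) >= min_pts || length(sel) == length(he_sim)) break
    if (bw > span) {
      warning("conditioning bandwidth exhausted; using nearest ", min_pts,
              " simulated loci")
      sel <- order(abs(he_sim - he_obs))[seq_len(min(min_pts, length(he_sim)))]
      break
    }
    bw <- bw * 2
  }
  sel
}

#' Conditional outlier probability of an observed (He, Fst) point
#'
#' Among simulated neutral loci whose He lies within `bandwidth` of the
#' observed He (bandwidth widened until at least `min_pts` matches),
#' `p_below` is the midrank fraction of simulated F_ST values below the
#' observed value: `(#below + 0.5 * #equal) / #matched`.
#'
#' @param he,fst observed values (vectors of equal length)
#' @param envelope a [build_neutral_envelope()] result with >= 500 points
#' @param bandwidth initial He matching half-width
#' @param min_pts minimum conditional sample size
#' @return numeric vector of `p_below` in `[0, 1]`
#' @export
outlier_probability <- function(he, fst, envelope, bandwidth = 0.025,
                                min_pts = 200) {
  pts <- envelope$sim_points
  ok <- !is.na(pts$Fst)
  he_sim <- pts$He[ok]; fst_sim <- pts$Fst[ok]
  if (length(fst_sim) < 500) stop("envelope needs >= 500 simulated points")
  vapply(seq_along(he), function(k) {
    sel <- cond_select(he_sim, he[k], bandwidth, min_pts)
    x <- fst_sim[sel]
    (sum(x < fst[k]) + 0.5 * sum(x == fst[k])) / length(x)
  }, numeric(1))
}

#' Classify selection from the conditional outlier probability
#'
#' `positive-candidate` when `p_below >= 0.975` (excess differentiation),
#' `balancing-candidate` when `p_below <= 0.025` (deficit), else `neutral`.
#'
#' @param p_below numeric vector in `[0, 1]`
#' @return character vector of classifications
#' @export
classify_selection <- function(p_below) {
  stopifnot(all(p_below >= 0 & p_below <= 1, na.rm = TRUE))
  ifelse(is.na(p_below), NA_character_,
         ifelse(p_below >= 0.975, "positive-candidate",
                ifelse(p_below <= 0.025, "balancing-candidate", "neutral")))
}

#' F_ST-outlier neutrality test on a panel
#'
#' The full FDIST-style stage: computes per-site pooled He and multi-population
#' Weir-Cockerham theta, calibrates the island-model migration rate so the
#' neutral envelope is centred on the observed chromosome-wide F_ST level,
#' simulates the envelope, and scores each candidate site's conditional
#' outlier probability and classification.
#'
#' @param panel a [haplotype_panel()]
#' @param sites candidate site ids/indices (NULL = all sites)
#' @param pops populations to include (NULL = all)
#' @param n_demes_total,theta_mut,theta_spread,n_replicates,seed forwarded to
#'   [island_model_config()]
#' @param batch calibration batch size
#' @return list with `results` (data.frame: site_id, He, Fst, p_below,
#'   classification), `envelope`, `calibration`
#' @export
fdist_test <- function(panel, sites = NULL, pops = NULL, n_demes_total = 100,
                       theta_mut = 0.05, theta_spread = 10,
                       n_replicates = 10000, seed = NULL, batch = 2000) {
  if (is.null(pops)) pops <- panel_pops(panel)
  obs_all <- site_fst(panel, pops = pops)
  cfg <- island_model_config(
    sample_sizes = vapply(pops, function(p) length(pop_rows(panel, p)), 1L),
    n_demes_total = n_demes_total, theta_mut = theta_mut,
    theta_spread = theta_spread, n_replicates = n_replicates, seed = seed)
  cal <- calibrate_migration(obs_all$theta[obs_all$defined], cfg,
                             batch = batch)
  cfg$scaled_migration <- cal$M
  env <- build_neutral_envelope(cfg)
  idx <- resolve_sites(panel, sites)
  af <- allele_freqs(panel, sites = idx, pops = pops)
  nmat <- matrix(af$n_chrom, ncol = length(pops))
  pmat <- matrix(af$p, ncol = length(pops))
  pbar <- rowSums(pmat * nmat) / rowSums(nmat)
  he <- 2 * pbar * (1 - pbar)
  fst <- obs_all$theta[idx]
  pb <- rep(NA_real_, length(idx))
  okobs <- he > 0 & he < 1 & !is.na(fst)
  if (any(okobs)) pb[okobs] <- outlier_probability(he[okobs], fst[okobs], env)
  res <- data.frame(site_id = panel$sites$site_id[idx], He = he, Fst = fst,
                    p_below = pb, classification = classify_selection(pb),
                    stringsAsFactors = FALSE, row.names = NULL)
  list(results = res, envelope = env, calibration = cal)
}
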