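#' Generate an island-model differentiated SNP panel (Balding-Nichols)
#'
#' Unlinked biallelic sites with a tunable expected F_ST: per site the
#' ancestral frequency is drawn `p0 ~ Uniform(0.05, 0.95)` and each deme's
#' frequency from `Beta(p0 (1-F)/F, (1-p0)(1-F)/F)` with `F = target_fst`;
#' chromosomes are independent Bernoulli draws at the deme frequency. Sites
#' are unlinked, so this panel exercises the F_ST and FDIST stages, not LD.
#'
#' @param n_demes number of populations (>= 2), labelled `D1`, `D2`, ...
#' @param n_per_deme sampled chromosomes per deme (even: chromosomes are
#'   paired into individuals)
#' @param target_fst expected differentiation F in (0, 1)
#' @param n_sites number of unlinked sites
#' @param seed RNG seed (NULL = current RNG state)
#' @param chrom chromosome label
#' @param spacing_bp distance between consecutive (nominal) positions
#' @return a [haplotype_panel()]
#' @export
gen_island_snp_panel <- function(n_demes = 4, n_per_deme = 100,
                                 target_fst = 0.10, n_sites = 1000,
                                 seed = NULL, chrom = "1",
                                 spacing_bp = 10000) {
  if (n_demes < 2) stop("n_demes must be >= 2")
  if (target_fst <= 0 || target_fst >= 1)
    stop("target_fst must be in (0, 1)")
  if (n_per_deme %% 2 != 0) stop("n_per_deme must be even (paired chromosomes)")
  with_seed(seed, {
    L <- n_sites
    p0 <- stats::runif(L, 0.05, 0.95)
    FF <- target_fst
    H <- matrix(0L, nrow = n_demes * n_per_deme, ncol = L)
    pops <- character(n_demes * n_per_deme)
    for (dm in seq_len(n_demes)) {
      pdm <- stats::rbeta(L, p0 * (1 - FF) / FF, (1 - p0) * (1 - FF) / FF)
      rows <- (dm - 1) * n_per_deme + seq_len(n_per_deme)
      H[rows, ] <- matrix(stats::rbinom(n_per_deme * L, 1L,
                                        rep(pdm, each = n_per_deme)),
                          nrow = n_per_deme)
      pops[rows] <- paste0("D", dm)
    }
    n_ind <- n_demes * n_per_deme / 2
    sites <- data.frame(site_id = sprintf("snp%05d", seq_len(L)),
                        chrom = chrom, pos_bp = spacing_bp * seq_len(L),
                        allele0 = "A", allele1 = "G",
                        stringsAsFactors = FALSE)
    haplotype_panel(sites, H,
                    sample_ids = sprintf("%s_ind%04d",
                                         rep(paste0("D", seq_len(n_demes)),
                                             each = n_per_deme / 2),
                                         seq_len(n_ind)),
                    pop_labels = pops)
  })
}

#' Configuration for the forward Wright-Fisher sweep simulator
#'
#' @param n_demes number of demes
#' @param deme_size_N haploid chromosomes per deme
#' @param migration_m per-generation per-chromosome migration probability
#' @param n_sites number of (evenly spaced) sites
#' @param region_bp simulated region length in bp
#' @param map_rate_cM_per_Mb constant recombination rate
#' @param sel_coefficient_s selective advantage of the sweep allele (applied
#'   in deme 1 only; 0 for a neutral run)
#' @param sweep_site_index site carrying the sweep allele
#' @param init_sweep_freq_f0 initial sweep-allele frequency in deme 1, seeded
#'   as identical copies of a single carrier haplotype
#' @param n_generations forward generations
#' @param sample_per_deme chromosomes sampled per deme at the end (even)
#' @param n_founders founder haplotypes for the mosaic founding generation
#' @param founder_seg_cM mean copying-segment length (cM) of the founder
#'   mosaic (controls background LD)
#' @param core_size sites around the sweep site recorded in the truth record
#' @param seed RNG seed
#' @return object of class `sweep_sim_config`
#' @export
sweep_sim_config <- function(n_demes = 2, deme_size_N = 1000,
                             migration_m = 0.01, n_sites = 2000,
                             region_bp = 5e6, map_rate_cM_per_Mb = 1,
                             sel_coefficient_s = 0.1,
                             sweep_site_index = n_sites %/% 2,
                             init_sweep_freq_f0 = 0.05, n_generations = 200,
                             sample_per_deme = 200, n_founders = 20,
                             founder_seg_cM = 0.5, core_size = 17,
                             seed = NULL) {
  if (migration_m < 0 || migration_m > 1) stop("migration_m must be in [0, 1]")
  if (sel_coefficient_s < 0) stop("sel_coefficient_s must be >= 0")
  if (init_sweep_freq_f0 <= 0 || init_sweep_freq_f0 >= 1)
    stop("init_sweep_freq_f0 must be in (0, 1)")
  if (sweep_site_index < 1 || sweep_site_index > n_sites)
    stop("sweep_site_index outside the site range")
  if (sample_per_deme %% 2 != 0) stop("sample_per_deme must be even")
  if (sample_per_deme > deme_size_N) stop("sample_per_deme > deme_size_N")
  structure(as.list(environment()), class = "sweep_sim_config")
}

#' Simulate a multi-deme panel with an optional planted selective sweep
#'
#' Forward-time haploid Wright-Fisher simulation with recombination at a
#' constant map rate, island migration, and fitness `1 + s` for sweep-allele
#' carriers in deme 1. The founding generation is a mosaic over
#' `n_founders` random haplotypes (block-like background LD); the sweep
#' allele starts as `round(f0 N)` identical copies of one carrier haplotype
#' in deme 1. If the sweep allele is lost everywhere, the simulation is
#' retried with the next derived seed (up to 50 attempts).
#'
#' @param config a [sweep_sim_config()]
#' @return list with `panel` (a [haplotype_panel()], monomorphic sites
#'   removed, populations `D1`, `D2`, ...), `map` (a [genetic_map()]), and
#'   `truth`: `sweep_site_id`, `sweep_site_retained`, `final_sweep_freq`
#'   (full-deme frequencies), `core_site_ids`, `sweep_core_string` (the
#'   seeded haplotype's alleles over the declared core), `attempts`
#' @export
gen_sweep_panel <- function(config) {
  stopifnot(inherits(config, "sweep_sim_config"))
  L <- config$n_sites
  pos <- round(seq(1, config$region_bp, length.out = L))
  pos_cM <- (pos - 1) / 1e6 * config$map_rate_cM_per_Mb
  map <- genetic_map(c(1, config$region_bp),
                     c(0, (config$region_bp - 1) / 1e6 *
                         config$map_rate_cM_per_Mb))
  base_seed <- config$seed
  sim <- NULL
  for (attempt in seq_len(50)) {
    seed_k <- if (is.null(base_seed)) NULL else
      (base_seed + (attempt - 1L) * 7919L) %% .Machine$integer.max
    res <- with_seed(seed_k, {
      wf <- sim_sweep_cpp(config$n_demes, config$deme_size_N,
                          config$migration_m, pos_cM,
                          config$sel_coefficient_s,
                          config$sweep_site_index - 1L,
                          config$init_sweep_freq_f0, config$n_generations,
                          config$n_founders, config$founder_seg_cM)
      if (wf$lost) NULL else {
        rows <- unlist(lapply(seq_len(config$n_demes), function(dm) {
          offs <- (dm - 1) * config$deme_size_N
          offs + sample.int(config$deme_size_N, config$sample_per_deme)
        }))
        list(wf = wf, rows = rows)
      }
    })
    if (!is.null(res)) { sim <- res; break }
  }
  if (is.null(sim))
    stop("sweep allele lost in all demes in 50 consecutive attempts")
  H <- sim$wf$haplotypes[sim$rows, , drop = FALSE]
  site_ids <- sprintf("s%05d", seq_len(L))
  core_lo <- max(1L, config$sweep_site_index - (config$core_size - 1L) %/% 2L)
  core_hi <- min(L, core_lo + config$core_size - 1L)
  core_ids <- site_ids[core_lo:core_hi]
  seed_hap <- sim$wf$seed_hap
  poly <- which(colSums(H) > 0 & colSums(H) < nrow(H))
  sites <- data.frame(site_id = site_ids[poly],
                      chrom = rep("1", length(poly)),
                      pos_bp = pos[poly],
                      allele0 = rep("A", length(poly)),
                      allele1 = rep("G", length(poly)),
                      stringsAsFactors = FALSE)
  pops <- rep(paste0("D", seq_len(config$n_demes)),
              each = config$sample_per_deme)
  n_ind <- length(sim$rows) / 2
  panel <- haplotype_panel(sites, H[, poly, drop = FALSE],
                           sample_ids = sprintf("%s_ind%04d",
                                                rep(paste0("D", seq_len(config$n_demes)),
                                                    each = config$sample_per_deme / 2),
                                                seq_len(n_ind)),
                           pop_labels = pops)
  retained_core <- intersect(core_lo:core_hi, poly)
  truth <- list(
    sweep_site_id = site_ids[config$sweep_site_index],
    sweep_site_pos = pos[config$sweep_site_index],
    sweep_site_retained = config$sweep_site_index %in% poly,
    final_sweep_freq = as.numeric(sim$wf$sweep_freq),
    core_site_ids = site_ids[retained_core],
    sweep_core_string = paste(ifelse(seed_hap[retained_core] == 1L, "G", "A"),
                              collapse = ""),
    seed_hap_retained = as.integer(seed_hap[poly]),
    attempts = attempt)
  list(panel = panel, map = map, truth = truth)
}

# rate column (cM/Mb) for a HapMap-format map file
write_genetic_map <- function(map, path) {
  n <- length(map$pos_bp)
  rate <- if (n > 1)
    c(diff(map$cM) / (diff(map$pos_bp) / 1e6),
      (map$cM[n] - map$cM[n - 1]) / ((map$pos_bp[n] - map$pos_bp[n - 1]) / 1e6))
  else 0
  utils::write.table(data.frame(position = map$pos_bp, rate = rate,
                                cM = map$cM),
                     path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Write a simulated panel as a fixture set in every requested format
#'
#' Emits the panel in each format, the genetic map (HapMap-style three-column
#' file), the truth record as JSON, and a manifest with md5 checksums.
#' Loading any emitted panel file reproduces the allele matrix exactly.
#'
#' @param panel a [haplotype_panel()]
#' @param map a [genetic_map()] or NULL
#' @param truth truth-record list or NULL
#' @param out_dir output directory (created if needed)
#' @param formats subset of `c("phased-vcf", "impute-hls", "tsv")`
#' @return data.frame manifest (`file`, `md5`), also written to
#'   `manifest.tsv`
#' @export
write_fixture_set <- function(panel, map = NULL, truth = NULL, out_dir,
                              formats = c("phased-vcf", "impute-hls", "tsv")) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  files <- character(0)
  for (fmt in formats) {
    fn <- switch(fmt,
                 "phased-vcf" = "panel.vcf",
                 "impute-hls" = "panel.hap",
                 "tsv" = "panel.tsv",
                 stop("unknown format: ", fmt))
    write_panel(panel, file.path(out_dir, fn), fmt)
    files <- c(files, fn)
    if (fmt == "impute-hls") files <- c(files, "panel.legend", "panel.sample")
  }
  pm <- data.frame(sample_id = panel$sample_ids,
                   pop = panel$pop_labels[seq(1, length(panel$pop_labels),
                                              2)])
  utils::write.table(pm, file.path(out_dir, "pop_map.tsv"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  files <- c(files, "pop_map.tsv")
  if (!is.null(map)) {
    write_genetic_map(map, file.path(out_dir, "genetic_map.txt"))
    files <- c(files, "genetic_map.txt")
  }
  if (!is.null(truth)) {
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, "truth.json")
  }
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir,
                                                              files))),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     quote = FALSE, row.names = FALSE, sep = "\t")
  manifest
}
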