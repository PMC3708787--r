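test_that("Balding-Nichols panel hits its target differentiation", {
  panel <- gen_island_snp_panel(n_demes = 4, n_per_deme = 100,
                                target_fst = 0.10, n_sites = 1000, seed = 7)
  expect_equal(n_chromosomes(panel), 400L)
  fst <- site_fst(panel)
  cmb <- wc_theta_multi(fst$a_comp[fst$defined], fst$b_comp[fst$defined])
  expect_gte(cmb$theta, 0.08)
  expect_lte(cmb$theta, 0.12)
  # panmixia limit
  p0 <- gen_island_snp_panel(n_demes = 4, n_per_deme = 100,
                             target_fst = 1e-6, n_sites = 500, seed = 8)
  f0 <- site_fst(p0)
  c0 <- wc_theta_multi(f0$a_comp[f0$defined], f0$b_comp[f0$defined])
  expect_lt(abs(c0$theta), 0.01)
  expect_error(gen_island_snp_panel(target_fst = 1.2), "target_fst")
})

test_that("generators are deterministic under a fixed seed", {
  a <- gen_island_snp_panel(n_sites = 100, seed = 5)
  b <- gen_island_snp_panel(n_sites = 100, seed = 5)
  expect_identical(a, b)
  cfg <- sweep_sim_config(n_sites = 200, region_bp = 1e6, deme_size_N = 100,
                          n_generations = 30, sample_per_deme = 40, seed = 6)
  s1 <- gen_sweep_panel(cfg)
  s2 <- gen_sweep_panel(cfg)
  expect_identical(s1$panel, s2$panel)
  expect_identical(s1$truth, s2$truth)
})

test_that("neutral sweep-site frequency behaves like a drift martingale", {
  # s = 0: conditional on retention, the mean final frequency stays near f0
  # once the retention bias is accounted for; cheap proxy at small scale:
  # over replicates, E[final freq | not lost] * P(not lost) ~ f0
  set.seed(1)
  fins <- c(); kept <- 0; tries <- 60
  for (k in seq_len(tries)) {
    cfg <- sweep_sim_config(n_demes = 1, deme_size_N = 200, n_sites = 60,
                            region_bp = 3e5, n_generations = 40,
                            sample_per_deme = 20, sel_coefficient_s = 0,
                            init_sweep_freq_f0 = 0.2, migration_m = 0,
                            seed = 1000 + k)
    out <- tryCatch(gen_sweep_panel(cfg), error = function(e) NULL)
    # count only first-attempt retentions to keep the martingale unbiased
    if (!is.null(out) && out$truth$attempts == 1) {
      kept <- kept + 1
      fins <- c(fins, out$truth$final_sweep_freq[1])
    }
  }
  est <- sum(fins) / tries  # lost attempts contribute 0
  se <- sd(c(fins, rep(0, tries - kept))) / sqrt(tries)
  expect_lt(abs(est - 0.2), 3 * se + 0.02)
})

test_that("positive selection drives the sweep allele upward", {
  mean_fin <- function(s, seeds) {
    mean(vapply(seeds, function(sd) {
      cfg <- sweep_sim_config(n_demes = 1, deme_size_N = 500, n_sites = 100,
                              region_bp = 5e5, n_generations = 150,
                              sample_per_deme = 20, sel_coefficient_s = s,
                              migration_m = 0, seed = sd)
      gen_sweep_panel(cfg)$truth$final_sweep_freq[1]
    }, numeric(1)))
  }
  m_sel <- mean_fin(0.05, 1:12)
  expect_gt(m_sel, 0.5)  # logistic growth dominates drift at s*t ~ 7.5
  m_neu <- mean_fin(0, 1:12)
  expect_gt(m_sel, m_neu)
})

test_that("fixture sets round-trip and the manifest is complete and stable", {
  res <- gen_sweep_panel(sweep_sim_config(n_sites = 120, region_bp = 5e5,
                                          deme_size_N = 100,
                                          n_generations = 20,
                                          sample_per_deme = 30, seed = 9))
  out1 <- file.path(withr::local_tempdir(), "fx1")
  man1 <- write_fixture_set(res$panel, res$map, res$truth, out1)
  expect_setequal(man1$file,
                  c("panel.vcf", "panel.hap", "panel.legend", "panel.sample",
                    "panel.tsv", "pop_map.tsv", "genetic_map.txt",
                    "truth.json"))
  pm <- file.path(out1, "pop_map.tsv")
  for (f in c("panel.vcf", "panel.hap", "panel.tsv")) {
    fmt <- c(panel.vcf = "phased-vcf", panel.hap = "impute-hls",
             panel.tsv = "tsv")[[f]]
    back <- load_panel(file.path(out1, f), fmt, pm)
    expect_equal(back$haplotypes, res$panel$haplotypes, ignore_attr = TRUE)
  }
  # identical seed -> identical checksums
  out2 <- file.path(withr::local_tempdir(), "fx2")
  res2 <- gen_sweep_panel(sweep_sim_config(n_sites = 120, region_bp = 5e5,
                                           deme_size_N = 100,
                                           n_generations = 20,
                                           sample_per_deme = 30, seed = 9))
  man2 <- write_fixture_set(res2$panel, res2$map, res2$truth, out2)
  expect_equal(man1$md5, man2$md5)
  # the emitted genetic map loads back
  gm <- load_genetic_map(file.path(out1, "genetic_map.txt"))
  expect_equal(interpolate_cM(gm, res$map$pos_bp), res$map$cM,
               tolerance = 1e-8)
})
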