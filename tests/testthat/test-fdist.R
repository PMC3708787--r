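test_that("classification thresholds reproduce reported outlier calls", {
  # P values as printed for known positive / balancing / neutral SNPs
  expect_equal(classify_selection(0.997845), "positive-candidate")
  expect_equal(classify_selection(0.001499), "balancing-candidate")
  expect_equal(classify_selection(0.451885), "neutral")
  expect_equal(classify_selection(c(0.975, 0.025)),
               c("positive-candidate", "balancing-candidate"))
  expect_error(classify_selection(1.2))
})

test_that("outlier probability counts conditionally matched loci", {
  env <- structure(list(sim_points = data.frame(
    He = rep(0.3, 1000),
    Fst = c(seq_len(975) / 1000, 2 + seq_len(25)))),
    class = "neutral_envelope")
  # below every conditional value
  expect_equal(outlier_probability(0.3, -1, env), 0)
  # exceeds 975, ties none
  expect_equal(outlier_probability(0.3, 1.5, env), 0.975)
  # ties all
  env2 <- structure(list(sim_points = data.frame(He = rep(0.3, 600),
                                                 Fst = rep(0.1, 600))),
                    class = "neutral_envelope")
  expect_equal(outlier_probability(0.3, 0.1, env2), 0.5)
  expect_error(outlier_probability(0.3, 0.1, structure(
    list(sim_points = data.frame(He = 1:10 / 20, Fst = 1:10 / 10)),
    class = "neutral_envelope")), ">= 500")
})

test_that("p_below is monotone in observed F_ST at fixed He", {
  set.seed(5)
  env <- structure(list(sim_points = data.frame(He = runif(2000, 0.2, 0.4),
                                                Fst = rbeta(2000, 2, 18))),
                   class = "neutral_envelope")
  fsts <- seq(0, 0.5, by = 0.05)
  p <- outlier_probability(rep(0.3, length(fsts)), fsts, env)
  expect_true(all(diff(p) >= 0))
})

test_that("panmixia limit gives mean F_ST near zero", {
  cfg <- island_model_config(sample_sizes = rep(50, 4), n_demes_total = 100,
                             scaled_migration = 1e4, seed = 42)
  pts <- simulate_island_loci(cfg, n = 2000)
  expect_lt(abs(mean(pts$Fst, na.rm = TRUE)), 0.01)
  expect_true(all(pts$He >= 0 & pts$He <= 1))
})

test_that("simulated loci are reproducible under a fixed seed", {
  cfg <- island_model_config(sample_sizes = c(30, 30), n_demes_total = 50,
                             scaled_migration = 5, seed = 7)
  a <- simulate_island_loci(cfg, n = 200)
  b <- simulate_island_loci(cfg, n = 200)
  expect_identical(a, b)
})

test_that("calibration matches the simulated median to the observed level", {
  set.seed(4)
  obs <- rbeta(500, 2, 18)  # level ~0.10
  cfg <- island_model_config(sample_sizes = rep(50, 4), n_demes_total = 100,
                             seed = 19)
  cal <- calibrate_migration(obs, cfg, batch = 2000)
  expect_lte(abs(cal$achieved - cal$target), 0.005)
  # self-consistency: fresh loci at the calibrated M recover the level
  cfg$scaled_migration <- cal$M
  fresh <- simulate_island_loci(cfg, n = 2000, seed = 77)
  expect_gte(median(fresh$Fst, na.rm = TRUE), 0.5 * cal$target)
  expect_lte(median(fresh$Fst, na.rm = TRUE), 1.5 * cal$target)
  # near-zero observed values push M toward the upper bracket
  cal0 <- calibrate_migration(rep(0.001, 50), cfg, batch = 500)
  expect_lt(cal0$achieved, 0.01)
})

test_that("envelope builds at a full study-scale sample", {
  # ten panels totalling 993 individuals (1986 chromosomes); replicate count
  # kept small here, the statistic scales linearly in it
  sizes <- c(53, 113, 85, 88, 170, 90, 50, 143, 88, 113) * 2
  cfg <- island_model_config(sample_sizes = sizes, n_demes_total = 100,
                             scaled_migration = 9, n_replicates = 1000,
                             seed = 2)
  env <- build_neutral_envelope(cfg)
  expect_equal(nrow(env$sim_points), 1000L)
  expect_true(all(env$sim_points$He >= 0 & env$sim_points$He <= 1))
  qc <- env$quantile_curves
  expect_true(all(qc$q025 <= qc$q50 & qc$q50 <= qc$q975))
})

test_that("envelope quantile curves are ordered and reproducible", {
  cfg <- island_model_config(sample_sizes = rep(40, 4), n_demes_total = 100,
                             scaled_migration = 9, n_replicates = 1500,
                             seed = 99)
  e1 <- build_neutral_envelope(cfg)
  e2 <- build_neutral_envelope(cfg)
  expect_identical(e1$sim_points, e2$sim_points)
  qc <- e1$quantile_curves
  expect_true(all(qc$q025 <= qc$q50 & qc$q50 <= qc$q975))
})
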