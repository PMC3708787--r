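test_that("two-locus statistics match hand evaluation", {
  r <- ld_pair_from_counts(40, 10, 10, 40)
  expect_equal(r$D, 0.15)
  expect_equal(r$Dprime, 0.6)
  expect_equal(r$r2, 0.36)
  expect_equal(r$LOD, (80 * log10(0.4) + 20 * log10(0.1)) - 100 * log10(0.25),
               tolerance = 1e-9)
  ind <- ld_pair_from_counts(25, 25, 25, 25)
  expect_equal(ind$D, 0)
  expect_equal(ind$Dprime, 0)
  expect_equal(ind$r2, 0)
  expect_equal(ind$LOD, 0)
  perf <- ld_pair_from_counts(50, 0, 0, 50)
  expect_equal(perf$Dprime, 1)
  expect_equal(perf$r2, 1)
  # degenerate frequencies flagged undefined
  expect_false(ld_pair_from_counts(50, 0, 50, 0)$defined)
})

test_that("|D'| confidence interval matches the brute-force grid", {
  cases <- list(c(500, 0, 0, 500), c(40, 10, 10, 40), c(25, 25, 25, 25),
                c(70, 5, 10, 15), c(10, 40, 35, 15), c(3, 9, 2, 86))
  for (cs in cases) {
    got <- dprime_ci(cs[1], cs[2], cs[3], cs[4])
    want <- brute_dprime_ci(cs[1], cs[2], cs[3], cs[4])
    expect_equal(unname(got), want, tolerance = 1e-9)
  }
  expect_gte(dprime_ci(500, 0, 0, 500)[["ci_low"]], 0.98)
  ci <- dprime_ci(40, 10, 10, 40)
  expect_lt(ci[["ci_low"]], 0.6)
  expect_gt(ci[["ci_high"]], 0.6)
  expect_lt(dprime_ci(25, 25, 25, 25)[["ci_high"]], 0.9)
})

test_that("Gabriel pair classes follow the CI rule", {
  expect_equal(classify_pair(0.85, 0.99), "strong-LD")
  expect_equal(classify_pair(0.10, 0.80), "strong-recombination")
  expect_equal(classify_pair(0.72, 0.95), "inconclusive")
  expect_equal(classify_pair(NA, NA), "undefined")
})

test_that("LD colour classes follow the triangle-plot convention", {
  expect_equal(ld_colour_class(1.0, 5.0), "bright-red")
  expect_equal(ld_colour_class(0.6, 8.37), "pink")
  expect_equal(ld_colour_class(0.3, 0.5), "white")
  expect_equal(ld_colour_class(1.0, 0.5), "blue")
  # tolerance on D' = 1
  expect_equal(ld_colour_class(1 - 1e-12, 3), "bright-red")
})

test_that("D' and r2 invariances hold over random tables", {
  set.seed(31)
  for (i in 1:200) {
    n <- as.vector(stats::rmultinom(1, 200, runif(4, 0.05, 1)))
    a <- ld_pair_from_counts(n[1], n[2], n[3], n[4])
    if (!a$defined) next
    # simultaneous swap at both sites: (n00,n01,n10,n11) -> (n11,n10,n01,n00)
    b <- ld_pair_from_counts(n[4], n[3], n[2], n[1])
    expect_equal(a$Dprime, b$Dprime, tolerance = 1e-12)
    expect_equal(a$r2, b$r2, tolerance = 1e-12)
    # single-site swap flips the sign of D, not D'
    c <- ld_pair_from_counts(n[2], n[1], n[4], n[3])
    expect_equal(a$D, -c$D, tolerance = 1e-12)
    expect_equal(a$Dprime, c$Dprime, tolerance = 1e-12)
    # r2 <= D'
    expect_lte(a$r2, a$Dprime + 1e-12)
  }
})

test_that("zero-recombination panel forms one full-span block", {
  set.seed(12)
  # 200 chromosomes drawn from two complementary 10-SNP haplotypes: no
  # recombinant gamete exists, so D' = 1 at every pair
  proto <- rbinom(10, 1, 0.5)
  H <- rbind(matrix(proto, 120, 10, byrow = TRUE),
             matrix(1 - proto, 80, 10, byrow = TRUE))
  panel <- make_panel(H)
  blocks <- gabriel_blocks(panel)
  expect_equal(nrow(blocks), 1L)
  expect_equal(attr(blocks, "site_indices")[[1]], 1:10)
  expect_gte(blocks$frac_strong_ld, 0.95)
})

test_that("independent sites almost never form blocks of span > 2", {
  set.seed(77)
  long <- 0
  for (rep in 1:10) {
    H <- matrix(rbinom(200 * 15, 1, runif(15, 0.2, 0.8)), nrow = 200,
                byrow = TRUE)
    blocks <- gabriel_blocks(make_panel(H))
    if (nrow(blocks) && any(blocks$n_sites > 2)) long <- long + 1
  }
  expect_lte(long, 1)
})

test_that("two perfect-LD clusters split by an independent SNP give 2 blocks", {
  set.seed(13)
  n <- 200
  left <- rbinom(n, 1, 0.5)
  mid <- rbinom(n, 1, 0.5)
  right <- rbinom(n, 1, 0.5)
  H <- cbind(left, left, left, left, left,
             mid,
             right, right, right, right, right)
  panel <- make_panel(H)
  blocks <- gabriel_blocks(panel)
  expect_equal(nrow(blocks), 2L)
  expect_setequal(blocks$n_sites, c(5L, 5L))
  expect_false(6L %in% unlist(attr(blocks, "site_indices")))
})

test_that("block partition is deterministic and non-overlapping", {
  panel <- gen_sweep_panel(sweep_sim_config(n_sites = 400, region_bp = 1e6,
                                            deme_size_N = 200,
                                            n_generations = 50,
                                            sample_per_deme = 60,
                                            seed = 5))$panel
  b1 <- gabriel_blocks(panel, pop = "D1", max_span_sites = 30)
  b2 <- gabriel_blocks(panel, pop = "D1", max_span_sites = 30)
  expect_identical(b1, b2)
  if (nrow(b1) > 1) {
    s <- b1[order(b1$start_site), ]
    expect_true(all(s$start_site[-1] > s$end_site[-nrow(s)]))
  }
})
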