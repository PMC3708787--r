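test_that("core haplotype enumeration tabulates strings and carriers", {
  H <- rbind(c(0L, 1L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  panel <- make_panel(H)
  cores <- enumerate_core_haplotypes(panel, 1:2, min_freq = 0)
  freqs <- vapply(cores$haps, `[[`, numeric(1), "frequency")
  expect_equal(sort(freqs, decreasing = TRUE), c(0.5, 0.25, 0.25))
  strs <- vapply(cores$haps, `[[`, character(1), "allele_string")
  expect_equal(strs[1], "AG")  # allele0 = A, allele1 = G
  # monomorphic core
  mono <- enumerate_core_haplotypes(make_panel(matrix(0L, 4, 2)), 1:2)
  expect_length(mono$haps, 1)
  expect_equal(mono$haps[[1]]$frequency, 1.0)
  # rare haplotypes filtered into $rare, frequencies may sum below 1
  set.seed(3)
  H2 <- matrix(rbinom(200 * 3, 1, 0.5), ncol = 3)
  cs <- enumerate_core_haplotypes(make_panel(H2), 1:3, min_freq = 0.10)
  expect_true(all(vapply(cs$haps, `[[`, numeric(1), "frequency") >= 0.10))
})

test_that("EHH equals hand-computed partition values", {
  # 6 carriers split (3, 2, 1) over the flank: (3 + 1 + 0) / 15
  H <- cbind(rep(1L, 6),
             c(0L, 0L, 0L, 1L, 1L, 0L),
             c(0L, 0L, 0L, 0L, 0L, 1L))
  panel <- make_panel(H)
  e <- ehh(panel, carrier_rows = 1:6, core_sites = 1, "downstream",
           x_bp = 3000)
  expect_equal(e, 4 / 15)
  # empty interval
  expect_equal(ehh(panel, 1:6, 1, "downstream", x_bp = 1000), 1.0)
  # all distinct beyond the first flanking site -> 0
  H3 <- cbind(rep(1L, 4), c(0L, 1L, 0L, 1L), c(0L, 0L, 1L, 1L))
  expect_equal(ehh(make_panel(H3), 1:4, 1, "downstream", 3000), 0)
})

test_that("partition EHH equals brute-force pair enumeration exactly", {
  set.seed(101)
  for (i in 1:60) {
    nc <- sample(seq(6, 30, 2), 1)
    L <- sample(10:50, 1)
    panel <- make_panel(matrix(rbinom(nc * L, 1, runif(1, 0.2, 0.8)),
                               nrow = nc))
    core <- sort(sample(seq_len(L), 2))
    core_idx <- core[1]:core[2]
    carriers <- sample(seq_len(nc), sample(3:nc, 1))
    dir <- sample(c("downstream", "upstream"), 1)
    x <- sample(panel$sites$pos_bp, 1)
    if (dir == "downstream") x <- max(x, panel$sites$pos_bp[core[2]])
    else x <- min(x, panel$sites$pos_bp[core[1]])
    expect_identical(ehh(panel, carriers, core_idx, dir, x),
                     brute_ehh(panel, carriers, core_idx, dir, x))
  }
})

test_that("EHH curves are non-increasing and start below 1", {
  set.seed(8)
  res <- gen_sweep_panel(sweep_sim_config(n_sites = 300, region_bp = 1e6,
                                          deme_size_N = 200,
                                          n_generations = 50,
                                          sample_per_deme = 60, seed = 21))
  panel <- res$panel
  cores <- enumerate_core_haplotypes(panel, 148:152, pop = "D1")
  cr <- cores$haps[[1]]$carrier_rows
  for (dir in c("downstream", "upstream")) {
    curve <- ehh_curve(panel, cr, 148:152, dir, res$map)
    expect_true(all(diff(curve$ehh) <= 1e-12))
    expect_true(all(curve$ehh >= 0 & curve$ehh <= 1))
  }
})

test_that("REHH matches hand combinatorics in both pooling conventions", {
  # target: 6 carriers partitioned (3,2,1) -> ehh 4/15
  # others: cores of 4 carriers each, partitions (4) and (2,2)
  H <- cbind(
    c(rep(1L, 6), rep(0L, 8)),                                  # core site
    c(rep(0L, 6), rep(1L, 4), rep(0L, 4)),                      # core site 2
    c(0L,0L,0L,1L,1L,0L,  0L,0L,0L,0L,  0L,0L,1L,1L),           # flank 1
    c(0L,0L,0L,0L,0L,1L,  0L,0L,0L,0L,  0L,0L,0L,0L))           # flank 2
  panel <- make_panel(H)
  cores <- enumerate_core_haplotypes(panel, 1:2, min_freq = 0)
  freqs <- vapply(cores$haps, `[[`, numeric(1), "frequency")
  tgt <- which(abs(freqs - 6 / 14) < 1e-9)
  map <- genetic_map(c(1, 10000), c(0, 0.01))
  # evaluation boundary: first marker >= 0.002 cM beyond the core edge at
  # site 2 (1000 bp = 0.001 cM here), i.e. site 4 -> flank = sites 3 and 4
  # within-core pooling: (6 + 2) / (6 + 6) = 2/3; rehh = (4/15)/(2/3) = 0.4
  r_wc <- rehh(panel, cores, tgt, "downstream", distance_cM = 0.002,
               map = map, others = "within-core")
  expect_equal(r_wc$ehh_target, 4 / 15)
  expect_equal(r_wc$ehh_others, 2 / 3)
  expect_equal(r_wc$rehh, 0.4)
  # combined pooling: same numerator, denominator C(8,2) = 28
  r_cb <- rehh(panel, cores, tgt, "downstream", distance_cM = 0.002,
               map = map, others = "combined")
  expect_equal(r_cb$ehh_others, 8 / 28)
  expect_equal(r_cb$rehh, (4 / 15) / (8 / 28))
  # identical decay on target and others -> rehh 1 (within-core convention)
  Hsame <- cbind(c(rep(1L, 4), rep(0L, 4)), rep(0L, 8),
                 c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L))
  pn <- make_panel(Hsame)
  cs <- enumerate_core_haplotypes(pn, 1:2, min_freq = 0)
  expect_equal(rehh(pn, cs, 1, "downstream", 0.001, map,
                    others = "within-core")$rehh, 1.0)
})

test_that("REHH boundary is the first marker at the target genetic distance", {
  # 1 cM/Mb map: 0.25 cM = 250 kb
  set.seed(17)
  H <- matrix(rbinom(20 * 50, 1, 0.5), nrow = 20)
  panel <- make_panel(H, pos = seq(1, 981000, by = 20000))
  map <- genetic_map(c(1, 1e6), c(0, 1))
  cores <- enumerate_core_haplotypes(panel, 10:12, min_freq = 0)
  r <- rehh(panel, cores, 1, "downstream", 0.25, map)
  edge <- panel$sites$pos_bp[12]
  cand <- panel$sites$pos_bp[panel$sites$pos_bp > edge &
                               (panel$sites$pos_bp - edge) / 1e6 >= 0.25]
  expect_equal(r$x_bp, min(cand))
})

test_that("scan assigns frequency bins, flags and tie percentiles", {
  # frequency 0.406 falls in bin 8 ([0.40, 0.45)); 1.0 in the top bin
  expect_equal(min(floor(0.406 / 0.05), 19), 8)
  expect_equal(min(floor(1.0 / 0.05), 19), 19)
  res <- gen_sweep_panel(sweep_sim_config(n_sites = 500, region_bp = 2e6,
                                          deme_size_N = 300,
                                          n_generations = 60,
                                          sample_per_deme = 80, seed = 33))
  blocks <- gabriel_blocks(res$panel, pop = "D1", max_span_sites = 20)
  sc <- rehh_scan(res$panel, pop = "D1", map = res$map, blocks = blocks)
  expect_true(nrow(sc) > 0)
  expect_true(all(sc$freq_bin %in% 0:19))
  expect_equal(sc$freq_bin, pmin(floor(sc$frequency / 0.05), 19))
  ok <- !is.na(sc$percentile)
  expect_true(all(sc$percentile[ok] >= 0 & sc$percentile[ok] <= 100))
  expect_equal(sc$significant[ok], sc$percentile[ok] >= 95)
  # within a bin where all records tie, every percentile is 50
  lr <- log(sc$rehh)
  for (b in unique(sc$freq_bin[ok])) {
    v <- lr[ok & sc$freq_bin == b]
    if (length(unique(v)) == 1)
      expect_true(all(sc$percentile[ok & sc$freq_bin == b] == 50))
  }
  # a planted top value in a 100-record bin lands at 99.5 (midrank, self tie)
  vals <- c(rnorm(99), 50)
  expect_equal(empirical_percentile(50, vals), 99.5)
})
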