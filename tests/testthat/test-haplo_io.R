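test_that("phased VCF loads into a panel with correct counts", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  gt <- matrix(c("0|1", "1|1", "0|0",
                 "0|0", "0|1", "1|0",
                 "1|1", "0|0", "0|1",
                 "0|1", "0|1", "0|0",
                 "1|0", "0|0", "1|1"), nrow = 5, byrow = TRUE)
  write_test_vcf(vcf, pos = c(100, 200, 300, 400, 500),
                 ref = rep("A", 5), alt = rep("G", 5), gt = gt)
  panel <- load_panel(vcf, "phased-vcf", test_pop_map(3))
  expect_equal(n_chromosomes(panel), 6L)
  expect_equal(n_sites(panel), 5L)
  expect_equal(panel$haplotypes[, 1], c(0L, 1L, 1L, 1L, 0L, 0L))
  expect_equal(panel$pop_labels, rep("POP1", 6))
})

test_that("unphased genotype is a format error naming the site", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  gt <- matrix(c("0|1", "1|1", "0|0",
                 "0/1", "0|1", "1|0"), nrow = 2, byrow = TRUE)
  write_test_vcf(vcf, pos = c(100, 200), ref = c("A", "C"),
                 alt = c("G", "T"), gt = gt)
  expect_error(load_panel(vcf, "phased-vcf", test_pop_map(3)), "rs2")
})

test_that("multiallelic sites are excluded with a warning, not an error", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  gt <- matrix("0|1", nrow = 5, ncol = 3)
  gt[3, 1] <- "1|2"
  write_test_vcf(vcf, pos = 1:5 * 100, ref = rep("A", 5),
                 alt = c("G", "G", "G,T", "G", "G"), gt = gt)
  expect_warning(panel <- load_panel(vcf, "phased-vcf", test_pop_map(3)),
                 "multiallelic")
  expect_equal(n_sites(panel), 4L)
  rep <- attr(panel, "load_report")
  expect_equal(rep$n_multiallelic, 1L)
  expect_true("rs3" %in% rep$excluded_sites)
})

test_that("individual absent from pop_map is a labelling error", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  gt <- matrix("0|1", nrow = 2, ncol = 3)
  write_test_vcf(vcf, pos = c(100, 200), ref = rep("A", 2),
                 alt = rep("G", 2), gt = gt)
  expect_error(load_panel(vcf, "phased-vcf", test_pop_map(2)), "IND3")
})

test_that("panel round-trips exactly through all three formats", {
  set.seed(42)
  H <- matrix(rbinom(20 * 30, 1, 0.4), nrow = 20)
  panel <- make_panel(H, pops = rep(c("CEU", "YRI"), each = 10))
  pm <- stats::setNames(panel$pop_labels[seq(1, 19, 2)], panel$sample_ids)
  for (fmt in c("phased-vcf", "impute-hls", "tsv")) {
    f <- file.path(withr::local_tempdir(),
                   paste0("p.", if (fmt == "impute-hls") "hap" else "x"))
    write_panel(panel, f, fmt)
    back <- load_panel(f, fmt, pm)
    expect_equal(back$haplotypes, panel$haplotypes, ignore_attr = TRUE)
    expect_equal(back$sites$site_id, panel$sites$site_id)
    expect_equal(back$sites$pos_bp, panel$sites$pos_bp)
    expect_equal(back$pop_labels, panel$pop_labels)
  }
})

test_that("genetic map loads, validates monotonicity and interpolates", {
  f <- withr::local_tempfile()
  writeLines(c("position rate cM", "1 1.0 0.0", "1000001 1.0 1.0"), f)
  map <- load_genetic_map(f)
  expect_length(map$pos_bp, 2)
  expect_equal(interpolate_cM(map, 1), 0)
  expect_equal(interpolate_cM(map, 500001), 0.5)
  # constant 1 cM/Mb: 250 kb offset = 0.25 cM
  expect_equal(interpolate_cM(map, 250001), 0.25)
  # extrapolation continues the terminal rate
  expect_equal(interpolate_cM(map, 2000001), 2.0)

  bad <- withr::local_tempfile()
  writeLines(c("1 1.0 1.0", "1000 1.0 0.5"), bad)
  expect_error(load_genetic_map(bad), "line 2")

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  expect_error(load_genetic_map(empty), "no map points")
})

test_that("interpolate_cM is non-decreasing in position for random maps", {
  set.seed(7)
  for (i in 1:20) {
    np <- sample(2:10, 1)
    map <- genetic_map(sort(sample.int(1e6, np)), cumsum(runif(np, 0, 0.5)))
    x <- sort(sample.int(1.2e6, 100))
    expect_true(all(diff(interpolate_cM(map, x)) >= -1e-12))
  }
})

test_that("subset_panel respects half-open regions and population sets", {
  set.seed(5)
  H <- matrix(rbinom(40 * 10, 1, 0.5), nrow = 40)
  panel <- make_panel(H, pops = rep(c("CEU", "YRI"), each = 20),
                      pos = 1:10 * 1000L)
  full <- subset_panel(panel)
  expect_equal(full$haplotypes, panel$haplotypes)
  none <- subset_panel(panel, start_bp = 100000, end_bp = 200000)
  expect_equal(n_sites(none), 0L)
  expect_equal(n_chromosomes(none), 40L)
  ceu <- subset_panel(panel, pops = "CEU")
  expect_equal(n_chromosomes(ceu), 20L)
  # half-open: end excluded
  sub <- subset_panel(panel, start_bp = 2000, end_bp = 5000)
  expect_equal(sub$sites$pos_bp, c(2000L, 3000L, 4000L))
  expect_error(subset_panel(panel, pops = "NOPE"), "NOPE")
  expect_error(subset_panel(panel, start_bp = 10, end_bp = 10), "malformed")
})

test_that("panel invariants are enforced at construction", {
  H <- matrix(0:1, nrow = 2, ncol = 4)
  sites <- data.frame(site_id = paste0("s", 1:4), chrom = "1",
                      pos_bp = c(1, 2, 2, 3), allele0 = "A", allele1 = "G")
  expect_error(haplotype_panel(sites, H, "i1", c("P", "P")),
               "strictly increasing")
  sites$pos_bp <- 1:4
  H2 <- H; H2[1, 2] <- 5L
  expect_error(haplotype_panel(sites, H2, "i1", c("P", "P")), "outside")
  expect_error(haplotype_panel(sites, rbind(H, 0L), c("i1"), rep("P", 3)),
               "2 x individuals")
})
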