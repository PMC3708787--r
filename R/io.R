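#' Load a phased haplotype panel from disk
#'
#' Reads phased biallelic haplotypes from one of three formats and attaches a
#' population label to every chromosome. Sites are returned sorted by
#' position; multiallelic sites and sites with missing genotypes are dropped
#' (and counted in the load report); an *unphased* genotype is a hard format
#' error, because haplotype identity is meaningless on unphased data.
#'
#' @param path file path. For `format = "impute-hls"` this is the `.hap` file
#'   (or the common prefix); `.legend` and `.sample` are found next to it.
#' @param format one of `"phased-vcf"`, `"impute-hls"`, `"tsv"`.
#' @param pop_map individual-to-population assignment: a named character
#'   vector (`names` = sample ids), a two-column data.frame
#'   (`sample_id`, `pop`), or a path to a two-column TSV. Every individual in
#'   the file must be present.
#' @return a [haplotype_panel()] with attribute `"load_report"`: a list with
#'   counts `n_multiallelic`, `n_missing_dropped` and the ids of excluded
#'   sites.
#' @export
load_panel <- function(path, format = c("phased-vcf", "impute-hls", "tsv"),
                       pop_map) {
  format <- match.arg(format)
  pm <- normalize_pop_map(pop_map)
  out <- switch(format,
    "phased-vcf" = read_phased_vcf(path),
    "impute-hls" = read_impute_hls(path),
    "tsv"        = read_tsv_panel(path))
  samples <- out$sample_ids
  absent <- setdiff(samples, names(pm))
  if (length(absent))
    stop("individual(s) absent from pop_map: ", paste(absent, collapse = ", "))
  pop_labels <- rep(unname(pm[samples]), each = 2L)
  ord <- order(out$sites$chrom, out$sites$pos_bp)
  panel <- haplotype_panel(out$sites[ord, , drop = FALSE],
                           out$haplotypes[, ord, drop = FALSE],
                           samples, pop_labels)
  attr(panel, "load_report") <- out$report
  panel
}

normalize_pop_map <- function(pop_map) {
  if (is.character(pop_map) && length(pop_map) == 1L && file.exists(pop_map)) {
    tab <- utils::read.table(pop_map, header = FALSE, stringsAsFactors = FALSE)
    pop_map <- stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
  }
  if (is.data.frame(pop_map))
    pop_map <- stats::setNames(as.character(pop_map[[2]]),
                               as.character(pop_map[[1]]))
  if (is.null(names(pop_map)) || any(names(pop_map) == ""))
    stop("pop_map must map sample ids to population codes")
  pop_map
}

read_phased_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(vcf@gt)[-1]))
  samples <- colnames(gt)
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  unphased <- apply(gt, 1L, function(g) any(grepl("/", g, fixed = TRUE)))
  if (any(unphased & !multi))
    stop("unphased genotype at site ", ids[which(unphased & !multi)[1]],
         ": phased VCF requires '|' separators")
  missing_gt <- apply(gt, 1L, function(g) any(is.na(g) | grepl(".", g,
                                                               fixed = TRUE)))
  keep <- !multi & !missing_gt
  if (any(multi))
    warning(sum(multi), " multiallelic site(s) excluded: ",
            paste(ids[multi], collapse = ", "))
  report <- list(n_multiallelic = sum(multi),
                 n_missing_dropped = sum(missing_gt & !multi),
                 excluded_sites = ids[!keep])
  if (!any(keep))
    return(list(sites = empty_sites(), haplotypes = empty_haps(samples),
                sample_ids = samples, report = report))
  gt <- gt[keep, , drop = FALSE]
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  H <- matrix(0L, nrow = 2L * length(samples), ncol = nrow(gt))
  H[seq(1L, nrow(H), 2L), ] <- t(matrix(as.integer(a1), nrow = nrow(gt)))
  H[seq(2L, nrow(H), 2L), ] <- t(matrix(as.integer(a2), nrow = nrow(gt)))
  sites <- data.frame(site_id = ids[keep], chrom = fix[keep, "CHROM"],
                      pos_bp = as.integer(fix[keep, "POS"]),
                      allele0 = fix[keep, "REF"], allele1 = fix[keep, "ALT"],
                      stringsAsFactors = FALSE)
  list(sites = sites, haplotypes = H, sample_ids = samples, report = report)
}

empty_sites <- function()
  data.frame(site_id = character(), chrom = character(), pos_bp = integer(),
             allele0 = character(), allele1 = character(),
             stringsAsFactors = FALSE)
empty_haps <- function(samples) matrix(integer(), nrow = 2L * length(samples),
                                       ncol = 0L)

impute_paths <- function(path) {
  prefix <- sub("\\.hap$", "", path)
  list(hap = paste0(prefix, ".hap"), legend = paste0(prefix, ".legend"),
       sample = paste0(prefix, ".sample"))
}

read_impute_hls <- function(path) {
  p <- impute_paths(path)
  for (f in unlist(p)) if (!file.exists(f)) stop("missing file: ", f)
  legend <- utils::read.table(p$legend, header = TRUE,
                              stringsAsFactors = FALSE)
  names(legend)[1:4] <- c("site_id", "pos_bp", "allele0", "allele1")
  samples <- utils::read.table(p$sample, header = TRUE,
                               stringsAsFactors = FALSE)[[1]]
  hap <- as.matrix(utils::read.table(p$hap, header = FALSE))
  if (nrow(hap) != nrow(legend))
    stop(".hap rows (", nrow(hap), ") != .legend sites (", nrow(legend), ")")
  if (ncol(hap) != 2L * length(samples))
    stop(".hap columns must be 2 x samples")
  chrom <- if ("chrom" %in% names(legend)) legend$chrom else
    attr_or(legend, "chrom", "1")
  missing_gt <- apply(hap, 1L, function(g) any(is.na(g) | !(g %in% 0:1)))
  report <- list(n_multiallelic = 0L, n_missing_dropped = sum(missing_gt),
                 excluded_sites = legend$site_id[missing_gt])
  keep <- !missing_gt
  sites <- data.frame(site_id = legend$site_id[keep], chrom = chrom,
                      pos_bp = as.integer(legend$pos_bp[keep]),
                      allele0 = as.character(legend$allele0[keep]),
                      allele1 = as.character(legend$allele1[keep]),
                      stringsAsFactors = FALSE)
  list(sites = sites, haplotypes = t(hap[keep, , drop = FALSE]),
       sample_ids = samples, report = report)
}

attr_or <- function(x, name, default) {
  v <- attr(x, name)
  if (is.null(v)) default else v
}

read_tsv_panel <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("site_id", "chrom", "pos", "allele0", "allele1")
  if (!all(meta %in% names(tab)))
    stop("tsv panel must have header columns: ", paste(meta, collapse = " "))
  hap_cols <- setdiff(names(tab), meta)
  samples <- unique(sub("_[AB]$", "", hap_cols))
  expect <- as.vector(rbind(paste0(samples, "_A"), paste0(samples, "_B")))
  if (!setequal(hap_cols, expect))
    stop("tsv haplotype columns must come in sampleID_A/sampleID_B pairs")
  H0 <- as.matrix(tab[, expect, drop = FALSE])
  missing_gt <- apply(H0, 1L, function(g) any(is.na(g) | !(g %in% 0:1)))
  report <- list(n_multiallelic = 0L, n_missing_dropped = sum(missing_gt),
                 excluded_sites = tab$site_id[missing_gt])
  keep <- !missing_gt
  sites <- data.frame(site_id = as.character(tab$site_id[keep]),
                      chrom = as.character(tab$chrom[keep]),
                      pos_bp = as.integer(tab$pos[keep]),
                      allele0 = as.character(tab$allele0[keep]),
                      allele1 = as.character(tab$allele1[keep]),
                      stringsAsFactors = FALSE)
  list(sites = sites, haplotypes = t(H0[keep, , drop = FALSE]),
       sample_ids = samples, report = report)
}

#' Write a haplotype panel to disk
#'
#' Inverse of [load_panel()]: emits the panel in one of the supported
#' formats. A panel written and re-loaded reproduces the allele matrix, site
#' order and population labels exactly.
#'
#' @param panel a [haplotype_panel()]
#' @param path output file (for `impute-hls`, the `.hap` path or prefix)
#' @param format one of `"phased-vcf"`, `"impute-hls"`, `"tsv"`
#' @return `path`, invisibly
#' @export
write_panel <- function(panel, path,
                        format = c("phased-vcf", "impute-hls", "tsv")) {
  format <- match.arg(format)
  switch(format,
    "phased-vcf" = write_phased_vcf(panel, path),
    "impute-hls" = write_impute_hls(panel, path),
    "tsv"        = write_tsv_panel(panel, path))
  invisible(path)
}

write_phased_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$sample_ids), collapse = "\t")),
             con)
  if (!nrow(panel$sites)) return(invisible(path))
  H <- panel$haplotypes
  odd <- seq(1L, nrow(H), 2L)
  gts <- matrix(paste0(t(H[odd, , drop = FALSE]), "|",
                       t(H[odd + 1L, , drop = FALSE])),
                nrow = ncol(H))
  lines <- paste(panel$sites$chrom, panel$sites$pos_bp, panel$sites$site_id,
                 panel$sites$allele0, panel$sites$allele1, ".", "PASS", ".",
                 "GT", apply(gts, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

write_impute_hls <- function(panel, path) {
  p <- impute_paths(path)
  utils::write.table(t(panel$haplotypes), p$hap, quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  leg <- data.frame(id = panel$sites$site_id, position = panel$sites$pos_bp,
                    allele0 = panel$sites$allele0,
                    allele1 = panel$sites$allele1,
                    chrom = panel$sites$chrom, stringsAsFactors = FALSE)
  utils::write.table(leg, p$legend, quote = FALSE, row.names = FALSE,
                     sep = " ")
  utils::write.table(data.frame(sample_id = panel$sample_ids), p$sample,
                     quote = FALSE, row.names = FALSE, sep = " ")
  invisible(path)
}

write_tsv_panel <- function(panel, path) {
  cols <- as.vector(rbind(paste0(panel$sample_ids, "_A"),
                          paste0(panel$sample_ids, "_B")))
  tab <- data.frame(site_id = panel$sites$site_id, chrom = panel$sites$chrom,
                    pos = panel$sites$pos_bp, allele0 = panel$sites$allele0,
                    allele1 = panel$sites$allele1, stringsAsFactors = FALSE)
  tab <- cbind(tab, stats::setNames(as.data.frame(t(panel$haplotypes)), cols))
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
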