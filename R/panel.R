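#' Construct a phased haplotype panel
#'
#' The central container of the package: a matrix of phased biallelic
#' haplotypes (one row per chromosome, two rows per individual) together with
#' per-site metadata and a population label for every chromosome. All
#' downstream statistics (allele frequencies, F_ST, LD, EHH) consume this
#' object.
#'
#' @param sites data.frame with columns `site_id`, `chrom`, `pos_bp`,
#'   `allele0`, `allele1` (and optionally `map_cM`), one row per variant,
#'   sorted by `(chrom, pos_bp)` with strictly increasing positions within a
#'   chromosome.
#' @param haplotypes integer matrix of 0/1 allele indices, one row per
#'   chromosome, one column per site; no missing values.
#' @param sample_ids character vector of individual identifiers; row `2i-1`
#'   and `2i` of `haplotypes` are the two chromosomes of individual `i`.
#' @param pop_labels character vector of population codes, one per chromosome
#'   row (both chromosomes of an individual carry the same code).
#' @return An object of class `haplotype_panel`: a list with elements
#'   `sites`, `haplotypes`, `sample_ids`, `pop_labels`.
#' @export
haplotype_panel <- function(sites, haplotypes, sample_ids, pop_labels) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  req <- c("site_id", "chrom", "pos_bp", "allele0", "allele1")
  missing_cols <- setdiff(req, names(sites))
  if (length(missing_cols))
    stop("sites is missing column(s): ", paste(missing_cols, collapse = ", "))
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  panel <- structure(
    list(sites = sites, haplotypes = haplotypes,
         sample_ids = as.character(sample_ids),
         pop_labels = as.character(pop_labels)),
    class = "haplotype_panel")
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  sites <- panel$sites
  H <- panel$haplotypes
  if (nrow(sites) != ncol(H))
    stop("number of site rows (", nrow(sites), ") != haplotype columns (",
         ncol(H), ")")
  if (nrow(H) != 2L * length(panel$sample_ids))
    stop("chromosome rows (", nrow(H), ") must be 2 x individuals (",
         length(panel$sample_ids), "): only paired chromosomes are supported")
  if (length(panel$pop_labels) != nrow(H))
    stop("pop_labels must have one entry per chromosome row")
  if (nrow(sites)) {
    if (any(sites$pos_bp < 1)) stop("pos_bp must be >= 1")
    if (any(sites$allele0 == sites$allele1))
      stop("allele0 == allele1 at site ",
           sites$site_id[which(sites$allele0 == sites$allele1)[1]])
    ord_ok <- unlist(lapply(split(sites$pos_bp, factor(sites$chrom,
                                                       unique(sites$chrom))),
                            function(p) length(p) < 2 || all(diff(p) > 0)))
    if (!all(ord_ok))
      stop("pos_bp must be strictly increasing within each chromosome")
    bad <- !(H %in% c(0L, 1L))
    if (any(bad))
      stop("haplotype matrix contains entries outside {0,1} (or NA)")
  }
  invisible(panel)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  pops <- table(x$pop_labels) / 2L
  cat("haplotype_panel:", nrow(x$haplotypes), "chromosomes (",
      length(x$sample_ids), "individuals ),", nrow(x$sites), "sites\n")
  cat("  chromosome(s):", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  cat("  populations:",
      paste(sprintf("%s (%d)", names(pops), as.integer(pops)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Number of chromosome rows / sites in a panel
#' @param panel a `haplotype_panel`
#' @return integer count
#' @export
n_chromosomes <- function(panel) nrow(panel$haplotypes)

#' @rdname n_chromosomes
#' @export
n_sites <- function(panel) nrow(panel$sites)

#' Population codes present in a panel
#' @param panel a `haplotype_panel`
#' @return character vector of distinct codes
#' @export
panel_pops <- function(panel) unique(panel$pop_labels)

# chromosome row indices for a set of populations (errors on unknown codes)
pop_rows <- function(panel, pops) {
  if (is.null(pops)) return(seq_len(nrow(panel$haplotypes)))
  unknown <- setdiff(pops, unique(panel$pop_labels))
  if (length(unknown))
    stop("unknown population code(s): ", paste(unknown, collapse = ", "))
  which(panel$pop_labels %in% pops)
}

#' Subset a panel by genomic region and population
#'
#' @param panel a `haplotype_panel`
#' @param chrom chromosome label, or NULL for all
#' @param start_bp,end_bp half-open region `[start_bp, end_bp)`; NULL keeps
#'   all positions
#' @param pops character vector of population codes to keep; NULL keeps all
#' @return a `haplotype_panel`; may contain zero sites
#' @export
subset_panel <- function(panel, chrom = NULL, start_bp = NULL, end_bp = NULL,
                         pops = NULL) {
  if (!is.null(start_bp) && !is.null(end_bp) && start_bp >= end_bp)
    stop("malformed region: start_bp must be < end_bp")
  keep_site <- rep(TRUE, nrow(panel$sites))
  if (!is.null(chrom)) keep_site <- keep_site & panel$sites$chrom == chrom
  if (!is.null(start_bp)) keep_site <- keep_site & panel$sites$pos_bp >= start_bp
  if (!is.null(end_bp)) keep_site <- keep_site & panel$sites$pos_bp < end_bp
  rows <- pop_rows(panel, pops)
  ind <- unique((rows + 1L) %/% 2L)
  rows <- as.vector(rbind(2L * ind - 1L, 2L * ind))
  structure(
    list(sites = panel$sites[keep_site, , drop = FALSE],
         haplotypes = panel$haplotypes[rows, keep_site, drop = FALSE],
         sample_ids = panel$sample_ids[ind],
         pop_labels = panel$pop_labels[rows]),
    class = "haplotype_panel")
}
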