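#' Construct a genetic map
#'
#' A monotone piecewise-linear mapping from physical position (bp) to genetic
#' position (cM), used to evaluate EHH at a target genetic distance.
#'
#' @param pos_bp integer vector, strictly increasing physical positions
#' @param cM numeric vector, non-decreasing genetic positions
#' @param chrom chromosome label
#' @return object of class `genetic_map`
#' @export
genetic_map <- function(pos_bp, cM, chrom = "1") {
  if (length(pos_bp) != length(cM)) stop("pos_bp and cM lengths differ")
  if (!length(pos_bp)) stop("no map points")
  if (any(diff(pos_bp) <= 0)) stop("map pos_bp must be strictly increasing")
  if (any(diff(cM) < 0)) stop("map cM must be non-decreasing")
  structure(list(pos_bp = as.numeric(pos_bp), cM = as.numeric(cM),
                 chrom = chrom), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("genetic_map: chrom", x$chrom, "-", length(x$pos_bp), "points spanning",
      x$pos_bp[1], "-", x$pos_bp[length(x$pos_bp)], "bp /",
      round(x$cM[length(x$cM)] - x$cM[1], 4), "cM\n")
  invisible(x)
}

#' Load a HapMap-format recombination map
#'
#' Three whitespace/tab-separated columns: physical position (bp),
#' recombination rate (cM/Mb; read but not used beyond the file) and
#' cumulative genetic position (cM). A header line is detected and skipped.
#' Duplicate positions are collapsed to the last occurrence.
#'
#' @param path map file
#' @param chrom chromosome label to attach
#' @return a [genetic_map()]
#' @export
load_genetic_map <- function(path, chrom = "1") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no map points in ", path)
  first <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (any(is.na(suppressWarnings(as.numeric(first))))) lines <- lines[-1]
  if (!length(lines)) stop("no map points in ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad_ncol <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad_ncol))
    stop("map line ", bad_ncol[1], " has fewer than 3 columns")
  pos <- as.numeric(vapply(fields, `[`, "", 1L))
  cm <- as.numeric(vapply(fields, `[`, "", 3L))
  if (any(is.na(pos)) || any(is.na(cm)))
    stop("non-numeric map entry at line ",
         which(is.na(pos) | is.na(cm))[1])
  dec <- which(diff(cm) < 0 & diff(pos) != 0)
  if (length(dec))
    stop("cM column decreases at line ", dec[1] + 1L)
  keep <- !duplicated(pos, fromLast = TRUE)
  genetic_map(pos[keep], cm[keep], chrom = chrom)
}

#' Interpolate genetic position at physical positions
#'
#' Linear interpolation between map points; positions beyond the map ends are
#' extrapolated at the terminal interval's rate; exact at map points. With a
#' single map point the map is treated as a constant.
#'
#' @param map a [genetic_map()]
#' @param pos_bp numeric vector of physical positions
#' @return numeric vector of cM values (non-decreasing in `pos_bp`)
#' @export
interpolate_cM <- function(map, pos_bp) {
  xp <- map$pos_bp; yp <- map$cM
  n <- length(xp)
  if (n == 1L) return(rep(yp, length(pos_bp)))
  y <- stats::approx(xp, yp, xout = pos_bp, rule = 2)$y
  lo <- pos_bp < xp[1]
  hi <- pos_bp > xp[n]
  if (any(lo)) {
    r <- (yp[2] - yp[1]) / (xp[2] - xp[1])
    y[lo] <- yp[1] + r * (pos_bp[lo] - xp[1])
  }
  if (any(hi)) {
    r <- (yp[n] - yp[n - 1]) / (xp[n] - xp[n - 1])
    y[hi] <- yp[n] + r * (pos_bp[hi] - xp[n])
  }
  y
}
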