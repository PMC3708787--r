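#' Validate an analysis configuration
#'
#' Checks a YAML file (or an equivalent named list) describing a full
#' four-stage analysis. All problems are collected and reported together, not
#' fail-fast.
#'
#' Required fields: `panel` (path), `format` (`phased-vcf` / `impute-hls` /
#' `tsv`), `pop_map` (path), `out_dir`, `seed`. Optional: `map` (path;
#' required for the REHH stage), `candidate_sites` (character vector),
#' `populations` (codes to analyse; default all), `fdist` (list:
#' `n_replicates`, `n_demes`, `theta_mut`, `batch`), `blocks` (list:
#' `maf_min`, `max_span_sites`), `rehh` (list: `distance_cM`, `min_freq`),
#' `stages` (subset of `freqs`, `fdist`, `fst-pair`, `blocks`, `rehh-scan`).
#'
#' @param config path to a YAML file, or a named list
#' @return object of class `scan_config` when valid; otherwise an object of
#'   class `scan_config_errors` (character vector of messages)
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config))
      return(structure("config file does not exist", class = "scan_config_errors"))
    config <- yaml::read_yaml(config)
  }
  errs <- character(0)
  need <- function(field) {
    if (is.null(config[[field]])) {
      errs <<- c(errs, paste0("missing required field: ", field))
      FALSE
    } else TRUE
  }
  path_field <- function(field) {
    if (need(field) && !file.exists(config[[field]]))
      errs <<- c(errs, paste0(field, " path does not exist: ",
                              config[[field]]))
  }
  path_field("panel")
  path_field("pop_map")
  if (need("format") &&
      !config$format %in% c("phased-vcf", "impute-hls", "tsv"))
    errs <- c(errs, paste0("unknown format: ", config$format))
  need("out_dir")
  if (need("seed") && (!is.numeric(config$seed) ||
                       config$seed != round(config$seed)))
    errs <- c(errs, "seed must be an integer")
  if (!is.null(config$map) && !file.exists(config$map))
    errs <- c(errs, paste0("map path does not exist: ", config$map))
  defaults <- list(
    fdist = list(n_replicates = 5000, n_demes = 100, theta_mut = 0.05,
                 theta_spread = 10, batch = 2000),
    blocks = list(maf_min = 0.05, max_span_sites = 120),
    rehh = list(distance_cM = 0.25, min_freq = 0.05),
    stages = c("freqs", "fdist", "fst-pair", "blocks", "rehh-scan"),
    candidate_sites = NULL, populations = NULL, map = NULL)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in c("fdist", "blocks", "rehh"))
    for (sub in names(defaults[[nm]]))
      if (is.null(config[[nm]][[sub]]))
        config[[nm]][[sub]] <- defaults[[nm]][[sub]]
  if (config$rehh$distance_cM <= 0)
    errs <- c(errs, "rehh: distance_cM must be > 0")
  if (config$blocks$maf_min < 0 || config$blocks$maf_min >= 0.5)
    errs <- c(errs, "blocks: maf_min must be in [0, 0.5)")
  if (config$fdist$n_replicates < 500)
    errs <- c(errs, "fdist: n_replicates must be >= 500")
  bad_stage <- setdiff(config$stages, defaults$stages)
  if (length(bad_stage))
    errs <- c(errs, paste0("unknown stage(s): ",
                           paste(bad_stage, collapse = ", ")))
  if ("rehh-scan" %in% config$stages && is.null(config$map))
    errs <- c(errs, "rehh-scan stage requires a map")
  if (length(errs)) return(structure(errs, class = "scan_config_errors"))
  structure(config, class = "scan_config")
}

#' @export
print.scan_config_errors <- function(x, ...) {
  cat("invalid analysis config:\n")
  for (e in x) cat(" -", e, "\n")
  invisible(x)
}

stage_log <- function(con, stage, ...) {
  line <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), "\t", stage, "\t",
                 paste(..., collapse = " "))
  writeLines(line, con)
}

#' Run the full selection-scan analysis
#'
#' Executes, from one validated configuration: (1) per-population allele
#' frequencies at the candidate sites; (2) the FDIST F_ST-outlier test with
#' migration calibration and per-candidate classification; (3) pairwise
#' F_ST between all analysed population pairs at the candidate sites with
#' chromosome-wide empirical percentiles; (4) Gabriel haplotype blocks and
#' the REHH scan with frequency-binned percentiles, per population. Writes
#' one TSV per stage, a JSON summary and a run log into `out_dir`. Fully
#' deterministic for a fixed config and seed.
#'
#' @param config a `scan_config` from [validate_config()], or a path / list
#'   accepted by it
#' @return object of class `scan_report`: list of stage results plus
#'   `out_dir` and `files`
#' @export
run_analysis <- function(config) {
  if (!inherits(config, "scan_config")) {
    config <- validate_config(config)
    if (inherits(config, "scan_config_errors"))
      stop("invalid config:\n", paste(" -", unclass(config), collapse = "\n"))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(config$out_dir, "run.log"), "w")
  on.exit(close(logcon))
  set.seed(config$seed)
  stage_log(logcon, "start", "seed =", config$seed,
            "panel =", config$panel,
            "md5 =", unname(tools::md5sum(config$panel)))

  panel <- load_panel(config$panel, config$format, config$pop_map)
  pops <- if (is.null(config$populations)) panel_pops(panel) else
    config$populations
  cand <- config$candidate_sites
  if (is.null(cand)) cand <- panel$sites$site_id
  report <- list(config = config, out_dir = config$out_dir,
                 files = character(0))
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                       sep = "\t")
    report$files <<- c(report$files, path)
  }
  run_stage <- function(stage, expr) {
    stage_log(logcon, stage, "begin")
    res <- tryCatch(expr, error = function(e) {
      stage_log(logcon, stage, "FAILED:", conditionMessage(e))
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           " (partial outputs preserved in ", config$out_dir, ")",
           call. = FALSE)
    })
    stage_log(logcon, stage, "done")
    res
  }

  if ("freqs" %in% config$stages) {
    report$freqs <- run_stage("freqs",
      allele_freqs(panel, sites = cand, pops = pops))
    emit(report$freqs, "allele_freqs.tsv")
  }
  if ("fdist" %in% config$stages) {
    report$fdist <- run_stage("fdist", {
      ft <- fdist_test(panel, sites = cand, pops = pops,
                       n_demes_total = config$fdist$n_demes,
                       theta_mut = config$fdist$theta_mut,
                       theta_spread = config$fdist$theta_spread,
                       n_replicates = config$fdist$n_replicates,
                       seed = config$seed, batch = config$fdist$batch)
      stage_log(logcon, "fdist", "calibrated M =", signif(ft$calibration$M, 5),
                "achieved =", signif(ft$calibration$achieved, 5))
      ft
    })
    emit(report$fdist$results, "fdist_outliers.tsv")
    emit(report$fdist$envelope$quantile_curves, "fdist_envelope.tsv")
  }
  if ("fst-pair" %in% config$stages) {
    report$pairwise_fst <- run_stage("fst-pair",
      pairwise_fst(panel, sites = cand, pops = pops))
    emit(report$pairwise_fst, "pairwise_fst.tsv")
  }
  if (any(c("blocks", "rehh-scan") %in% config$stages)) {
    map <- if (!is.null(config$map)) load_genetic_map(config$map) else NULL
    report$blocks <- list(); report$rehh <- list()
    for (pp in pops) {
      blk <- run_stage(paste0("blocks[", pp, "]"),
        gabriel_blocks(panel, pop = pp, maf_min = config$blocks$maf_min,
                       max_span_sites = config$blocks$max_span_sites))
      report$blocks[[pp]] <- blk
      emit(blk, paste0("blocks_", pp, ".tsv"))
      if ("rehh-scan" %in% config$stages && nrow(blk)) {
        sc <- run_stage(paste0("rehh[", pp, "]"),
          rehh_scan(panel, pop = pp, map = map, blocks = blk,
                    distance_cM = config$rehh$distance_cM,
                    min_freq = config$rehh$min_freq))
        report$rehh[[pp]] <- sc
        emit(sc, paste0("rehh_scan_", pp, ".tsv"))
      }
    }
  }

  summ <- list(seed = config$seed,
               n_individuals = length(panel$sample_ids),
               n_sites = n_sites(panel), populations = pops,
               stages = config$stages,
               n_candidates = length(cand),
               fdist_M = if (!is.null(report$fdist))
                 report$fdist$calibration$M else NULL,
               n_blocks = if (length(report$blocks))
                 vapply(report$blocks, nrow, 1L) else NULL,
               files = basename(report$files))
  jsonlite::write_json(summ, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report$files <- c(report$files, file.path(config$out_dir, "summary.json"))
  stage_log(logcon, "end", "files =", length(report$files))
  class(report) <- "scan_report"
  report
}

#' @export
print.scan_report <- function(x, ...) {
  cat("scan_report: stages", paste(x$config$stages, collapse = ", "), "\n")
  cat("  outputs in", x$out_dir, ":\n")
  for (f in basename(x$files)) cat("   -", f, "\n")
  invisible(x)
}
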