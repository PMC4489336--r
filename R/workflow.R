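# Orchestration: configuration, the two study drivers (correlation-based
# and simulation-based), and a small command-line dispatcher.

#' Build a run configuration
#'
#' Either `vcf` + `pheno` (paths) or `synthetic` (a [cohort_spec()]) must
#' be supplied.  A saved config plus its seed reproduces every
#' deterministic stage bit-identically.
#'
#' @param vcf,pheno input file paths (real-data route).
#' @param synthetic a [cohort_spec()] (synthetic route).
#' @param maf_threshold MAF cutoff defining rare variants.
#' @param tests test statistics to run.
#' @param replicates null phenotype replicates for the simulation study.
#' @param section_series section counts (default derived from the test
#'   count).
#' @param band correlation half-bandwidth in windows.
#' @param weights_kind kernel weight scheme.
#' @param genome_length,region_length lengths in bp; their ratio is the
#'   extrapolation factor (defaults: 3.096e9 and the synthetic region's
#'   own length, i.e. ratio computed at run time).
#' @param seed master seed.
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(vcf = NULL, pheno = NULL, synthetic = NULL,
                       maf_threshold = 0.01,
                       tests = c("burden", "skat"),
                       replicates = 1000, section_series = NULL,
                       band = 1000, weights_kind = "beta_1_25",
                       genome_length = 3.096e9, region_length = NULL,
                       seed = 1L, out_dir = tempfile("winsig_run_")) {
  if (is.null(synthetic) && (is.null(vcf) || is.null(pheno)))
    stop_winsig("supply either a synthetic cohort_spec or vcf + pheno paths",
                "winsig_bad_argument")
  cfg <- structure(list(vcf = vcf, pheno = pheno, synthetic = synthetic,
                        maf_threshold = maf_threshold, tests = tests,
                        replicates = replicates,
                        section_series = section_series, band = band,
                        weights_kind = weights_kind,
                        genome_length = genome_length,
                        region_length = region_length,
                        seed = as.integer(seed), out_dir = out_dir),
                   class = "run_config")
  cfg$hash <- config_hash(cfg)
  cfg
}

config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg[setdiff(names(cfg), "hash")])),
             collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

load_cohort <- function(cfg) {
  if (!is.null(cfg$synthetic)) {
    spec <- cfg$synthetic
    spec$seed <- derive_seed(cfg$seed, "cohort_master")
    g <- sample_cohort(generate_founders(spec), spec)
  } else {
    g <- read_genotypes(cfg$vcf)
  }
  g
}

#' Correlation-based threshold study
#'
#' Builds the banded analytic correlation matrix per test kind, computes
#' eigenvalue-based effective-test estimates for nested region sizes, and
#' writes/returns the mean `-log10(0.05/m_e)` table.
#'
#' @param cfg a [run_config()]; `cfg$tests` may contain `"skat"` and/or
#'   `"burden"` (SKAT-O has no analytic correlation and is excluded).
#' @param sizes region sizes in windows (default powers of two up to the
#'   band cap).
#' @return data.frame (one row per kind x size) with the columns of
#'   [section_me_table()] plus `kind`; written to
#'   `<out_dir>/correlation_study.tsv`.
#' @export
run_correlation_study <- function(cfg, sizes = NULL) {
  t0 <- Sys.time()
  g <- load_cohort(cfg)
  part <- split_by_maf(g, cfg$maf_threshold)
  ws <- build_windows(length(part$rare_idx))
  kinds <- intersect(cfg$tests, c("skat", "burden"))
  if (length(kinds) == 0L)
    stop_winsig("no analytic-correlation test kinds in config",
                "winsig_bad_argument")
  band <- min(cfg$band, n_windows(ws) - 1)
  sizes <- sizes %||% 2^(2:floor(log2(min(n_windows(ws), 2000))))
  out <- do.call(rbind, lapply(kinds, function(k) {
    cb <- build_correlation_band(g, ws, part, kind = k,
                                 weights_kind = cfg$weights_kind,
                                 band = band)
    cbind(kind = k, section_me_table(cb, sizes))
  }))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(cfg$out_dir, "correlation_study.tsv")
  data.table::fwrite(cbind(out, config = cfg$hash), path, sep = "\t")
  write_run_log(cfg, "correlation_study", t0)
  out
}

#' Simulation-based threshold study
#'
#' The full pipeline: simulate null phenotypes, run the configured tests
#' across replicates, section, extract empirical 5th-percentile
#' thresholds, regress against the Bonferroni scale and extrapolate using
#' the genome/region length ratio.
#'
#' @param cfg a [run_config()].
#' @param test_class `"windows"`, `"single"`, or `"combined"`.
#' @return named list of `threshold_prediction`s, one per window-test
#'   statistic in `cfg$tests`; points and predictions are written under
#'   `cfg$out_dir`.
#' @export
run_simulation_study <- function(cfg, test_class = "windows") {
  t0 <- Sys.time()
  g <- load_cohort(cfg)
  part <- split_by_maf(g, cfg$maf_threshold)
  ws <- build_windows(length(part$rare_idx))
  pheno <- simulate_null_phenotypes(n_individuals(g), cfg$replicates,
                                    seed = derive_seed(cfg$seed, "pheno"))
  region_length <- cfg$region_length %||% diff(range(g$positions))
  r_ratio <- max(cfg$genome_length / region_length, 1)

  window_stats <- intersect(cfg$tests, c("burden", "skat", "skato"))
  need_single <- test_class %in% c("single", "combined")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  preds <- list()
  for (stat in window_stats) {
    store <- run_tests(g, part, ws, pheno,
                       tests = c(stat, if (need_single) "single"),
                       weights_kind = cfg$weights_kind)
    pred <- estimate_threshold(store, test_class = test_class,
                               section_series = cfg$section_series,
                               R_ratio = r_ratio)
    preds[[stat]] <- pred
    data.table::fwrite(cbind(pred$points, stat = stat, config = cfg$hash),
                       file.path(cfg$out_dir,
                                 sprintf("points_%s.tsv", stat)),
                       sep = "\t")
    jsonlite::write_json(
      c(pred[c("b0", "b1", "x_star", "y_star", "alpha_c",
               "m_e_genomewide", "R_ratio", "m_max")],
        list(stat = stat, config = cfg$hash, seed = cfg$seed)),
      file.path(cfg$out_dir, sprintf("prediction_%s.json", stat)),
      auto_unbox = TRUE, digits = NA)
  }
  write_run_log(cfg, "simulation_study", t0)
  preds
}

write_run_log <- function(cfg, stage, t0) {
  log_path <- file.path(cfg$out_dir, "run_log.tsv")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  line <- sprintf("%s\t%s\t%s\t%d\t%.2f", format(Sys.time()), stage,
                  cfg$hash, cfg$seed,
                  as.numeric(difftime(Sys.time(), t0, units = "secs")))
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
  invisible(log_path)
}

#' Command-line dispatcher
#'
#' Subcommands: `simulate-cohort`, `run-tests`, `null-correlations`,
#' `meff`, `estimate-threshold`, `report`.  Flags are `--key value` pairs
#' mirroring [run_config()] fields (flags win over a `--config` file
#' written by [write_cohort_spec()]).  Intended to be called from
#' `Rscript -e 'winsig::cli_main()'` or the installed
#' `exec/winsig` script.
#'
#' @param args character vector (default `commandArgs(TRUE)`).
#' @return exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(TRUE)) {
  if (length(args) == 0L) {
    cat("usage: winsig <simulate-cohort|run-tests|null-correlations|",
        "meff|estimate-threshold|report> [--key value ...]\n", sep = "")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- parse_cli_flags(args[-1])
  seed <- as.integer(opt$seed %||% 1)
  out_dir <- opt$out %||% "."
  spec <- if (!is.null(opt$config)) read_cohort_spec(opt$config)
          else cohort_spec(
            n_individuals = as.numeric(opt[["n"]] %||% 500),
            n_sites = as.numeric(opt[["sites"]] %||% 50000),
            seed = seed)
  maf <- as.numeric(opt[["maf-threshold"]] %||% 0.01)
  cfg <- run_config(vcf = opt$vcf, pheno = opt$pheno,
                    synthetic = if (is.null(opt$vcf)) spec,
                    maf_threshold = maf,
                    tests = strsplit(opt$test %||% "burden,skat", ",")[[1]],
                    replicates = as.numeric(opt$replicates %||% 1000),
                    band = as.numeric(opt$band %||% 1000),
                    weights_kind = opt$weights %||% "beta_1_25",
                    genome_length = as.numeric(opt[["genome-length"]] %||%
                                                 3.096e9),
                    region_length = if (!is.null(opt[["region-length"]]))
                      as.numeric(opt[["region-length"]]),
                    seed = seed, out_dir = out_dir)
  switch(cmd,
    "simulate-cohort" = {
      g <- load_cohort(cfg)
      write_cohort_vcf(g, file.path(out_dir, "cohort.vcf"))
      ph <- simulate_null_phenotypes(n_individuals(g), 1, seed = seed)
      write_phenotypes(ph, g$sample_ids, file.path(out_dir, "pheno.tsv"))
    },
    "run-tests" = {
      g <- load_cohort(cfg)
      part <- split_by_maf(g, maf)
      ws <- build_windows(length(part$rare_idx))
      ph <- simulate_null_phenotypes(n_individuals(g), cfg$replicates,
                                     seed = seed)
      store <- run_tests(g, part, ws, ph, tests = cfg$tests,
                         weights_kind = cfg$weights_kind)
      write_pvalue_store(store, file.path(out_dir, "pvalues.tsv"))
    },
    "null-correlations" = {
      g <- load_cohort(cfg)
      part <- split_by_maf(g, maf)
      ws <- build_windows(length(part$rare_idx))
      cb <- build_correlation_band(
        g, ws, part, kind = intersect(cfg$tests, c("skat", "burden"))[1],
        weights_kind = cfg$weights_kind,
        band = min(cfg$band, n_windows(ws) - 1))
      write_correlation_band(cb, file.path(out_dir, "correlations.tsv"))
    },
    "meff" = { run_correlation_study(cfg) },
    "estimate-threshold" = ,
    "report" = { run_simulation_study(cfg) },
    stop_winsig(sprintf("unknown subcommand '%s'", cmd),
                "winsig_bad_argument"))
  invisible(0L)
}

parse_cli_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop_winsig(sprintf("expected --flag, got '%s'", args[i]),
                  "winsig_bad_argument")
    key <- sub("^--", "", args[i])
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- args[i + 1]; i <- i + 2L
    }
  }
  out
}
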