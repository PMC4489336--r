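# Seedable synthetic cohorts: a founder haplotype panel with a rare-skewed
# allele-frequency spectrum, mosaic (Li-Stephens-style) haplotype copying to
# induce linkage disequilibrium that decays with inter-site distance, and
# i.i.d. standard-normal null phenotypes.
#
# The generator emulates the *statistical* features a window-based
# significance analysis depends on -- a MAF spectrum dominated by rare
# variants and banded inter-window correlation -- not demographic realism.

#' Specify a synthetic cohort
#'
#' Defaults describe the desk-scale stand-in for a sequenced chromosome:
#' 500 individuals x 50,000 sites and a per-site template switch rate of
#' 0.002 (LD correlation length of a few hundred sites).
#'
#' The founder frequency spectrum is a two-component mixture anchored on
#' the site-frequency fractions printed for deep WGS data (roughly 70% of
#' sites below frequency 0.005, ~73% below 0.01, ~80% below 0.05): with
#' probability `rare_mass` a frequency is drawn from a steep power law
#' `density ~ f^-a` on `[1/n_founder_haplotypes, rare_cutoff)` (the
#' singleton-dominated rare tail), otherwise from `density ~ 1/f` on
#' `[rare_cutoff, 0.5]` (the classical neutral shape for the common
#' range).  A single truncated power law cannot reproduce all three
#' printed fractions at a representable founder-panel resolution.
#'
#' @param n_individuals diploid sample size.
#' @param n_sites variant sites on the synthetic chromosome.
#' @param n_founder_haplotypes founder panel size (also sets the lowest
#'   representable founder frequency, `1/n_founder_haplotypes`).
#' @param copy_switch_rate per-site probability that a copied haplotype
#'   switches founder template; 1 gives independent sites, values near 0
#'   give intact founder haplotypes.
#' @param maf_spectrum_exponent exponent `a` of the rare-tail power law.
#' @param rare_cutoff frequency boundary between the two components.
#' @param rare_mass total spectrum mass below `rare_cutoff`.
#' @param mean_gap_bp mean base-pair gap between adjacent sites.
#' @param seed integer; fully determines all generator output.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_individuals = 500, n_sites = 50000,
                        n_founder_haplotypes = 400,
                        copy_switch_rate = 0.002,
                        maf_spectrum_exponent = 2.8,
                        rare_cutoff = 0.005, rare_mass = 0.70,
                        mean_gap_bp = 80, seed = 1L) {
  for (nm in c("n_individuals", "n_sites", "n_founder_haplotypes"))
    assert_scalar_count(get(nm), nm)
  if (copy_switch_rate <= 0 || copy_switch_rate > 1)
    stop_winsig("copy_switch_rate must be in (0, 1]", "winsig_bad_argument")
  if (maf_spectrum_exponent <= 0)
    stop_winsig("maf_spectrum_exponent must be positive",
                "winsig_bad_argument")
  if (rare_cutoff <= 0 || rare_cutoff >= 0.5 || rare_mass < 0 ||
      rare_mass > 1)
    stop_winsig("rare_cutoff must be in (0, 0.5), rare_mass in [0, 1]",
                "winsig_bad_argument")
  structure(list(n_individuals = n_individuals, n_sites = n_sites,
                 n_founder_haplotypes = n_founder_haplotypes,
                 copy_switch_rate = copy_switch_rate,
                 maf_spectrum_exponent = maf_spectrum_exponent,
                 rare_cutoff = rare_cutoff, rare_mass = rare_mass,
                 mean_gap_bp = mean_gap_bp, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Fraction of the configured frequency spectrum below a cutoff
#'
#' Closed-form CDF of the truncated power-law spectrum; used both for
#' inverse-CDF sampling and as the independent bookkeeping oracle for the
#' realised spectrum.
#'
#' @param spec a [cohort_spec()].
#' @param x frequency cutoff.
#' @return `P(f < x)` under the spectrum.
#' @export
spectrum_fraction_below <- function(spec, x) {
  comp <- spectrum_components(spec)
  vapply(x, function(xx) {
    xx <- pmin(pmax(xx, comp$lo), comp$hi)
    if (comp$degenerate) return(as.numeric(xx >= comp$hi))
    if (comp$rare_point) {
      # rare mass sits exactly at lo; it counts as below any x > lo
      if (xx <= comp$lo) 0
      else comp$w + (1 - comp$w) * powerlaw_cdf(xx, comp$lo, comp$hi, 1)
    } else if (xx < comp$cut) {
      comp$w * powerlaw_cdf(xx, comp$lo, comp$cut, comp$a)
    } else {
      comp$w + (1 - comp$w) * powerlaw_cdf(xx, comp$cut, comp$hi, 1)
    }
  }, numeric(1))
}

# Piecewise spectrum bookkeeping.  If the founder panel cannot represent
# frequencies below the cutoff, the rare mass concentrates at the lowest
# representable frequency (panel singletons).
spectrum_components <- function(spec) {
  lo <- 1 / spec$n_founder_haplotypes
  hi <- 0.5
  cut <- spec$rare_cutoff
  if (lo >= hi) return(list(lo = lo, hi = hi, degenerate = TRUE))
  list(lo = lo, hi = hi, cut = max(cut, lo), w = spec$rare_mass,
       a = spec$maf_spectrum_exponent, rare_point = (lo >= cut),
       degenerate = FALSE)
}

powerlaw_cdf <- function(x, lo, hi, a) {
  if (abs(a - 1) < 1e-12) {
    log(x / lo) / log(hi / lo)
  } else {
    (lo^(1 - a) - x^(1 - a)) / (lo^(1 - a) - hi^(1 - a))
  }
}

powerlaw_inv <- function(u, lo, hi, a) {
  if (abs(a - 1) < 1e-12) {
    lo * (hi / lo)^u
  } else {
    (lo^(1 - a) - u * (lo^(1 - a) - hi^(1 - a)))^(1 / (1 - a))
  }
}

spectrum_sample <- function(spec, n) {
  comp <- spectrum_components(spec)
  if (comp$degenerate) return(rep(comp$hi, n))
  rare <- runif(n) < comp$w
  out <- numeric(n)
  if (any(rare)) {
    out[rare] <- if (comp$rare_point) comp$lo
                 else powerlaw_inv(runif(sum(rare)), comp$lo, comp$cut,
                                   comp$a)
  }
  if (any(!rare))
    out[!rare] <- powerlaw_inv(runif(sum(!rare)), comp$cut, comp$hi, 1)
  out
}

#' Generate the founder haplotype panel
#'
#' Site `j` receives a target frequency drawn from the spectrum; the number
#' of carrier haplotypes is `max(1, floor(f * n_founder_haplotypes))`
#' (never zero, so no site is monomorphic in the panel), assigned to
#' founders uniformly at random.  Positions are 1-based and strictly
#' increasing with geometric-like random gaps.
#'
#' @param spec a [cohort_spec()].
#' @return list with `haplotypes` (0/1 integer matrix, founders x sites),
#'   `positions`, and `freq` (realised founder minor-allele frequency).
#' @export
generate_founders <- function(spec) {
  set.seed(derive_seed(spec$seed, "founders"))
  nf <- spec$n_founder_haplotypes
  m <- spec$n_sites
  f <- spectrum_sample(spec, m)
  carriers <- pmax(1L, as.integer(floor(f * nf)))
  H <- matrix(0L, nrow = nf, ncol = m)
  for (j in seq_len(m)) H[sample.int(nf, carriers[j]), j] <- 1L
  gaps <- 1 + rexp(m, rate = 1 / max(spec$mean_gap_bp - 1, 1))
  list(haplotypes = H,
       positions = cumsum(round(gaps)),
       freq = carriers / nf)
}

#' Sample a diploid cohort by mosaic haplotype copying
#'
#' Each of the `2 * n_individuals` haplotypes is a mosaic of founder
#' templates: at every site the copied template switches to a uniformly
#' chosen founder with probability `copy_switch_rate`, otherwise the
#' current template continues.  Short switch rates yield long shared
#' segments and hence LD decaying with distance.  The two haplotypes of an
#' individual are summed into dosages.
#'
#' @param founders result of [generate_founders()].
#' @param spec the same [cohort_spec()].
#' @param drop_monomorphic drop sites with no minor allele in the sample
#'   (default `TRUE`, mirroring real-data cleaning).
#' @return a [genotype_matrix()].
#' @export
sample_cohort <- function(founders, spec, drop_monomorphic = TRUE) {
  if (is.null(founders$haplotypes) || nrow(founders$haplotypes) == 0L)
    stop_winsig("empty founder panel", "winsig_bad_argument")
  set.seed(derive_seed(spec$seed, "cohort"))
  H <- founders$haplotypes
  nf <- nrow(H)
  m <- ncol(H)
  n <- spec$n_individuals
  site_idx <- seq_len(m)
  dos <- matrix(0L, nrow = n, ncol = m)
  for (i in seq_len(n)) {
    h <- integer(m)
    for (copy in 1:2) {
      seg <- cumsum(c(TRUE, runif(m - 1) < spec$copy_switch_rate))
      tpl <- sample.int(nf, max(seg), replace = TRUE)
      h <- h + H[cbind(tpl[seg], site_idx)]
    }
    dos[i, ] <- h
  }
  genotype_matrix(dos, founders$positions, chrom = "synth1",
                  sample_ids = sprintf("I%04d", seq_len(n)),
                  drop_monomorphic = drop_monomorphic)
}

#' Simulate null phenotypes
#'
#' Independent standard-normal trait values, independent of any genotype:
#' the null world in which family-wise error is measured.
#'
#' @param n individuals.
#' @param replicates number of independent phenotype sets.
#' @param seed integer seed.
#' @return object of class `phenotype_set`: list with `values`
#'   (`n x replicates` matrix) and `seed`.
#' @export
simulate_null_phenotypes <- function(n, replicates, seed = 1L) {
  n <- assert_scalar_count(n, "n")
  replicates <- assert_scalar_count(replicates, "replicates")
  set.seed(derive_seed(seed, "phenotypes"))
  structure(list(values = matrix(rnorm(n * replicates), nrow = n),
                 seed = as.integer(seed)),
            class = "phenotype_set")
}

#' Inject a genetic effect into phenotypes (power demonstrations)
#'
#' Off the main path: the significance-threshold pipeline is defined under
#' the null.  Adds `beta * dosage` for the selected variants.
#'
#' @param pheno a [simulate_null_phenotypes()] result.
#' @param g a [genotype_matrix()].
#' @param variant_idx columns of `g` given an effect.
#' @param beta per-allele effect size (recycled).
#' @return a modified `phenotype_set`.
#' @export
inject_effect <- function(pheno, g, variant_idx, beta) {
  shift <- g$dosages[, variant_idx, drop = FALSE] %*%
    rep_len(beta, length(variant_idx))
  pheno$values <- pheno$values + as.vector(shift)
  pheno
}

#' Write a synthetic cohort as VCF and phenotypes as TSV
#'
#' Emits a minimal VCF 4.2 with GT fields so synthetic and real data enter
#' the pipeline identically.  Dosages must be integral (pre-imputation).
#'
#' @param g a [genotype_matrix()] with integer dosages.
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(g, path) {
  d <- g$dosages
  if (any(abs(d - round(d)) > 0))
    stop_winsig("VCF writer requires integral dosages", "winsig_bad_argument")
  gt_code <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", g$chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", g$sample_ids), collapse = "\t"))
  gt <- matrix(gt_code[t(d) + 1L], nrow = ncol(d))  # variants x samples
  body <- do.call(paste, c(
    list(g$chrom, as.integer(g$positions), g$variant_ids, "A", "T", ".",
         "PASS", ".", "GT"),
    as.data.frame(gt, optional = TRUE),              # one column per sample
    list(sep = "\t")))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_cohort_vcf
#' @param pheno a `phenotype_set`.
#' @param sample_ids individual identifiers, in row order of
#'   `pheno$values`.
#' @export
write_phenotypes <- function(pheno, sample_ids, path) {
  v <- pheno$values
  df <- data.frame(sample_id = sample_ids, v)
  names(df)[-1] <- if (ncol(v) == 1L) "phenotype"
                   else paste0("phenotype_", seq_len(ncol(v)))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a phenotype TSV (`sample_id<TAB>phenotype[...]`)
#' @param path TSV path.
#' @return a `phenotype_set` with `sample_ids` attached.
#' @export
read_phenotypes <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  if (names(df)[1] != "sample_id")
    stop_winsig("phenotype table must start with a sample_id column",
                "winsig_io")
  structure(list(values = as.matrix(df[, -1, drop = FALSE]),
                 sample_ids = df$sample_id, seed = NA_integer_),
            class = "phenotype_set")
}

#' Round-trip a cohort spec through a YAML-style key/value config block
#' @param spec a [cohort_spec()].
#' @param path config file path.
#' @return `path` invisibly / a `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  writeLines(sprintf("%s: %s", names(unclass(spec)),
                     vapply(unclass(spec), format, character(1))), path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  kv <- read.dcf(textConnection(readLines(path)))
  args <- lapply(as.list(kv[1, ]), as.numeric)
  do.call(cohort_spec, args)
}
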