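# Shared fixtures and small oracles.  Everything is generated in code under
# fixed seeds; cohorts used by several test files are memoised per session.

.fixture_env <- new.env(parent = emptyenv())

cached_cohort <- function(key, spec) {
  if (!exists(key, envir = .fixture_env)) {
    g <- sample_cohort(generate_founders(spec), spec)
    assign(key, g, envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# mid-size cohort with visible LD, shared by correlation/workflow tests.
# n = 400 keeps the finite-sample correlation floor of SKAT quadratic
# forms (~ effective rank / n) small enough for banded matrices to stay
# near-PSD.
band_cohort <- function() {
  cached_cohort("band", cohort_spec(n_individuals = 400, n_sites = 6000,
                                    n_founder_haplotypes = 200,
                                    copy_switch_rate = 0.005, seed = 101))
}

# write a VCF fixture from raw lines (header supplied here)
write_vcf_fixture <- function(body_lines, samples = c("A", "B", "C")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body_lines), path)
  path
}

# Monte-Carlo standard error of a sample correlation via the influence
# function (delta method), valid for the heavy-tailed squared statistics
# used here where normal-theory SEs fail
mc_cor_se <- function(a, b) {
  r <- cor(a, b)
  u <- (a - mean(a)) / sd(a)
  v <- (b - mean(b)) / sd(b)
  inf <- u * v - (r / 2) * (u^2 + v^2)
  sd(inf) / sqrt(length(a))
}

# hand-built uniform-P store (independent tests), for pipeline oracles
uniform_store <- function(m, R, seed) {
  set.seed(seed)
  structure(list(p = matrix(runif(m * R), nrow = m),
                 kind = rep("window", m),
                 stat = rep("burden", m),
                 position = seq_len(m) * 1000,
                 test_id = paste0("t", seq_len(m)),
                 n_replicates = R),
            class = "pvalue_store")
}

# random correlation matrix from a low-rank factor model (always PSD)
random_factor_corr <- function(m, rank = 3) {
  L <- matrix(rnorm(m * rank), m)
  S <- tcrossprod(L) + diag(runif(m, 0.1, 1))
  stats::cov2cor(S)
}
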