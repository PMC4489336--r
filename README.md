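# winsig

Genome-wide significance thresholds for whole-genome sequencing (WGS)
association scans that mix single-marker tests of common variants with
overlapping sliding-window tests — burden, SKAT, SKAT-O — of rare
variants.

## Who this is for

Analysts planning or interpreting a WGS scan of a quantitative trait need
a per-test significance level `alpha_c` that keeps the family-wise error
rate (FWER) at `alpha` across *all* tests performed. The classical GWAS
threshold (5e-8) was derived for independent common variants; sliding
windows of rare variants overlap by construction and are linked by LD, so
the right correction uses the effective number of independent tests
`m_e <= m`:

    alpha_c = 1 - (1 - alpha)^(1/m_e)  ~  alpha / m_e

`winsig` estimates `m_e` two ways:

1. **Analytic correlations** between window statistics under the null —
   for SKAT, `corr(Q_i, Q_j) = tr(A_i A_j) / sqrt(tr(A_i^2) tr(A_j^2))`
   with `A_k = P K_k P`, `K_k = (G_k W)(G_k W)'`; for burden, the squared
   correlation of the projected allele-count scores — followed by
   eigenvalue-based estimators of `m_e` (Li & Ji; Li et al.).
2. **An empirical pipeline**: simulate null phenotypes, run every test per
   replicate, cut the chromosome into contiguous sections of equal test
   count, take the 5th percentile of per-section minimum P-values, average
   per section size, regress against the Bonferroni scale
   `-log10(0.05/m)`, and extrapolate the fit to the genome-equivalent test
   count (`R * m_max`, with `R` the genome/region length ratio).

A seedable synthetic-cohort generator (founder haplotypes with a
rare-skewed frequency spectrum, mosaic copying for distance-decaying LD,
null Gaussian phenotypes) makes every stage testable end to end without
controlled-access data.

## Worked example

```r
library(winsig)

spec <- cohort_spec(n_individuals = 500, n_sites = 12000, seed = 7)
g    <- sample_cohort(generate_founders(spec), spec)
part <- split_by_maf(g, 0.05)                 # rare: MAF < 0.05
ws   <- build_windows(length(part$rare_idx))  # 50-variant, half-overlap
ws
#> <window_set> 384 windows of 50 rare variants (step 25) over 9,624 ranks

ph    <- simulate_null_phenotypes(500, replicates = 1000, seed = 8)
store <- run_tests(g, part, ws, ph, tests = "burden")
pred  <- estimate_threshold(store, "windows", R_ratio = 15.6)
pred
#> <threshold_prediction> y = -0.0254 + 0.9911 x; alpha_c = 9.82e-06 (m_e = 5,093)
```

The fitted line relates the empirical `-log10` FWER-5% threshold (`y`) to
the Bonferroni scale `x = -log10(0.05/m)`; every point sits below the
line of equality because overlapping windows are correlated. Evaluated at
the genome-equivalent test count `15.6 * 384 = 5,990`, the predicted
threshold `alpha_c = 9.82e-06` is milder than the Bonferroni value
`0.05/5990 = 8.35e-06`, and the implied effective number of independent
tests is `0.05/alpha_c = 5,093`, about 85% of the actual count. At
chromosome scale the published analysis reports genome-wide `m_e` between
~0.6M and ~1.9M and thresholds between 2.5e-8 and 8e-8 depending on the
statistic and MAF cutoff.

Window counts reproduce the published tiling arithmetic exactly:

```r
n_windows(build_windows(1853923))   # rare variants at MAF < 0.01
#> [1] 74156
```

Analytic correlations and eigenvalue estimators:

```r
cb  <- build_correlation_band(g, ws, part, kind = "skat", band = 100)
tab <- section_me_table(cb, sizes = c(64, 128, 256))
sig <- significance_threshold(me_li_ji(spectrum_of(band_to_matrix(cb, 1:256)))$m_e)
```

## Command line

A thin CLI wraps the same functions:

```sh
Rscript -e 'winsig::cli_main()' simulate-cohort --n 500 --sites 50000 --seed 1 --out out/
Rscript -e 'winsig::cli_main()' estimate-threshold --maf-threshold 0.01 \
  --test burden,skat --replicates 1000 --seed 1 --out out/
```

See `?cli_main` for the subcommands (`simulate-cohort`, `run-tests`,
`null-correlations`, `meff`, `estimate-threshold`, `report`) and flags.

## Scope

Quantitative traits, diploid autosomal genotypes, intercept-only or
fixed-covariate null models. No binary-trait tests, kinship adjustment,
imputation-format (DS/GP) input, or confidence intervals on the
extrapolated threshold (the regression points share data and are not
independent). The methods vignette (`vignettes/winsig-methods.Rmd`)
documents model assumptions, conventions, numerical choices, and known
limitations.
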