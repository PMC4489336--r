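---
title: "Estimating genome-wide significance for window-based rare-variant scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genome-wide significance for window-based rare-variant scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(winsig)
```

## The problem

A whole-genome sequencing (WGS) association scan of a quantitative trait
typically combines two families of tests: single-marker linear-regression
tests (an $F_{1,N-2}$ test per common variant), and region-based tests of
rare variants — here, sliding windows of 50 rare variants with adjacent
windows overlapping by 25, analysed with a burden test, SKAT, or SKAT-O.
Overlapping windows share half their variants and nearby windows share
linkage disequilibrium (LD), so the tests are strongly dependent: a
Bonferroni correction on the raw test count $m$ overstates the multiplicity
burden. The quantity that matters is the *effective number of independent
tests* $m_e \le m$, which converts a family-wise error rate (FWER) target
$\alpha$ into a per-test level

$$\alpha_c = 1 - (1 - \alpha)^{1/m_e} \approx \alpha / m_e .$$

`winsig` estimates $m_e$ (and hence $\alpha_c$) for a window-based analytic
strategy by two complementary routes, and provides a seedable synthetic
cohort generator so the whole pipeline is testable without access to a
large sequenced cohort.

## Route 1: analytic null correlations and eigenvalue estimators

For a window with genotype submatrix $G$ (centred) and diagonal weight
matrix $W$, the SKAT statistic is the quadratic form $Q = e' K e$ with
$K = (GW)(GW)'$ and $e$ the null-model residuals. With $e \sim N(0,
\sigma^2 P)$, where $P = I - H$ is the residual projection of the null
design, the covariance of two Gaussian quadratic forms gives

$$\operatorname{corr}(Q_i, Q_j) =
  \frac{\operatorname{tr}(A_i A_j)}
       {\sqrt{\operatorname{tr}(A_i^2)\operatorname{tr}(A_j^2)}},
  \qquad A_k = P K_k P,$$

computable from genotypes alone. The burden statistic is the squared score
of the window allele-count sum $x$; for two windows the correlation of the
squared scores is the squared correlation of the underlying Gaussian
scores, $(x_i' P x_j)^2 / ((x_i' P x_i)(x_j' P x_j))$. SKAT-O has no
tractable analytic correlation and is handled only by the simulation
route. Both formulas are implemented in the $N \times k$ factor
representation ($Z = P\,GW$), so cost scales with window size rather than
$N^2$.

`build_correlation_band()` evaluates these for all window pairs within a
configurable half-bandwidth (default 1,000 windows — empirically,
correlations above 0.1 rarely extend further), `spectrum_of()` takes the
eigenvalues $\lambda_1 \ge \dots \ge \lambda_m$ of the band-completed
matrix, and two estimators convert the spectrum to $m_e$:

* Li & Ji: $m_e = \sum_i \big[ I(\lambda_i \ge 1) + (\lambda_i -
  \lfloor\lambda_i\rfloor) \big]$;
* Li et al.: $m_e = m - \sum_i I(\lambda_i > 1)(\lambda_i - 1)$, always
  at or below the former.

Matrix sizes are capped at 2,000 windows (dense eigendecompositions become
impractical beyond that); larger regions are chunked into consecutive
blocks and averaged (`section_me_table()`).

### A finite-sample caveat found during development

Two PSD quadratic forms in the *same* residual vector are never
uncorrelated: if $A_i$ and $A_j$ have effective rank $r$, random $r$-
dimensional subspaces of $\mathbb{R}^N$ overlap enough that
$\operatorname{corr}(Q_i, Q_j) \gtrsim r/N$ *regardless of genomic
distance*. We verified this floor agrees exactly between the analytic
formula and Monte Carlo. At $N \approx 2{,}400$ it is $\sim 0.02$ and
harmless; at a desk-scale $N = 150$ it reaches $\sim 0.2$, and zero-filling
outside a band then produces visible negative eigenvalues. Consequences
adopted here: small negative eigenvalues are clamped to zero with the
clamped mass recorded, the banded-PSD sanity check in the test suite runs
at $N = 400$ with a band wide enough that out-of-band entries are near the
floor, and burden bands (floor $\sim 1/N$) are essentially exact at any
scale.

## Route 2: simulate, section, take percentiles, regress, extrapolate

The empirical route mirrors how a study would calibrate its own threshold:

1. simulate null phenotypes $y \sim N(0, I)$, independent of genotypes
   (1,000 replicates at full scale; smaller counts in desk-scale tests,
   stated where used);
2. run all tests for every replicate (`run_tests()`), storing a tests
   $\times$ replicates matrix of P-values;
3. partition the chromosome's tests into $S$ contiguous sections of
   near-equal test count (`partition_sections()`; sizes differ by at most
   one — 74,156 window tests in 1,024 sections gives sizes 72/73);
4. per section and replicate, record the minimum P-value; the 5th
   percentile of the minima across replicates (nearest-rank convention)
   estimates the per-test level that controls FWER at 5% within that
   section (`empirical_alpha()`);
5. average $-\log_{10}$ thresholds over same-size sections into one point
   per section count, with the across-section SD (`aggregate_points()`);
6. regress $y$ (empirical $-\log_{10}$ threshold) on $x =
   -\log_{10}(0.05/m)$ by unweighted OLS and evaluate the fit at
   $x^* = -\log_{10}\!\big(0.05/(R\,m_{\max})\big)$, where $R$ is the
   genome-to-region length ratio (default genome length
   $3.096 \times 10^9$ bp; a 198 Mb chromosome gives $R = 15.6$). Then
   $\alpha_c = 10^{-y^*}$ and $m_e = 0.05/\alpha_c$
   (`extrapolate_genomewide()`).

Independent tests fall on the line of equality $y = x$; correlated tests
fall below it with slope near, but not above, one. No standard error is
attached to $\alpha_c$: the points are produced by repeatedly re-sectioning
the same data and are not independent, so only per-point SDs are reported.

### Conventions chosen where the procedure was underdetermined

* **Percentile rule.** Nearest rank, $k = \lceil 0.05R \rceil$, applied to
  the sorted minima. At 1,000 replicates the difference from interpolated
  percentiles is in the fourth digit.
* **Per-size averaging.** The nominal section size $m/S$ (not the mix of
  $\lfloor m/S \rfloor$ / $\lceil m/S \rceil$) defines the $x$ coordinate.
* **Section series.** Powers of two from the largest $S$ keeping roughly
  72 tests per section down to $S = 1$, scaled proportionally for small
  regions, with a floor of $S = 8$ so the regression always has enough
  points at smoke scale.
* **Combined strategy.** Sections are anchored on window tests;
  single-marker tests join the section whose window block genomically
  contains them, and the combined $x$ coordinate uses the combined test
  count under a uniform-density assumption.

## Test statistics and the quadratic-form tail

The burden test regresses the phenotype on the window allele-count sum
(the published description; the exact normalisation of the displayed
statistic is irrecoverable from the source, but constants cancel in both
correlations and P-values). SKAT's null law is a positive mixture of
$\chi^2_1$ variables with weights $\sigma^2 \cdot
\operatorname{eig}(PKP)$. `quad_form_pvalue()` inverts the characteristic
function (Imhof's integral) over phase-limited Gauss–Legendre panels with
a rolling truncation bound; a single eigenvalue short-circuits to the
exact chi-square, and if the truncation point is unreachable (pathological
eigenvalue spread) the Liu et al. moment-matching approximation is used
and recorded in the result. Accuracy is absolute ($\sim 10^{-6}$), not
relative in the deep tail. Eigenvalues below $10^{-10}$ of the largest are
discarded.

SKAT-O evaluates $Q_\rho = (1-\rho)Q_{\text{SKAT}} + \rho
Q_{\text{burden}}$ on the grid $\rho \in \{0, 0.01, 0.04, 0.09, 0.16,
0.25, 0.5, 1\}$ (the field's convention; the source is silent), takes the
minimum per-$\rho$ P-value, and converts it to an overall P-value by the
standard one-dimensional integral conditioning on the burden-direction
chi-square, with $\rho = 1$ capped at 0.999 inside the integrand and the
per-$\rho$ quantiles taken from a moment-matched approximation. The result
is clamped to the hard bounds $[\min_\rho p_\rho,\; n_\rho \min_\rho
p_\rho]$ of any minimum-P combination. Default variant weights are
$\mathrm{Beta}(\text{MAF}; 1, 25)$ density values; flat weights are
available for hand-checkable examples.

## The synthetic cohort

The generator is a stated world, not a tuning knob. Defaults: 500
individuals $\times$ 50,000 sites; a founder panel of 400 haplotypes whose
minor-allele frequency spectrum is a two-component mixture anchored on the
site-frequency fractions printed for deep WGS data ($\sim$70% of sites
below 0.005, $\sim$73% below 0.01, $\sim$80% below 0.05): mass 0.70
follows a steep power law $f^{-2.8}$ on $[1/400, 0.005)$ (the
singleton-dominated rare tail) and the rest follows the neutral $1/f$
shape on $[0.005, 0.5]$. A single truncated power law can match the first
anchor or the common-variant fraction, not both, and with essentially no
mass between the 0.01 and 0.05 cutoffs it erases the published
MAF-threshold ordering of inter-window correlation; mosaic
haplotype copying with a per-site template-switch probability of 0.002,
giving an LD correlation length of a few hundred sites (the banded
correlation structure of a sequenced chromosome, scaled down
proportionally); inter-site gaps averaging 80 bp (chromosome-like variant
density); and i.i.d. standard-normal phenotypes. One integer seed
determines everything; each stage derives its own stream.

What it does *not* emulate: demographic history, selection, mutation-age /
frequency correlation, genotyping error, or exact site counts of any real
cohort. A green end-to-end test therefore establishes that the *pipeline*
is calibrated (its thresholds control FWER on data with rare-skewed
spectra and decaying LD), not that any particular published threshold is
recovered — chromosome-scale thresholds depend on the original cohort's
genotypes, which are not redistributable.

One documented consequence: in real cohorts common variants are old and
carry far more pairwise LD than recent rare variants, which is why
re-windowing at a higher MAF cutoff increases inter-window correlation.
Mosaic copying assigns founder carriers independently at every site, so
LD has the same structure in every frequency class, and that ordering is
structurally absent at desk scale (differences $\sim 0.005$ with unstable
sign). The corresponding acceptance assertion is kept as specified and is
expected to fail on synthetic data; all other qualitative orderings
(SKAT vs burden stringency, combined vs window-only, estimator
dominance) reproduce.

## Numerical choices and degenerate inputs

* Missing genotypes are mean-imputed per variant at load time (preserves
  allele frequency; keeps kernels well-defined); dosage columns are
  flipped so entries always count the minor allele, making all results
  invariant to REF/ALT labelling.
* Monomorphic sites are excluded at load; multi-allelic VCF records are
  split into one bi-allelic column per alternate allele.
* Constant regressors (after projection), all-zero kernels, empty regions
  and empty spectra raise typed errors rather than returning silent
  defaults.
* Analytic correlations are clamped to $[0, 1]$ with a $10^{-8}$ tolerance
  for floating-point noise; eigenvalue spectra record clamped negative
  mass.
* The Li–Ji estimator's floor function is discontinuous at integers; a
  $10^{-9}$ guard keeps eigenvalues that are integral up to rounding on
  the intended side.

## Known limitations

* Quantitative traits only — no binary-trait (logistic) tests, kinship or
  mixed-model adjustment, or small-sample moment corrections.
* The exact-vs-approximate threshold forms differ by the constant factor
  $-\ln(1-\alpha)/\alpha$ ($\approx 2.6\%$ at $\alpha = 0.05$) at any
  $m_e$; all printed comparisons use the approximate (Bonferroni-style)
  form.
* The extrapolation assumes uniform variant density across the genome and
  carries no confidence interval, for the dependence reason above.
* Desk-scale SKAT correlation matrices carry the $r/N$ floor discussed
  earlier; conclusions about banding should be drawn at realistic $N$.
* At small $N$ with very rare cutoffs, the burden score is strongly
  skewed and the $F$ test's far tail is slightly heavy, so the empirical
  threshold can come out *more* stringent than Bonferroni (implied
  $m_e > m$). The pipeline absorbs this honestly — its threshold still
  controls FWER for that test family — and
  `extrapolate_genomewide()` warns when it happens. At
  cohort-scale $N$ the effect disappears.
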