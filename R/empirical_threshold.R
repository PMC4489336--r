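# The simulate -> section -> percentile -> regress -> extrapolate pipeline.
#
# The chromosome's tests are partitioned into S contiguous sections of
# (nearly) equal test count; per section and replicate the minimum P-value
# is taken; its 5th percentile across replicates estimates the significance
# threshold alpha_c controlling FWER at 5% within that section.  Averaging
# -log10 thresholds over same-size sections gives one point per section
# size; regressing those points on the Bonferroni scale -log10(0.05/m) and
# evaluating the fit at the genome-equivalent test count extrapolates the
# genome-wide threshold.

#' Partition m tests into S contiguous, nearly equal sections
#'
#' The first `m %% S` sections contain `ceiling(m/S)` tests, the remainder
#' `floor(m/S)`, so sizes differ by at most one and contiguity in test
#' order (hence genomic order) is preserved.
#'
#' @param m number of tests.
#' @param S number of sections (`1 <= S <= m`).
#' @return object of class `section_scheme`: list with `n_sections`,
#'   `sizes`, `assignment` (section id per test), `m`, `nominal_size`
#'   (`m / S`).
#' @export
partition_sections <- function(m, S) {
  m <- assert_scalar_count(m, "m")
  S <- assert_scalar_count(S, "S")
  if (S > m) stop_winsig("more sections than tests", "winsig_bad_argument")
  base <- floor(m / S)
  extra <- m %% S
  sizes <- rep(base, S)
  if (extra > 0) sizes[seq_len(extra)] <- base + 1
  structure(list(n_sections = S, sizes = sizes,
                 assignment = rep(seq_len(S), times = sizes),
                 m = m, nominal_size = m / S),
            class = "section_scheme")
}

#' Per-section, per-replicate minimum P-values
#'
#' Sections are defined over the store's window tests (or over all tests
#' if the store holds a single kind).  Single-marker tests are assigned to
#' the section whose window block genomically contains them, so the
#' `"single"` and `"combined"` classes use the same genomic pieces as the
#' `"windows"` class.
#'
#' @param store a `pvalue_store`.
#' @param scheme a [partition_sections()] scheme over the store's window
#'   tests (or all tests when only one kind is present).
#' @param test_class `"windows"`, `"single"`, or `"combined"`.
#' @return `S x R` matrix of minima; sections with no test of the
#'   requested class are `NA` rows (flagged, excluded downstream).
#' @export
section_min_p <- function(store, scheme,
                          test_class = c("windows", "single", "combined")) {
  test_class <- match.arg(test_class)
  is_win <- store$kind == "window"
  anchor <- if (any(is_win)) which(is_win) else seq_along(store$kind)
  if (scheme$m != length(anchor))
    stop_winsig("scheme size does not match the store's anchor tests",
                "winsig_bad_argument")
  S <- scheme$n_sections
  R <- store$n_replicates

  if (test_class %in% c("windows", "combined") && any(is_win)) {
    win_min <- group_colmins(store$p[anchor, , drop = FALSE],
                             scheme$assignment, S)
  } else win_min <- NULL
  if (test_class %in% c("single", "combined")) {
    sng <- which(store$kind == "single")
    if (length(sng) == 0L && test_class == "single")
      stop_winsig("store has no single-marker tests", "winsig_degenerate")
    if (length(sng) > 0L) {
      # genomic boundaries: first anchor position of each section
      bound <- store$position[anchor][match(seq_len(S), scheme$assignment)]
      sec_of <- pmin(pmax(findInterval(store$position[sng], bound), 1L), S)
      sng_min <- group_colmins(store$p[sng, , drop = FALSE], sec_of, S)
    } else sng_min <- NULL
  } else sng_min <- NULL

  out <- switch(test_class,
    windows = win_min,
    single = sng_min,
    combined = if (is.null(sng_min)) win_min else pmin(win_min, sng_min,
                                                       na.rm = TRUE))
  out[!is.finite(out)] <- NA_real_
  out
}

# Column-wise minima by row group without per-cell R calls: for each group
# transpose once and use max.col on the negated block.
group_colmins <- function(p, groups, n_groups) {
  R <- ncol(p)
  out <- matrix(NA_real_, n_groups, R)
  for (s in seq_len(n_groups)) {
    idx <- which(groups == s)
    if (length(idx) == 0L) next
    block <- p[idx, , drop = FALSE]
    if (anyNA(block)) block[is.na(block)] <- Inf
    if (length(idx) == 1L) {
      out[s, ] <- block
    } else {
      tb <- t(block)
      out[s, ] <- tb[cbind(seq_len(R),
                           max.col(-tb, ties.method = "first"))]
    }
  }
  out
}

#' Empirical per-section significance threshold
#'
#' Nearest-rank percentile of the replicate minima: with R replicates the
#' threshold is the `ceiling(percentile/100 * R)`-th smallest minimum.
#' This is the empirical estimate of the per-test level controlling FWER
#' at `percentile`% within the section.
#'
#' @param minima `S x R` matrix from [section_min_p()].
#' @param percentile percentile of the minima (default 5).
#' @return length-`S` vector of thresholds (`NA` for flagged sections).
#' @export
empirical_alpha <- function(minima, percentile = 5) {
  minima <- as.matrix(minima)
  R <- ncol(minima)
  if (R == 0L) stop_winsig("zero replicates", "winsig_bad_argument")
  if (R < 20)
    warning("fewer than 20 replicates: the ", percentile,
            "th percentile is degenerate")
  k <- max(1L, ceiling(percentile / 100 * R))
  apply(minima, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NA_real_)
    sort(v, partial = min(k, length(v)))[min(k, length(v))]
  })
}

#' Collapse per-section thresholds into one point per section size
#'
#' @param thresholds list of per-section threshold vectors, one per
#'   sectioning scheme.
#' @param schemes list of the matching [partition_sections()] schemes.
#' @param alpha FWER being controlled (default 0.05).
#' @return data.frame of threshold points: `x = -log10(alpha/m_bar)` with
#'   `m_bar` the nominal section test count, `y` = mean over sections of
#'   `-log10(threshold)`, `sd` across sections, `n_sections_averaged`.
#' @export
aggregate_points <- function(thresholds, schemes, alpha = 0.05) {
  stopifnot(length(thresholds) == length(schemes))
  rows <- lapply(seq_along(schemes), function(i) {
    thr <- thresholds[[i]]
    thr <- thr[!is.na(thr)]
    if (length(thr) == 0L) return(NULL)
    y <- -log10(thr)
    data.frame(x = -log10(alpha / schemes[[i]]$nominal_size),
               y = mean(y),
               sd = if (length(y) > 1) sd(y) else 0,
               n_sections_averaged = length(y),
               m_bar = schemes[[i]]$nominal_size)
  })
  do.call(rbind, rows)
}

#' Extrapolate the genome-wide significance threshold
#'
#' Ordinary least squares of `y` on `x` over the threshold points, then
#' evaluation at `x* = -log10(alpha/(R_ratio * m_max))`, the Bonferroni
#' abscissa of the genome-equivalent number of tests.  The predicted
#' threshold is `alpha_c = 10^-y*` and the implied genome-wide effective
#' number of independent tests is `alpha / alpha_c`.
#'
#' @param points data.frame from [aggregate_points()].
#' @param R_ratio genome-to-region length ratio (>= 1); 1 evaluates the fit
#'   at the full analysed region itself.
#' @param m_max total number of tests in the analysed region.
#' @param alpha FWER (default 0.05).
#' @return object of class `threshold_prediction`: list with `b0`, `b1`,
#'   `x_star`, `y_star`, `alpha_c`, `m_e_genomewide`, `R_ratio`, `m_max`,
#'   `points`.
#' @export
extrapolate_genomewide <- function(points, R_ratio, m_max, alpha = 0.05) {
  if (nrow(points) < 3)
    stop_winsig("need at least 3 threshold points", "winsig_bad_argument")
  if (R_ratio < 1)
    stop_winsig("R_ratio must be >= 1", "winsig_bad_argument")
  if (length(unique(points$x)) < 2)
    stop_winsig("degenerate (collinear) points", "winsig_degenerate")
  fit <- lm(y ~ x, data = points)
  b <- coef(fit)
  x_star <- -log10(alpha / (R_ratio * m_max))
  y_star <- unname(b[1] + b[2] * x_star)
  if (alpha / 10^(-y_star) > R_ratio * m_max)
    warning("implied m_e exceeds the actual test count; the test family ",
            "is anti-conservative at this scale (e.g. skewed burden ",
            "scores at small n), not merely correlated")
  structure(list(b0 = unname(b[1]), b1 = unname(b[2]),
                 x_star = x_star, y_star = y_star,
                 alpha_c = 10^(-y_star),
                 m_e_genomewide = alpha / 10^(-y_star),
                 R_ratio = R_ratio, m_max = m_max, alpha = alpha,
                 points = points),
            class = "threshold_prediction")
}

#' @export
print.threshold_prediction <- function(x, ...) {
  cat(sprintf(
    "<threshold_prediction> y = %.4f + %.4f x; alpha_c = %.3g (m_e = %s)\n",
    x$b0, x$b1, x$alpha_c, format(round(x$m_e_genomewide), big.mark = ",")))
  invisible(x)
}

#' Default section-count series for a region with m tests
#'
#' Powers of two from the largest `S` keeping at least ~72 tests per
#' section (the smallest section size used at chromosome scale, scaled
#' down proportionally for smaller regions) down to `S = 1`.  A floor of
#' `S = 8` (capped at `m/2`) guarantees enough points for the regression
#' on small synthetic regions.
#'
#' @param m number of tests.
#' @return decreasing integer vector of section counts.
#' @export
default_section_series <- function(m) {
  s_max <- max(8, 2^max(0, floor(log2(m / 72))))
  s_max <- min(s_max, 2^max(0, floor(log2(m / 2))))
  rev(2^(0:log2(s_max)))
}

#' Run the sectioning pipeline on a P-value store
#'
#' Convenience driver: for each section count in `section_series`,
#' partitions, takes minima, extracts the 5th-percentile threshold,
#' aggregates to points, and extrapolates.
#'
#' @inheritParams section_min_p
#' @inheritParams extrapolate_genomewide
#' @param section_series decreasing vector of section counts (default
#'   [default_section_series()] on the class's anchor test count).
#' @param percentile percentile defining the empirical threshold.
#' @return a `threshold_prediction`.
#' @export
estimate_threshold <- function(store, test_class = "windows",
                               section_series = NULL, R_ratio = 1,
                               percentile = 5, alpha = 0.05) {
  is_win <- store$kind == "window"
  m_anchor <- if (any(is_win)) sum(is_win) else length(store$kind)
  m_max <- switch(test_class,
                  windows = m_anchor,
                  single = sum(store$kind == "single"),
                  combined = length(store$kind))
  section_series <- section_series %||% default_section_series(m_anchor)
  schemes <- lapply(section_series, function(S)
    partition_sections(m_anchor, S))
  thresholds <- lapply(schemes, function(sch)
    empirical_alpha(section_min_p(store, sch, test_class), percentile))
  points <- aggregate_points(thresholds, schemes, alpha)
  # combined/single classes test more/fewer than the anchor count per
  # section; x is recomputed on the class's own total for extrapolation
  if (test_class != "windows") {
    scale_f <- m_max / m_anchor
    points$x <- points$x + log10(scale_f)
    points$m_bar <- points$m_bar * scale_f
  }
  extrapolate_genomewide(points, R_ratio, m_max, alpha)
}
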