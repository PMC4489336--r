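# Eigenvalue-based estimators of the effective number of independent
# tests, and conversion of m_e to a per-test significance threshold.

#' Eigenvalue spectrum of a test-statistic correlation matrix
#'
#' @param corr symmetric matrix with unit diagonal (typically a
#'   [band_to_matrix()] completion).
#' @return object of class `spectrum`: list with `eigenvalues`
#'   (descending, small banding-induced negatives clamped to zero, clamped
#'   mass recorded in `clamped`) and `m`.
#' @export
spectrum_of <- function(corr) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) ||
      max(abs(corr - t(corr))) > 1e-8)
    stop_winsig("correlation matrix must be symmetric", "winsig_bad_argument")
  if (max(abs(diag(corr) - 1)) > 1e-6)
    stop_winsig("correlation matrix must have unit diagonal",
                "winsig_bad_argument")
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  clamped <- -sum(ev[ev < 0])
  structure(list(eigenvalues = pmax(ev, 0), m = nrow(corr),
                 clamped = clamped),
            class = "spectrum")
}

check_spectrum <- function(s) {
  if (!inherits(s, "spectrum") || length(s$eigenvalues) == 0L)
    stop_winsig("empty or invalid spectrum", "winsig_bad_argument")
}

new_me <- function(me, method, m) {
  structure(list(m_e = min(max(me, 1), m), method = method, m = m),
            class = "me_estimate")
}

#' Effective number of independent tests (Li & Ji estimator)
#'
#' `m_e = sum_i [ I(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ]`:
#' each eigenvalue contributes its fractional part plus a full unit when it
#' reaches one.
#'
#' @param s a [spectrum_of()] result.
#' @return an `me_estimate` (list with `m_e`, `method`, `m`).
#' @export
me_li_ji <- function(s) {
  check_spectrum(s)
  lam <- s$eigenvalues
  # the floor makes the formula discontinuous at integers; a 1e-9 guard
  # keeps eigenvalues that are integers up to rounding on the right side
  fl <- floor(lam + 1e-9)
  new_me(sum((lam >= 1 - 1e-9) + pmax(lam - fl, 0)), "li_ji", s$m)
}

#' Effective number of independent tests (Li et al. estimator)
#'
#' `m_e = m - sum_i I(lambda_i > 1)(lambda_i - 1)`: the test count reduced
#' by the excess variance of eigenvalues above one.  Gives estimates
#' slightly smaller than [me_li_ji()].
#'
#' @inheritParams me_li_ji
#' @return an `me_estimate`.
#' @export
me_li_et_al <- function(s) {
  check_spectrum(s)
  lam <- s$eigenvalues
  new_me(s$m - sum(pmax(lam - 1, 0)), "li_et_al", s$m)
}

#' Per-test significance threshold from an effective test count
#'
#' @param m_e effective number of independent tests (scalar or
#'   `me_estimate`).
#' @param alpha family-wise error rate to control (default 0.05).
#' @param form `"exact"`: `1 - (1 - alpha)^(1/m_e)`; `"approx"`:
#'   `alpha / m_e` (indistinguishable for large `m_e`).
#' @return the per-test level `alpha_c`.
#' @export
significance_threshold <- function(m_e, alpha = 0.05,
                                   form = c("exact", "approx")) {
  form <- match.arg(form)
  if (inherits(m_e, "me_estimate")) m_e <- m_e$m_e
  if (m_e < 1) stop_winsig("m_e must be >= 1", "winsig_bad_argument")
  if (alpha <= 0 || alpha >= 1)
    stop_winsig("alpha must be in (0, 1)", "winsig_bad_argument")
  switch(form,
         exact = 1 - (1 - alpha)^(1 / m_e),
         approx = alpha / m_e)
}

#' Mean effective-test thresholds for nested region sizes
#'
#' For each requested section size (in windows), splits the band's windows
#' into disjoint consecutive blocks of that size, computes both
#' eigenvalue-based `m_e` estimates per block from the band-completed
#' correlation matrix, and averages `-log10(alpha/m_e)` across blocks --
#' the data behind the correlation-based threshold curves.  Sizes are
#' capped at 2,000 windows per matrix (dense eigendecompositions become
#' impractical beyond that); larger regions are handled by the simulation
#' pipeline instead.
#'
#' @param cb a [build_correlation_band()] result.
#' @param sizes vector of section sizes in windows.
#' @param alpha FWER (default 0.05).
#' @param max_size eigendecomposition cap (default 2000).
#' @return data.frame with one row per size: `m`, mean `m_e` by method,
#'   mean `-log10` thresholds (`thr_li_ji`, `thr_li_et_al`) and the
#'   Bonferroni reference `thr_bonferroni`, plus `n_blocks`.
#' @export
section_me_table <- function(cb, sizes, alpha = 0.05, max_size = 2000) {
  sizes <- sort(unique(sizes))
  if (any(sizes > max_size)) {
    warning("sizes above the ", max_size, "-window cap dropped")
    sizes <- sizes[sizes <= max_size]
  }
  sizes <- sort(unique(pmin(sizes, cb$n_windows)))
  rows <- lapply(sizes, function(sz) {
    n_blk <- cb$n_windows %/% sz
    me1 <- me2 <- numeric(n_blk)
    for (b in seq_len(n_blk)) {
      win <- ((b - 1) * sz + 1):(b * sz)
      s <- spectrum_of(band_to_matrix(cb, win))
      me1[b] <- me_li_ji(s)$m_e
      me2[b] <- me_li_et_al(s)$m_e
    }
    data.frame(m = sz,
               me_li_ji = mean(me1), me_li_et_al = mean(me2),
               thr_li_ji = mean(-log10(alpha / me1)),
               thr_li_et_al = mean(-log10(alpha / me2)),
               thr_bonferroni = -log10(alpha / sz),
               n_blocks = n_blk)
  })
  do.call(rbind, rows)
}
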