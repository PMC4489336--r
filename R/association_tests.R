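# Single-marker F tests, burden, SKAT and SKAT-O window tests.
#
# All tests share one null model (intercept-only by default).  The burden
# test regresses the phenotype on the window's minor-allele count sum; SKAT
# is the quadratic form Q = e' K e in the weighted centred-genotype kernel
# K = (GW)(GW)'; SKAT-O optimises over convex combinations of the two
# kernels on a rho grid.

#' Variant weights for window kernels
#'
#' @param maf per-variant minor-allele frequencies.
#' @param kind `"beta_1_25"` (SKAT convention: `dbeta(maf, 1, 25)`),
#'   `"flat"`, or `"custom"`.
#' @param weights numeric weights when `kind = "custom"`.
#' @return object of class `weight_scheme` (list with `kind`, `w`).
#' @export
weight_scheme <- function(maf, kind = c("beta_1_25", "flat", "custom"),
                          weights = NULL) {
  kind <- match.arg(kind)
  w <- switch(kind,
    beta_1_25 = stats::dbeta(pmin(pmax(maf, 1e-12), 1), 1, 25),
    flat = rep(1, length(maf)),
    custom = {
      if (is.null(weights) || length(weights) != length(maf))
        stop_winsig("custom weights must match the number of variants",
                    "winsig_bad_argument")
      weights
    })
  if (any(!is.finite(w)) || any(w < 0) || all(w == 0))
    stop_winsig("weights must be finite, non-negative, not all zero",
                "winsig_bad_argument")
  structure(list(kind = kind, w = w), class = "weight_scheme")
}

# Shared score-F machinery: F test of a single regressor x added to the
# null design, F = (x'Pe)^2/(x'Px) / (RSS_1 / (n - d - 1)).  For the
# intercept-only null this is the F_{1, N-2} simple-linear-regression test.
score_f_pvalue <- function(x, nm) {
  xp <- drop(nm$project(x))
  sxx <- sum(xp^2)
  if (sxx < .Machine$double.eps * nm$n)
    stop_winsig("regressor is constant after projection: test undefined",
                "winsig_degenerate")
  e <- nm$residuals
  ess <- sum(xp * e)^2 / sxx
  df2 <- nm$df_resid - 1
  rss <- max(sum(e^2) - ess, 0)
  if (rss == 0) return(2e-16)  # perfect fit; below representable F tail
  f <- ess * df2 / rss
  pf(f, 1, df2, lower.tail = FALSE)
}

#' Single-marker association test
#'
#' Linear regression of the phenotype on a variant's minor-allele dosage;
#' with the default intercept-only null this yields the `F_{1, N-2}` test.
#'
#' @param dosage length-`N` dosage vector (must be polymorphic).
#' @param null_model a [fit_null_model()] object for the same phenotype.
#' @return the P-value.
#' @export
single_marker_test <- function(dosage, null_model) {
  score_f_pvalue(dosage, null_model)
}

new_window_result <- function(statistic, p, kind, window_id, method = NA) {
  structure(list(statistic = statistic, p_value = p, kind = kind,
                 window_id = window_id, method = method),
            class = "window_test_result")
}

#' Burden test of a rare-variant window
#'
#' The burden score is the row sum of the window genotype submatrix (total
#' minor-allele count per individual); the test is the same F test as
#' [single_marker_test()] applied to that score.
#'
#' @param G_w `N x k` window genotype submatrix.
#' @param null_model a [fit_null_model()] object.
#' @param window_id identifier carried into the result.
#' @return a `window_test_result` (`statistic` is the explained sum of
#'   squares of the score regression).
#' @export
burden_test <- function(G_w, null_model, window_id = NA) {
  x <- rowSums(as.matrix(G_w))
  p <- score_f_pvalue(x, null_model)
  xp <- drop(null_model$project(x))
  stat <- sum(xp * null_model$residuals)^2 / sum(xp^2)
  new_window_result(stat, p, "burden", window_id)
}

#' SKAT test of a rare-variant window
#'
#' `Q = e' K e` with `K = (G W)(G W)'`, `G` centred per column, `e` the
#' null-model residuals.  The P-value is the upper tail of the
#' mixture-of-chi-squares law with weights `sigma2 * eig(P K P)`, computed
#' by [quad_form_pvalue()].
#'
#' @inheritParams burden_test
#' @param weights a [weight_scheme()] for the window's variants.
#' @return a `window_test_result` with the method used for the tail
#'   probability (`davies` or `liu`) in `$method`.
#' @export
skat_test <- function(G_w, weights, null_model, window_id = NA) {
  Z <- skat_factor(G_w, weights, null_model)
  if (max(abs(Z)) < 1e-10 * max(1, abs(G_w)))
    stop_winsig("all-zero kernel: degenerate window", "winsig_degenerate")
  q <- sum(crossprod(Z, null_model$residuals)^2)
  lam <- pmax(eigen(crossprod(Z), symmetric = TRUE, only.values = TRUE)$values, 0)
  p <- quad_form_pvalue(null_model$sigma2 * lam, q)
  new_window_result(q, as.numeric(p), "skat", window_id,
                    method = attr(p, "method"))
}

# Projected weighted genotype factor Zc = P (Gc W); the kernel is Zc Zc'.
skat_factor <- function(G_w, weights, null_model) {
  G_w <- as.matrix(G_w)
  if (!inherits(weights, "weight_scheme"))
    stop_winsig("weights must be a weight_scheme", "winsig_bad_argument")
  if (length(weights$w) != ncol(G_w))
    stop_winsig("weight scheme does not match window width",
                "winsig_bad_argument")
  null_model$project(sweep(G_w, 2, weights$w, `*`))
}

#' SKAT-O: optimal combination of SKAT and burden kernels
#'
#' Evaluates `Q_rho = (1 - rho) Q_skat + rho Q_burden-kernel` over a rho
#' grid, takes the minimum of the per-rho P-values, and converts it to an
#' overall P-value through the one-dimensional integral of the cited
#' optimal-test construction (conditioning on the common burden-direction
#' chi-square).  `rho_grid = 0` reduces to [skat_test()]; `rho_grid = 1`
#' reduces to the quadratic-form P-value of the weighted burden kernel.
#'
#' @inheritParams skat_test
#' @param rho_grid increasing values in `[0, 1]`.
#' @return a `window_test_result`; `$statistic` is the minimum per-rho
#'   P-value (the optimised functional), `$method` records the rho at
#'   which it was attained.
#' @export
skato_test <- function(G_w, weights, null_model,
                       rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                       window_id = NA) {
  if (length(rho_grid) == 0L || is.unsorted(rho_grid) ||
      any(rho_grid < 0 | rho_grid > 1))
    stop_winsig("rho_grid must be sorted within [0, 1]", "winsig_bad_argument")
  Z <- skat_factor(G_w, weights, null_model)
  if (max(abs(Z)) < 1e-10 * max(1, abs(G_w)))
    stop_winsig("all-zero kernel: degenerate window", "winsig_degenerate")
  k <- ncol(Z)
  e <- null_model$residuals
  s2 <- null_model$sigma2
  zte <- drop(crossprod(Z, e))
  q_skat <- sum(zte^2)
  q_burd <- sum(zte)^2
  ZtZ <- crossprod(Z)

  p_rho <- numeric(length(rho_grid))
  lam_rho <- vector("list", length(rho_grid))
  for (i in seq_along(rho_grid)) {
    rho <- rho_grid[i]
    q <- (1 - rho) * q_skat + rho * q_burd
    Rh <- cs_sqrt(k, rho)
    lam <- pmax(eigen(Rh %*% ZtZ %*% Rh, symmetric = TRUE,
                      only.values = TRUE)$values, 0) * s2
    lam_rho[[i]] <- lam
    p_rho[i] <- as.numeric(quad_form_pvalue(lam, q))
  }
  t_min <- min(p_rho)
  rho_min <- rho_grid[which.min(p_rho)]
  if (length(rho_grid) == 1L)
    return(new_window_result(t_min, p_rho[1],
                             if (rho_grid == 0) "skato" else "skato",
                             window_id, method = sprintf("rho=%g", rho_grid)))

  p <- skato_combine(Z, s2, rho_grid, p_rho, lam_rho)
  # hard validity bounds for a minimum-P combination
  p <- min(max(p, t_min), min(1, t_min * length(rho_grid)))
  new_window_result(t_min, p, "skato", window_id,
                    method = sprintf("rho=%g", rho_min))
}

# Square root of the compound-symmetry matrix (1-rho) I + rho 11'.
cs_sqrt <- function(k, rho) {
  a <- sqrt(1 - rho)
  b <- (sqrt(1 - rho + k * rho) - a) / k
  diag(a, k) + matrix(b, k, k)
}

# Overall P-value for min_rho p_rho, conditioning on the chi-square of the
# burden direction (Lee et al. construction).  All quantities in
# sigma^2-scaled units via Zt = sqrt(s2) * Z.
skato_combine <- function(Z, s2, rho_grid, p_rho, lam_rho) {
  Zt <- Z * sqrt(s2)
  k <- ncol(Zt)
  zbar <- rowMeans(Zt)
  zb2 <- sum(zbar^2)
  if (zb2 < .Machine$double.eps) return(min(p_rho) * length(rho_grid))
  cof <- drop(crossprod(zbar, Zt)) / zb2
  Z1 <- outer(zbar, cof)           # projection of columns onto zbar
  Z2 <- Zt - Z1
  lam <- eigen(crossprod(Z2), symmetric = TRUE, only.values = TRUE)$values
  lam <- lam[lam > 1e-10 * max(lam, 1e-300)]
  if (length(lam) == 0L) return(min(p_rho) * length(rho_grid))
  mu_q <- sum(lam)
  var_remain <- 4 * sum(crossprod(Z1) * crossprod(Z2))
  var_q <- 2 * sum(lam^2) + var_remain
  tau <- (k^2 * rho_grid + sum(cof^2) * (1 - rho_grid)) * zb2

  rho_c <- pmin(rho_grid, 0.999)   # cap rho = 1 inside the integrand
  t_min <- min(p_rho)
  qmin <- vapply(seq_along(rho_grid), function(i)
    liu_quantile(lam_rho[[i]], t_min), numeric(1))

  sd_ratio <- sqrt(max(var_q - var_remain, 0)) / sqrt(var_q)
  # beyond ~100 sd the kappa survival is far below any accuracy target;
  # treat it as zero rather than stretching the inversion grid
  far <- mu_q + 100 * sqrt(var_q)
  grid <- imhof_grid(lam, q_max = far, tol = 1e-5)
  surv_fun <- if (is.null(grid)) {
    function(qq) vapply(qq, function(q1) liu_upper(lam, q1), numeric(1))
  } else {
    # vectorised inversion: sin(A - qu/2) split into the two fixed
    # transforms of cos(qu/2) and sin(qu/2)
    a_u <- grid$w * exp(-grid$L) * sin(grid$A)
    b_u <- grid$w * exp(-grid$L) * cos(grid$A)
    function(qq) {
      half_qu <- outer(qq, grid$u / 2)
      drop(0.5 + (cos(half_qu) %*% a_u - sin(half_qu) %*% b_u) / pi)
    }
  }
  # interpolation table of the kappa survival: smooth and monotone, so a
  # dense table is far cheaper than re-inverting at every quadrature node
  q_tab <- seq(0, far, length.out = 256L)
  s_tab <- pmin(pmax(surv_fun(q_tab), 0), 1)
  surv_at <- stats::approxfun(q_tab, s_tab, rule = 2)
  integrand <- function(x) {
    m1 <- Reduce(pmin, lapply(seq_along(tau), function(i)
      (qmin[i] - tau[i] * x) / (1 - rho_c[i])))
    out <- numeric(length(x))
    out[m1 > far] <- dchisq(x[m1 > far], df = 1)
    mid <- which(m1 > 0 & m1 <= far)
    if (length(mid)) {
      m1_st <- (m1[mid] - mu_q) * sd_ratio + mu_q
      out[mid] <- (1 - surv_at(m1_st)) * dchisq(x[mid], df = 1)
    }
    out
  }
  int <- tryCatch(
    integrate(integrand, lower = 0, upper = 40, subdivisions = 200L,
              rel.tol = 1e-5, abs.tol = 1e-9, stop.on.error = FALSE)$value,
    error = function(e) NA_real_)
  if (!is.finite(int)) return(min(p_rho) * length(rho_grid))
  1 - int
}
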