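# Tail probabilities of positive linear combinations of chi-square variables,
# the null law of SKAT-type quadratic-form statistics.
#
# Method: Imhof's characteristic-function inversion
#   P(Q > q) = 1/2 + (1/pi) Int_0^Inf sin(theta(u)) / (u rho(u)) du,
#   theta(u) = (1/2) sum atan(lambda_i u) - q u / 2,
#   rho(u)   = prod (1 + lambda_i^2 u^2)^(1/4),
# integrated over phase-limited Gauss-Legendre panels (each panel spans at
# most ~pi of phase, so an 8-point rule is essentially exact) with a
# rolling truncation bound: past u, 1/(u rho(u)) decays at least like
# u^(-1 - j/2) with j = #{i : lambda_i u >= 1}, giving
# tail(u) <= 2 / (pi j rho(u)).  A single eigenvalue is an exact
# chi-square.  Integration stops when the bound drops below the tolerance
# or the panel budget is exhausted; the result is kept if the achieved
# bound is still below 1e-4 (few-eigenvalue spectra decay slowly), and
# only otherwise does the Liu et al. moment-matching approximation take
# over.  Absolute accuracy is therefore ~tol, never a relative deep-tail
# guarantee.

#' Upper-tail probability of a weighted sum of chi-square variables
#'
#' Computes `P(sum_i lambda_i X_i > q)` where the `X_i` are independent
#' 1-d.f. chi-square variables -- the asymptotic null distribution of
#' variance-component score statistics such as SKAT's `Q = e' K e`.
#'
#' Eigenvalues smaller than `1e-10` times the largest are truncated to
#' zero before inversion; they carry no probability mass at double
#' precision but destabilise the integrand.  The method actually used is
#' recorded in the `"method"` attribute (`"exact"` for a single
#' chi-square, `"davies"` for the inversion, `"liu"` for the fallback).
#'
#' @param eigenvalues non-negative mixture weights (at least one
#'   positive).
#' @param q observed statistic (scalar).
#' @param tol absolute accuracy target of the inversion.
#' @return upper-tail probability in `(0, 1]` with attribute `"method"`.
#' @export
quad_form_pvalue <- function(eigenvalues, q, tol = 1e-6) {
  if (q <= 0) return(structure(1, method = "exact"))
  lam <- prune_spectrum(eigenvalues)
  if (length(lam) == 1L)
    return(structure(pchisq(q / lam, df = 1, lower.tail = FALSE),
                     method = "exact"))
  grid <- imhof_grid(lam, q_max = q, tol = tol)
  if (is.null(grid))
    return(structure(min(max(liu_upper(lam, q), 2e-16), 1), method = "liu"))
  structure(min(max(imhof_eval(grid, q), 2e-16), 1), method = "davies")
}

prune_spectrum <- function(eigenvalues) {
  if (length(eigenvalues) == 0L || all(!is.finite(eigenvalues)))
    stop_winsig("empty eigenvalue spectrum", "winsig_degenerate")
  lam <- eigenvalues[is.finite(eigenvalues) & eigenvalues > 0]
  if (length(lam) == 0L)
    stop_winsig("all eigenvalues are zero: degenerate quadratic form",
                "winsig_degenerate")
  lam[lam > 1e-10 * max(lam)]
}

# 8-point Gauss-Legendre rule on [0, 1].
gl8 <- local({
  x <- c(-0.9602898564975362, -0.7966664774136267, -0.5255324099163290,
         -0.1834346424956498,  0.1834346424956498,  0.5255324099163290,
          0.7966664774136267,  0.9602898564975362)
  w <- c(0.1012285362903763, 0.2223810344533745, 0.3137066458778873,
         0.3626837833783620, 0.3626837833783620, 0.3137066458778873,
         0.2223810344533745, 0.1012285362903763)
  list(x = (x + 1) / 2, w = w / 2)
})

# Precompute integration nodes for a fixed spectrum, reusable across many
# observed statistics up to q_max: theta(u) = A(u) - q u / 2 depends on q
# only through the linear term, so A(u) and log rho(u) are cached.
# Returns NULL if the truncation point cannot be reached within the panel
# budget.
imhof_grid <- function(lam, q_max, tol = 1e-6, max_panels = 3e5,
                       block = 4096L, tol_hard = 1e-4) {
  h <- 2 * pi / (sum(lam) + max(q_max, sum(lam) * 0.01))
  us <- ws <- As <- Ls <- vector("list", 64L)
  nb <- 0L
  u0 <- 0
  n_panels <- 0L
  bound <- Inf
  b_next <- 64L
  repeat {
    b <- min(b_next, max_panels - n_panels)
    b_next <- min(2L * b_next, block)
    if (b <= 0L) break
    u <- u0 + h * (rep(seq_len(b) - 1L, each = 8L) + gl8$x)
    nb <- nb + 1L
    if (nb > length(us)) {  # grow
      length(us) <- length(ws) <- length(As) <- length(Ls) <- 2L * nb
    }
    us[[nb]] <- u
    ws[[nb]] <- rep(h * gl8$w, times = b)
    lu <- outer(lam, u)
    As[[nb]] <- 0.5 * colSums(atan(lu))
    Ls[[nb]] <- 0.25 * colSums(log1p(lu^2))
    u0 <- u0 + b * h
    n_panels <- n_panels + b
    j <- sum(lam * u0 >= 1)
    if (j >= 1L) {
      rho <- exp(0.25 * sum(log1p(lam^2 * u0^2)))
      bound <- 2 / (pi * j * rho)
      if (bound < tol / 2) break
    }
  }
  if (bound > tol_hard) return(NULL)
  u <- unlist(us[seq_len(nb)])
  list(u = u,
       w = unlist(ws[seq_len(nb)]) / u,  # fold 1/u into the weight
       A = unlist(As[seq_len(nb)]),
       L = unlist(Ls[seq_len(nb)]),
       q_max = q_max, lam = lam, bound = bound)
}

imhof_eval <- function(grid, q) {
  0.5 + sum(grid$w * sin(grid$A - 0.5 * q * grid$u) * exp(-grid$L)) / pi
}

# Liu, Tang & Zhang (2009) four-moment approximation.
liu_upper <- function(lam, q) {
  c1 <- sum(lam); c2 <- sum(lam^2); c3 <- sum(lam^3); c4 <- sum(lam^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- 1 / s2
    a <- sqrt(l)
  }
  mu_x <- l + delta
  sigma_x <- sqrt(2) * a
  t_star <- (q - c1) / sqrt(2 * c2)
  pchisq(t_star * sigma_x + mu_x, df = l, ncp = delta, lower.tail = FALSE)
}

# Liu-type quantile with matched moments (used for per-rho quantiles in
# the SKAT-O combination).
liu_quantile <- function(lam, prob_upper) {
  c1 <- sum(lam); c2 <- sum(lam^2); c3 <- sum(lam^3); c4 <- sum(lam^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- 1 / s2
    a <- sqrt(l)
  }
  mu_x <- l + delta
  sigma_x <- sqrt(2 * (l + 2 * delta))
  q_x <- qchisq(prob_upper, df = l, ncp = delta, lower.tail = FALSE)
  c1 + (q_x - mu_x) / sigma_x * sqrt(2 * c2)
}

# Batch form used by the window test runner: one grid per eigenvalue set,
# evaluated at many statistics.
quad_form_pvalues <- function(eigenvalues, q, tol = 1e-6) {
  out <- numeric(length(q))
  pos <- q > 0
  out[!pos] <- 1
  if (!any(pos)) return(out)
  lam <- prune_spectrum(eigenvalues)
  if (length(lam) == 1L) {
    out[pos] <- pchisq(q[pos] / lam, df = 1, lower.tail = FALSE)
    return(out)
  }
  grid <- imhof_grid(lam, q_max = max(q[pos]), tol = tol)
  if (is.null(grid)) {
    out[pos] <- vapply(q[pos], function(qq)
      min(max(liu_upper(lam, qq), 2e-16), 1), numeric(1))
  } else {
    out[pos] <- vapply(q[pos], function(qq)
      min(max(imhof_eval(grid, qq), 2e-16), 1), numeric(1))
  }
  out
}
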