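# Analytic null correlations between window test statistics, from
# genotypes alone.
#
# For SKAT statistics Q_i = e' K_i e with e ~ N(0, sigma^2 P) the
# covariance of Gaussian quadratic forms gives
#   corr(Q_i, Q_j) = tr(A_i A_j) / sqrt(tr(A_i^2) tr(A_j^2)),
# with A_k = P K_k P.  For burden statistics (squared score of the
# projected allele-count sum x_k) the correlation of the squared scores is
# the squared correlation of the underlying Gaussian scores,
#   corr(T_i, T_j) = (x_i' P x_j)^2 / ((x_i' P x_i)(x_j' P x_j)).
# Both are free of sigma^2 and of the phenotype.  All computations use the
# N x k factor Zc = P (G W), never an N x N kernel, so cost scales with
# window size.

#' Projection operator of a null design without a phenotype
#'
#' @param n sample size.
#' @param covariates optional covariate matrix (intercept always included).
#' @return list with `project` (closure applying `I - H`) and `n`.
#' @export
null_projection <- function(n, covariates = NULL) {
  X <- cbind(rep(1, n), covariates)
  qrX <- qr(X)
  list(project = function(v) { v <- as.matrix(v); v - qr.fitted(qrX, v) },
       n = n)
}

clamp01 <- function(r, tol = 1e-8) {
  if (r < -tol)
    stop_winsig("analytic correlation below zero beyond tolerance",
                "winsig_numeric")
  min(max(r, 0), 1)
}

#' Analytic null correlation between two SKAT statistics
#'
#' @param G_i,G_j window genotype submatrices from the same cohort.
#' @param weights_i,weights_j [weight_scheme()]s for each window.
#' @param proj a [null_projection()] (or a fitted `null_model`).
#' @return correlation in `[0, 1]`.
#' @export
skat_null_correlation <- function(G_i, G_j, weights_i, weights_j, proj) {
  Zi <- proj$project(sweep(as.matrix(G_i), 2, weights_i$w, `*`))
  Zj <- proj$project(sweep(as.matrix(G_j), 2, weights_j$w, `*`))
  ti <- sum(crossprod(Zi)^2)
  tj <- sum(crossprod(Zj)^2)
  if (ti == 0 || tj == 0)
    stop_winsig("zero kernel in a window", "winsig_degenerate")
  clamp01(sum(crossprod(Zi, Zj)^2) / sqrt(ti * tj))
}

#' Analytic null correlation between two burden statistics
#'
#' @param x_i,x_j burden scores (window row sums) for the two windows.
#' @param proj a [null_projection()].
#' @return correlation in `[0, 1]`.
#' @export
burden_null_correlation <- function(x_i, x_j, proj) {
  xi <- drop(proj$project(x_i))
  xj <- drop(proj$project(x_j))
  si <- sum(xi^2); sj <- sum(xj^2)
  if (si < .Machine$double.eps || sj < .Machine$double.eps)
    stop_winsig("constant projected burden score", "winsig_degenerate")
  clamp01(sum(xi * xj)^2 / (si * sj))
}

#' Banded inter-window null correlation matrix
#'
#' Computes `corr(T_i, T_j)` for all window pairs with `|i - j| <= band`;
#' correlations beyond the band are treated as zero downstream (published
#' heat maps show correlations above 0.1 rarely extending past ~1,000
#' windows, the default band).
#'
#' @param g a [genotype_matrix()].
#' @param ws a [build_windows()] tiling.
#' @param part the matching [split_by_maf()] partition.
#' @param kind `"skat"` or `"burden"`.
#' @param weights_kind weight scheme for SKAT kernels.
#' @param band half-bandwidth in windows (`>= 1`; clipped with a warning
#'   if it exceeds the window count).
#' @return object of class `correlation_band`: list with `i`, `j`, `value`
#'   (upper-triangle band entries, `i < j`), `n_windows`, `band`, `kind`.
#' @export
build_correlation_band <- function(g, ws, part, kind = c("skat", "burden"),
                                   weights_kind = "beta_1_25", band = 1000) {
  kind <- match.arg(kind)
  if (band < 1) stop_winsig("band must be >= 1", "winsig_bad_argument")
  m <- n_windows(ws)
  if (band >= m) {
    warning("band exceeds window count; clipped to ", m - 1)
    band <- m - 1
  }
  proj <- null_projection(n_individuals(g))
  if (kind == "skat") {
    fac <- lapply(seq_len(m), function(w) {
      idx <- window_variant_idx(ws, part, w)
      wsch <- weight_scheme(g$maf[idx], weights_kind)
      proj$project(sweep(g$dosages[, idx, drop = FALSE], 2, wsch$w, `*`))
    })
    self <- vapply(fac, function(Z) sum(crossprod(Z)^2), numeric(1))
    pair_fun <- function(i, j)
      sum(crossprod(fac[[i]], fac[[j]])^2) / sqrt(self[i] * self[j])
  } else {
    xs <- proj$project(burden_scores(g, part, ws))
    self <- colSums(xs^2)
    pair_fun <- function(i, j)
      sum(xs[, i] * xs[, j])^2 / (self[i] * self[j])
  }
  if (any(self == 0))
    stop_winsig("zero kernel / constant burden score in a window",
                "winsig_degenerate")
  ii <- jj <- vv <- vector("list", m)
  for (w in seq_len(m - 1)) {
    js <- (w + 1):min(w + band, m)
    ii[[w]] <- rep.int(w, length(js))
    jj[[w]] <- js
    vv[[w]] <- vapply(js, function(j) clamp01(pair_fun(w, j)), numeric(1))
  }
  structure(list(i = unlist(ii), j = unlist(jj), value = unlist(vv),
                 n_windows = m, band = band, kind = kind),
            class = "correlation_band")
}

#' @export
print.correlation_band <- function(x, ...) {
  cat(sprintf(
    "<correlation_band> %s, %d windows, half-bandwidth %d, mean off-diag %.4f\n",
    x$kind, x$n_windows, x$band, mean(x$value)))
  invisible(x)
}

#' Complete a correlation band to a dense symmetric matrix
#'
#' Entries beyond the band are zero; the diagonal is one.  Banding can
#' break exact positive semidefiniteness -- downstream eigen analysis
#' clamps small negative eigenvalues.
#'
#' @param cb a `correlation_band`.
#' @param windows optional window subset (consecutive indices) to
#'   materialise; default all.
#' @return dense symmetric matrix.
#' @export
band_to_matrix <- function(cb, windows = NULL) {
  windows <- windows %||% seq_len(cb$n_windows)
  m <- length(windows)
  M <- diag(1, m)
  keep <- cb$i %in% windows & cb$j %in% windows
  if (any(keep)) {
    i <- match(cb$i[keep], windows)
    j <- match(cb$j[keep], windows)
    M[cbind(i, j)] <- cb$value[keep]
    M[cbind(j, i)] <- cb$value[keep]
  }
  M
}

#' Mean off-diagonal correlation within the band
#' @param cb a `correlation_band`.
#' @param max_lag restrict to pairs with `j - i <= max_lag` (default: the
#'   full band).
#' @return scalar mean.
#' @export
mean_band_correlation <- function(cb, max_lag = cb$band) {
  mean(cb$value[cb$j - cb$i <= max_lag])
}

#' Persist / load a correlation band as TSV triples with a JSON header
#' @param cb a `correlation_band`.
#' @param path file path.
#' @return `path` invisibly / a `correlation_band`.
#' @export
write_correlation_band <- function(cb, path) {
  hdr <- jsonlite::toJSON(cb[c("kind", "band", "n_windows")],
                          auto_unbox = TRUE)
  writeLines(paste0("# ", hdr), path)
  data.table::fwrite(data.table::data.table(i = cb$i, j = cb$j,
                                            corr = cb$value),
                     path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_correlation_band
#' @export
read_correlation_band <- function(path) {
  hdr <- jsonlite::fromJSON(sub("^# ", "", readLines(path, n = 1)))
  df <- data.table::fread(path, sep = "\t", skip = 1, data.table = FALSE)
  structure(list(i = df$i, j = df$j, value = df$corr,
                 n_windows = hdr$n_windows, band = hdr$band,
                 kind = hdr$kind),
            class = "correlation_band")
}
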