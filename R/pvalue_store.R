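# Batch execution of tests across replicates, producing a PValueStore:
# a tests x replicates matrix of null P-values with per-test metadata
# (window-based vs single-marker, genomic anchor position).

#' Run association tests for many null phenotype replicates
#'
#' Window tests are run on the rare variants of `part` tiled by `ws`;
#' single-marker tests on the common variants.  Burden and single-marker
#' F tests are fully vectorised; SKAT evaluates one quadratic-form tail
#' probability per window x replicate; SKAT-O is supported but markedly
#' slower (one combination integral per window x replicate).
#'
#' @param g a [genotype_matrix()].
#' @param part a [split_by_maf()] partition of `g`.
#' @param ws a [build_windows()] tiling of `part`'s rare variants.
#' @param pheno a `phenotype_set` (`N x R` values).
#' @param tests subset of `c("single", "burden", "skat", "skato")`.
#' @param weights_kind weight scheme for SKAT/SKAT-O kernels.
#' @param covariates optional covariates for the null model.
#' @return object of class `pvalue_store`: list with `p` (tests x R
#'   matrix), `kind` (`"window"`/`"single"`), `stat` (test name),
#'   `position` (genomic anchor: first variant of a window, or the variant
#'   position), `test_id`.
#' @export
run_tests <- function(g, part, ws, pheno,
                      tests = c("single", "burden", "skat"),
                      weights_kind = "beta_1_25", covariates = NULL) {
  tests <- match.arg(tests, c("single", "burden", "skat", "skato"),
                     several.ok = TRUE)
  Y <- pheno$values
  n <- nrow(Y)
  if (n != n_individuals(g))
    stop_winsig("phenotype rows must match individuals", "winsig_bad_argument")
  nm0 <- fit_null_model(Y[, 1], covariates)
  E <- nm0$project(Y)                      # residual matrix, n x R
  syy <- colSums(E^2)
  df2 <- nm0$df_resid - 1

  blocks <- list()
  win_pos <- g$positions[part$rare_idx[ws$windows$start_rank + 1]]

  for (tt in tests) {
    if (tt == "single") {
      if (length(part$common_idx) == 0L) next
      D <- g$dosages[, part$common_idx, drop = FALSE]
      p <- batch_score_f(nm0$project(D), E, syy, df2)
      blocks[[tt]] <- list(p = p, kind = "single", stat = "single",
                           position = g$positions[part$common_idx],
                           id = paste0("snp_", part$common_idx))
    } else if (tt == "burden") {
      X <- burden_scores(g, part, ws)
      p <- batch_score_f(nm0$project(X), E, syy, df2)
      blocks[[tt]] <- list(p = p, kind = "window", stat = "burden",
                           position = win_pos,
                           id = paste0("burden_w", ws$windows$window_id))
    } else {
      p <- batch_window_quadform(g, part, ws, E, nm0, weights_kind,
                                 skato = (tt == "skato"))
      blocks[[tt]] <- list(p = p, kind = "window", stat = tt,
                           position = win_pos,
                           id = paste0(tt, "_w", ws$windows$window_id))
    }
  }
  if (length(blocks) == 0L)
    stop_winsig("no tests produced any results", "winsig_degenerate")
  structure(list(p = do.call(rbind, lapply(blocks, `[[`, "p")),
                 kind = unlist(lapply(blocks, function(b)
                   rep(b$kind, nrow(b$p)))),
                 stat = unlist(lapply(blocks, function(b)
                   rep(b$stat, nrow(b$p)))),
                 position = unlist(lapply(blocks, `[[`, "position")),
                 test_id = unlist(lapply(blocks, `[[`, "id")),
                 n_replicates = ncol(Y)),
            class = "pvalue_store")
}

#' @export
print.pvalue_store <- function(x, ...) {
  cat(sprintf("<pvalue_store> %d tests x %d replicates (%s)\n",
              nrow(x$p), x$n_replicates,
              paste(unique(x$stat), collapse = ", ")))
  invisible(x)
}

# Window burden scores as an n x m matrix.
burden_scores <- function(g, part, ws) {
  m <- n_windows(ws)
  X <- matrix(0, nrow = n_individuals(g), ncol = m)
  for (w in seq_len(m)) {
    idx <- window_variant_idx(ws, part, w)
    X[, w] <- rowSums(g$dosages[, idx, drop = FALSE])
  }
  X
}

# Vectorised score-F P-values: Xp (n x m, projected regressors), E (n x R
# projected phenotypes).  Returns m x R.  Columns of Xp that are constant
# after projection yield NA rows (degenerate tests, flagged not faked).
batch_score_f <- function(Xp, E, syy, df2) {
  sxx <- colSums(Xp^2)
  a <- crossprod(Xp, E)                    # m x R score products
  ess <- a^2 / sxx                         # explained SS
  f <- ess * df2 / pmax(outer(rep(1, nrow(ess)), syy) - ess, 1e-300)
  p <- pf(f, 1, df2, lower.tail = FALSE)
  p[sxx < .Machine$double.eps * nrow(Xp), ] <- NA_real_
  p
}

batch_window_quadform <- function(g, part, ws, E, nm0, weights_kind, skato) {
  m <- n_windows(ws)
  R <- ncol(E)
  s2 <- colSums(E^2) / nm0$df_resid
  p <- matrix(NA_real_, m, R)
  for (w in seq_len(m)) {
    idx <- window_variant_idx(ws, part, w)
    G_w <- g$dosages[, idx, drop = FALSE]
    wsch <- weight_scheme(g$maf[idx], weights_kind)
    Z <- nm0$project(sweep(G_w, 2, wsch$w, `*`))
    if (max(abs(Z)) == 0) next
    if (!skato) {
      lam <- pmax(eigen(crossprod(Z), symmetric = TRUE,
                        only.values = TRUE)$values, 0)
      q <- colSums(crossprod(Z, E)^2)
      p[w, ] <- quad_form_pvalues(lam, q / s2)
    } else {
      for (r in seq_len(R)) {
        nm_r <- nm0
        nm_r$residuals <- E[, r]
        nm_r$sigma2 <- s2[r]
        p[w, r] <- tryCatch(
          skato_test(G_w, wsch, nm_r, window_id = w)$p_value,
          winsig_error = function(e) NA_real_)
      }
    }
  }
  p
}

#' Write a P-value store as a tall TSV (replicate, test_id, kind, p)
#' @param store a `pvalue_store`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pvalue_store <- function(store, path) {
  R <- store$n_replicates
  data.table::fwrite(
    data.table::data.table(
      replicate = rep(seq_len(R), each = nrow(store$p)),
      test_id = rep(store$test_id, R),
      kind = rep(store$stat, R),
      p = as.vector(store$p)),
    path, sep = "\t")
  invisible(path)
}
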