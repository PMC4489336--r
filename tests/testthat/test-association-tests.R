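# Single-marker, burden, SKAT and SKAT-O tests.

make_window <- function(n = 60, k = 8, seed = 100, maf = 0.1) {
  set.seed(seed)
  G <- matrix(rbinom(n * k, 2, maf), n, k)
  while (any(colSums(G) == 0)) G <- matrix(rbinom(n * k, 2, maf), n, k)
  G
}

test_that("single-marker F test matches the regression t-squared oracle", {
  x <- c(0, 1, 2, 0, 1, 1)
  y <- c(0.3, 1.2, 2.4, -0.1, 0.8, 1.5)
  nm <- fit_null_model(y)
  p <- single_marker_test(x, nm)
  # independent oracle: lm slope t-test (F = t^2 on 1, N-2 dof)
  p_lm <- summary(lm(y ~ x))$coefficients["x", "Pr(>|t|)"]
  expect_equal(p, p_lm, tolerance = 1e-12)
})

test_that("perfect fit and orthogonal phenotype hit the documented extremes", {
  x <- c(0, 1, 2, 1, 0, 2)
  y_perf <- scale(x, scale = FALSE)[, 1]
  expect_lt(single_marker_test(x, fit_null_model(y_perf)), 1e-15)
  y_orth <- c(1, -1, 0, 1, -1, 0)  # orthogonal to centred x and to 1
  stopifnot(abs(sum(y_orth * scale(x, scale = FALSE))) < 1e-12)
  expect_equal(single_marker_test(x, fit_null_model(y_orth)), 1)
  expect_error(single_marker_test(rep(1, 6), fit_null_model(rnorm(6))),
               class = "winsig_degenerate")
})

test_that("a one-variant window's burden test equals the single-marker test", {
  G <- make_window(n = 40, k = 1, seed = 2)
  set.seed(3); y <- rnorm(40)
  nm <- fit_null_model(y)
  expect_equal(burden_test(G, nm)$p_value,
               single_marker_test(G[, 1], nm), tolerance = 1e-12)
})

test_that("SKAT Q equals the brute-force kernel quadratic form", {
  G <- matrix(c(0, 1, 2, 0,
                1, 0, 1, 2), ncol = 2)
  y <- c(0.5, -1, 2, 0.25)
  nm <- fit_null_model(y)
  w <- weight_scheme(c(0.2, 0.3), "flat")
  res <- skat_test(G, w, nm)
  Gc <- scale(G, scale = FALSE)
  K <- (Gc %*% diag(2)) %*% t(Gc %*% diag(2))
  e <- y - mean(y)
  expect_equal(res$statistic, drop(t(e) %*% K %*% e), tolerance = 1e-10)
})

test_that("zero residuals give Q = 0, p = 1; empty kernels error", {
  G <- make_window(n = 30, k = 4, seed = 5)
  nm <- fit_null_model(rep(2.5, 30))
  w <- weight_scheme(colMeans(G) / 2, "beta_1_25")
  res <- skat_test(G, w, nm)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(skat_test(matrix(1, 30, 2), weight_scheme(c(.1, .1), "flat"),
                         fit_null_model(rnorm(30))),
               class = "winsig_degenerate")
})

test_that("all tests are invariant to phenotype location shifts", {
  G <- make_window()
  set.seed(7); y <- rnorm(60)
  w <- weight_scheme(colMeans(G) / 2, "beta_1_25")
  nm1 <- fit_null_model(y)
  nm2 <- fit_null_model(y + 100)
  expect_equal(single_marker_test(G[, 1], nm1),
               single_marker_test(G[, 1], nm2), tolerance = 1e-9)
  expect_equal(burden_test(G, nm1)$p_value, burden_test(G, nm2)$p_value,
               tolerance = 1e-9)
  expect_equal(skat_test(G, w, nm1)$p_value, skat_test(G, w, nm2)$p_value,
               tolerance = 1e-9)
  expect_equal(skato_test(G, w, nm1)$p_value, skato_test(G, w, nm2)$p_value,
               tolerance = 1e-6)
})

test_that("SKAT is invariant to variant order; burden to joint permutation", {
  G <- make_window()
  set.seed(8); y <- rnorm(60)
  nm <- fit_null_model(y)
  maf <- colMeans(G) / 2
  perm <- sample(ncol(G))
  expect_equal(skat_test(G, weight_scheme(maf, "beta_1_25"), nm)$p_value,
               skat_test(G[, perm], weight_scheme(maf[perm], "beta_1_25"),
                         nm)$p_value, tolerance = 1e-9)
  ip <- sample(nrow(G))
  expect_equal(burden_test(G, nm)$p_value,
               burden_test(G[ip, ], fit_null_model(y[ip]))$p_value,
               tolerance = 1e-9)
})

test_that("single-variant SKAT and burden p-values agree in rank", {
  G <- make_window(n = 50, k = 1, seed = 9, maf = 0.3)
  w <- weight_scheme(colMeans(G) / 2, "flat")
  set.seed(10)
  ps <- t(replicate(300, {
    nm <- fit_null_model(rnorm(50))
    c(skat_test(G, w, nm)$p_value, burden_test(G, nm)$p_value)
  }))
  expect_gt(cor(ps[, 1], ps[, 2], method = "spearman"), 0.9999)
})

test_that("SKAT-O reduces to SKAT at rho 0 and the burden kernel at rho 1", {
  G <- make_window(n = 80, k = 10, seed = 12, maf = 0.05)
  maf <- colMeans(G) / 2
  w <- weight_scheme(maf, "beta_1_25")
  set.seed(13); y <- rnorm(80)
  nm <- fit_null_model(y)
  expect_equal(skato_test(G, w, nm, rho_grid = 0)$p_value,
               skat_test(G, w, nm)$p_value, tolerance = 1e-12)
  # rho = 1: quadratic form of the weighted burden kernel
  Z <- winsig:::skat_factor(G, w, nm)
  zb <- rowSums(Z)
  p_direct <- as.numeric(quad_form_pvalue(sum(zb^2) * nm$sigma2,
                                          sum(zb * nm$residuals)^2))
  expect_equal(skato_test(G, w, nm, rho_grid = 1)$p_value, p_direct,
               tolerance = 1e-10)
  # combined p respects the min-p bounds
  full <- skato_test(G, w, nm)
  p_all <- c(skat_test(G, w, nm)$p_value, p_direct)
  expect_gte(full$p_value, full$statistic - 1e-12)
  expect_lte(full$p_value, min(1, full$statistic * 8) + 1e-12)
  expect_lte(full$statistic, min(p_all) + 1e-12)
})

test_that("burden type-I error is nominal at alpha 0.05", {
  g <- band_cohort()
  part <- split_by_maf(g, 0.01)
  ws <- build_windows(length(part$rare_idx))
  ph <- simulate_null_phenotypes(n_individuals(g), 20, seed = 55)
  store <- run_tests(g, part, ws, ph, tests = "burden")
  pb <- as.vector(store$p)
  expect_gt(length(pb), 2000)
  expect_lt(abs(mean(pb < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / length(pb)) + 0.005)
})

test_that("the batch runner agrees with scalar tests and labels tests", {
  g <- band_cohort()
  part <- split_by_maf(g, 0.01)
  ws <- build_windows(length(part$rare_idx))
  ph <- simulate_null_phenotypes(n_individuals(g), 3, seed = 60)
  store <- run_tests(g, part, ws, ph, tests = c("single", "burden", "skat"))
  expect_setequal(unique(store$stat), c("single", "burden", "skat"))
  expect_equal(sum(store$stat == "single"), length(part$common_idx))
  expect_equal(sum(store$stat == "burden"), n_windows(ws))

  nm <- fit_null_model(ph$values[, 2])
  w <- 5
  idx <- window_variant_idx(ws, part, w)
  direct_b <- burden_test(g$dosages[, idx], nm)$p_value
  row_b <- which(store$stat == "burden")[w]
  expect_equal(store$p[row_b, 2], direct_b, tolerance = 1e-9)
  direct_s <- skat_test(g$dosages[, idx],
                        weight_scheme(g$maf[idx], "beta_1_25"), nm)$p_value
  row_s <- which(store$stat == "skat")[w]
  expect_equal(store$p[row_s, 2], direct_s, tolerance = 1e-5)

  path <- tempfile(fileext = ".tsv")
  write_pvalue_store(store, path)
  tall <- data.table::fread(path)
  expect_equal(nrow(tall), nrow(store$p) * 3)
})
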