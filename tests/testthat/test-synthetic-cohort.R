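# Synthetic cohort generator: frequency spectrum, LD structure, phenotypes.

test_that("realised founder spectrum matches its closed-form bookkeeping", {
  spec <- cohort_spec(n_sites = 50000, seed = 42)
  fo <- generate_founders(spec)
  target <- spectrum_fraction_below(spec, 0.005)
  expect_gt(target, 0.6)   # the stated world is rare-skewed
  expect_lt(abs(mean(fo$freq < 0.005) - target), 0.03)
  expect_true(all(diff(fo$positions) >= 1))
  expect_true(all(fo$freq > 0 & fo$freq <= 0.5))
})

test_that("two founder haplotypes at frequency 0.5 keep both alleles everywhere", {
  spec <- cohort_spec(n_individuals = 20, n_sites = 200,
                      n_founder_haplotypes = 2, seed = 3)
  fo <- generate_founders(spec)
  expect_true(all(colSums(fo$haplotypes) == 1))
})

test_that("the generator is seed-deterministic", {
  spec <- cohort_spec(n_individuals = 30, n_sites = 150,
                      n_founder_haplotypes = 40, seed = 11)
  expect_identical(generate_founders(spec)$haplotypes,
                   generate_founders(spec)$haplotypes)
  g1 <- sample_cohort(generate_founders(spec), spec)
  g2 <- sample_cohort(generate_founders(spec), spec)
  expect_identical(g1$dosages, g2$dosages)
  spec2 <- cohort_spec(n_individuals = 30, n_sites = 150,
                       n_founder_haplotypes = 40, seed = 12)
  expect_false(identical(sample_cohort(generate_founders(spec2), spec2)$dosages,
                         g1$dosages))
})

test_that("switch rate 1 gives essentially independent adjacent sites", {
  spec <- cohort_spec(n_individuals = 2000, n_sites = 120,
                      n_founder_haplotypes = 100, copy_switch_rate = 1,
                      maf_spectrum_exponent = 1, seed = 21)
  g <- sample_cohort(generate_founders(spec), spec)
  keep <- which(g$maf > 0.05)
  r <- vapply(seq_len(length(keep) - 1), function(k)
    cor(g$dosages[, keep[k]], g$dosages[, keep[k + 1]]), numeric(1))
  expect_lt(mean(abs(r)), 0.05)
})

test_that("switch rate near 0 copies intact founder haplotypes", {
  spec <- cohort_spec(n_individuals = 30, n_sites = 50,
                      n_founder_haplotypes = 10, copy_switch_rate = 1e-9,
                      maf_spectrum_exponent = 1, seed = 8)
  fo <- generate_founders(spec)
  g <- sample_cohort(fo, spec, drop_monomorphic = FALSE)
  H <- fo$haplotypes
  sums <- lapply(seq_len(nrow(H)), function(i)
    lapply(i:nrow(H), function(j) H[i, ] + H[j, ]))
  sums <- do.call(rbind, unlist(sums, recursive = FALSE))
  found <- apply(g$dosages, 1, function(row)
    any(colSums(abs(t(sums) - row)) == 0))
  expect_true(all(found))
})

test_that("mean dosage tracks twice the founder frequency", {
  # switch rate 1 makes every haplotype-site an independent founder draw,
  # so the mean dosage per site is exactly Binomial(2n, f)/n
  spec <- cohort_spec(n_individuals = 400, n_sites = 600,
                      n_founder_haplotypes = 100, copy_switch_rate = 1,
                      seed = 13)
  fo <- generate_founders(spec)
  g <- sample_cohort(fo, spec, drop_monomorphic = FALSE)
  f <- fo$freq
  se <- sqrt(2 * f * (1 - f) / spec$n_individuals)
  dev <- abs(colMeans(g$dosages) - 2 * f)
  expect_gt(mean(dev <= 4 * se), 0.99)
})

test_that("LD decays with inter-site distance", {
  # flatter spectrum so common variants are plentiful; switch rate 0.01
  # puts the LD correlation length at ~50 sites (~4 kb here)
  spec <- cohort_spec(n_individuals = 300, n_sites = 2000,
                      n_founder_haplotypes = 100, copy_switch_rate = 0.01,
                      maf_spectrum_exponent = 1, seed = 71)
  g <- sample_cohort(generate_founders(spec), spec)
  idx <- which(g$maf >= 0.1)
  D <- g$dosages[, idx]
  r2 <- cor(D)^2
  dist <- abs(outer(g$positions[idx], g$positions[idx], "-"))
  ut <- upper.tri(r2)
  bins <- cut(dist[ut], c(0, 1000, 5000, 20000, Inf))
  means <- tapply(r2[ut], bins, mean)
  ses <- tapply(r2[ut], bins, function(v) sd(v) / sqrt(length(v)))
  # non-increasing across bins up to Monte-Carlo error, strict overall
  expect_true(all(diff(means) < 2 * (head(ses, -1) + tail(ses, -1))))
  expect_gt(means[1], means[3] + 2 * (ses[1] + ses[3]))
})

test_that("null phenotypes are standard normal, reproducible, seed-sensitive", {
  ph <- simulate_null_phenotypes(1e5, 1, seed = 4)
  expect_lt(abs(mean(ph$values)), 4 / sqrt(1e5))
  expect_lt(abs(var(as.vector(ph$values)) - 1), 0.05)
  expect_identical(simulate_null_phenotypes(50, 3, seed = 9)$values,
                   simulate_null_phenotypes(50, 3, seed = 9)$values)
  expect_false(identical(simulate_null_phenotypes(50, 3, seed = 9)$values,
                         simulate_null_phenotypes(50, 3, seed = 10)$values))
})

test_that("null P-values are uniform for score tests on synthetic cohorts", {
  g <- band_cohort()
  part <- split_by_maf(g, 0.01)
  ws <- build_windows(length(part$rare_idx))
  ph <- simulate_null_phenotypes(n_individuals(g), 30, seed = 77)
  store <- run_tests(g, part, ws, ph, tests = c("single", "burden", "skat"))
  pb <- as.vector(store$p[store$stat %in% c("single", "burden"), ])
  expect_gt(length(pb), 2000)
  ks <- suppressWarnings(ks.test(pb, "punif"))
  # 1% critical value ~ 1.63/sqrt(n); statistics, not p, because of ties
  expect_lt(unname(ks$statistic), 1.63 / sqrt(length(pb)))
  # SKAT may be conservative at very rare MAF: one-sided check
  psk <- as.vector(store$p[store$stat == "skat", ])
  expect_lt(mean(psk < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / length(psk)))
})

test_that("phenotype and cohort-spec files round-trip", {
  ph <- simulate_null_phenotypes(25, 2, seed = 6)
  path <- tempfile(fileext = ".tsv")
  write_phenotypes(ph, sprintf("I%02d", 1:25), path)
  ph2 <- read_phenotypes(path)
  expect_equal(unname(ph2$values), unname(ph$values), tolerance = 1e-12)
  expect_equal(ph2$sample_ids[1], "I01")

  spec <- cohort_spec(n_individuals = 77, n_sites = 1234, seed = 5)
  cfg <- tempfile(fileext = ".cfg")
  write_cohort_spec(spec, cfg)
  spec2 <- read_cohort_spec(cfg)
  expect_equal(spec2$n_individuals, 77)
  expect_equal(spec2$n_sites, 1234)
  expect_equal(spec2$copy_switch_rate, spec$copy_switch_rate)
})

test_that("spec validation rejects degenerate parameters", {
  expect_error(cohort_spec(copy_switch_rate = 0), class = "winsig_bad_argument")
  expect_error(cohort_spec(n_individuals = 0), class = "winsig_bad_argument")
  expect_error(cohort_spec(maf_spectrum_exponent = -1),
               class = "winsig_bad_argument")
})
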